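corrected_enrichment <- function(ct, sample, compartment, metabolite, index) {
  r <- ct[ct$sample_id == sample & ct$compartment == compartment &
            ct$metabolite == metabolite, ]
  r$fraction[match(index, r$isotopolog_index)]
}

test_that("generators are pure functions of preset and seed", {
  p <- arm_preset("wt")
  expect_identical(simulate_deuterium_lactate_arm(p, seed = 11),
                   simulate_deuterium_lactate_arm(p, seed = 11))
  expect_false(identical(simulate_deuterium_lactate_arm(p, seed = 11),
                         simulate_deuterium_lactate_arm(p, seed = 12)))
  expect_identical(simulate_glucose_infusion_arm(p, seed = 11),
                   simulate_glucose_infusion_arm(p, seed = 11))
  expect_identical(simulate_lactate_c13_arm(p, seed = 11),
                   simulate_lactate_c13_arm(p, seed = 11))
  expect_identical(simulate_metabolome(seed = 11), simulate_metabolome(seed = 11))
  o1 <- simulate_ocr_plate(c(basal = 1, state3 = 2, state4o = 3, maximal = 4,
                             nonmito = 5), noise_sd = 1, seed = 11)
  o2 <- simulate_ocr_plate(c(basal = 1, state3 = 2, state4o = 3, maximal = 4,
                             nonmito = 5), noise_sd = 1, seed = 11)
  expect_identical(o1, o2)
})

test_that("deuterium arm at zero noise reproduces the preset exactly", {
  for (lab in c("wt", "mfn12")) {
    p <- arm_preset(lab)
    pt <- simulate_deuterium_lactate_arm(p, n_animals = 2, noise_sd = 0,
                                         seed = 1)
    est <- estimate_import_fractions(pt)
    expect_equal(est$summary$mean_import, p$f_import, tolerance = 1e-8)
    # pyruvate and alanine carry no deuterium after oxidation
    ct <- correct_peak_table(pt, tracer_element = "H", n_label = 1)
    expect_lt(corrected_enrichment(ct, sprintf("%s_01", lab), "tissue",
                                   "pyruvate", 1), 1e-10)
    expect_lt(corrected_enrichment(ct, sprintf("%s_01", lab), "tissue",
                                   "alanine", 1), 1e-10)
    # malate picks up the transferred label
    e_mal <- corrected_enrichment(ct, sprintf("%s_01", lab), "tissue",
                                  "malate", 1)
    e_lac <- corrected_enrichment(ct, sprintf("%s_01", lab), "tissue",
                                  "lactate", 1)
    expect_equal(e_mal, p$malate_transfer * e_lac, tolerance = 1e-8)
  }
})

test_that("glucose arm reproduces dilution algebra at zero noise", {
  # d = 0: no glycogen dilution, tissue 3PG m+3 equals plasma glucose m+6
  p0 <- arm_preset("wt", glycogen_dilution = 0)
  pt <- simulate_glucose_infusion_arm(p0, n_animals = 1, noise_sd = 0, seed = 1)
  ct <- correct_peak_table(pt, tracer_element = "C")
  e_g6 <- corrected_enrichment(ct, "wt_01", "plasma", "glucose", 6)
  e_3pg <- corrected_enrichment(ct, "wt_01", "tissue", "3pg", 3)
  expect_equal(e_3pg, e_g6, tolerance = 1e-8)
  # f_import = 1: tissue lactate m+3 equals plasma lactate m+3
  p1 <- arm_preset("wt", f_import = 1)
  pt1 <- simulate_glucose_infusion_arm(p1, n_animals = 1, noise_sd = 0, seed = 1)
  ct1 <- correct_peak_table(pt1, tracer_element = "C")
  expect_equal(corrected_enrichment(ct1, "wt_01", "tissue", "lactate", 3),
               corrected_enrichment(ct1, "wt_01", "plasma", "lactate", 3),
               tolerance = 1e-8)
})

test_that("mutant glucose arm shows higher normalized TCA labeling and a
           higher lactate/pyruvate enrichment ratio than wild type", {
  vals <- lapply(c("wt", "mfn12"), function(lab) {
    pt <- simulate_glucose_infusion_arm(arm_preset(lab), n_animals = 1,
                                        noise_sd = 0, seed = 1)
    ct <- correct_peak_table(pt, tracer_element = "C")
    id <- sprintf("%s_01", lab)
    g6 <- corrected_enrichment(ct, id, "tissue", "glucose", 6)
    list(cit_norm = corrected_enrichment(ct, id, "tissue", "citrate", 2) / g6,
         lac_pyr = corrected_enrichment(ct, id, "tissue", "lactate", 3) /
           corrected_enrichment(ct, id, "tissue", "pyruvate", 3))
  })
  expect_gt(vals[[2]]$cit_norm, vals[[1]]$cit_norm)
  expect_gt(vals[[2]]$lac_pyr, vals[[1]]$lac_pyr)
})

test_that("lactate 13C arm reproduces direct/indirect pathway directions", {
  # gluconeogenesis off: no m+3 reaches 3PG
  pg <- arm_preset("wt", gluconeogenesis = 0)
  pt <- simulate_lactate_c13_arm(pg, n_animals = 1, noise_sd = 0, seed = 1)
  ct <- correct_peak_table(pt, tracer_element = "C")
  expect_lt(corrected_enrichment(ct, "wt_01", "tissue", "3pg", 3), 1e-10)
  # mutant: lower 3PG/PEP labeling, higher pyruvate normalized to PEP
  vals <- lapply(c("wt", "mfn12"), function(lab) {
    pt <- simulate_lactate_c13_arm(arm_preset(lab), n_animals = 1,
                                   noise_sd = 0, seed = 1)
    ct <- correct_peak_table(pt, tracer_element = "C")
    id <- sprintf("%s_01", lab)
    pep <- corrected_enrichment(ct, id, "tissue", "pep", 3)
    list(pg3 = corrected_enrichment(ct, id, "tissue", "3pg", 3),
         pyr_norm = normalized_enrichment(
           corrected_enrichment(ct, id, "tissue", "pyruvate", 0:3),
           corrected_enrichment(ct, id, "tissue", "pep", 0:3), 3, 3))
  })
  expect_lt(vals[[2]]$pg3, vals[[1]]$pg3)
  expect_gt(vals[[2]]$pyr_norm, vals[[1]]$pyr_norm)
})

test_that("forward convolution and correction are exact inverses in the
           full simulate-correct loop", {
  p <- arm_preset("mfn12_azd3965")
  pt <- simulate_glucose_infusion_arm(p, n_animals = 2, noise_sd = 0, seed = 4)
  ct <- correct_peak_table(pt, tracer_element = "C")
  # every corrected fraction is a clean two-channel MID: M0 + Mk = 1
  sums <- tapply(ct$fraction,
                 paste(ct$sample_id, ct$compartment, ct$metabolite),
                 sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("ex vivo and OCR simulators close the loop with their estimators", {
  tc <- simulate_exvivo_timecourse(2, noise_sd = 0, tissue_weight_mg = 20)
  expect_equal(production_rate(tc)$rate, 0.1, tolerance = 1e-10)
  expect_equal(production_rate(simulate_exvivo_timecourse(0, noise_sd = 0,
                                                          tissue_weight_mg = 20))$slope,
               0, tolerance = 1e-12)
  expect_error(simulate_exvivo_timecourse(-1), ">= 0")
  # mean recovered slope unbiased to < 1% over 200 replicates
  slopes <- vapply(1:200, function(s) {
    production_rate(simulate_exvivo_timecourse(2, noise_sd = 5,
                                               tissue_weight_mg = 20,
                                               seed = s))$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 2) / 2, 0.01)

  plate <- simulate_ocr_plate(c(basal = 150, state3 = 300, state4o = 60,
                                maximal = 280, nonmito = 15),
                              blank_level = 0, noise_sd = 0, seed = 1)
  st <- ocr_states(plate$traces, plate$injections)
  expect_equal(respiratory_control_ratio(st$state3, st$state4o), 5.0)
  expect_error(simulate_ocr_plate(c(basal = 1, state3 = 2)), "missing")
})

test_that("metabolome preset controls the truly altered subset", {
  tab <- simulate_metabolome(seed = 2)
  expect_identical(length(unique(tab$feature)), 187L)
  expect_identical(length(unique(tab$feature[tab$altered])), 64L)
  expect_identical(nrow(tab), 187L * 20L)
  expect_error(simulate_metabolome(n_features = 10, n_altered = 11),
               "exceed")
  # null preset: Bonferroni keeps nearly everything non-significant
  null_tab <- simulate_metabolome(effect_sd = 0, seed = 3)
  st <- run_feature_stats(null_tab, method = "multiple_t")
  expect_lte(count_altered(st)$n_significant, 3L)
})

test_that("import-fraction estimates recover every preset arm to 0.03", {
  for (lab in c("wt", "mfn12", "mfn12_hif1a_dpa", "mfn12_azd3965")) {
    p <- arm_preset(lab)
    means <- vapply(1:20, function(s) {
      pt <- simulate_deuterium_lactate_arm(p, seed = s)
      estimate_import_fractions(pt)$summary$mean_import
    }, numeric(1))
    expect_lt(abs(mean(means) - p$f_import), 0.03)
  }
})
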