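make_flat_plate <- function(sample_level, blank_level) {
  simulate_ocr_plate(state_levels = c(basal = sample_level,
                                      state3 = sample_level,
                                      state4o = sample_level,
                                      maximal = sample_level,
                                      nonmito = sample_level),
                     blank_level = blank_level, noise_sd = 0, seed = 1)
}

test_that("OCR states are blank-subtracted window means", {
  plate <- make_flat_plate(100, 20)
  st <- ocr_states(plate$traces, plate$injections)
  expect_equal(st$basal, 80)
  expect_equal(st$state3, 80)
  expect_equal(st$state4o, 80)
  expect_equal(st$maximal, 80)
  expect_equal(st$nonmito, 80)
  same <- make_flat_plate(55, 55)
  st0 <- ocr_states(same$traces, same$injections)
  expect_true(all(abs(unlist(st0)) < 1e-12))
  # constructed state levels recovered exactly with blank at zero
  plate2 <- simulate_ocr_plate(c(basal = 150, state3 = 300, state4o = 60,
                                 maximal = 280, nonmito = 15),
                               blank_level = 0, noise_sd = 0, seed = 2)
  st2 <- ocr_states(plate2$traces, plate2$injections)
  expect_equal(st2$state3, 300)
  expect_equal(st2$state4o, 60)
})

test_that("OCR states are invariant to adding a constant to all wells", {
  plate <- simulate_ocr_plate(c(basal = 150, state3 = 300, state4o = 60,
                                maximal = 280, nonmito = 15),
                              blank_level = 20, noise_sd = 1.5, seed = 3)
  st <- ocr_states(plate$traces, plate$injections)
  shifted <- plate
  shifted$traces$ocr <- shifted$traces$ocr + 37
  st2 <- ocr_states(shifted$traces, shifted$injections)
  expect_equal(st, st2, tolerance = 1e-12)
})

test_that("OCR state extraction enforces its preconditions", {
  plate <- make_flat_plate(100, 20)
  no_adp <- plate$injections[plate$injections$label != "ADP", ]
  expect_error(ocr_states(plate$traces, no_adp), "ADP")
  dup <- rbind(plate$injections, plate$injections[1, ])
  expect_error(ocr_states(plate$traces, dup), "unique")
  only_samples <- plate$traces[!plate$traces$is_blank, ]
  expect_error(ocr_states(only_samples, plate$injections), "blank")
  # empty window: oligomycin scheduled after the last measurement
  late <- plate$injections
  late$time_min[late$label == "Oligo"] <- max(plate$traces$time_min) + 10
  expect_error(ocr_states(plate$traces, late), "window")
})

test_that("respiratory control ratio divides state 3 by state 4o", {
  expect_equal(respiratory_control_ratio(300, 60), 5.0)
  expect_equal(respiratory_control_ratio(60, 60), 1.0)
  expect_equal(respiratory_control_ratio(0, 60), 0.0)
  expect_error(respiratory_control_ratio(300, 0), "positive")
  expect_error(respiratory_control_ratio(300, -5), "positive")
})

test_that("energy charge spans [0, 1] and is monotone in ATP", {
  expect_equal(energy_charge(0, 0, 7), 1.0)
  expect_equal(energy_charge(3, 0, 0), 0.0)
  expect_equal(energy_charge(1, 1, 1), 0.5)
  expect_error(energy_charge(0, 0, 0), "all-zero")
  expect_error(energy_charge(-1, 1, 1), ">= 0")
  atp <- seq(0, 5, by = 0.25)
  ec <- energy_charge(rep(1, length(atp)), rep(1, length(atp)), atp)
  expect_true(all(diff(ec) > 0))
  expect_true(all(ec >= 0 & ec <= 1))
})

test_that("internal-standard quantification scales by the spike", {
  expect_equal(quantify_internal_standard(1000, 2000, 200), 100)
  expect_equal(quantify_internal_standard(0, 5000, 200), 0)
  expect_equal(quantify_internal_standard(2000, 1000, 200), 400)
  expect_error(quantify_internal_standard(10, 0, 200), "positive")
  expect_error(quantify_internal_standard(-1, 10, 200), ">= 0")
})

test_that("production rate recovers an exact line and reports the fit", {
  tc <- simulate_exvivo_timecourse(rate_nmol_per_min = 2, noise_sd = 0,
                                   tissue_weight_mg = 20, seed = 1)
  pr <- production_rate(tc)
  expect_equal(pr$rate, 0.1, tolerance = 1e-10)
  expect_equal(pr$slope, 2, tolerance = 1e-10)
  expect_equal(pr$r_squared, 1, tolerance = 1e-10)
  flat <- simulate_exvivo_timecourse(0, noise_sd = 0, tissue_weight_mg = 20)
  expect_equal(production_rate(flat)$slope, 0, tolerance = 1e-12)
  expect_error(production_rate(list(points = tc$points[1:2, ],
                                    spike_nmol = 200, tissue_weight_mg = 20)),
               "3 time points")
  expect_error(production_rate(tc$points, tissue_weight_mg = 0), "weight")
})

test_that("noisy slopes fall within their OLS sampling distribution", {
  # known noise SD: the fitted slope should sit within 3 SE of truth in
  # ~99.7% of replicates; allow a small margin on 200 seeds
  times <- c(0, 10, 30, 60, 120, 180)
  sd_noise <- 5
  se_slope <- sd_noise / sqrt(sum((times - mean(times))^2))
  hits <- 0L
  for (s in 1:200) {
    tc <- simulate_exvivo_timecourse(2, noise_sd = sd_noise,
                                     tissue_weight_mg = 20, seed = s)
    if (abs(production_rate(tc)$slope - 2) <= 3 * se_slope) hits <- hits + 1L
  }
  expect_gte(hits, 193L)
})

test_that("ddCt fold changes follow the efficiency-2 model", {
  expect_equal(relative_quantity_ddct(20, 18, 20, 18), 1.0)
  expect_equal(relative_quantity_ddct(19, 18, 20, 18), 2.0)
  expect_equal(relative_quantity_ddct(21, 18, 20, 18), 0.5)
  expect_equal(relative_quantity_ddct(c(19, 21), c(18, 18), 20, 18), c(2, 0.5))
  expect_error(relative_quantity_ddct(NA, 18, 20, 18), "finite")
  expect_error(relative_quantity_ddct(Inf, 18, 20, 18), "finite")
})

test_that("activity slope uses the longest linear prefix, not the global fit", {
  t_all <- 0:59
  exact <- 0.4 - 0.01 * t_all
  expect_equal(linear_activity_slope(exact)$slope, -0.01, tolerance = 1e-12)
  flat <- rep(0.25, 30)
  f <- linear_activity_slope(flat)
  expect_equal(f$slope, 0)
  expect_identical(f$window, 30L)
  # linear for 20 min, then plateau: the longest near-linear prefix wins,
  # recovering the initial rate far better than a global fit would
  y <- c(0.4 - 0.01 * 0:19, rep(0.4 - 0.01 * 19, 40))
  fit <- linear_activity_slope(y)
  global <- lm(y ~ t_all)
  expect_lt(abs(fit$slope - (-0.01)), abs(coef(global)[2] - (-0.01)))
  expect_lt(abs(fit$slope - (-0.01)), 0.0015)
  expect_lt(fit$window, 30)
  expect_gte(fit$r_squared, 0.98)
  expect_error(linear_activity_slope(c(0.1, 0.2, 0.3)), "at least 5")
})

test_that("paired ratios demand matching sample identities", {
  expect_equal(unname(ratio_metric(4, 2)), 2.0)
  expect_equal(unname(ratio_metric(3.3, 3.3)), 1.0)
  ids <- c("a", "b")
  r <- ratio_metric(c(4, 9), c(2, 3), ids = ids, ids_denominator = ids)
  expect_equal(r, c(a = 2, b = 3))
  expect_error(ratio_metric(c(4, 9), c(2, 3), ids = ids,
                            ids_denominator = rev(ids)), "do not match")
  expect_error(ratio_metric(4, 0), "positive")
  expect_error(ratio_metric(c(1, 2), 1), "lengths differ")
})
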