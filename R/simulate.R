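# Synthetic cohort generator: every input the pipeline consumes, with the
# statistical structure the analysis assumes, parameterized by
# genotype/treatment presets.

.arm_labels <- c("wt", "mfn12", "mfn12_hif1a_dpa", "mfn12_azd3965")

# per-arm generative parameters; columns documented in arm_preset()
.arm_table <- data.frame(
  label = .arm_labels,
  f_import = c(0.44, 0.94, 0.53, 0.26),
  glycogen_dilution = c(0.40, 0.10, 0.35, 0.10),
  pyruvate_dilution = c(0.10, 0.50, 0.20, 0.50),
  pdh_contribution = c(0.50, 0.80, 0.60, 0.60),
  glycolytic_transmission = c(0.60, 0.25, 0.50, 0.25),
  malate_transfer = c(0.15, 0.50, 0.20, 0.20),
  seed = c(101L, 102L, 103L, 104L),
  stringsAsFactors = FALSE
)

#' Generative parameters of one genotype/treatment arm
#'
#' Each arm preset fixes the "true" physiology of a simulated infusion
#' cohort. The headline parameter is `f_import`, the true fraction of
#' tissue lactate supplied by circulatory import: 0.44 (wild type), 0.94
#' (mfn1,2 double knockout), 0.53 (mfn1,2 with stabilized Hif1a), 0.26
#' (mfn1,2 under MCT1 inhibition by AZD3965). Steady-state plasma
#' enrichments default to 0.10 (lactate m+1 and m+3) and 0.15 (glucose
#' m+6): infusion-scale values that cancel in every ratio-based estimator.
#' The remaining fields shape the 13C arms: `glycogen_dilution` (fraction
#' of tissue 3PG carbon from unlabeled glycogen; larger in wild type, where
#' glycogenolysis is intact), `pyruvate_dilution` (labeling dilution from
#' 3PG to the pyruvate pool; larger in mutants, whose glycolytic flux is
#' low relative to pyruvate pool turnover), `pdh_contribution` (scaling of
#' TCA m+2 from the effective pyruvate pool), `glycolytic_transmission`
#' (fraction of plasma glucose m+3 labeling transmitted to 3PG in the
#' 13C-lactate arm; reduced in mutants), `malate_transfer` (deuterium
#' transfer from tissue lactate to malate via NADH), and the noise model
#' (`noise_sd_enrichment`, additive Gaussian on true enrichments;
#' `ion_noise_sdlog`, log-normal scale on per-metabolite total ion counts).
#'
#' @param label One of `"wt"`, `"mfn12"`, `"mfn12_hif1a_dpa"`,
#'   `"mfn12_azd3965"`.
#' @param ... Named overrides for any preset field.
#' @return A validated `arm_preset` list.
#' @export
#' @examples
#' arm_preset("wt")$f_import
arm_preset <- function(label = .arm_labels, ...) {
  label <- match.arg(label)
  row <- .arm_table[.arm_table$label == label, ]
  preset <- list(
    label = label,
    f_import = row$f_import,
    plasma_enrichments = c(lactate_m1 = 0.10, glucose_m6 = 0.15,
                           lactate_m3_glc = 0.12, lactate_m3 = 0.10),
    gluconeogenesis = 0.25,
    glycogen_dilution = row$glycogen_dilution,
    pyruvate_dilution = row$pyruvate_dilution,
    pdh_contribution = row$pdh_contribution,
    glycolytic_transmission = row$glycolytic_transmission,
    malate_transfer = row$malate_transfer,
    noise_sd_enrichment = 0.005,
    ion_count_scale = 1e6,
    ion_noise_sdlog = 0.2,
    n_animals = 8L,
    seed = row$seed
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(preset))
  if (length(unknown)) {
    stop("unknown preset field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  preset[names(dots)] <- dots
  validate_arm_preset(preset)
}

#' Validate an arm preset
#'
#' @param preset An `arm_preset` list.
#' @return The preset, classed, or an error.
#' @export
validate_arm_preset <- function(preset) {
  fracs <- c(preset$f_import, preset$plasma_enrichments,
             preset$gluconeogenesis, preset$pyruvate_dilution,
             preset$pdh_contribution, preset$glycolytic_transmission,
             preset$malate_transfer)
  if (any(!is.finite(fracs)) || any(fracs < 0) || any(fracs > 1)) {
    stop("preset fractions must lie in [0, 1]", call. = FALSE)
  }
  if (preset$glycogen_dilution < 0 || preset$glycogen_dilution >= 1) {
    stop("glycogen_dilution must lie in [0, 1)", call. = FALSE)
  }
  if (preset$noise_sd_enrichment < 0 || preset$ion_noise_sdlog < 0) {
    stop("noise parameters must be >= 0", call. = FALSE)
  }
  if (preset$n_animals < 1) stop("n_animals must be >= 1", call. = FALSE)
  class(preset) <- "arm_preset"
  preset
}

#' All four packaged arm presets
#'
#' @return Named list of [arm_preset()] objects.
#' @export
arm_presets <- function() {
  setNames(lapply(.arm_labels, arm_preset), .arm_labels)
}

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

# one-hot true MID: enrichment e at channel `index`, remainder at M0
.true_mid <- function(e, index, n) {
  f <- numeric(n + 1L)
  f[1L] <- 1 - e
  f[index + 1L] <- f[index + 1L] + e
  f
}

# forward-convolve a true MID with natural abundance and scale to ion areas
.observed_areas <- function(true_fracs, M, scale) {
  convolve_mid(true_fracs, M) * scale
}

# assemble peak-table rows for one metabolite block
.peak_rows <- function(sample_id, arm_label, compartment, metabolite, areas) {
  data.frame(sample_id = sample_id, arm_label = arm_label,
             compartment = compartment, metabolite = metabolite,
             isotopolog_index = seq_along(areas) - 1L, area = areas,
             stringsAsFactors = FALSE)
}

# correction matrices for a set of metabolites under one tracer
.arm_matrices <- function(registry, metabolites, tracer_element, n_label) {
  out <- list()
  for (m in metabolites) {
    entry <- .registry_entry(registry, m)
    n <- if (is.null(n_label)) entry$n_tracer_atoms else n_label
    out[[m]] <- list(M = build_na_matrix(entry$fragment_formula,
                                         tracer_element, n,
                                         max_shift = n + 3L),
                     n = n)
  }
  out
}

#' Simulate a [2-2H]lactate infusion arm
#'
#' Per animal: plasma lactate m+1 enrichment is drawn around the preset's
#' steady-state value; tissue lactate m+1 is `f_import` times the animal's
#' realized plasma value (plus noise); malate m+1 receives a
#' `malate_transfer` fraction of the tissue lactate label (deuterium moved
#' via NADH); pyruvate and alanine carry no label, since lactate-to-pyruvate
#' oxidation removes the C2 deuterium. True MIDs are forward-convolved with
#' the same natural-abundance matrices the correction module builds, then
#' scaled to ion counts with per-(sample, metabolite) log-normal variation
#' that leaves each MID intact.
#'
#' @param preset An [arm_preset()].
#' @param n_animals Animals in the arm.
#' @param noise_sd Additive SD on true enrichments.
#' @param seed RNG seed; identical seeds give identical tables.
#' @param registry Metabolite registry supplying fragment formulas.
#' @return A `peak_table` with plasma lactate and tissue lactate, malate,
#'   pyruvate and alanine blocks per animal (shifts 0..4).
#' @export
simulate_deuterium_lactate_arm <- function(preset,
                                           n_animals = preset$n_animals,
                                           noise_sd = preset$noise_sd_enrichment,
                                           seed = preset$seed,
                                           registry = load_registry()) {
  preset <- validate_arm_preset(unclass(preset))
  set.seed(seed)
  mats <- .arm_matrices(registry, c("lactate", "malate", "pyruvate", "alanine"),
                        tracer_element = "H", n_label = 1L)
  rows <- list()
  for (i in seq_len(n_animals)) {
    id <- sprintf("%s_%02d", preset$label, i)
    e_plasma <- .clamp01(preset$plasma_enrichments[["lactate_m1"]] +
                           rnorm(1, 0, noise_sd))
    e_tissue <- .clamp01(preset$f_import * e_plasma + rnorm(1, 0, noise_sd))
    e_malate <- .clamp01(preset$malate_transfer * e_tissue +
                           rnorm(1, 0, noise_sd))
    e_pyr <- .clamp01(0 + rnorm(1, 0, noise_sd))
    e_ala <- .clamp01(0 + rnorm(1, 0, noise_sd))
    block <- function(compartment, metabolite, e) {
      scale <- preset$ion_count_scale *
        rlnorm(1, 0, preset$ion_noise_sdlog * (noise_sd > 0))
      areas <- .observed_areas(.true_mid(e, 1L, mats[[metabolite]]$n),
                               mats[[metabolite]]$M, scale)
      .peak_rows(id, preset$label, compartment, metabolite, areas)
    }
    rows[[length(rows) + 1L]] <- rbind(
      block("plasma", "lactate", e_plasma),
      block("tissue", "lactate", e_tissue),
      block("tissue", "malate", e_malate),
      block("tissue", "pyruvate", e_pyr),
      block("tissue", "alanine", e_ala))
  }
  validate_peak_table(do.call(rbind, rows))
}

#' Simulate a steady-state [U-13C]glucose infusion arm
#'
#' Plasma glucose m+6 sits at the preset enrichment; tissue glucose matches
#' plasma (free exchange); tissue 3PG m+3 is glucose m+6 diluted by
#' glycogenolysis (`1 - glycogen_dilution`); tissue pyruvate m+3 derives
#' from 3PG attenuated by `pyruvate_dilution`; plasma lactate m+3 has its
#' own preset value; tissue lactate m+3 mixes imported plasma lactate with
#' intramuscular pyruvate by `f_import`; citrate m+2 is `pdh_contribution`
#' times the effective pyruvate feeding the TCA cycle (the same
#' import-weighted mixture). Noise and ion scaling as in
#' [simulate_deuterium_lactate_arm()].
#'
#' @inheritParams simulate_deuterium_lactate_arm
#' @return A `peak_table` with plasma glucose/lactate and tissue glucose,
#'   3PG, pyruvate, lactate and citrate blocks per animal.
#' @export
simulate_glucose_infusion_arm <- function(preset,
                                          n_animals = preset$n_animals,
                                          noise_sd = preset$noise_sd_enrichment,
                                          seed = preset$seed,
                                          registry = load_registry()) {
  preset <- validate_arm_preset(unclass(preset))
  set.seed(seed)
  mets <- c("glucose", "3pg", "pyruvate", "lactate", "citrate")
  mats <- .arm_matrices(registry, mets, tracer_element = "C", n_label = NULL)
  rows <- list()
  for (i in seq_len(n_animals)) {
    id <- sprintf("%s_%02d", preset$label, i)
    nz <- function() rnorm(1, 0, noise_sd)
    g6 <- .clamp01(preset$plasma_enrichments[["glucose_m6"]] + nz())
    g6_tis <- .clamp01(g6 + nz())
    pg3 <- .clamp01(g6 * (1 - preset$glycogen_dilution) + nz())
    pyr <- .clamp01((1 - preset$pyruvate_dilution) * pg3 + nz())
    lac_pl <- .clamp01(preset$plasma_enrichments[["lactate_m3_glc"]] + nz())
    lac_tis <- .clamp01(preset$f_import * lac_pl +
                          (1 - preset$f_import) * pyr + nz())
    eff_pyr <- (1 - preset$f_import) * pyr + preset$f_import * lac_tis
    cit <- .clamp01(preset$pdh_contribution * eff_pyr + nz())
    block <- function(compartment, metabolite, e, index) {
      scale <- preset$ion_count_scale *
        rlnorm(1, 0, preset$ion_noise_sdlog * (noise_sd > 0))
      areas <- .observed_areas(.true_mid(e, index, mats[[metabolite]]$n),
                               mats[[metabolite]]$M, scale)
      .peak_rows(id, preset$label, compartment, metabolite, areas)
    }
    rows[[length(rows) + 1L]] <- rbind(
      block("plasma", "glucose", g6, 6L),
      block("plasma", "lactate", lac_pl, 3L),
      block("tissue", "glucose", g6_tis, 6L),
      block("tissue", "3pg", pg3, 3L),
      block("tissue", "pyruvate", pyr, 3L),
      block("tissue", "lactate", lac_tis, 3L),
      block("tissue", "citrate", cit, 2L))
  }
  validate_peak_table(do.call(rbind, rows))
}

#' Simulate a steady-state [U-13C]lactate infusion arm
#'
#' Plasma lactate m+3 sits at the preset enrichment. The indirect pathway
#' runs through hepatic gluconeogenesis: plasma glucose m+3 is
#' `gluconeogenesis` times plasma lactate m+3, and tissue 3PG/PEP m+3
#' receive a `glycolytic_transmission` fraction of that glucose labeling
#' (reduced in mutant presets, whose glycolysis is suppressed). The direct
#' pathway imports labeled lactate: tissue lactate m+3 mixes plasma lactate
#' and glycolytic pyruvate by `f_import`, the measured pyruvate pool mixes
#' the two sources the same way, and citrate m+2 is `pdh_contribution`
#' times that effective pyruvate.
#'
#' @inheritParams simulate_deuterium_lactate_arm
#' @return A `peak_table` with plasma lactate/glucose and tissue 3PG, PEP,
#'   pyruvate, lactate and citrate blocks per animal.
#' @export
simulate_lactate_c13_arm <- function(preset,
                                     n_animals = preset$n_animals,
                                     noise_sd = preset$noise_sd_enrichment,
                                     seed = preset$seed,
                                     registry = load_registry()) {
  preset <- validate_arm_preset(unclass(preset))
  set.seed(seed)
  mets <- c("lactate", "glucose", "3pg", "pep", "pyruvate", "citrate")
  mats <- .arm_matrices(registry, mets, tracer_element = "C", n_label = NULL)
  rows <- list()
  for (i in seq_len(n_animals)) {
    id <- sprintf("%s_%02d", preset$label, i)
    nz <- function() rnorm(1, 0, noise_sd)
    lac_pl <- .clamp01(preset$plasma_enrichments[["lactate_m3"]] + nz())
    glc_pl <- .clamp01(preset$gluconeogenesis * lac_pl + nz())
    pg3 <- .clamp01(glc_pl * preset$glycolytic_transmission + nz())
    pep <- .clamp01(glc_pl * preset$glycolytic_transmission + nz())
    pyr_gly <- (1 - preset$pyruvate_dilution) * pep
    lac_tis <- .clamp01(preset$f_import * lac_pl +
                          (1 - preset$f_import) * pyr_gly + nz())
    pyr_obs <- .clamp01((1 - preset$f_import) * pyr_gly +
                          preset$f_import * lac_tis + nz())
    cit <- .clamp01(preset$pdh_contribution * pyr_obs + nz())
    block <- function(compartment, metabolite, e, index) {
      scale <- preset$ion_count_scale *
        rlnorm(1, 0, preset$ion_noise_sdlog * (noise_sd > 0))
      areas <- .observed_areas(.true_mid(e, index, mats[[metabolite]]$n),
                               mats[[metabolite]]$M, scale)
      .peak_rows(id, preset$label, compartment, metabolite, areas)
    }
    rows[[length(rows) + 1L]] <- rbind(
      block("plasma", "lactate", lac_pl, 3L),
      block("plasma", "glucose", glc_pl, 3L),
      block("tissue", "3pg", pg3, 3L),
      block("tissue", "pep", pep, 3L),
      block("tissue", "pyruvate", pyr_obs, 3L),
      block("tissue", "lactate", lac_tis, 3L),
      block("tissue", "citrate", cit, 2L))
  }
  validate_peak_table(do.call(rbind, rows))
}

#' Simulate an ex vivo glycolysis time course
#'
#' Medium samples at fixed time points, with the target (m+1 lactate) peak
#' area growing so that the amount quantified against the spiked internal
#' standard equals `rate * time` plus Gaussian noise. Standard-peak areas
#' are drawn around a constant; because quantification divides by the
#' realized standard area, standard jitter does not perturb the recovered
#' amounts.
#'
#' @param rate_nmol_per_min True production rate (nmol/min), >= 0.
#' @param spike_nmol Internal standard spike (default 200 nmol).
#' @param times Sampling times in minutes.
#' @param noise_sd SD of additive noise on quantified nanomoles.
#' @param tissue_weight_mg Tissue wet weight carried on the result.
#' @param standard_area Mean standard peak area.
#' @param seed RNG seed.
#' @return List with `points` (data.frame `time_min`, `target_area`,
#'   `standard_area`), `spike_nmol`, `tissue_weight_mg`; accepted directly
#'   by [production_rate()].
#' @export
simulate_exvivo_timecourse <- function(rate_nmol_per_min, spike_nmol = 200,
                                       times = c(0, 10, 30, 60, 120, 180),
                                       noise_sd = 0, tissue_weight_mg = 20,
                                       standard_area = 1e5, seed = 1) {
  if (rate_nmol_per_min < 0) stop("rate must be >= 0", call. = FALSE)
  set.seed(seed)
  # detector floor: quantified amounts cannot produce negative peak areas
  nmol <- pmax(rate_nmol_per_min * times + rnorm(length(times), 0, noise_sd), 0)
  std <- standard_area * rlnorm(length(times), 0, 0.05 * (noise_sd > 0))
  list(points = data.frame(time_min = times,
                           target_area = nmol / spike_nmol * std,
                           standard_area = std),
       spike_nmol = spike_nmol, tissue_weight_mg = tissue_weight_mg)
}

#' Simulate an OCR plate run
#'
#' Piecewise-constant oxygen consumption traces for sample and blank wells
#' over the standard injection sequence (ADP, oligomycin, CCCP, antimycin
#' A), with `cycles_per_state` measurement cycles per segment and optional
#' Gaussian noise. Blank wells sit at `blank_level` throughout.
#'
#' @param state_levels Named vector with `basal`, `state3`, `state4o`,
#'   `maximal`, `nonmito` true OCR levels (before blank subtraction).
#' @param blank_level OCR of blank (no mitochondria) wells.
#' @param n_wells,n_blank Number of sample and blank wells.
#' @param cycles_per_state Measurement cycles per segment (convention: 3).
#' @param cycle_min Minutes per measurement cycle.
#' @param noise_sd SD of additive noise on each measurement.
#' @param seed RNG seed.
#' @return List with `traces` (data.frame `well`, `is_blank`, `time_min`,
#'   `ocr`) and `injections` (data.frame `label`, `time_min`); accepted
#'   directly by [ocr_states()].
#' @export
simulate_ocr_plate <- function(state_levels, blank_level = 20, n_wells = 3,
                               n_blank = 2, cycles_per_state = 3,
                               cycle_min = 6, noise_sd = 0, seed = 1) {
  need <- c("basal", "state3", "state4o", "maximal", "nonmito")
  missing <- setdiff(need, names(state_levels))
  if (length(missing)) {
    stop("state_levels is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  set.seed(seed)
  n_seg <- length(need)
  times <- cycle_min * seq_len(n_seg * cycles_per_state)
  seg <- rep(seq_len(n_seg), each = cycles_per_state)
  levels_t <- unname(state_levels[need])[seg]
  inj <- data.frame(
    label = c("ADP", "Oligo", "CCCP", "antA"),
    time_min = cycle_min * cycles_per_state * 1:4 + cycle_min / 2,
    stringsAsFactors = FALSE)
  mk_well <- function(w, base) {
    data.frame(well = w, is_blank = base == "blank", time_min = times,
               ocr = (if (base == "blank") blank_level else levels_t) +
                 rnorm(length(times), 0, noise_sd),
               stringsAsFactors = FALSE)
  }
  traces <- rbind(
    do.call(rbind, lapply(sprintf("S%02d", seq_len(n_wells)), mk_well,
                          base = "sample")),
    do.call(rbind, lapply(sprintf("B%02d", seq_len(n_blank)), mk_well,
                          base = "blank")))
  list(traces = traces, injections = inj)
}

#' Simulate a metabolome screen with a designated altered subset
#'
#' Log-normal abundances for `n_features` metabolites in two groups
#' (`wt`, `mfn12`), with the first `n_altered` features shifted in the
#' mutant group by `effect_sd` within-group SDs on the log scale
#' (alternating direction, mirroring the mix of accumulating and depleted
#' metabolites in a perturbed tissue).
#'
#' @param n_features Total features (default 187).
#' @param n_altered Truly altered features (default 64).
#' @param effect_sd Mean shift in SD units on the log scale.
#' @param n_per_group Animals per group.
#' @param sdlog Within-group SD on the log scale.
#' @param seed RNG seed.
#' @return Tidy data.frame: `sample_id`, `group`, `feature`, `value`,
#'   `altered` (the designated truth, for recovery checks).
#' @export
simulate_metabolome <- function(n_features = 187, n_altered = 64,
                                effect_sd = 5, n_per_group = 10,
                                sdlog = 0.25, seed = 1) {
  if (n_altered > n_features) {
    stop("n_altered cannot exceed n_features", call. = FALSE)
  }
  set.seed(seed)
  mu <- rnorm(n_features, log(1e4), 1)
  feats <- sprintf("met_%03d", seq_len(n_features))
  altered <- seq_len(n_features) <= n_altered
  shift <- ifelse(altered, effect_sd * sdlog, 0) *
    rep_len(c(1, -1), n_features)
  out <- list()
  for (g in c("wt", "mfn12")) {
    for (i in seq_len(n_per_group)) {
      lmu <- mu + if (g == "mfn12") shift else 0
      out[[length(out) + 1L]] <- data.frame(
        sample_id = sprintf("%s_%02d", g, i), group = g, feature = feats,
        value = exp(rnorm(n_features, lmu, sdlog)),
        altered = altered, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
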