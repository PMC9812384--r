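# Tracer inference: deuterium mixing model, pathway-normalized enrichment,
# circulatory turnover flux.

#' Partition tissue lactate between import and intramuscular production
#'
#' Steady-state two-source mixing model for a [2-2H]lactate infusion.
#' Lactate-pyruvate exchange outside the tissue removes the C2 deuterium, so
#' tissue lactate m+1 can only come from direct import of circulating
#' labeled lactate. The imported fraction is therefore the ratio of tissue
#' to plasma m+1 enrichment; its complement is attributed to reduction of
#' intramuscular pyruvate (which carries no label).
#'
#' Measurement noise can push the raw ratio above 1; the raw value is kept
#' (`raw_ratio`, with `flagged = TRUE`) and only the reported fractions are
#' clipped to `[0, 1]`, so QC problems stay visible.
#'
#' @param tissue_lactate_mid,plasma_lactate_mid Corrected [mid()] objects
#'   (or fraction vectors) for tissue and plasma lactate.
#' @param index Labeled channel, default 1 (m+1).
#' @param floor Detection floor for the plasma (denominator) enrichment;
#'   below GC-MS precision the ratio is unreliable. Default 0.001.
#' @return A `source_partition`: list with `import_fraction`,
#'   `intramuscular_fraction`, `raw_ratio`, `flagged`.
#' @export
#' @examples
#' p <- mid(c(0.90, 0.10), corrected = TRUE)
#' t <- mid(c(0.956, 0.044), corrected = TRUE)
#' import_fraction_deuterium(t, p)$import_fraction  # 0.44
import_fraction_deuterium <- function(tissue_lactate_mid, plasma_lactate_mid,
                                      index = 1L, floor = 0.001) {
  for (x in list(tissue_lactate_mid, plasma_lactate_mid)) {
    if (inherits(x, "mid") && !x$corrected) {
      stop("MIDs must be natural-abundance corrected before mixing-model ",
           "estimation", call. = FALSE)
    }
  }
  e_plasma <- fractional_enrichment(plasma_lactate_mid, index)
  if (e_plasma <= floor) {
    stop("plasma enrichment (", format(e_plasma), ") is at or below the ",
         "detection floor (", floor, "): unreliable denominator",
         call. = FALSE)
  }
  e_tissue <- fractional_enrichment(tissue_lactate_mid, index)
  raw <- e_tissue / e_plasma
  import <- min(max(raw, 0), 1)
  structure(list(import_fraction = import,
                 intramuscular_fraction = 1 - import,
                 raw_ratio = raw,
                 flagged = raw > 1),
            class = "source_partition")
}

#' @export
print.source_partition <- function(x, ...) {
  cat(sprintf("source partition: %.1f%% import / %.1f%% intramuscular%s\n",
              100 * x$import_fraction, 100 * x$intramuscular_fraction,
              if (x$flagged) sprintf(" (raw ratio %.3f > 1, clipped)", x$raw_ratio)
              else ""))
  invisible(x)
}

#' Enrichment of one metabolite normalized to a reference
#'
#' Ratio of fractional enrichments, `E_target(i) / E_reference(j)`, used to
#' compare direct-pathway contributions across genotypes: e.g. TCA m+2
#' normalized to glucose m+6 in a 13C-glucose infusion, or pyruvate m+3
#' normalized to PEP m+3 in a 13C-lactate infusion.
#'
#' @param target_mid,reference_mid Corrected MIDs or fraction vectors.
#' @param target_index,reference_index 0-based channels.
#' @param floor Detection floor for the reference enrichment.
#' @return Numeric ratio.
#' @export
normalized_enrichment <- function(target_mid, reference_mid, target_index,
                                  reference_index, floor = 0.001) {
  e_ref <- fractional_enrichment(reference_mid, reference_index)
  if (e_ref <= floor) {
    stop("reference enrichment (", format(e_ref),
         ") is at or below the detection floor (", floor, ")", call. = FALSE)
  }
  fractional_enrichment(target_mid, target_index) / e_ref
}

#' Circulatory turnover flux from a steady-state infusion
#'
#' At isotopic steady state, infusing tracer at mass rate `R` and measuring
#' plasma enrichment `E` gives the whole-body turnover flux. The default
#' endogenous-appearance convention is `Fcirc = R * (1 - E) / E`; the
#' alternative total-turnover convention `R / E` is available because the
#' tracer literature uses both.
#'
#' @param infusion_rate Tracer mass infusion rate, mg min^-1 kg^-1.
#' @param plasma_enrichment Steady-state plasma enrichment in `(0, 1]`.
#' @param convention `"endogenous"` (default) or `"total"`.
#' @return Flux in mg min^-1 kg^-1.
#' @export
#' @examples
#' fcirc(3.6, 0.2)  # 14.4
fcirc <- function(infusion_rate, plasma_enrichment,
                  convention = c("endogenous", "total")) {
  convention <- match.arg(convention)
  if (infusion_rate <= 0) stop("infusion_rate must be positive", call. = FALSE)
  if (plasma_enrichment <= 0) {
    stop("plasma enrichment must be > 0 at isotopic steady state",
         call. = FALSE)
  }
  if (plasma_enrichment > 1) stop("enrichment cannot exceed 1", call. = FALSE)
  switch(convention,
         endogenous = infusion_rate * (1 - plasma_enrichment) / plasma_enrichment,
         total = infusion_rate / plasma_enrichment)
}

#' Mass infusion rate from solution concentration and pump rate
#'
#' Converts a tracer solution concentration and a body-mass-scaled pump rate
#' into the mass infusion rate used by [fcirc()]. Units: `conc_mM` mmol/L,
#' `rate` ul min^-1 g^-1 (numerically equal to ml min^-1 kg^-1), molar mass
#' g/mol; result mg min^-1 kg^-1.
#'
#' @param concentration_mM Solution concentration, mM.
#' @param volumetric_rate Pump rate, ul min^-1 per g body mass.
#' @param molar_mass Molar mass of the infused compound, g/mol.
#' @return Mass infusion rate, mg min^-1 kg^-1.
#' @export
#' @examples
#' infusion_mass_rate(200, 0.1, 180.16)  # ~3.6
infusion_mass_rate <- function(concentration_mM, volumetric_rate, molar_mass) {
  args <- c(concentration_mM, volumetric_rate, molar_mass)
  if (any(!is.finite(args)) || any(args <= 0)) {
    stop("all inputs must be positive", call. = FALSE)
  }
  # mM * g/mol / 1000 = mg per ml; ul/min/g == ml/min/kg
  concentration_mM * molar_mass / 1000 * volumetric_rate
}

#' Summarize per-animal source partitions for one arm
#'
#' Group value = mean of per-animal import fractions (not the ratio of
#' means); SD uses the n-1 denominator and is `NA` for a single animal.
#'
#' @param partitions List of `source_partition` objects, or a numeric vector
#'   of per-animal import fractions.
#' @return List with `mean_import`, `sd_import`, `mean_intramuscular`,
#'   `sd_intramuscular`, `n`, `n_flagged`.
#' @export
arm_summary <- function(partitions) {
  if (is.numeric(partitions)) {
    imp <- partitions
    flagged <- rep(FALSE, length(imp))
  } else {
    if (length(partitions) == 0L) stop("no partitions supplied", call. = FALSE)
    imp <- vapply(partitions, function(p) p$import_fraction, numeric(1))
    flagged <- vapply(partitions, function(p) isTRUE(p$flagged), logical(1))
  }
  if (length(imp) == 0L) stop("no partitions supplied", call. = FALSE)
  n <- length(imp)
  list(mean_import = mean(imp),
       sd_import = if (n > 1L) sd(imp) else NA_real_,
       mean_intramuscular = mean(1 - imp),
       sd_intramuscular = if (n > 1L) sd(1 - imp) else NA_real_,
       n = n, n_flagged = sum(flagged))
}

#' Estimate import fractions for every animal in a peak table
#'
#' End-to-end wrapper for a [2-2H]lactate infusion experiment: corrects the
#' plasma and tissue lactate isotopolog blocks of each animal for natural
#' abundance (deuterium tracer: one label position) and applies the
#' deuterium mixing model per animal, then summarizes each arm.
#'
#' @param peaks Raw `peak_table` containing plasma and tissue lactate rows.
#' @param registry Metabolite registry.
#' @param metabolite Traced metabolite, default `"lactate"`.
#' @param index Labeled channel, default 1 (m+1).
#' @param floor Detection floor for plasma enrichment.
#' @return List with `per_animal` (one row per sample: import and
#'   intramuscular fraction, raw ratio, flag) and `summary` (one row per
#'   arm: mean, SD, n).
#' @export
estimate_import_fractions <- function(peaks, registry = load_registry(),
                                      metabolite = "lactate", index = 1L,
                                      floor = 0.001) {
  peaks <- as.data.frame(peaks)
  sub <- peaks[peaks$metabolite == metabolite, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop("peak table contains no '", metabolite, "' rows", call. = FALSE)
  }
  corrected <- correct_peak_table(sub, registry, tracer_element = "H",
                                  n_label = 1L)
  rows <- list()
  for (s in unique(corrected$sample_id)) {
    cs <- corrected[corrected$sample_id == s, , drop = FALSE]
    pl <- cs[cs$compartment == "plasma", , drop = FALSE]
    ti <- cs[cs$compartment == "tissue", , drop = FALSE]
    if (nrow(pl) == 0L || nrow(ti) == 0L) {
      stop("sample '", s, "' lacks a plasma or tissue lactate block",
           call. = FALSE)
    }
    part <- import_fraction_deuterium(
      ti$fraction[order(ti$isotopolog_index)],
      pl$fraction[order(pl$isotopolog_index)],
      index = index, floor = floor)
    rows[[s]] <- data.frame(
      sample_id = s, arm_label = cs$arm_label[1],
      import_fraction = part$import_fraction,
      intramuscular_fraction = part$intramuscular_fraction,
      raw_ratio = part$raw_ratio, flagged = part$flagged,
      stringsAsFactors = FALSE)
  }
  per_animal <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  summ <- do.call(rbind, lapply(split(per_animal, per_animal$arm_label),
    function(d) {
      s <- arm_summary(d$import_fraction)
      data.frame(arm_label = d$arm_label[1], mean_import = s$mean_import,
                 sd_import = s$sd_import,
                 mean_intramuscular = s$mean_intramuscular,
                 sd_intramuscular = s$sd_intramuscular, n = s$n,
                 stringsAsFactors = FALSE)
    }))
  rownames(summ) <- NULL
  list(per_animal = per_animal, summary = summ)
}
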