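# Respirometry, energy state, ex vivo flux, qPCR and enzyme activity.

# coefficient of determination, robust to a constant response (returns NA
# there instead of summary.lm's 0/0)
.r_squared <- function(y, resid) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= .Machine$double.eps * max(sum(y^2), 1)) return(NA_real_)
  max(0, min(1, 1 - sum(resid^2) / ss_tot))
}

#' Respiration states from plate OCR traces
#'
#' Computes basal, state 3 (post-ADP), state 4o (post-oligomycin), maximal
#' (post-CCCP, if injected) and non-mitochondrial (post-antimycin A)
#' respiration from oxygen consumption traces of sample wells, subtracting
#' the mean OCR of blank wells (no mitochondria) over the same measurement
#' window. The measurement cycle immediately following each injection is
#' excluded by default because it overlaps the mixing period.
#'
#' @param traces data.frame with columns `well`, `is_blank` (logical),
#'   `time_min`, `ocr` (pmol O2/min). At least one sample and one blank
#'   well are required.
#' @param injections data.frame with columns `label`, `time_min`; labels
#'   must be unique and include `ADP` and `Oligo`; `CCCP` and `antA` are
#'   optional.
#' @param drop_first_cycle Exclude the first measurement after each
#'   injection.
#' @return Named list: `basal`, `state3`, `state4o`, `maximal` (or `NA` if
#'   CCCP was not injected), `nonmito` (or `NA` without antimycin).
#' @export
ocr_states <- function(traces, injections, drop_first_cycle = TRUE) {
  need <- c("well", "is_blank", "time_min", "ocr")
  if (!all(need %in% names(traces))) {
    stop("traces must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(injections$label)) {
    stop("injection labels must be unique", call. = FALSE)
  }
  for (lab in c("ADP", "Oligo")) {
    if (!lab %in% injections$label) {
      stop("required injection '", lab, "' is missing", call. = FALSE)
    }
  }
  inj <- setNames(injections$time_min, injections$label)
  if (any(traces$is_blank) == FALSE || all(traces$is_blank)) {
    stop("need at least one sample trace and one blank trace", call. = FALSE)
  }
  bounds <- list(
    basal   = c(-Inf, inj[["ADP"]]),
    state3  = c(inj[["ADP"]], inj[["Oligo"]]),
    state4o = c(inj[["Oligo"]],
                min(inj[names(inj) %in% c("CCCP", "antA")], Inf)),
    maximal = if ("CCCP" %in% names(inj))
                c(inj[["CCCP"]], if ("antA" %in% names(inj)) inj[["antA"]] else Inf),
    nonmito = if ("antA" %in% names(inj)) c(inj[["antA"]], Inf)
  )
  window_mean <- function(d, lo, hi, drop) {
    t_in <- sort(unique(d$time_min[d$time_min > lo & d$time_min <= hi]))
    if (drop && is.finite(lo) && length(t_in) > 1L) t_in <- t_in[-1L]
    if (length(t_in) == 0L) return(NA_real_)
    mean(d$ocr[d$time_min %in% t_in])
  }
  out <- list()
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (is.null(b)) { out[[nm]] <- NA_real_; next }
    samp <- window_mean(traces[!traces$is_blank, ], b[1], b[2], drop_first_cycle)
    blk <- window_mean(traces[traces$is_blank, ], b[1], b[2], drop_first_cycle)
    if (is.na(samp) || is.na(blk)) {
      stop("no measurements in the ", nm, " window", call. = FALSE)
    }
    out[[nm]] <- samp - blk
  }
  out
}

#' Respiratory control ratio
#'
#' State 3 (ADP-stimulated) respiration divided by state 4o
#' (oligomycin-inhibited) respiration; an index of coupling quality of the
#' mitochondrial preparation.
#'
#' @param state3,state4o Blank-subtracted respiration rates.
#' @return `state3 / state4o`.
#' @export
respiratory_control_ratio <- function(state3, state4o) {
  if (!is.finite(state4o) || state4o <= 0) {
    stop("state 4o must be positive (uncoupled or invalid preparation)",
         call. = FALSE)
  }
  state3 / state4o
}

#' Adenylate energy charge
#'
#' `(ATP + 0.5 * ADP) / (ATP + ADP + AMP)`: 1 when all adenylate is ATP,
#' 0 when all is AMP.
#'
#' @param amp,adp,atp Pool sizes (any common unit); vectorized.
#' @return Values in `[0, 1]`.
#' @export
#' @examples
#' energy_charge(1, 1, 1)  # 0.5
energy_charge <- function(amp, adp, atp) {
  if (any(c(amp, adp, atp) < 0, na.rm = TRUE)) {
    stop("nucleotide pools must be >= 0", call. = FALSE)
  }
  total <- amp + adp + atp
  if (any(total <= 0)) stop("all-zero nucleotide pools", call. = FALSE)
  (atp + 0.5 * adp) / total
}

#' Quantify an analyte against a spiked internal standard
#'
#' `target_area / standard_area * spike_nmol`: converts a peak-area ratio to
#' absolute nanomoles using a known spike (e.g. m+1 lactate area against a
#' 200 nmol fully 13C-labeled m+3 lactate spike).
#'
#' @param target_area,standard_area Peak areas; vectorized.
#' @param spike_nmol Amount of internal standard added, nmol.
#' @return Nanomoles of target.
#' @export
quantify_internal_standard <- function(target_area, standard_area,
                                       spike_nmol = 200) {
  if (any(standard_area <= 0)) {
    stop("standard peak area must be positive", call. = FALSE)
  }
  if (spike_nmol <= 0) stop("spike amount must be positive", call. = FALSE)
  if (any(target_area < 0)) stop("target areas must be >= 0", call. = FALSE)
  target_area / standard_area * spike_nmol
}

#' Production rate from an ex vivo time course
#'
#' Quantifies each time point against the internal standard, fits an
#' ordinary least-squares line of nanomoles versus time, and scales the
#' slope by tissue weight. The intercept is fitted by default because
#' time-zero medium may carry over label; `force_origin = TRUE` constrains
#' the line through zero.
#'
#' @param tc Either the list returned by [simulate_exvivo_timecourse()] or
#'   a data.frame with columns `time_min`, `target_area`, `standard_area`.
#' @param spike_nmol Internal standard amount (ignored if `tc` carries one).
#' @param tissue_weight_mg Tissue wet weight (ignored if `tc` carries one).
#' @param force_origin Fit without intercept.
#' @return List: `rate` (nmol min^-1 mg^-1), `slope` (nmol/min),
#'   `intercept` (nmol), `r_squared`, `n`.
#' @export
production_rate <- function(tc, spike_nmol = 200, tissue_weight_mg = NULL,
                            force_origin = FALSE) {
  if (is.list(tc) && !is.data.frame(tc) && !is.null(tc$points)) {
    if (!is.null(tc$spike_nmol)) spike_nmol <- tc$spike_nmol
    if (!is.null(tc$tissue_weight_mg)) tissue_weight_mg <- tc$tissue_weight_mg
    tc <- tc$points
  }
  if (is.null(tissue_weight_mg) || tissue_weight_mg <= 0) {
    stop("a positive tissue weight is required", call. = FALSE)
  }
  if (nrow(tc) < 3L) {
    stop("at least 3 time points are required for a rate fit", call. = FALSE)
  }
  nmol <- quantify_internal_standard(tc$target_area, tc$standard_area,
                                     spike_nmol)
  fit <- if (force_origin) lm(nmol ~ 0 + time_min, data = cbind(tc, nmol))
         else lm(nmol ~ time_min, data = cbind(tc, nmol))
  slope <- unname(coef(fit)[["time_min"]])
  intercept <- if (force_origin) 0 else unname(coef(fit)[["(Intercept)"]])
  r2 <- .r_squared(nmol, stats::residuals(fit))
  list(rate = slope / tissue_weight_mg, slope = slope, intercept = intercept,
       r_squared = r2, n = nrow(tc))
}

#' Relative quantification by the 2^-ddCt method
#'
#' `2^-((Ct_target,sample - Ct_ref,sample) - (Ct_target,cal - Ct_ref,cal))`,
#' assuming amplification efficiency exactly 2. Vectorized over samples.
#'
#' @param ct_target_sample,ct_ref_sample Ct of target and reference gene in
#'   the sample of interest.
#' @param ct_target_calibrator,ct_ref_calibrator Ct of the same assays in
#'   the calibrator sample.
#' @return Fold change relative to the calibrator.
#' @export
relative_quantity_ddct <- function(ct_target_sample, ct_ref_sample,
                                   ct_target_calibrator, ct_ref_calibrator) {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_calibrator,
           ct_ref_calibrator)
  if (any(!is.finite(cts))) stop("all Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}

#' Initial-rate slope from an absorbance series
#'
#' OLS slope of absorbance versus time over the longest initial window that
#' is still linear (prefix R^2 >= `r2_min`), for enzyme activity assays read
#' at fixed intervals. Enzyme assays typically start linear and plateau as
#' substrate depletes; a global fit would underestimate activity.
#'
#' @param absorbance Numeric series of absorbance readings.
#' @param time Reading times in minutes; defaults to 1-min intervals.
#' @param min_points Minimum window length (default 5).
#' @param r2_min Linearity threshold for the prefix window.
#' @param restrict If `FALSE`, fit the full series.
#' @return List: `slope` (dA/min), `intercept`, `r_squared`, `window` (number
#'   of points used).
#' @export
linear_activity_slope <- function(absorbance, time = NULL, min_points = 5L,
                                  r2_min = 0.98, restrict = TRUE) {
  n <- length(absorbance)
  if (n < min_points) {
    stop("need at least ", min_points, " readings", call. = FALSE)
  }
  if (is.null(time)) time <- seq_len(n) - 1
  prefix_fit <- function(k) {
    x <- time[seq_len(k)]; y <- absorbance[seq_len(k)]
    f <- lm(y ~ x)
    r2 <- .r_squared(y, stats::residuals(f))
    if (is.na(r2)) r2 <- 1  # flat series: slope 0 fits exactly
    list(slope = unname(coef(f)[["x"]]),
         intercept = unname(coef(f)[["(Intercept)"]]), r2 = r2, k = k)
  }
  if (!restrict) {
    f <- prefix_fit(n)
  } else {
    f <- NULL
    for (k in seq(n, min_points)) {
      cand <- prefix_fit(k)
      if (cand$r2 >= r2_min) { f <- cand; break }
    }
    if (is.null(f)) {
      warning("no prefix of >= ", min_points, " points reaches R^2 >= ",
              r2_min, "; using the full series", call. = FALSE)
      f <- prefix_fit(n)
    }
  }
  list(slope = f$slope, intercept = f$intercept, r_squared = f$r2,
       window = f$k)
}

#' Paired ratio metric
#'
#' Plain per-sample ratio (NAD+/NADH, NADP+/NADPH, GSH/GSSG, ...). When
#' sample ids are supplied for both vectors they must match exactly, so a
#' shuffled pairing is an error rather than a silent mismatch.
#'
#' @param numerator,denominator Paired measurements.
#' @param ids,ids_denominator Optional sample ids for each vector.
#' @return Vector of ratios (named by `ids` when given).
#' @export
ratio_metric <- function(numerator, denominator, ids = NULL,
                         ids_denominator = NULL) {
  if (length(numerator) != length(denominator)) {
    stop("numerator and denominator lengths differ", call. = FALSE)
  }
  if (!is.null(ids) || !is.null(ids_denominator)) {
    if (!identical(ids, ids_denominator)) {
      stop("sample ids of numerator and denominator do not match",
           call. = FALSE)
    }
  }
  if (any(denominator <= 0)) {
    stop("denominators must be positive", call. = FALSE)
  }
  out <- numerator / denominator
  if (!is.null(ids)) names(out) <- ids
  out
}
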