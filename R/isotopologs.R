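# Mass-isotopolog distribution (MID) math: natural-abundance correction,
# enrichment, total labeling, TIC normalization.

#' Construct a mass-isotopolog distribution
#'
#' A MID is the normalized vector of isotopolog fractions M0..Mn of one
#' metabolite fragment in one sample; element `i + 1` is the fraction of the
#' pool carrying `i` heavy tracer atoms.
#'
#' @param fractions Non-negative numeric vector summing to 1 (tolerance
#'   1e-9), or any non-negative vector with `normalize = TRUE`.
#' @param metabolite Optional metabolite name.
#' @param corrected Has natural abundance been removed?
#' @param normalize Rescale `fractions` to sum 1.
#' @return An object of class `mid`.
#' @export
#' @examples
#' mid(c(0.56, 0.44), metabolite = "lactate", corrected = TRUE)
mid <- function(fractions, metabolite = NA_character_, corrected = FALSE,
                normalize = FALSE) {
  if (!is.numeric(fractions) || length(fractions) < 1L) {
    stop("fractions must be a numeric vector", call. = FALSE)
  }
  if (any(!is.finite(fractions)) || any(fractions < 0)) {
    stop("MID fractions must be finite and >= 0", call. = FALSE)
  }
  s <- sum(fractions)
  if (normalize) {
    if (s <= 0) stop("cannot normalize an all-zero MID", call. = FALSE)
    fractions <- fractions / s
  } else if (abs(s - 1) > 1e-9) {
    stop("MID fractions must sum to 1 (got ", format(s),
         "); use normalize = TRUE for raw vectors", call. = FALSE)
  }
  structure(list(metabolite = metabolite, fractions = as.numeric(fractions),
                 corrected = isTRUE(corrected)),
            class = "mid")
}

#' @export
print.mid <- function(x, ...) {
  cat("MID", if (!is.na(x$metabolite)) paste0("(", x$metabolite, ")"),
      if (x$corrected) "[corrected]" else "[raw]", "\n")
  v <- round(x$fractions, 4)
  names(v) <- paste0("M", seq_along(v) - 1L)
  print(v)
  invisible(x)
}

.mid_fractions <- function(x) {
  if (inherits(x, "mid")) x$fractions else as.numeric(x)
}

# non-negative least squares min ||Mx - b|| s.t. x >= 0, posed as a strictly
# convex QP (M has full column rank after the condition-number guard)
.nnls <- function(M, b) {
  n <- ncol(M)
  fit <- solve.QP(Dmat = crossprod(M), dvec = crossprod(M, b),
                  Amat = diag(n), bvec = numeric(n))
  pmax(fit$solution, 0)
}

#' Build a natural-abundance correction matrix
#'
#' Column `j + 1` of the returned square matrix gives the probability of
#' observing mass shift `i` (row `i + 1`) for a species carrying exactly
#' `j` tracer labels: the convolution of the natural-isotope mass-shift
#' distributions of every non-tracer atom in the fragment and of the
#' `n - j` unlabeled tracer atoms, truncated at `max_shift`. With perfect
#' tracer purity the matrix is lower-triangular (labels cannot be lost).
#' Deuterium tracers are handled like any other: H natural abundance is
#' small but nonzero and is modeled explicitly, so a tracer-derived m+1
#' channel is separated from the 13C background of the carbon skeleton.
#'
#' @param fragment_formula Hill-notation string or named atom-count vector
#'   for the derivatized fragment (including TBDMS Si/C/H).
#' @param tracer_element Element carrying the label (`"C"` or `"H"`).
#' @param n_tracer_atoms Number of positions that can carry label.
#' @param max_shift Largest observed mass shift; default
#'   `n_tracer_atoms + 3` captures the Si/S isotope tail of TBDMS fragments.
#' @param abundances Isotope mass-shift table, see [isotope_abundances()].
#' @param purity Isotopic purity of the tracer (probability that a nominally
#'   labeled position is heavy). Default 1 assumes a pure infusate; values
#'   below 1 break lower-triangularity by design.
#' @return `(max_shift + 1)` square matrix of class `matrix`.
#' @export
#' @examples
#' M <- build_na_matrix("C11H25O3Si2", "C", 3)
#' colSums(M)
build_na_matrix <- function(fragment_formula, tracer_element, n_tracer_atoms,
                            max_shift = n_tracer_atoms + 3L,
                            abundances = isotope_abundances(), purity = 1) {
  counts <- .as_formula_counts(fragment_formula)
  if (!tracer_element %in% names(counts)) {
    stop("fragment formula contains no ", tracer_element, " atoms",
         call. = FALSE)
  }
  n_avail <- counts[[tracer_element]]
  if (n_tracer_atoms < 1 || n_tracer_atoms > n_avail) {
    stop("n_tracer_atoms must be between 1 and the ", tracer_element,
         " count of the fragment (", n_avail, ")", call. = FALSE)
  }
  if (max_shift < n_tracer_atoms) {
    stop("max_shift (", max_shift, ") must be >= n_tracer_atoms (",
         n_tracer_atoms, ")", call. = FALSE)
  }
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]", call. = FALSE)
  unknown <- setdiff(names(counts), names(abundances))
  if (length(unknown)) {
    stop("no isotope data for element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  # shift distribution of all atoms that are never labeled
  base <- 1.0
  for (e in names(counts)) {
    if (e == tracer_element) next
    base <- .conv(base, .conv_atoms(abundances[[e]], counts[[e]]))
  }
  p_tracer <- abundances[[tracer_element]]
  m <- max_shift + 1L
  M <- matrix(0, m, m)
  for (j in 0:max_shift) {
    rem <- max(n_avail - j, 0L)               # unlabeled tracer-element atoms
    col <- .conv(base, .conv_atoms(p_tracer, rem))
    lab <- if (j == 0L) 1.0 else stats::dbinom(0:j, j, purity)
    col <- .conv(col, lab)
    k <- min(length(col), m)                  # pad or truncate at max_shift
    M[seq_len(k), j + 1L] <- col[seq_len(k)]
  }
  M
}

#' Forward-convolve a true MID with natural abundance
#'
#' Computes the observed (uncorrected) isotopolog pattern `M %*% x` implied
#' by a true label distribution; the exact inverse operation of
#' [correct_mid()] at zero noise.
#'
#' @param x `mid` object or numeric fraction vector (padded with zeros to
#'   the matrix dimension).
#' @param matrix Correction matrix from [build_na_matrix()].
#' @return Numeric vector of observed relative intensities (length
#'   `nrow(matrix)`).
#' @export
convolve_mid <- function(x, matrix) {
  f <- .mid_fractions(x)
  if (length(f) > nrow(matrix)) {
    stop("MID longer than the correction matrix dimension", call. = FALSE)
  }
  as.vector(matrix %*% c(f, numeric(nrow(matrix) - length(f))))
}

#' Correct raw isotopolog areas for natural abundance
#'
#' Solves `observed = M %*% true` for `true >= 0` by non-negative least
#' squares (Lawson-Hanson NNLS) and renormalizes to a fractional MID.
#' NNLS rather than plain inversion is used because noisy low-abundance
#' channels otherwise produce negative fractions. If the NNLS residual
#' exceeds `residual_warn` of the total signal, a per-record quality
#' warning is emitted rather than an error.
#'
#' @param raw_areas Numeric vector of ion areas for shifts `0..max_shift`;
#'   length must equal the matrix dimension.
#' @param matrix Correction matrix from [build_na_matrix()].
#' @param n_tracer_atoms Number of label positions; the corrected MID is
#'   truncated to `M0..Mn` and renormalized. Defaults to the full matrix
#'   dimension.
#' @param metabolite Optional name carried on the result.
#' @param residual_warn Relative-residual threshold for the quality warning.
#' @return A corrected [mid()] with attribute-like fields `residual_frac`.
#' @export
correct_mid <- function(raw_areas, matrix, n_tracer_atoms = ncol(matrix) - 1L,
                        metabolite = NA_character_, residual_warn = 0.1) {
  if (length(raw_areas) != nrow(matrix)) {
    stop("raw_areas length (", length(raw_areas),
         ") does not match matrix dimension (", nrow(matrix), ")",
         call. = FALSE)
  }
  if (any(!is.finite(raw_areas)) || any(raw_areas < 0)) {
    stop("raw areas must be finite and >= 0", call. = FALSE)
  }
  total <- sum(raw_areas)
  if (total <= 0) stop("all-zero area vector: no signal to correct",
                       call. = FALSE)
  kap <- kappa(matrix, exact = TRUE)
  if (!is.finite(kap) || kap > 1e10) {
    stop("correction matrix is ill-conditioned (condition number ",
         format(kap, digits = 3), ")", call. = FALSE)
  }
  sol <- .nnls(matrix, as.numeric(raw_areas) / total) * total
  resid <- sqrt(sum((as.vector(matrix %*% sol) - raw_areas)^2))
  if (resid > residual_warn * total) {
    warning(if (!is.na(metabolite)) paste0("[", metabolite, "] "),
            "NNLS residual is ", format(100 * resid / total, digits = 3),
            "% of total signal; corrected MID may be unreliable",
            call. = FALSE)
  }
  keep <- sol[seq_len(n_tracer_atoms + 1L)]
  if (sum(keep) <= 0) {
    stop("corrected MID is zero within M0..M", n_tracer_atoms, call. = FALSE)
  }
  out <- mid(keep, metabolite = metabolite, corrected = TRUE, normalize = TRUE)
  out$residual_frac <- resid / total
  out
}

#' Fractional enrichment at one isotopolog index
#'
#' Returns `M[index]` of a corrected MID, e.g. glucose m+6 or lactate m+1
#' enrichment.
#'
#' @param x `mid` or numeric fraction vector.
#' @param index 0-based mass shift.
#' @return Fraction in `[0, 1]`.
#' @export
fractional_enrichment <- function(x, index) {
  f <- .mid_fractions(x)
  if (index < 0 || index > length(f) - 1L) {
    stop("index ", index, " out of range 0..", length(f) - 1L, call. = FALSE)
  }
  f[index + 1L]
}

#' Average labeled fraction of tracer atoms
#'
#' `sum(i * Mi) / n` over a corrected MID: the mean fraction of labelable
#' atoms that carry label, used when positional scrambling makes single
#' isotopolog channels ambiguous.
#'
#' @param x `mid` or numeric fraction vector of length `n + 1`, `n >= 1`.
#' @return Value in `[0, 1]`.
#' @export
total_labeling <- function(x) {
  f <- .mid_fractions(x)
  n <- length(f) - 1L
  if (n < 1L) stop("total labeling is undefined for a single-channel MID",
                   call. = FALSE)
  sum((0:n) * f) / n
}

#' Total-ion-count normalization
#'
#' Divides each sample's feature abundances by that sample's total so each
#' sample sums to 1 (features in rows, samples in columns).
#'
#' @param abundance_table Numeric matrix, features x samples.
#' @return Matrix of the same shape with unit column sums.
#' @export
tic_normalize <- function(abundance_table) {
  m <- as.matrix(abundance_table)
  totals <- colSums(m)
  bad <- which(totals <= 0)
  if (length(bad)) {
    nm <- if (!is.null(colnames(m))) colnames(m)[bad] else bad
    stop("zero-total sample(s): ", paste(nm, collapse = ", "), call. = FALSE)
  }
  sweep(m, 2L, totals, "/")
}

#' Natural-abundance correct an entire peak table
#'
#' Groups a raw peak table by (sample, compartment, metabolite), builds one
#' correction matrix per metabolite from the registry, and corrects each
#' complete isotopolog block by NNLS. Missing isotopolog rows are an error,
#' never imputed.
#'
#' @param peaks A `peak_table` (see [read_peak_table()]).
#' @param registry A `metabolite_registry`.
#' @param tracer_element `"C"` for 13C tracers, `"H"` for deuterium.
#' @param n_label Label positions per metabolite: `NULL` uses the registry's
#'   `n_tracer_atoms` (carbon tracers); a single number applies to all
#'   metabolites (e.g. `1` for a singly deuterated tracer); a named vector
#'   overrides per metabolite.
#' @param purity Tracer isotopic purity passed to [build_na_matrix()].
#' @return Tidy data.frame of corrected fractions with columns
#'   `sample_id, arm_label, compartment, metabolite, isotopolog_index,
#'   fraction, corrected`.
#' @export
correct_peak_table <- function(peaks, registry = load_registry(),
                               tracer_element = "C", n_label = NULL,
                               purity = 1) {
  peaks <- validate_peak_table(as.data.frame(peaks))
  if (nrow(peaks) == 0L) stop("empty peak table", call. = FALSE)
  out <- list()
  for (m in unique(peaks$metabolite)) {
    entry <- .registry_entry(registry, m)
    n <- if (is.null(n_label)) entry$n_tracer_atoms
         else if (!is.null(names(n_label))) {
           if (!m %in% names(n_label)) entry$n_tracer_atoms
           else as.integer(n_label[[m]])
         } else as.integer(n_label)
    sub <- peaks[peaks$metabolite == m, , drop = FALSE]
    max_shift <- max(sub$isotopolog_index)
    if (max_shift < n) {
      stop("metabolite '", m, "': observed shifts only reach ", max_shift,
           " but ", n, " label positions are expected", call. = FALSE)
    }
    M <- build_na_matrix(entry$fragment_formula, tracer_element, n,
                         max_shift = max_shift, purity = purity)
    for (grp in split(sub, paste(sub$sample_id, sub$compartment, sep = "\r"))) {
      grp <- grp[order(grp$isotopolog_index), , drop = FALSE]
      if (!identical(grp$isotopolog_index, 0:max_shift)) {
        stop("incomplete isotopolog block for ", grp$sample_id[1], "/",
             grp$compartment[1], "/", m,
             ": indices 0..", max_shift, " are required (missing rows are ",
             "not imputed)", call. = FALSE)
      }
      cm <- correct_mid(grp$area, M, n_tracer_atoms = n, metabolite = m)
      out[[length(out) + 1L]] <- data.frame(
        sample_id = grp$sample_id[1], arm_label = grp$arm_label[1],
        compartment = grp$compartment[1], metabolite = m,
        isotopolog_index = 0:n, fraction = cm$fractions,
        corrected = TRUE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
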