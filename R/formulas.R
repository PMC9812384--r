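# Elemental formulas and natural isotope abundances.
#
# Abundances are stored as mass-shift distributions: element E maps to a
# vector p where p[k+1] is the probability that one atom of E carries a
# mass shift of k (in integer mass units) from naturally occurring heavy
# isotopes. 36S (shift +4) is retained even though it is negligible.
.isotope_shift_dists <- list(
  C  = c(0.98930, 0.01070),            # 12C, 13C
  H  = c(0.999885, 0.000115),          # 1H, 2H
  N  = c(0.99636, 0.00364),            # 14N, 15N
  O  = c(0.99757, 0.00038, 0.00205),   # 16O, 17O, 18O
  Si = c(0.92223, 0.04685, 0.03092),   # 28Si, 29Si, 30Si
  S  = c(0.94990, 0.00750, 0.04250, 0.00000, 0.00010), # 32-36S
  P  = 1.0                             # monoisotopic
)

#' Natural isotope abundance table
#'
#' Mass-shift probability distributions of the elements handled by the
#' natural-abundance correction, from standard terrestrial abundances
#' (13C 0.0107, 2H 0.000115, 15N 0.00364, 17O/18O, 29Si/30Si, 33S/34S/36S).
#' Element `E` maps to a vector `p` with `p[k + 1]` the probability that a
#' single atom of `E` is observed `k` mass units heavy.
#'
#' @param element Optional element symbol; if given, only that element's
#'   distribution is returned.
#' @return A named list of numeric probability vectors, or a single vector.
#' @export
#' @examples
#' isotope_abundances("C")
isotope_abundances <- function(element = NULL) {
  if (is.null(element)) return(.isotope_shift_dists)
  if (!element %in% names(.isotope_shift_dists)) {
    stop("no isotope data for element '", element, "'", call. = FALSE)
  }
  .isotope_shift_dists[[element]]
}

#' Parse an elemental formula in Hill notation
#'
#' Converts a formula string such as `"C11H25O3Si2"` (a TBDMS-derivatized
#' GC-MS fragment) into a named integer vector of atom counts. Counts
#' default to 1 when omitted; repeated element symbols are summed.
#'
#' @param formula Single formula string.
#' @return Named integer vector of atom counts.
#' @export
#' @examples
#' parse_formula("C11H25O3Si2")
parse_formula <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L || is.na(formula)) {
    stop("formula must be a single character string", call. = FALSE)
  }
  f <- trimws(formula)
  if (!nzchar(f)) stop("empty formula", call. = FALSE)
  tokens <- regmatches(f, gregexpr("[A-Z][a-z]?[0-9]*", f))[[1]]
  if (paste(tokens, collapse = "") != f) {
    stop("malformed formula '", formula, "': unparseable characters remain",
         call. = FALSE)
  }
  elem <- sub("[0-9]*$", "", tokens)
  cnt <- sub("^[A-Za-z]+", "", tokens)
  n <- ifelse(cnt == "", 1L, suppressWarnings(as.integer(cnt)))
  if (anyNA(n) || any(n < 1L)) {
    stop("malformed formula '", formula, "': atom counts must be positive",
         call. = FALSE)
  }
  out <- tapply(n, elem, sum)
  setNames(as.integer(out[unique(elem)]), unique(elem))
}

# coerce a formula argument (string or named count vector) to counts
.as_formula_counts <- function(fragment_formula) {
  if (is.character(fragment_formula)) return(parse_formula(fragment_formula))
  if (is.numeric(fragment_formula) && !is.null(names(fragment_formula))) {
    if (any(fragment_formula < 0) || any(fragment_formula != round(fragment_formula))) {
      stop("atom counts must be non-negative integers", call. = FALSE)
    }
    return(fragment_formula[fragment_formula > 0])
  }
  stop("fragment_formula must be a Hill-notation string or a named count vector",
       call. = FALSE)
}

# discrete convolution of two probability vectors (polynomial product)
.conv <- function(a, b) {
  if (length(a) == 0L) return(b)
  if (length(b) == 0L) return(a)
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

# mass-shift distribution of k iid atoms with single-atom distribution p
.conv_atoms <- function(p, k) {
  out <- 1.0
  if (k <= 0L) return(out)
  for (i in seq_len(k)) out <- .conv(out, p)
  out
}
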