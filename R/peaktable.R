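# Peak-table I/O: tidy CSVs of integrated GC-MS ion areas.

.peak_cols <- c("sample_id", "arm_label", "compartment", "metabolite",
                "isotopolog_index", "area")
.compartments <- c("plasma", "tissue", "medium")

#' Read a peak table CSV
#'
#' Peak tables are tidy CSVs with one row per integrated isotopolog ion:
#' `sample_id,arm_label,compartment,metabolite,isotopolog_index,area`
#' plus an optional `tissue_weight_mg` column. Isotopolog indices are
#' 0-based mass shifts (`0` = unlabeled, i.e. m+0). Missing isotopolog
#' rows are never imputed; downstream correction requires a complete
#' `0..max` block per (sample, compartment, metabolite).
#'
#' @param path CSV path.
#' @return A validated `data.frame` of class `peak_table`. An empty file
#'   (header only) yields an empty table with a warning.
#' @export
read_peak_table <- function(path) {
  if (!file.exists(path)) stop("peak table not found: ", path, call. = FALSE)
  pt <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(pt) == 0L) {
    warning("peak table '", path, "' contains no data rows", call. = FALSE)
  }
  validate_peak_table(pt)
}

#' Validate a peak table
#'
#' Enforces the schema contract: required columns present, compartments
#' within the fixed vocabulary (`plasma`, `tissue`, `medium`; unknown values
#' are rejected rather than coerced), integer indices >= 0, finite
#' non-negative areas, positive tissue weights where given, and no duplicate
#' (sample, compartment, metabolite, isotopolog) keys. If a registry is
#' supplied, isotopolog indices may not exceed that metabolite's
#' `n_tracer_atoms + max_extra_shift` (the natural-abundance tail).
#'
#' @param pt A data.frame with peak-table columns.
#' @param registry Optional `metabolite_registry` for index bounds.
#' @param max_extra_shift Allowed shift beyond `n_tracer_atoms` for raw
#'   (uncorrected) tables; default 3 matches the Si/S isotope tail of TBDMS
#'   fragments.
#' @return The table, classed `peak_table`.
#' @export
validate_peak_table <- function(pt, registry = NULL, max_extra_shift = 3L) {
  missing <- setdiff(.peak_cols, names(pt))
  if (length(missing)) {
    stop("peak table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(pt) > 0L) {
    bad <- setdiff(unique(pt$compartment), .compartments)
    if (length(bad)) {
      stop("unknown compartment value(s): ", paste(bad, collapse = ", "),
           "; expected one of ", paste(.compartments, collapse = "/"),
           call. = FALSE)
    }
    idx <- pt$isotopolog_index
    if (anyNA(idx) || any(idx < 0) || any(idx != round(idx))) {
      stop("isotopolog_index must be integers >= 0", call. = FALSE)
    }
    if (anyNA(pt$area) || any(!is.finite(pt$area))) {
      stop("areas must be finite", call. = FALSE)
    }
    if (any(pt$area < 0)) {
      stop("negative ion areas in rows: ",
           paste(which(pt$area < 0), collapse = ", "), call. = FALSE)
    }
    key <- paste(pt$sample_id, pt$compartment, pt$metabolite,
                 pt$isotopolog_index, sep = "\r")
    if (anyDuplicated(key)) {
      off <- pt[duplicated(key), c("sample_id", "compartment", "metabolite",
                                   "isotopolog_index")]
      stop("duplicate peak-table keys: ",
           paste(apply(off, 1L, paste, collapse = "/"), collapse = "; "),
           call. = FALSE)
    }
    if ("tissue_weight_mg" %in% names(pt)) {
      w <- pt$tissue_weight_mg
      if (any(!is.na(w) & w <= 0)) {
        stop("tissue_weight_mg must be positive", call. = FALSE)
      }
    }
    if (!is.null(registry)) {
      for (m in unique(pt$metabolite)) {
        n <- .registry_entry(registry, m)$n_tracer_atoms
        mx <- max(pt$isotopolog_index[pt$metabolite == m])
        if (mx > n + max_extra_shift) {
          stop("metabolite '", m, "' has isotopolog index ", mx,
               " beyond n_tracer_atoms + ", max_extra_shift, call. = FALSE)
        }
      }
    }
  }
  pt$isotopolog_index <- as.integer(pt$isotopolog_index)
  class(pt) <- unique(c("peak_table", class(pt)))
  pt
}

#' Write a peak table CSV
#'
#' @param pt A `peak_table`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_peak_table <- function(pt, path) {
  write.csv(as.data.frame(pt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write result tables and a machine-readable run summary
#'
#' Writes one tidy CSV per named result table plus `run_summary.json`
#' recording the seed, a hash of the configuration, and package/R versions.
#' Output is byte-identical across reruns with the same tables and config.
#'
#' @param tables Named list of data.frames (may be empty).
#' @param summary Named list of run metadata; a `seed` entry is recommended.
#' @param outdir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(tables, summary, outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", outdir, call. = FALSE)
  }
  if (file.access(outdir, mode = 2L) != 0L) {
    stop("output directory is not writable: ", outdir, call. = FALSE)
  }
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(outdir, paste0(nm, ".csv"))
    write.csv(as.data.frame(tables[[nm]]), p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  cfg <- summary[order(names(summary))]
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeLines(paste(names(cfg), vapply(cfg, function(x)
    paste(format(x), collapse = ","), character(1)), sep = "="), tmp)
  run <- c(summary, list(
    config_hash = unname(md5sum(tmp)),
    package_version = as.character(packageVersion("midflux")),
    r_version = paste(R.version$major, R.version$minor, sep = ".")
  ))
  sp <- file.path(outdir, "run_summary.json")
  write_json(run, sp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, sp))
}
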