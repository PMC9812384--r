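# Metabolite registry: fragment formulas and labelable-atom counts.

.pathway_tags <- c("glycolysis", "TCA", "amino acid", "nucleotide", "other")

#' Load a metabolite registry
#'
#' A registry maps each metabolite to the elemental formula of the GC-MS
#' fragment that was integrated (derivatized form, including Si and C added
#' by TBDMS groups), the number of carbon positions that can carry tracer
#' label, and a pathway tag. The packaged default covers the central-carbon
#' set (glucose, G6P, 3PG, PEP, pyruvate, lactate, alanine, citrate,
#' glutamate, fumarate, malate) with conventional methoxime-TBDMS M-57
#' fragments; the study's actual integrated fragments are instrument
#' specific, so the defaults are explicitly replaceable by supplying a CSV
#' with columns `metabolite,fragment_formula,n_tracer_atoms,pathway_tag`.
#'
#' @param path Path to a registry CSV; `NULL` loads the packaged default.
#' @return A `data.frame` of class `metabolite_registry`.
#' @export
#' @examples
#' reg <- load_registry()
#' reg[reg$metabolite == "lactate", ]
load_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_registry.csv", package = "midflux")
  }
  if (!file.exists(path)) stop("registry file not found: ", path, call. = FALSE)
  reg <- read.csv(path, stringsAsFactors = FALSE)
  validate_registry(reg)
}

#' Validate a metabolite registry
#'
#' Checks the invariants every registry must satisfy: unique metabolite
#' names, parseable formulas, at least one labelable atom, and no more
#' labelable carbons than the fragment contains.
#'
#' @param reg A data.frame with the registry columns.
#' @return The validated registry (invisibly classed).
#' @export
validate_registry <- function(reg) {
  required <- c("metabolite", "fragment_formula", "n_tracer_atoms", "pathway_tag")
  missing <- setdiff(required, names(reg))
  if (length(missing)) {
    stop("registry is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dup <- unique(reg$metabolite[duplicated(reg$metabolite)])
  if (length(dup)) {
    stop("duplicate registry entries: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(reg))) {
    counts <- tryCatch(parse_formula(reg$fragment_formula[i]), error = function(e) {
      stop("registry line ", i, " (", reg$metabolite[i], "): ",
           conditionMessage(e), call. = FALSE)
    })
    n <- reg$n_tracer_atoms[i]
    if (!is.finite(n) || n < 1 || n != round(n)) {
      stop("registry line ", i, " (", reg$metabolite[i],
           "): n_tracer_atoms must be a positive integer", call. = FALSE)
    }
    nc <- if ("C" %in% names(counts)) counts[["C"]] else 0L
    if (n > nc) {
      stop("registry line ", i, " (", reg$metabolite[i],
           "): n_tracer_atoms (", n, ") exceeds fragment carbons (", nc, ")",
           call. = FALSE)
    }
    if (!reg$pathway_tag[i] %in% .pathway_tags) {
      stop("registry line ", i, " (", reg$metabolite[i],
           "): unknown pathway_tag '", reg$pathway_tag[i], "'", call. = FALSE)
    }
  }
  reg$n_tracer_atoms <- as.integer(reg$n_tracer_atoms)
  class(reg) <- c("metabolite_registry", "data.frame")
  reg
}

# lookup helper; errors if the metabolite is not registered
.registry_entry <- function(reg, metabolite) {
  i <- match(metabolite, reg$metabolite)
  if (is.na(i)) stop("metabolite '", metabolite, "' is not in the registry",
                     call. = FALSE)
  reg[i, , drop = FALSE]
}
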