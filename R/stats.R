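# Group-comparison workflow: normality-routed test selection, multiplicity
# correction, altered-feature counting, z-scores, PCA summaries.

#' Choose a test family by the normality cascade
#'
#' Each group is tested for normality with Shapiro-Wilk. If every group
#' passes at `alpha`, a parametric test on the raw scale is chosen (t for
#' two groups, one-way ANOVA for more). Otherwise, if all values are
#' strictly positive, the data are log-transformed and retested; if every
#' group then passes, the parametric family is used on the log scale.
#' Failing that, the nonparametric route is taken (Mann-Whitney for two
#' groups, Kruskal-Wallis plus Dunn's post hoc for more). Groups smaller
#' than 3 cannot be tested for normality and route nonparametric with a
#' warning. The "all groups must pass" rule is the conservative reading of
#' per-group normality testing.
#'
#' @param groups Named list of numeric vectors, one per group (>= 2 groups).
#' @param alpha Significance level for the Shapiro-Wilk tests.
#' @param control Optional control-group name; with a parametric family and
#'   more than two groups the post hoc becomes Dunnett versus this group
#'   instead of Tukey all-pairs.
#' @return A `test_decision`: list with `transform` (`"none"`/`"log"`),
#'   `family` (`"t"`, `"anova"`, `"mann_whitney"`, `"kruskal"`), `posthoc`
#'   (`"tukey"`, `"dunnett"`, `"dunn"`, `"none"`), and the per-group
#'   Shapiro-Wilk p-values that drove the decision.
#' @export
normality_route <- function(groups, alpha = 0.05, control = NULL) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("groups must be a list of >= 2 numeric vectors", call. = FALSE)
  }
  if (any(vapply(groups, length, integer(1)) == 0L)) {
    stop("empty group", call. = FALSE)
  }
  k <- length(groups)
  parametric_family <- if (k == 2L) "t" else "anova"
  parametric_posthoc <- if (k == 2L) "none"
                        else if (!is.null(control)) "dunnett" else "tukey"
  nonparametric <- list(
    transform = "none",
    family = if (k == 2L) "mann_whitney" else "kruskal",
    posthoc = if (k == 2L) "none" else "dunn")
  shapiro_safe <- function(x) {
    if (length(unique(x)) == 1L) return(0)  # degenerate: not normal
    shapiro.test(x)$p.value
  }
  decision <- function(transform, family, posthoc, p_raw, p_log = NULL) {
    structure(list(transform = transform, family = family, posthoc = posthoc,
                   shapiro_p = p_raw, shapiro_p_log = p_log,
                   control = control),
              class = "test_decision")
  }
  if (any(vapply(groups, length, integer(1)) < 3L)) {
    warning("groups with n < 3 cannot be tested for normality; ",
            "routing nonparametric", call. = FALSE)
    return(decision(nonparametric$transform, nonparametric$family,
                    nonparametric$posthoc, p_raw = rep(NA_real_, k)))
  }
  p_raw <- vapply(groups, shapiro_safe, numeric(1))
  if (all(p_raw > alpha)) {
    return(decision("none", parametric_family, parametric_posthoc, p_raw))
  }
  if (all(unlist(groups) > 0)) {
    p_log <- vapply(lapply(groups, log), shapiro_safe, numeric(1))
    if (all(p_log > alpha)) {
      return(decision("log", parametric_family, parametric_posthoc,
                      p_raw, p_log))
    }
    return(decision(nonparametric$transform, nonparametric$family,
                    nonparametric$posthoc, p_raw, p_log))
  }
  decision(nonparametric$transform, nonparametric$family,
           nonparametric$posthoc, p_raw)
}

# Dunn's post hoc for Kruskal-Wallis: pairwise z tests on mean ranks with
# tie correction, Bonferroni-adjusted. No installed package provides this.
.dunn_test <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  N <- length(x)
  r <- rank(x)
  ties <- table(x)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  combs <- utils::combn(names(groups), 2L)
  p <- apply(combs, 2L, function(pr) {
    z <- (rbar[[pr[1]]] - rbar[[pr[2]]]) /
      sqrt(s2 * (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
    2 * pnorm(-abs(z))
  })
  data.frame(comparison = apply(combs, 2L, paste, collapse = "-"),
             p = as.numeric(p),
             p_adj = pmin(1, as.numeric(p) * ncol(combs)),
             stringsAsFactors = FALSE)
}

#' Compare groups for one feature under a routing decision
#'
#' Two groups: two-tailed Student's t (equal variances, optionally on log
#' scale) or Mann-Whitney. More groups: one-way ANOVA with Tukey all-pairs
#' or Dunnett-versus-control post hoc, or Kruskal-Wallis with Dunn's post
#' hoc. If the parametric family meets degenerate (zero) variance, the
#' comparison falls back to the nonparametric test with a warning.
#'
#' @param groups Named list of numeric group vectors.
#' @param decision A `test_decision` from [normality_route()]; computed on
#'   the fly if `NULL`.
#' @param alpha Alpha forwarded to [normality_route()] when routing here.
#' @param control Control-group name forwarded to [normality_route()].
#' @return List with `p` (two-group p-value or omnibus p), `posthoc`
#'   (data.frame of adjusted pairwise p-values, or `NULL`), and the
#'   `decision` used.
#' @export
compare_feature <- function(groups, decision = NULL, alpha = 0.05,
                            control = NULL) {
  if (is.null(decision)) {
    decision <- normality_route(groups, alpha = alpha, control = control)
  }
  if (decision$transform == "log") groups <- lapply(groups, log)
  k <- length(groups)
  degenerate <- var(unlist(groups)) == 0 ||
    all(vapply(groups, function(g) var(g) == 0, logical(1)))
  if (decision$family %in% c("t", "anova") && degenerate &&
      var(unlist(groups)) > 0) {
    warning("degenerate within-group variance; falling back to ",
            "nonparametric test", call. = FALSE)
    decision$family <- if (k == 2L) "mann_whitney" else "kruskal"
    decision$posthoc <- if (k == 2L) "none" else "dunn"
  }
  if (var(unlist(groups)) == 0) {
    # all observations identical: no evidence of any effect
    return(list(p = 1, posthoc = NULL, decision = decision))
  }
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (k == 2L) {
    p <- switch(decision$family,
      t = t.test(groups[[1]], groups[[2]], var.equal = TRUE)$p.value,
      mann_whitney = suppressWarnings(
        wilcox.test(groups[[1]], groups[[2]])$p.value),
      stop("family '", decision$family, "' is not valid for 2 groups",
           call. = FALSE))
    return(list(p = p, posthoc = NULL, decision = decision))
  }
  if (decision$family == "anova") {
    fit <- aov(x ~ g)
    p <- summary(fit)[[1]][["Pr(>F)"]][1]
    posthoc <- if (decision$posthoc == "dunnett") {
      if (is.null(decision$control)) {
        stop("Dunnett post hoc requires a named control group", call. = FALSE)
      }
      g2 <- stats::relevel(g, ref = decision$control)
      fit2 <- aov(x ~ g2)
      ht <- summary(glht(fit2, linfct = mcp(g2 = "Dunnett")))
      data.frame(comparison = names(ht$test$coefficients),
                 p_adj = as.numeric(ht$test$pvalues),
                 stringsAsFactors = FALSE)
    } else {
      tk <- TukeyHSD(fit)$g
      data.frame(comparison = rownames(tk), p_adj = tk[, "p adj"],
                 stringsAsFactors = FALSE, row.names = NULL)
    }
    return(list(p = p, posthoc = posthoc, decision = decision))
  }
  if (decision$family == "kruskal") {
    p <- kruskal.test(x, g)$p.value
    return(list(p = p, posthoc = .dunn_test(groups), decision = decision))
  }
  stop("unsupported family '", decision$family, "'", call. = FALSE)
}

#' Bonferroni adjustment of a p-value vector
#'
#' `min(1, m * p)` per test; monotone and order preserving.
#'
#' @param pvals Raw p-values in `[0, 1]`.
#' @param method Only `"bonferroni"` is offered here; other methods should
#'   go through [stats::p.adjust()] directly.
#' @return Adjusted p-values.
#' @export
adjust_multiplicity <- function(pvals, method = "bonferroni") {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = method)
}

#' Per-feature group tests across a tidy feature table
#'
#' Applies either plain multiple two-tailed t tests (the convention for
#' metabolomics/proteomics abundance screens) or the full normality-routed
#' cascade to every feature of a tidy table, then adjusts across features.
#'
#' @param feature_table data.frame with columns `sample_id`, `group`,
#'   `feature`, `value`.
#' @param method `"multiple_t"` or `"cascade"`.
#' @param adjust Multiplicity method (default `"bonferroni"`).
#' @param control Optional control group (cascade post hocs only).
#' @return data.frame with `feature`, `p`, `p_adj`.
#' @export
run_feature_stats <- function(feature_table,
                              method = c("multiple_t", "cascade"),
                              adjust = "bonferroni", control = NULL) {
  method <- match.arg(method)
  need <- c("group", "feature", "value")
  if (!all(need %in% names(feature_table))) {
    stop("feature table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  feats <- unique(feature_table$feature)
  p <- vapply(feats, function(f) {
    d <- feature_table[feature_table$feature == f, ]
    groups <- split(d$value, d$group)
    if (method == "multiple_t") {
      if (var(d$value) == 0) return(1)
      t.test(groups[[1]], groups[[2]], var.equal = TRUE)$p.value
    } else {
      compare_feature(groups, control = control)$p
    }
  }, numeric(1))
  data.frame(feature = feats, p = unname(p),
             p_adj = adjust_multiplicity(unname(p), adjust),
             stringsAsFactors = FALSE)
}

#' Count significantly altered features
#'
#' @param feature_stats data.frame with a `p_adj` column (e.g. from
#'   [run_feature_stats()]), or a numeric vector of adjusted p-values.
#' @param alpha Significance threshold on adjusted p-values.
#' @return List: `n_significant`, `n_total`, `percent` (rounded to the
#'   nearest integer).
#' @export
#' @examples
#' count_altered(c(rep(0.001, 64), rep(0.9, 123)))  # 64 of 187 -> 34%
count_altered <- function(feature_stats, alpha = 0.05) {
  p <- if (is.data.frame(feature_stats)) feature_stats$p_adj
       else as.numeric(feature_stats)
  if (length(p) == 0L || is.null(p)) {
    stop("no adjusted p-values supplied", call. = FALSE)
  }
  n_sig <- sum(p < alpha)
  list(n_significant = n_sig, n_total = length(p),
       percent = round(100 * n_sig / length(p)))
}

#' Row-wise z-score matrix
#'
#' Centers and scales each feature row to mean 0, SD 1 (for heatmaps).
#' Zero-variance rows cannot be scaled; they are set to 0 and reported in
#' the `flagged` attribute rather than dropped silently.
#'
#' @param feature_table Numeric matrix, features x samples.
#' @return Matrix of z-scores with attribute `flagged` (row names or
#'   indices of constant rows).
#' @export
zscore_matrix <- function(feature_table) {
  m <- as.matrix(feature_table)
  mu <- rowMeans(m)
  s <- apply(m, 1L, sd)
  flagged <- which(s == 0)
  z <- (m - mu) / ifelse(s == 0, 1, s)
  z[flagged, ] <- 0
  attr(z, "flagged") <- if (!is.null(rownames(m))) rownames(m)[flagged]
                        else unname(flagged)
  z
}

#' PCA scores, explained variance and group confidence ellipses
#'
#' Principal components of a samples x features table with percent of total
#' variance per component and, when group labels are given, a 95% confidence
#' ellipse per group (covariance ellipse of the group's scores scaled by
#' `qchisq(0.95, 2)`).
#'
#' @param feature_table Numeric matrix, samples in rows.
#' @param n_components Number of components to report.
#' @param groups Optional factor/character vector of group labels.
#' @param scale. Scale features to unit variance before PCA.
#' @param ellipse_level Confidence level of the group ellipses.
#' @return List: `scores` (samples x n_components), `percent_variance`
#'   (all components), `loadings`, `ellipses` (per group: center, covariance,
#'   squared radius), or `NULL` without groups.
#' @export
pca_summary <- function(feature_table, n_components = 2L, groups = NULL,
                        scale. = FALSE, ellipse_level = 0.95) {
  m <- as.matrix(feature_table)
  if (nrow(m) < n_components) {
    stop("fewer samples (", nrow(m), ") than components (", n_components, ")",
         call. = FALSE)
  }
  if (nrow(m) < 3L) stop("PCA summary requires >= 3 samples", call. = FALSE)
  keep <- apply(m, 2L, var) > 0 | !scale.
  fit <- prcomp(m[, keep, drop = FALSE], center = TRUE, scale. = scale.)
  pct <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  scores <- fit$x[, seq_len(n_components), drop = FALSE]
  ellipses <- NULL
  if (!is.null(groups)) {
    groups <- as.character(groups)
    ellipses <- lapply(split(seq_len(nrow(m)), groups), function(idx) {
      sc <- scores[idx, , drop = FALSE]
      list(center = colMeans(sc),
           cov = if (length(idx) > 2L) cov(sc) else NULL,
           radius2 = qchisq(ellipse_level, df = 2L),
           n = length(idx))
    })
  }
  list(scores = scores, percent_variance = pct,
       loadings = fit$rotation[, seq_len(n_components), drop = FALSE],
       ellipses = ellipses)
}
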