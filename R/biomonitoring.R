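#' Substitute values below the limit of detection
#'
#' Biomonitoring and water measurements below the analytical limit of
#' detection (LOD) are replaced by LOD/2, the substitution convention used
#' for the non-detected water samples here. A value exactly at the LOD is
#' "not below" and is kept. The operation is idempotent provided
#' `lod/2 >= ` no further substitution threshold, i.e. applying it twice
#' changes nothing.
#'
#' @param values Numeric vector of concentrations, ug/L; must be
#'   non-negative unless flagged below-LOD.
#' @param lod Limit of detection, ug/L; must be positive.
#' @param below_lod Optional logical vector flagging censored entries;
#'   flagged entries are substituted regardless of their numeric value.
#' @return Numeric vector with below-LOD entries replaced by `lod / 2`.
#' @export
#' @examples
#' substitute_lod(c(0.04, 0.31, 0.05), lod = 0.05) # 0.025, 0.31, 0.05
substitute_lod <- function(values, lod, below_lod = NULL) {
  if (!is.finite(lod) || lod <= 0) {
    stop_domain("substitute_lod: lod must be positive")
  }
  if (is.null(below_lod)) {
    below_lod <- rep(FALSE, length(values))
  }
  if (length(below_lod) != length(values)) {
    stop_domain("substitute_lod: below_lod must match values in length")
  }
  if (any(values < 0 & !below_lod, na.rm = TRUE)) {
    stop_domain("substitute_lod: negative unflagged value")
  }
  replace_at <- below_lod | (!is.na(values) & values < lod)
  values[replace_at] <- lod / 2
  values
}

#' Mann-Whitney U test for two groups
#'
#' Two-sided nonparametric comparison of two groups, used for the
#' non-normally distributed internal-dose measurements. The U statistic
#' is computed from rank sums with midranks for ties. The p-value is
#' exact when the smaller group has at most 8 observations and there are
#' no ties, and otherwise uses the normal approximation with tie
#' correction (no continuity correction).
#'
#' @param a,b Numeric vectors, both non-empty.
#' @param labels Character vector of length 2 naming the groups.
#' @return A `group_comparison` list: `labels`, `n` (per group), `U`,
#'   `p_value`, `mean` and `median` per group, and `method`.
#' @export
#' @examples
#' mann_whitney(c(1, 2), c(3, 4)) # U = 0, exact p = 1/3
mann_whitney <- function(a, b, labels = c("a", "b")) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L) {
    stop_domain("mann_whitney: both groups must be non-empty")
  }
  has_ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !has_ties && min(length(a), length(b)) <= 8L
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = FALSE)
  )
  structure(list(labels = labels,
                 n = c(length(a), length(b)),
                 U = unname(wt$statistic),
                 p_value = min(wt$p.value, 1),
                 mean = c(mean(a), mean(b)),
                 median = c(stats::median(a), stats::median(b)),
                 method = if (exact) "exact" else "normal approximation"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U test (%s, two-sided)\n", x$method))
  cat(sprintf("  %s: n=%d mean=%.3f median=%.3f\n", x$labels[1], x$n[1],
              x$mean[1], x$median[1]))
  cat(sprintf("  %s: n=%d mean=%.3f median=%.3f\n", x$labels[2], x$n[2],
              x$mean[2], x$median[2]))
  cat(sprintf("  U = %.1f, p = %.4g\n", x$U, x$p_value))
  invisible(x)
}

#' Correlation between external and internal dose
#'
#' Pearson (default) or Spearman correlation with a two-sided
#' t-approximation p-value, as used to relate environmental cadmium
#' exposure to blood cadmium and age to urinary cadmium. Spearman
#' operates on midranks.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @param method `"pearson"` or `"spearman"`.
#' @return A `correlation_result` list: `method`, `r`, `p_value`, `n`.
#' @export
#' @examples
#' dose_correlation(1:10, 2 * (1:10) + 1)$r # 1
dose_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) != length(y) || length(x) < 3L) {
    stop_domain("dose_correlation: need equal-length vectors with >= 3 ",
                "complete pairs")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop_domain("dose_correlation: undefined for zero-variance input")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, alternative = "two.sided",
                    exact = FALSE)
  )
  structure(list(method = method, r = unname(ct$estimate),
                 p_value = ct$p.value, n = length(x)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.3f, p = %.4g, n = %d\n",
              tools::toTitleCase(x$method), x$r, x$p_value, x$n))
  invisible(x)
}

#' Biomonitoring statistics for a cohort
#'
#' Runs the standard internal-dose analyses on an individual-level cohort
#' table: group summaries and Mann-Whitney comparisons of blood cadmium
#' (BCd) and urinary cadmium (UCd) by sex and by smoking status, and the
#' three external-internal correlations — UCd vs age, BCd vs total
#' environmental exposure, and BCd vs tobacco cadmium intake among
#' smokers.
#'
#' @param cohort A `cohort_table` (see [read_cohort_table()],
#'   [generate_cohort()]).
#' @param records A `food_table` supplying mean concentrations for the
#'   per-individual exposure computation.
#' @param config An [exposure_config()].
#' @param method Correlation method, `"pearson"` (default) or
#'   `"spearman"`.
#' @return A `biomonitoring_stats` list: `comparisons` (named list of
#'   `group_comparison`s: `bcd_by_sex`, `ucd_by_sex`, `bcd_by_smoking`,
#'   `ucd_by_smoking`), `correlations` (named list of
#'   `correlation_result`s: `ucd_age`, `bcd_exposure`,
#'   `bcd_tobacco_smokers`) and `exposure` (the per-individual exposure
#'   frame from [cohort_exposures()]).
#' @export
biomonitoring_stats <- function(cohort, records = shanghai_food_table(),
                                config = exposure_config(),
                                method = "pearson") {
  stopifnot(inherits(cohort, "cohort_table"))
  expo <- cohort_exposures(cohort, records, config)
  male <- cohort$sex == "male"
  smoker <- cohort$smoker
  comparisons <- list(
    bcd_by_sex = mann_whitney(cohort$bcd[male], cohort$bcd[!male],
                              labels = c("male", "female")),
    ucd_by_sex = mann_whitney(cohort$ucd[male], cohort$ucd[!male],
                              labels = c("male", "female")),
    bcd_by_smoking = mann_whitney(cohort$bcd[smoker], cohort$bcd[!smoker],
                                  labels = c("smoker", "nonsmoker")),
    ucd_by_smoking = mann_whitney(cohort$ucd[smoker], cohort$ucd[!smoker],
                                  labels = c("smoker", "nonsmoker"))
  )
  correlations <- list(
    ucd_age = dose_correlation(cohort$age, cohort$ucd, method = method),
    bcd_exposure = dose_correlation(expo$total, cohort$bcd, method = method),
    bcd_tobacco_smokers = dose_correlation(expo$tobacco[smoker],
                                           cohort$bcd[smoker],
                                           method = method)
  )
  structure(list(comparisons = comparisons, correlations = correlations,
                 exposure = expo),
            class = "biomonitoring_stats")
}

#' @export
print.biomonitoring_stats <- function(x, ...) {
  cat("Biomonitoring statistics\n\nGroup comparisons:\n")
  for (nm in names(x$comparisons)) {
    cc <- x$comparisons[[nm]]
    cat(sprintf("  %-16s U = %8.1f  p = %.4g  (%s %.2f vs %s %.2f ug/L)\n",
                nm, cc$U, cc$p_value, cc$labels[1], cc$mean[1],
                cc$labels[2], cc$mean[2]))
  }
  cat("\nCorrelations:\n")
  for (nm in names(x$correlations)) {
    cr <- x$correlations[[nm]]
    cat(sprintf("  %-20s r = %6.3f  p = %.4g  (n = %d)\n", nm, cr$r,
                cr$p_value, cr$n))
  }
  invisible(x)
}

#' Write biomonitoring statistics to JSON
#'
#' @param x A `biomonitoring_stats`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_biomonitoring_stats <- function(x, path) {
  stopifnot(inherits(x, "biomonitoring_stats"))
  out <- list(
    comparisons = lapply(x$comparisons, function(cc) {
      list(labels = cc$labels, n = cc$n, U = cc$U, p_value = cc$p_value,
           mean = cc$mean, median = cc$median, method = cc$method)
    }),
    correlations = lapply(x$correlations, unclass)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
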