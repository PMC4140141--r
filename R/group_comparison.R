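#' Chi-squared test of probe-sign composition across gene groups
#'
#' Builds the gene-group x {negative, positive} contingency table of
#' significant probes (zero-sign probes are excluded — only the two signs
#' are tabulated) and applies Pearson's chi-squared test without continuity
#' correction. A matrix of counts with columns `negative` and `positive`
#' can be supplied directly, e.g. to test a published table.
#'
#' @param x A `probe_stats` data frame (see [filter_significant()]) or a
#'   counts matrix (rows = groups, columns = negative/positive).
#' @return A list of class `sign_contingency` with the table, expected
#'   counts, `chi2`, `dof` and `p_value`. If any expected cell is below 1
#'   a warning string is attached as `$warning`.
#' @examples
#' counts <- rbind(immune = c(2026, 3285), cellcycle = c(1010, 3427),
#'                 stable = c(485, 1816))
#' colnames(counts) <- c("negative", "positive")
#' sign_contingency_test(counts)$p_value  # < 2.2e-16
#' @export
sign_contingency_test <- function(x) {
  if (is.matrix(x)) {
    tab <- x
  } else {
    stopifnot(is.data.frame(x))
    signed <- x[x$sign %in% c("negative", "positive"), , drop = FALSE]
    if (!nrow(signed)) stop("no signed probes to tabulate")
    tab <- table(signed$group,
                 factor(signed$sign, levels = c("negative", "positive")))
    tab <- unclass(tab)
  }
  if (nrow(tab) < 2) stop("need at least 2 groups")
  if (any(rowSums(tab) == 0)) stop("every group needs at least one signed probe")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  out <- list(table = tab,
              expected = ct$expected,
              chi2 = unname(ct$statistic),
              dof = unname(ct$parameter),
              p_value = ct$p.value)
  if (any(ct$expected < 1))
    out$warning <- "expected cell count below 1; chi-squared approximation unreliable"
  class(out) <- "sign_contingency"
  out
}

#' @export
print.sign_contingency <- function(x, ...) {
  cat("probe-sign contingency (Pearson chi-squared, no continuity correction)\n")
  print(x$table)
  cat(sprintf("chi2 = %.4g, df = %d, p = %.4g\n", x$chi2, x$dof, x$p_value))
  if (!is.null(x$warning)) cat("warning:", x$warning, "\n")
  invisible(x)
}

#' F test comparing methyl-score dispersion between two groups
#'
#' Two-sided F test of the variance ratio `var(a) / var(b)` with
#' `(length(a) - 1, length(b) - 1)` degrees of freedom, used to ask whether
#' one gene group's methyl scores are more spread out than another's.
#'
#' @param scores_a,scores_b Numeric vectors of methyl scores (>= 2 values,
#'   non-zero variance each).
#' @param conf_level Confidence level for the reported interval.
#' @return A list with `F_ratio`, `dof`, `p_value` and `conf_int`.
#' @export
score_dispersion_test <- function(scores_a, scores_b, conf_level = 0.95) {
  scores_a <- scores_a[!is.na(scores_a)]
  scores_b <- scores_b[!is.na(scores_b)]
  if (length(scores_a) < 2 || length(scores_b) < 2)
    stop("need at least 2 values per group")
  if (stats::var(scores_a) == 0 || stats::var(scores_b) == 0)
    stop("zero variance in one of the groups")
  ft <- stats::var.test(scores_a, scores_b, conf.level = conf_level)
  list(F_ratio = unname(ft$statistic),
       dof = unname(ft$parameter),
       p_value = ft$p.value,
       conf_int = as.numeric(ft$conf.int))
}

#' Pairwise or pooled dispersion comparison across gene groups
#'
#' Compares a reference group's methyl-score variance against every other
#' group (pairwise, the default) or against all other groups pooled.
#'
#' @param stats A `probe_stats` data frame.
#' @param reference Group whose dispersion is compared.
#' @param mode `"pairwise"` or `"pooled"`.
#' @return A data frame with one row per comparison.
#' @export
score_dispersion <- function(stats, reference = "immune",
                             mode = c("pairwise", "pooled")) {
  mode <- match.arg(mode)
  stopifnot(reference %in% stats$group)
  a <- stats$methyl_score[stats$group == reference]
  others <- setdiff(unique(stats$group), reference)
  if (mode == "pooled") {
    b <- stats$methyl_score[stats$group != reference]
    res <- score_dispersion_test(a, b)
    return(data.frame(comparison = paste0(reference, " vs pooled"),
                      F_ratio = res$F_ratio, p_value = res$p_value))
  }
  do.call(rbind, lapply(others, function(g) {
    res <- score_dispersion_test(a, stats$methyl_score[stats$group == g])
    data.frame(comparison = paste0(reference, " vs ", g),
               F_ratio = res$F_ratio, p_value = res$p_value)
  }))
}

#' Per-group methyl-score summaries
#'
#' Median, quartiles and interquartile range per gene group, using type-7
#' (linear interpolation) quantiles so boxplot-style figures are exactly
#' reproducible.
#'
#' @param stats A `probe_stats` data frame, or a named list of numeric
#'   vectors of scores.
#' @return A data frame with columns `group`, `n`, `min`, `q1`, `median`,
#'   `q3`, `max`, `iqr`.
#' @export
score_summary <- function(stats) {
  by_group <- if (is.data.frame(stats))
    split(stats$methyl_score, stats$group)
  else stats
  stopifnot(length(by_group) > 0, all(lengths(by_group) > 0))
  do.call(rbind, lapply(names(by_group), function(g) {
    v <- by_group[[g]][!is.na(by_group[[g]])]
    qs <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
    data.frame(group = g, n = length(v), min = qs[1], q1 = qs[2],
               median = qs[3], q3 = qs[4], max = qs[5], iqr = qs[4] - qs[2])
  }))
}
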