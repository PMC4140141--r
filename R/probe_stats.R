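#' Two-sided Mann-Whitney p-value for one probe
#'
#' Compares the beta values of the disease and healthy groups with the
#' two-sample Mann-Whitney (Wilcoxon rank-sum) test. The exact null
#' distribution is used when both groups have at most 10 observations and
#' there are no ties; otherwise the tie-corrected normal approximation with
#' continuity correction is used. If every value is identical across both
#' groups the test is degenerate and p = 1 is returned.
#'
#' @param x,y Numeric vectors (disease and healthy betas); at least 2
#'   non-missing values each.
#' @return Two-sided p-value.
#' @examples
#' mw_probe_test(c(1, 2, 3), c(4, 5, 6))  # 0.1
#' @export
mw_probe_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("need at least 2 non-missing values per group")
  if (length(unique(c(x, y))) == 1L) return(1)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= 10 && length(y) <= 10
  p <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE)$p.value)
  if (!is.finite(p)) p <- 1
  min(p, 1)
}

#' Methyl score of one probe
#'
#' The methyl score is the mean beta value in the disease group minus the
#' mean in the healthy group, computed on non-missing values. Probes with a
#' negative score ("negative probes") are less methylated in disease.
#'
#' @inheritParams mw_probe_test
#' @return Mean difference in `[-1, 1]`.
#' @export
methyl_score <- function(x, y) {
  mean(x, na.rm = TRUE) - mean(y, na.rm = TRUE)
}

#' False-discovery-rate q-values
#'
#' Converts p-values to q-values either with Storey's method (the default:
#' the null proportion pi0 is estimated on the lambda grid 0.05, 0.10, ...,
#' 0.95 via a cubic smoothing spline evaluated at the largest lambda, and
#' `q = cummin(pi0 * m * p / rank)` capped at 1) or with the
#' Benjamini-Hochberg step-up (equivalent to Storey with pi0 fixed at 1).
#'
#' @param p Numeric vector of p-values in `[0, 1]`; no NaN allowed.
#' @param method `"storey"` or `"bh"`.
#' @param lambda Grid for the pi0 estimate (Storey only).
#' @return Vector of q-values, with the pi0 estimate attached as attribute
#'   `"pi0"` for the Storey method.
#' @export
compute_qvalues <- function(p, method = c("storey", "bh"),
                            lambda = seq(0.05, 0.95, by = 0.05)) {
  method <- match.arg(method)
  if (!length(p)) stop("empty p-value vector")
  if (any(is.na(p))) stop("NaN/NA p-values not allowed")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (method == "bh") return(stats::p.adjust(p, method = "BH"))
  pi0 <- estimate_pi0(p, lambda)
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(pi0 * m * p[o] / (m:1)))
  q <- q[order(o)]
  attr(q, "pi0") <- pi0
  q
}

#' @rdname compute_qvalues
#' @export
estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  pi0_raw <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_raw, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  if (pi0 <= 0) {
    warning("pi0 estimate <= 0; clamped to 1/m")
    pi0 <- 1 / length(p)
  }
  min(pi0, 1)
}

#' Per-probe differential methylation screen
#'
#' The core fitting function: for every annotated probe it compares disease
#' and healthy beta values with the Mann-Whitney test ([mw_probe_test()]),
#' attaches an FDR q-value ([compute_qvalues()]), computes the methyl score
#' ([methyl_score()]) and classifies the probe's sign (negative = less
#' methylated in disease, positive = more, zero = identical means). Tests
#' run on beta values directly — rank tests are invariant to monotone
#' transforms, so an M-value transform would not change the p-values.
#'
#' Probes absent from the annotation, and probes with fewer than 2
#' non-missing values in either condition, are dropped with a message.
#'
#' @param beta A [beta_matrix()].
#' @param annotation Probe annotation data frame (see [read_annotation()]).
#' @param fdr_method `"storey"` (default) or `"bh"`.
#' @return An object of class `methdiff`: list with `stats` (data frame
#'   with columns `probe_id`, `gene_id`, `group`, `tss_offset`, `p_value`,
#'   `q_value`, `methyl_score`, `sign`), sample counts, `fdr_method`,
#'   `pi0` (Storey only) and the matched call.
#' @seealso [filter_significant()], [summary.methdiff()]
#' @examples
#' sim <- simulate_methylation(sim_config(
#'   genes_per_group = c(immune = 15, cellcycle = 10, stable = 8)))
#' fit <- meth_diff(sim$beta, sim$annotation)
#' fit
#' @export
meth_diff <- function(beta, annotation, fdr_method = c("storey", "bh")) {
  stopifnot(inherits(beta, "beta_matrix"))
  fdr_method <- match.arg(fdr_method)
  ann <- annotation[annotation$probe_id %in% rownames(beta$values), ,
                    drop = FALSE]
  n_unann <- nrow(beta$values) - length(unique(ann$probe_id))
  if (n_unann > 0)
    message(n_unann, " probe(s) without annotation dropped")
  if (!nrow(ann)) stop("no annotated probes in the beta matrix")
  values <- beta$values[ann$probe_id, , drop = FALSE]
  dis <- values[, beta$condition == "disease", drop = FALSE]
  hea <- values[, beta$condition == "healthy", drop = FALSE]

  ok <- rowSums(!is.na(dis)) >= 2 & rowSums(!is.na(hea)) >= 2
  if (any(!ok)) {
    message(sum(!ok), " probe(s) with < 2 non-missing values in a condition dropped")
    ann <- ann[ok, , drop = FALSE]
    dis <- dis[ok, , drop = FALSE]
    hea <- hea[ok, , drop = FALSE]
  }
  n <- nrow(ann)
  if (!n) stop("no probes left after missing-value filtering")

  p <- vapply(seq_len(n), function(i) mw_probe_test(dis[i, ], hea[i, ]),
              numeric(1))
  score <- rowMeans(dis, na.rm = TRUE) - rowMeans(hea, na.rm = TRUE)
  q <- compute_qvalues(p, method = fdr_method)
  sign_lab <- ifelse(score < 0, "negative", ifelse(score > 0, "positive", "zero"))

  stats_df <- data.frame(probe_id = ann$probe_id,
                         gene_id = ann$gene_id,
                         group = ann$group,
                         tss_offset = ann$tss_offset,
                         p_value = p,
                         q_value = as.numeric(q),
                         methyl_score = unname(score),
                         sign = sign_lab,
                         stringsAsFactors = FALSE)
  rownames(stats_df) <- NULL
  structure(list(stats = stats_df,
                 n_disease = ncol(dis), n_healthy = ncol(hea),
                 fdr_method = fdr_method,
                 pi0 = attr(q, "pi0"),
                 call = match.call()),
            class = "methdiff")
}

#' @export
print.methdiff <- function(x, ...) {
  cat(sprintf("methdiff: %d probes, %d disease vs %d healthy samples\n",
              nrow(x$stats), x$n_disease, x$n_healthy))
  cat(sprintf("  FDR: %s%s; %d probe(s) with q <= 0.05\n", x$fdr_method,
              if (!is.null(x$pi0)) sprintf(" (pi0 = %.3f)", x$pi0) else "",
              sum(x$stats$q_value <= 0.05)))
  invisible(x)
}

#' Summarise a differential methylation screen
#'
#' Counts significant probes and their signs per gene group, and summarises
#' methyl scores of significant probes within the analysis scope.
#'
#' @param object A `methdiff` fit.
#' @param q_max,window Passed to [filter_significant()].
#' @param ... Unused.
#' @return A `summary.methdiff` list with the per-group sign table and
#'   methyl-score summaries.
#' @export
summary.methdiff <- function(object, q_max = 0.05,
                             window = c(-2000, 2000), ...) {
  sig <- suppressMessages(filter_significant(object, q_max = q_max,
                                             window = window))
  signs <- if (nrow(sig))
    table(group = sig$group, sign = factor(sig$sign,
          levels = c("negative", "positive", "zero")))
  else table(group = character(), sign = character())
  structure(list(n_probes = nrow(object$stats),
                 n_significant = nrow(sig),
                 q_max = q_max, window = window,
                 fdr_method = object$fdr_method, pi0 = object$pi0,
                 sign_table = signs,
                 score_summary = if (nrow(sig)) score_summary(sig) else NULL),
            class = "summary.methdiff")
}

#' @export
print.summary.methdiff <- function(x, ...) {
  cat(sprintf("%d probes tested; %d significant (q <= %g, %+d..%+d bp from TSS)\n",
              x$n_probes, x$n_significant, x$q_max, x$window[1], x$window[2]))
  if (x$n_significant) {
    cat("probe signs per group:\n")
    print(x$sign_table)
    cat("methyl-score summary of significant probes:\n")
    print(x$score_summary, digits = 3)
  }
  invisible(x)
}

#' @export
plot.methdiff <- function(x, q_max = 0.05, ...) {
  st <- x$stats
  sig <- st$q_value <= q_max
  graphics::plot(st$tss_offset, st$methyl_score,
                 col = ifelse(sig, "firebrick", "grey70"),
                 pch = 16, cex = 0.4,
                 xlab = "TSS-relative position (bp)",
                 ylab = "methyl score (disease - healthy)", ...)
  graphics::abline(h = 0, v = 0, lty = 3)
  invisible(x)
}

#' Keep significant probes within the analysis scope
#'
#' Retains probes with `q_value <= q_max` whose TSS-relative offset lies in
#' the closed interval `window` (both bounds inclusive: a probe with q
#' exactly at the threshold, or sitting on a window edge, is kept).
#'
#' @param x A `methdiff` fit or its `stats` data frame.
#' @param q_max FDR threshold (default 0.05).
#' @param window `c(lo, hi)` TSS-relative scope in bp (default +/-2,000).
#' @return The surviving rows as a `probe_stats` data frame; per-group
#'   counts are reported with a message, and an empty survivor set raises
#'   a warning (downstream stages treat it as a no-op).
#' @export
filter_significant <- function(x, q_max = 0.05, window = c(-2000, 2000)) {
  st <- if (inherits(x, "methdiff")) x$stats else x
  stopifnot(is.data.frame(st), all(c("q_value", "tss_offset") %in% names(st)))
  keep <- st$q_value <= q_max &
    st$tss_offset >= window[1] & st$tss_offset <= window[2]
  out <- st[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) {
    warning("no probes survive q <= ", q_max, " within [",
            window[1], ", ", window[2], "]")
  } else {
    counts <- table(out$group)
    message("significant probes per group: ",
            paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  }
  class(out) <- c("probe_stats", "data.frame")
  out
}
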