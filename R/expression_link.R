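# per-gene methylation summary over a probe subset:
# freq_neg excludes zero-sign probes from the denominator; mean_score
# averages all probes; interaction = freq_neg * mean_score
gene_meth_summary <- function(stats) {
  neg <- stats$sign == "negative"
  pos <- stats$sign == "positive"
  agg <- rowsum(cbind(neg = as.numeric(neg), pos = as.numeric(pos),
                      score = stats$methyl_score, n = 1),
                stats$gene_id)
  signed <- agg[, "neg"] + agg[, "pos"]
  freq_neg <- ifelse(signed > 0, agg[, "neg"] / signed, NA_real_)
  mean_score <- agg[, "score"] / agg[, "n"]
  data.frame(gene_id = rownames(agg),
             n_probes = as.integer(agg[, "n"]),
             freq_neg = unname(freq_neg),
             mean_score = unname(mean_score),
             interaction = unname(freq_neg * mean_score),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Compare methylation summaries between up- and down-regulated genes
#'
#' Genes are split by the sign of their differential mRNA expression
#' (positive = up-regulated in disease); per gene, the fraction of negative
#' probes and the mean methyl score are computed over the significant
#' probes in `scope`, and each parameter is compared between the two
#' expression groups with a Mann-Whitney test.
#'
#' @param stats A `probe_stats` data frame of significant probes.
#' @param expression Expression table (`gene_id`, `delta_mrna`); zero
#'   deltas are dropped (their sign is undefined), unmatched genes are
#'   dropped and counted.
#' @param scope `c(lo, hi)` TSS-relative interval (default +/-2,000 bp).
#' @return A list of class `expression_split`: per-gene `summary` table
#'   (with `expr_sign`), `p_methyl_score`, `p_freq_neg`, `n_up`, `n_down`.
#' @export
split_by_expression_sign <- function(stats, expression,
                                     scope = c(-2000, 2000)) {
  stopifnot(is.data.frame(expression),
            all(c("gene_id", "delta_mrna") %in% names(expression)))
  zero <- expression$delta_mrna == 0
  if (any(zero)) {
    message(sum(zero), " gene(s) with zero differential expression dropped")
    expression <- expression[!zero, , drop = FALSE]
  }
  st <- stats[stats$tss_offset >= scope[1] & stats$tss_offset <= scope[2], ,
              drop = FALSE]
  if (!nrow(st)) stop("no significant probes in scope")
  gs <- gene_meth_summary(st)
  idx <- match(gs$gene_id, expression$gene_id)
  dropped <- sum(is.na(idx))
  if (dropped)
    message(dropped, " gene(s) absent from the expression table dropped")
  gs <- gs[!is.na(idx), , drop = FALSE]
  gs$delta_mrna <- expression$delta_mrna[idx[!is.na(idx)]]
  gs$expr_sign <- ifelse(gs$delta_mrna > 0, "up", "down")
  n_up <- sum(gs$expr_sign == "up")
  n_down <- sum(gs$expr_sign == "down")
  if (n_up < 2) stop("fewer than 2 up-regulated genes")
  if (n_down < 2) stop("fewer than 2 down-regulated genes")
  up <- gs[gs$expr_sign == "up", ]
  down <- gs[gs$expr_sign == "down", ]
  fr_up <- up$freq_neg[!is.na(up$freq_neg)]
  fr_down <- down$freq_neg[!is.na(down$freq_neg)]
  structure(list(summary = gs,
                 p_methyl_score = mw_probe_test(up$mean_score, down$mean_score),
                 p_freq_neg = mw_probe_test(fr_up, fr_down),
                 n_up = n_up, n_down = n_down),
            class = "expression_split")
}

#' @export
print.expression_split <- function(x, ...) {
  cat(sprintf("expression_split: %d up- vs %d down-regulated genes\n",
              x$n_up, x$n_down))
  cat(sprintf("  mean methyl score, up vs down: Mann-Whitney p = %.3g\n",
              x$p_methyl_score))
  cat(sprintf("  freq-neg,          up vs down: Mann-Whitney p = %.3g\n",
              x$p_freq_neg))
  invisible(x)
}

# Spearman rho and two-sided p; exact null for n < 10 and tie-free data,
# t-approximation otherwise
spearman_test <- function(x, y) {
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p = NA_real_))
  rho <- stats::cor(rank(x), rank(y))
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n < 10 && !ties) {
    ct <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
    return(list(rho = unname(ct$estimate), p = ct$p.value))
  }
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * stats::pt(-abs(t_stat), df = n - 2))
}

#' Windowed Spearman correlation of methylation with expression
#'
#' Slides 140-bp windows (shift 1 bp by default) along the TSS axis; in
#' each window, every gene with at least one significant probe inside the
#' window gets a window-local methylation summary (freq-neg, mean methyl
#' score, or their product — the interaction parameter), which is
#' rank-correlated (Spearman) with the gene's differential mRNA
#' expression. Windows with fewer than `min_genes` genes are masked.
#'
#' @param stats A `probe_stats` data frame (typically one gene group).
#' @param expression Expression table (`gene_id`, `delta_mrna`), zeros
#'   dropped.
#' @param windows A [make_windows()] result (default +/-2,000, 140 bp,
#'   step 1).
#' @param parameter Which per-gene summary to correlate.
#' @param min_genes Minimum genes per window for a reported rho.
#' @return A data frame of class `correlation_track` with columns
#'   `window_id`, `rho`, `p_value`, `n_genes`.
#' @export
windowed_correlation <- function(stats, expression, windows = make_windows(),
                                 parameter = c("interaction", "freq_neg",
                                               "mean_score"),
                                 min_genes = 10) {
  parameter <- match.arg(parameter)
  expression <- expression[expression$delta_mrna != 0, , drop = FALSE]
  st <- stats[stats$gene_id %in% expression$gene_id, , drop = FALSE]
  dm <- stats::setNames(expression$delta_mrna, expression$gene_id)

  o <- order(st$tss_offset)
  off <- st$tss_offset[o]
  gene <- st$gene_id[o]
  neg <- as.numeric(st$sign[o] == "negative")
  pos <- as.numeric(st$sign[o] == "positive")
  sc <- st$methyl_score[o]
  ihi <- findInterval(windows$hi + 0.5, off)
  ilo <- findInterval(windows$lo - 0.5, off)

  n_win <- nrow(windows)
  rho <- rep(NA_real_, n_win)
  pval <- rep(NA_real_, n_win)
  n_genes <- integer(n_win)
  for (w in seq_len(n_win)) {
    if (ihi[w] <= ilo[w]) next
    idx <- seq.int(ilo[w] + 1L, ihi[w])
    agg <- rowsum(cbind(neg[idx], pos[idx], sc[idx], 1), gene[idx])
    signed <- agg[, 1] + agg[, 2]
    freq_neg <- ifelse(signed > 0, agg[, 1] / signed, NA_real_)
    val <- switch(parameter,
                  freq_neg = freq_neg,
                  mean_score = agg[, 3] / agg[, 4],
                  interaction = freq_neg * (agg[, 3] / agg[, 4]))
    keep <- !is.na(val)
    val <- val[keep]
    dmv <- dm[rownames(agg)[keep]]
    n_genes[w] <- length(val)
    if (length(val) < min_genes) next
    ct <- spearman_test(val, dmv)
    rho[w] <- ct$rho
    pval[w] <- ct$p
  }
  out <- data.frame(window_id = windows$window_id, rho = rho,
                    p_value = pval, n_genes = n_genes)
  attr(out, "parameter") <- parameter
  class(out) <- c("correlation_track", "data.frame")
  out
}

#' @export
plot.correlation_track <- function(x, alpha = 0.05, ...) {
  col <- ifelse(!is.na(x$p_value) & x$p_value < alpha, "firebrick", "grey40")
  graphics::plot(x$window_id, x$rho, type = "p", pch = 16, cex = 0.3,
                 col = col, xlim = rev(range(x$window_id)),
                 xlab = "window 5' offset (bp from TSS)",
                 ylab = "Spearman rho", ...)
  graphics::abline(h = 0, v = 0, lty = 3)
  invisible(x)
}

#' Strongest correlation window of a track
#'
#' The unmasked window with the smallest correlation p-value (the largest
#' `|rho|` breaks ties), i.e. the most convincingly correlated region
#' rather than the largest raw `|rho|`, which tends to sit in sparse
#' windows.
#'
#' @param track A [windowed_correlation()] result.
#' @return One-row data frame.
#' @export
peak_correlation <- function(track) {
  ok <- which(!is.na(track$rho) & !is.na(track$p_value))
  if (!length(ok)) stop("no unmasked windows in the track")
  best <- ok[order(track$p_value[ok], -abs(track$rho[ok]))][1]
  track[best, , drop = FALSE]
}
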