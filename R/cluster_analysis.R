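#' Classify promoter probe-sign homogeneity per gene ("cluster phenomenon")
#'
#' For each gene, collects its significant probes inside the promoter
#' interval (default 0 to -1,700 bp, both ends inclusive) and, if at least
#' `min_probes` remain, classifies the gene by the homogeneity of their
#' methyl-score signs: `neg` (all negative — clustered demethylation in
#' disease), `pos` (all positive) or `negpos` (mixed). Zero-score probes
#' carry no sign and are excluded before classification; genes below the
#' probe threshold are omitted with a message.
#'
#' @param stats A `probe_stats` data frame of significant probes
#'   (see [filter_significant()]).
#' @param promoter `c(lo, hi)` promoter interval in TSS-relative bp.
#' @param min_probes Minimum signed significant promoter probes per gene
#'   (default 3, i.e. "more than two probes").
#' @return A data frame of class `cluster_calls` with columns `gene_id`,
#'   `group`, `n_sig_probes`, `category`.
#' @export
classify_promoter_clusters <- function(stats, promoter = c(-1700, 0),
                                       min_probes = 3) {
  stopifnot(is.data.frame(stats))
  promoter <- sort(promoter)
  prom <- stats[stats$tss_offset >= promoter[1] &
                stats$tss_offset <= promoter[2] &
                stats$sign %in% c("negative", "positive"), , drop = FALSE]
  if (!nrow(prom)) {
    message("no signed significant probes in the promoter interval")
    out <- data.frame(gene_id = character(0), group = character(0),
                      n_sig_probes = integer(0), category = character(0))
    class(out) <- c("cluster_calls", "data.frame")
    return(out)
  }
  n_by_gene <- table(prom$gene_id)
  neg_by_gene <- tapply(prom$sign == "negative", prom$gene_id, sum)
  grp_by_gene <- tapply(prom$group, prom$gene_id, `[`, 1)
  genes <- names(n_by_gene)
  n <- as.integer(n_by_gene)
  n_neg <- as.integer(neg_by_gene[genes])
  keep <- n >= min_probes
  if (any(!keep))
    message(sum(!keep), " gene(s) with fewer than ", min_probes,
            " signed promoter probes omitted")
  category <- ifelse(n_neg == n, "neg", ifelse(n_neg == 0, "pos", "negpos"))
  out <- data.frame(gene_id = genes[keep],
                    group = as.character(grp_by_gene[genes])[keep],
                    n_sig_probes = n[keep],
                    category = category[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cluster_calls", "data.frame")
  out
}

#' Frequency of the cluster phenomenon
#'
#' The fraction of classified genes whose promoter probes are homogeneous
#' in sign: `(neg + pos) / (neg + pos + negpos)`.
#'
#' @param calls A [classify_promoter_clusters()] result (typically one
#'   gene group's calls).
#' @return A list with `fraction`, the raw `counts` per category and
#'   `n_total`.
#' @examples
#' calls <- data.frame(category = rep(c("neg", "pos", "negpos"),
#'                                    c(131, 159, 143)))
#' cluster_frequency(calls)$fraction  # 290/433 = 0.6697
#' @export
cluster_frequency <- function(calls) {
  if (!nrow(calls)) stop("no cluster calls")
  counts <- table(factor(calls$category, levels = c("neg", "pos", "negpos")))
  total <- sum(counts)
  list(fraction = (counts[["neg"]] + counts[["pos"]]) / total,
       counts = counts, n_total = total)
}

#' Chi-squared test for enrichment of all-negative promoter clusters
#'
#' Pearson chi-squared (no continuity correction) on the gene-group x
#' {neg, not-neg} table of cluster calls, asking whether clustered
#' promoter demethylation is over-represented in one group.
#'
#' @param calls A [classify_promoter_clusters()] result covering >= 2
#'   groups, or a counts matrix with columns `neg` and `not_neg`.
#' @return A `sign_contingency`-style list (table, chi2, dof, p_value).
#' @export
neg_enrichment_test <- function(calls) {
  if (is.matrix(calls)) {
    tab <- calls
  } else {
    if (length(unique(calls$group)) < 2) stop("need at least 2 groups")
    tab <- table(calls$group, factor(calls$category == "neg",
                                     levels = c(TRUE, FALSE),
                                     labels = c("neg", "not_neg")))
    tab <- unclass(tab)
  }
  sign_contingency_test(tab)
}

#' Positional scan of the cluster phenomenon
#'
#' Slides a wide window (default 800 bp, 50-bp shift, from +750 down to
#' -1,500) along the TSS axis; in each window, genes contributing at least
#' `min_probes` signed significant probes ("more than three") are
#' classified as all-negative, all-positive or mixed, and the per-window
#' fractions are reported. Windows with no qualifying gene carry NA
#' fractions.
#'
#' @param stats A `probe_stats` data frame (one gene group).
#' @param range `c(start, end)` of the scan, 5' offsets in bp.
#' @param width,step Window width and shift in bp.
#' @param min_probes Minimum signed probes per gene per window (default 4).
#' @return A data frame of class `cluster_scan` with columns `window_id`,
#'   `lo`, `hi`, `n_genes`, `frac_all_neg`, `frac_all_pos`.
#' @export
scan_cluster_windows <- function(stats, range = c(750, -1500),
                                 width = 800, step = 50, min_probes = 4) {
  windows <- make_windows(start = max(range), end = min(range),
                          width = width, step = step)
  signed <- stats[stats$sign %in% c("negative", "positive"), , drop = FALSE]
  res <- lapply(seq_len(nrow(windows)), function(i) {
    w <- signed[signed$tss_offset >= windows$lo[i] &
                signed$tss_offset <= windows$hi[i], , drop = FALSE]
    if (!nrow(w))
      return(data.frame(n_genes = 0L, frac_all_neg = NA_real_,
                        frac_all_pos = NA_real_))
    n <- table(w$gene_id)
    qual <- names(n)[n >= min_probes]
    if (!length(qual))
      return(data.frame(n_genes = 0L, frac_all_neg = NA_real_,
                        frac_all_pos = NA_real_))
    w <- w[w$gene_id %in% qual, , drop = FALSE]
    n_neg <- tapply(w$sign == "negative", w$gene_id, sum)[qual]
    n_all <- tapply(w$sign, w$gene_id, length)[qual]
    data.frame(n_genes = length(qual),
               frac_all_neg = mean(n_neg == n_all),
               frac_all_pos = mean(n_neg == 0))
  })
  out <- cbind(windows[, c("window_id", "lo", "hi")], do.call(rbind, res))
  rownames(out) <- NULL
  class(out) <- c("cluster_scan", "data.frame")
  out
}

#' @export
plot.cluster_scan <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(x$frac_all_neg, names.arg = x$window_id, las = 2,
                    cex.names = 0.6, ylab = "fraction all-negative genes",
                    main = "clustered demethylation", ...)
  graphics::barplot(x$frac_all_pos, names.arg = x$window_id, las = 2,
                    cex.names = 0.6, ylab = "fraction all-positive genes",
                    main = "clustered methylation gain", ...)
  invisible(x)
}
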