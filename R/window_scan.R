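#' Build a TSS-relative sliding-window list
#'
#' Windows are closed intervals `[w - width, w]` labelled by their 5'
#' (more-positive) offset `w`, stepped downstream-to-upstream from `start`
#' until the window just covers `end`. With the defaults the first window
#' spans +2,000..+1,860 (gene body) and the last -1,860..-2,000 (promoter);
#' at step 1 there are `start - (end + width) + 1` windows.
#'
#' @param start 5' offset of the first window (default +2,000 bp).
#' @param end 3'-most covered offset (default -2,000 bp); `start > end`.
#' @param width Window width in bp (default 140).
#' @param step Shift between consecutive windows in bp (default 1).
#' @return A data frame of class `meth_windows` with columns `window_id`
#'   (the 5' offset), `lo` and `hi`.
#' @export
make_windows <- function(start = 2000, end = -2000, width = 140, step = 1) {
  if (width <= 0 || step <= 0) stop("width and step must be positive")
  if (start <= end) stop("start must exceed end")
  if (start - width < end) stop("range narrower than one window")
  w <- seq(start, end + width, by = -step)
  out <- data.frame(window_id = w, lo = w - width, hi = w)
  class(out) <- c("meth_windows", "data.frame")
  out
}

# cumulative-count window aggregation over sorted integer offsets;
# closed intervals, so bounds are nudged by 0.5 before findInterval
window_counts <- function(offsets, windows, weights = NULL) {
  o <- order(offsets)
  off <- offsets[o]
  ihi <- findInterval(windows$hi + 0.5, off)
  ilo <- findInterval(windows$lo - 0.5, off)
  n <- ihi - ilo
  if (is.null(weights)) return(list(order = o, ilo = ilo, ihi = ihi, n = n))
  w <- as.matrix(weights)
  cs <- matrix(0, nrow = length(off) + 1, ncol = ncol(w),
               dimnames = list(NULL, colnames(w)))
  if (length(off))
    cs[-1, ] <- apply(w[o, , drop = FALSE], 2, cumsum)
  sums <- cs[ihi + 1, , drop = FALSE] - cs[ilo + 1, , drop = FALSE]
  list(order = o, ilo = ilo, ihi = ihi, n = n, sums = sums)
}

#' Sliding-window profile of one gene group
#'
#' For each window, counts the significant probes of the group whose
#' TSS-relative offset falls inside the closed interval, and summarises
#' them: `freq_neg` is the fraction of signed probes that are negative
#' (zero-sign probes are excluded from the denominator) and `mean_score`
#' the mean methyl score of all probes in the window.
#'
#' @param stats A `probe_stats` data frame, typically one gene group's
#'   significant probes (see [filter_significant()]).
#' @param windows A [make_windows()] result.
#' @return An object of class `window_profile`: list with `windows`, the
#'   per-window `profile` data frame (`window_id`, `n_probes`, `n_neg`,
#'   `n_pos`, `freq_neg`, `mean_score`) and the probe table used.
#' @export
profile_group <- function(stats, windows = make_windows()) {
  stopifnot(is.data.frame(stats),
            all(c("tss_offset", "sign", "methyl_score") %in% names(stats)))
  neg <- as.numeric(stats$sign == "negative")
  pos <- as.numeric(stats$sign == "positive")
  wc <- window_counts(stats$tss_offset, windows,
                      cbind(neg = neg, pos = pos, score = stats$methyl_score))
  n_neg <- wc$sums[, "neg"]; n_pos <- wc$sums[, "pos"]
  signed <- n_neg + n_pos
  profile <- data.frame(window_id = windows$window_id,
                        n_probes = wc$n,
                        n_neg = n_neg, n_pos = n_pos,
                        freq_neg = ifelse(signed > 0, n_neg / signed, NA_real_),
                        mean_score = ifelse(wc$n > 0, wc$sums[, "score"] / wc$n,
                                            NA_real_))
  structure(list(windows = windows, profile = profile,
                 probes = stats[, c("tss_offset", "sign", "methyl_score")]),
            class = "window_profile")
}

#' @export
print.window_profile <- function(x, ...) {
  cat(sprintf("window_profile: %d windows, %d probes\n",
              nrow(x$profile), nrow(x$probes)))
  invisible(x)
}

# vectorised tie-corrected normal-approximation Mann-Whitney p for two
# groups of -1/+1 sign indicators, given per-group negative/positive counts
mw_indicator_p <- function(neg_a, pos_a, neg_b, pos_b) {
  n1 <- neg_a + pos_a
  n2 <- neg_b + pos_b
  N <- n1 + n2
  t_neg <- neg_a + neg_b
  t_pos <- pos_a + pos_b
  r_neg <- (1 + t_neg) / 2
  r_pos <- t_neg + (1 + t_pos) / 2
  W <- neg_a * r_neg + pos_a * r_pos
  mu <- n1 * (N + 1) / 2
  tie_term <- (t_neg^3 - t_neg + t_pos^3 - t_pos) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  sigma <- sqrt(pmax(sigma2, 0))
  z <- pmax(abs(W - mu) - 0.5, 0)
  p <- ifelse(sigma > 0, 2 * stats::pnorm(-z / sigma), 1)
  pmin(p, 1)
}

# vectorised Pearson chi-squared p (no continuity correction) for 2x2
# tables (neg_a, pos_a) vs (neg_b, pos_b)
prop_chisq_p <- function(neg_a, pos_a, neg_b, pos_b) {
  n <- neg_a + pos_a + neg_b + pos_b
  num <- n * (neg_a * pos_b - pos_a * neg_b)^2
  den <- (neg_a + pos_a) * (neg_b + pos_b) * (neg_a + neg_b) * (pos_a + pos_b)
  chi2 <- ifelse(den > 0, num / den, NA_real_)
  ifelse(is.na(chi2), 1, stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Per-window difference between two group profiles
#'
#' Subtracts group B's per-window summary from group A's (`freq_neg` or
#' `mean_score`) and tests each window with a Mann-Whitney test on the two
#' groups' per-probe values inside the window: methyl scores for
#' `mode = "mean_score"`, and -1/+1 sign indicators for
#' `mode = "freq_neg"` (a two-proportion chi-squared test is available via
#' `test = "proportion"`). Windows where either group has fewer than
#' `min_probes` contributing probes are masked (delta and p set to NA).
#' No multiple-testing correction is applied across windows; the track
#' reports raw per-window significance.
#'
#' @param track_a,track_b [profile_group()] results on the same window list.
#' @param mode `"freq_neg"` or `"mean_score"`.
#' @param min_probes Minimum contributing probes per group per window
#'   (signed probes for `freq_neg`, all probes for `mean_score`).
#' @param test Per-window test for `freq_neg` mode.
#' @return A data frame of class `difference_track` with columns
#'   `window_id`, `delta`, `p_value`, `n_a`, `n_b`.
#' @export
difference_track <- function(track_a, track_b,
                             mode = c("freq_neg", "mean_score"),
                             min_probes = 3,
                             test = c("mannwhitney", "proportion")) {
  mode <- match.arg(mode)
  test <- match.arg(test)
  stopifnot(inherits(track_a, "window_profile"),
            inherits(track_b, "window_profile"))
  if (!identical(track_a$windows$window_id, track_b$windows$window_id))
    stop("window lists of the two tracks differ")
  pa <- track_a$profile; pb <- track_b$profile

  if (mode == "freq_neg") {
    n_a <- pa$n_neg + pa$n_pos
    n_b <- pb$n_neg + pb$n_pos
    delta <- pa$freq_neg - pb$freq_neg
    p <- if (test == "mannwhitney")
      mw_indicator_p(pa$n_neg, pa$n_pos, pb$n_neg, pb$n_pos)
    else
      prop_chisq_p(pa$n_neg, pa$n_pos, pb$n_neg, pb$n_pos)
  } else {
    n_a <- pa$n_probes
    n_b <- pb$n_probes
    delta <- pa$mean_score - pb$mean_score
    p <- rep(NA_real_, nrow(pa))
    wa <- window_counts(track_a$probes$tss_offset, track_a$windows)
    wb <- window_counts(track_b$probes$tss_offset, track_b$windows)
    sa <- track_a$probes$methyl_score[wa$order]
    sb <- track_b$probes$methyl_score[wb$order]
    todo <- which(n_a >= min_probes & n_b >= min_probes)
    for (w in todo) {
      xa <- sa[seq.int(wa$ilo[w] + 1L, wa$ihi[w])]
      xb <- sb[seq.int(wb$ilo[w] + 1L, wb$ihi[w])]
      p[w] <- mw_probe_test(xa, xb)
    }
  }
  mask <- n_a < min_probes | n_b < min_probes
  delta[mask] <- NA_real_
  p[mask] <- NA_real_
  out <- data.frame(window_id = pa$window_id, delta = delta, p_value = p,
                    n_a = n_a, n_b = n_b)
  class(out) <- c("difference_track", "data.frame")
  out
}

#' Contiguous runs of significant windows in a difference track
#'
#' @param track A [difference_track()] result.
#' @param alpha Per-window significance threshold.
#' @param sign Optional restriction: `"positive"`/`"negative"` keeps only
#'   windows whose delta has that sign.
#' @return A data frame with one row per run: 5' and 3' window ids and the
#'   run length; ordered longest first.
#' @export
significant_runs <- function(track, alpha = 0.05, sign = NULL) {
  sig <- !is.na(track$p_value) & track$p_value < alpha
  if (!is.null(sign)) {
    sig <- sig & !is.na(track$delta) &
      (if (sign == "positive") track$delta > 0 else track$delta < 0)
  }
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  if (!any(keep))
    return(data.frame(from = numeric(0), to = numeric(0), n_windows = integer(0)))
  out <- data.frame(from = track$window_id[starts[keep]],
                    to = track$window_id[ends[keep]],
                    n_windows = r$lengths[keep])
  out[order(-out$n_windows), , drop = FALSE]
}

#' @export
plot.difference_track <- function(x, alpha = 0.05, ...) {
  col <- ifelse(!is.na(x$p_value) & x$p_value < alpha, "firebrick", "grey60")
  graphics::plot(x$window_id, x$delta, col = col, pch = 16, cex = 0.3,
                 xlab = "window 5' offset (bp from TSS)",
                 ylab = "difference (group A - group B)",
                 xlim = rev(range(x$window_id)), ...)
  graphics::abline(h = 0, v = 0, lty = 3)
  invisible(x)
}
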