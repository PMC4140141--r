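# Independent oracles used across tests.

# exhaustive-enumeration two-sided Mann-Whitney p for tie-free samples:
# enumerate every assignment of the pooled ranks to group 1
mw_enum_p <- function(x, y) {
  stopifnot(anyDuplicated(c(x, y)) == 0)
  n1 <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  splits <- utils::combn(length(r), n1)
  w_all <- colSums(matrix(r[splits], nrow = n1))
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# textbook Benjamini-Hochberg step-up, written as the definition
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m * p[o[i]] / i)
    q[o[i]] <- prev
  }
  q
}

# naive O(windows x probes) recount of per-window probe/sign totals
recount_windows <- function(stats, windows) {
  out <- lapply(seq_len(nrow(windows)), function(i) {
    inw <- stats$tss_offset >= windows$lo[i] & stats$tss_offset <= windows$hi[i]
    data.frame(n_probes = sum(inw),
               n_neg = sum(inw & stats$sign == "negative"),
               n_pos = sum(inw & stats$sign == "positive"))
  })
  do.call(rbind, out)
}

# hand-rolled Pearson chi-squared statistic, sum (O - E)^2 / E
pearson_chi2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}
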