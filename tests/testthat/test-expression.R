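test_that("Spearman rho equals rank-then-Pearson, ties included", {
  set.seed(50)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    x <- sample(round(runif(n), 1))  # plenty of ties
    y <- rnorm(n)
    res <- methscan:::spearman_test(x, y)
    expect_equal(res$rho, stats::cor(rank(x), rank(y)), tolerance = 1e-12)
    t_ref <- res$rho * sqrt((n - 2) / (1 - res$rho^2))
    expect_equal(res$p, 2 * stats::pt(-abs(t_ref), n - 2), tolerance = 1e-12)
  }
})

test_that("Spearman is invariant under monotone transforms and exact for small n", {
  set.seed(51)
  x <- runif(15); y <- rnorm(15)
  r1 <- methscan:::spearman_test(x, y)
  r2 <- methscan:::spearman_test(exp(3 * x), y^3 + 5 * y)
  expect_equal(r1$rho, r2$rho, tolerance = 1e-12)
  expect_equal(r1$p, r2$p, tolerance = 1e-12)
  xs <- runif(8); ys <- rnorm(8)
  res <- methscan:::spearman_test(xs, ys)
  ref <- stats::cor.test(xs, ys, method = "spearman", exact = TRUE)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
})

test_that("windowed correlation hits -1 on anti-monotone data and masks small n", {
  # 12 genes, one negative-signed probe each at offset -100, scores increasing
  n <- 12
  st <- fake_stats(tss_offset = rep(-100, n), sign = rep("negative", n),
                   gene_id = paste0("g", 1:n),
                   methyl_score = -seq(0.05, 0.3, length.out = n))
  ex <- data.frame(gene_id = paste0("g", 1:n),
                   delta_mrna = seq_len(n))  # perfectly anti-monotone in score
  w <- make_windows(start = 0, end = -200, width = 200, step = 100)
  ct <- windowed_correlation(st, ex, windows = w, parameter = "mean_score")
  covered <- w$lo <= -100 & w$hi >= -100
  expect_equal(ct$rho[covered], rep(-1, sum(covered)))
  expect_equal(ct$n_genes[covered], rep(n, sum(covered)))
  ct2 <- windowed_correlation(st, ex, windows = w, parameter = "mean_score",
                              min_genes = n + 1)
  expect_true(all(is.na(ct2$rho)))
  expect_equal(ct2$n_genes[covered], rep(n, sum(covered)))
})

test_that("interaction parameter multiplies freq-neg and mean score", {
  st <- fake_stats(tss_offset = rep(0, 5),
                   sign = c("negative", "positive", "negative", "negative",
                            "negative"),
                   gene_id = c("g1", "g1", "g2", "g2", "g3"),
                   methyl_score = c(-0.2, 0.4, -0.1, -0.3, -0.4))
  # interactions: g1 = 0.5 * 0.1 = 0.05; g2 = 1 * -0.2; g3 = 1 * -0.4,
  # and delta_mrna is chosen monotone in them, so rho = 1
  ex <- data.frame(gene_id = c("g1", "g2", "g3"), delta_mrna = c(5, 2, 1))
  w <- make_windows(start = 50, end = -50, width = 100, step = 100)
  ct_int <- windowed_correlation(st, ex, windows = w, parameter = "interaction",
                                 min_genes = 3)
  expect_equal(ct_int$rho, 1)
  ga <- methscan:::gene_meth_summary(st)
  expect_equal(ga$interaction[ga$gene_id == "g1"], 0.5 * 0.1)
  expect_equal(ga$interaction[ga$gene_id == "g2"], 1 * -0.2)
})

test_that("randomly permuted expression decorrelates the track", {
  set.seed(52)
  sim <- suppressMessages(simulate_methylation(small_config(seed = 52)))
  fit <- suppressMessages(meth_diff(sim$beta, sim$annotation))
  sig <- suppressMessages(filter_significant(fit))
  simm <- sig[sig$group == "immune", ]
  ex <- sim$expression
  ex$delta_mrna <- sample(ex$delta_mrna)
  ct <- windowed_correlation(simm, ex, min_genes = 5)
  rho <- ct$rho[!is.na(ct$rho)]
  expect_true(length(rho) > 50)
  expect_lt(abs(mean(rho)), 0.2)
})

test_that("expression-sign split separates planted methylation summaries", {
  sim <- suppressMessages(simulate_methylation(small_config(seed = 53)))
  fit <- suppressMessages(meth_diff(sim$beta, sim$annotation))
  sig <- suppressMessages(filter_significant(fit))
  simm <- sig[sig$group == "immune", ]
  sp <- suppressMessages(split_by_expression_sign(simm, sim$expression))
  expect_gt(sp$n_up, 2)
  expect_gt(sp$n_down, 0)
  up <- sp$summary[sp$summary$expr_sign == "up", ]
  down <- sp$summary[sp$summary$expr_sign == "down", ]
  # hypomethylated genes are the up-regulated ones (negative expr slope)
  expect_lt(mean(up$mean_score), mean(down$mean_score))
  expect_true(sp$p_methyl_score >= 0 && sp$p_methyl_score <= 1)
})

test_that("expression join drops unmatched genes and names a starved side", {
  st <- fake_stats(tss_offset = rep(0, 10),
                   sign = rep(c("negative", "positive"), 5),
                   gene_id = rep(paste0("g", 1:5), each = 2),
                   methyl_score = rep(c(-0.1, 0.2), 5))
  ex <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   delta_mrna = c(1, -2, 3, -0.5))
  expect_message(sp <- split_by_expression_sign(st, ex), "absent")
  expect_false("g5" %in% sp$summary$gene_id)  # no expression value: dropped
  expect_equal(sp$n_up, 2)
  expect_equal(sp$n_down, 2)
  ex2 <- data.frame(gene_id = paste0("g", 1:5),
                    delta_mrna = c(1, 2, 3, 4, -2))
  expect_error(suppressMessages(split_by_expression_sign(st, ex2)),
               "down-regulated")
})

test_that("no reported rho rests on fewer than min_genes genes", {
  set.seed(54)
  sim <- suppressMessages(simulate_methylation(small_config(seed = 54)))
  fit <- suppressMessages(meth_diff(sim$beta, sim$annotation))
  sig <- suppressMessages(filter_significant(fit))
  ct <- windowed_correlation(sig[sig$group == "immune", ], sim$expression,
                             min_genes = 8)
  expect_true(all(is.na(ct$rho) | ct$n_genes >= 8))
})
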