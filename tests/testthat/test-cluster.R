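test_that("promoter cluster categories follow sign homogeneity", {
  st <- fake_stats(
    tss_offset = c(-100, -500, -1000,   -50, -300, -900,   -10, -20, -1699,
                   -200, -400),
    sign = c("negative", "negative", "negative",
             "positive", "negative", "positive",
             "positive", "positive", "positive",
             "negative", "negative"),
    gene_id = rep(c("gNeg", "gMix", "gPos", "gTwo"), c(3, 3, 3, 2)))
  calls <- suppressMessages(classify_promoter_clusters(st))
  expect_setequal(calls$gene_id, c("gNeg", "gMix", "gPos"))
  expect_equal(calls$category[calls$gene_id == "gNeg"], "neg")
  expect_equal(calls$category[calls$gene_id == "gMix"], "negpos")
  expect_equal(calls$category[calls$gene_id == "gPos"], "pos")
  expect_false("gTwo" %in% calls$gene_id)  # exactly 2 probes: "more than two"
})

test_that("probes outside the promoter interval and zero signs are ignored", {
  st <- fake_stats(
    tss_offset = c(-100, -500, -1000, 50, -1701, -800),
    sign = c("negative", "negative", "negative", "positive", "positive",
             "zero"),
    gene_id = rep("g1", 6))
  calls <- suppressMessages(classify_promoter_clusters(st))
  # +50 is gene body, -1701 outside, zero-sign carries no sign: all-negative
  expect_equal(calls$category, "neg")
  expect_equal(calls$n_sig_probes, 3L)
})

test_that("classification agrees with a brute-force oracle and partitions genes", {
  set.seed(40)
  for (i in 1:20) {
    st <- random_stats(80, range = c(-2000, 500), n_genes = 12)
    calls <- suppressMessages(classify_promoter_clusters(st))
    expect_equal(anyDuplicated(calls$gene_id), 0)
    prom <- st[st$tss_offset >= -1700 & st$tss_offset <= 0 &
               st$sign != "zero", ]
    for (g in unique(prom$gene_id)) {
      signs <- prom$sign[prom$gene_id == g]
      if (length(signs) < 3) {
        expect_false(g %in% calls$gene_id)
      } else {
        want <- if (all(signs == "negative")) "neg"
                else if (all(signs == "positive")) "pos" else "negpos"
        expect_equal(calls$category[calls$gene_id == g], want)
      }
    }
    if (nrow(calls)) {
      fr <- cluster_frequency(calls)
      expect_equal(sum(fr$counts), nrow(calls))
    }
  }
})

test_that("cluster frequency reproduces its defining ratio", {
  calls <- data.frame(category = rep(c("neg", "pos", "negpos"),
                                     c(131, 159, 143)))
  fr <- cluster_frequency(calls)
  expect_equal(fr$fraction, 290 / 433)
  expect_equal(round(100 * fr$fraction, 2), 66.97)
  expect_equal(cluster_frequency(data.frame(category = rep("negpos", 5)))$fraction, 0)
  expect_equal(cluster_frequency(data.frame(category = rep(c("neg", "pos"), 4)))$fraction, 1)
  expect_error(cluster_frequency(data.frame(category = character(0))), "no cluster")
})

test_that("neg-enrichment chi-squared matches the hand formula", {
  tab <- rbind(a = c(30, 70), b = c(10, 90))
  colnames(tab) <- c("neg", "not_neg")
  res <- neg_enrichment_test(tab)
  expect_equal(res$chi2, 12.5, tolerance = 1e-10)
  calls <- data.frame(gene_id = paste0("g", 1:40),
                      group = rep(c("immune", "stable"), each = 20),
                      category = c(rep("neg", 15), rep("negpos", 5),
                                   rep("neg", 2), rep("pos", 18)))
  res2 <- neg_enrichment_test(calls)
  expect_equal(sum(res2$table), 40)
  expect_lt(res2$p_value, 0.01)
  expect_error(neg_enrichment_test(calls[calls$group == "immune", ]),
               "2 groups")
})

test_that("positional cluster scan applies the more-than-three rule", {
  w_hits <- function(scan, off) scan[scan$lo <= off & scan$hi >= off, ]
  st4 <- fake_stats(tss_offset = c(-100, -150, -200, -250),
                    sign = rep("negative", 4), gene_id = rep("g1", 4))
  scan <- scan_cluster_windows(st4)
  hit <- w_hits(scan, -250)
  hit <- hit[hit$n_genes > 0, ]
  expect_true(nrow(hit) > 0)
  expect_true(all(hit$frac_all_neg == 1))
  expect_true(all(hit$frac_all_pos == 0))
  # a gene with only 3 probes in a window does not qualify there
  st3 <- st4[1:3, ]
  scan3 <- scan_cluster_windows(st3)
  expect_true(all(scan3$n_genes == 0))
  expect_true(all(is.na(scan3$frac_all_neg)))
})

test_that("scan windows follow the 800-bp / 50-bp convention and bound fractions", {
  scan <- scan_cluster_windows(fake_stats(tss_offset = 0, sign = "negative"))
  expect_equal(scan$window_id[1], 750)
  expect_equal(scan$window_id[nrow(scan)], -700)
  expect_equal(scan$lo[nrow(scan)], -1500)
  expect_true(all(diff(scan$window_id) == -50))
  set.seed(41)
  st <- random_stats(120, range = c(-1600, 800), n_genes = 8)
  scan2 <- scan_cluster_windows(st)
  ok <- !is.na(scan2$frac_all_neg)
  expect_true(all(scan2$frac_all_neg[ok] + scan2$frac_all_pos[ok] <= 1 + 1e-12))
})
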