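test_that("default windows span +2000..+1860 down to -1860..-2000", {
  w <- make_windows()
  expect_equal(w$lo[1], 1860)
  expect_equal(w$hi[1], 2000)
  expect_equal(w$lo[nrow(w)], -2000)
  expect_equal(w$hi[nrow(w)], -1860)
  expect_equal(nrow(w), 2000 - (-2000 + 140) + 1)
  # step-1 window count formula over random small ranges
  set.seed(30)
  for (i in 1:15) {
    start <- sample(50:400, 1)
    width <- sample(10:40, 1)
    end <- start - width - sample(1:200, 1)
    expect_equal(nrow(make_windows(start, end, width, 1)),
                 start - (end + width) + 1)
  }
})

test_that("coarse steps tile the range", {
  w <- make_windows(start = 420, end = 0, width = 140, step = 140)
  expect_equal(nrow(w), 3)
  expect_equal(w$window_id, c(420, 280, 140))
  expect_error(make_windows(100, 200), "start must exceed end")
  expect_error(make_windows(100, 0, width = 0), "positive")
  expect_error(make_windows(100, 50, width = 200), "narrower")
})

test_that("window profiles match a naive recount", {
  set.seed(31)
  w <- make_windows(start = 300, end = -300, width = 50, step = 7)
  for (i in 1:30) {
    st <- random_stats(sample(1:80, 1), range = c(-350, 350))
    prof <- profile_group(st, w)$profile
    ref <- recount_windows(st, w)
    expect_equal(prof$n_probes, ref$n_probes)
    expect_equal(prof$n_neg, ref$n_neg)
    expect_equal(prof$n_pos, ref$n_pos)
  }
})

test_that("profile summaries follow their definitions", {
  st <- fake_stats(tss_offset = -100, sign = "negative")
  w <- make_windows()
  prof <- profile_group(st, w)$profile
  covers <- w$lo <= -100 & w$hi >= -100
  expect_true(all(prof$freq_neg[covers] == 1))
  expect_true(all(is.na(prof$freq_neg[!covers])))
  st2 <- fake_stats(tss_offset = c(-100, -100), sign = c("negative", "positive"),
                    methyl_score = c(-0.2, 0.4))
  prof2 <- profile_group(st2, w)$profile
  expect_true(all(prof2$freq_neg[covers] == 0.5))
  expect_equal(prof2$mean_score[covers], rep(0.1, sum(covers)))
})

test_that("a profile of a union is the count-weighted merge of the parts", {
  set.seed(32)
  w <- make_windows(start = 500, end = -500, width = 80, step = 11)
  a <- random_stats(40, range = c(-600, 600))
  b <- random_stats(35, range = c(-600, 600))
  b$probe_id <- paste0("x", b$probe_id)
  pa <- profile_group(a, w)$profile
  pb <- profile_group(b, w)$profile
  pu <- profile_group(rbind(a, b), w)$profile
  expect_equal(pu$n_probes, pa$n_probes + pb$n_probes)
  expect_equal(pu$n_neg, pa$n_neg + pb$n_neg)
  signed <- pu$n_neg + pu$n_pos
  merged <- ifelse(signed > 0, (pa$n_neg + pb$n_neg) / signed, NA_real_)
  expect_equal(pu$freq_neg, merged)
})

test_that("profiles are translation-equivariant", {
  set.seed(33)
  st <- random_stats(50, range = c(-500, 500))
  k <- 90
  w1 <- make_windows(start = 700, end = -700, width = 60, step = 5)
  w2 <- make_windows(start = 700 + k, end = -700 + k, width = 60, step = 5)
  st2 <- st; st2$tss_offset <- st2$tss_offset + k
  p1 <- profile_group(st, w1)$profile
  p2 <- profile_group(st2, w2)$profile
  expect_equal(p1$n_probes, p2$n_probes)
  expect_equal(p1$freq_neg, p2$freq_neg)
})

test_that("difference track is null for identical groups and masks sparse windows", {
  set.seed(34)
  w <- make_windows(start = 200, end = -200, width = 100, step = 20)
  st <- random_stats(60, range = c(-250, 250))
  pa <- profile_group(st, w)
  tr <- difference_track(pa, pa, mode = "freq_neg", min_probes = 1)
  ok <- !is.na(tr$delta)
  expect_true(any(ok))
  expect_true(all(tr$delta[ok] == 0))
  expect_true(all(tr$p_value[ok] == 1))
  trs <- difference_track(pa, pa, mode = "mean_score", min_probes = 2)
  ok2 <- !is.na(trs$delta)
  expect_true(all(abs(trs$delta[ok2]) < 1e-12))
  expect_true(all(trs$p_value[ok2] == 1))
  # masking: fewer than min_probes in either group blanks the window
  a <- fake_stats(tss_offset = c(0, 0, 0, 0), sign = rep("negative", 4))
  b <- fake_stats(tss_offset = c(0, 0), sign = rep("positive", 2))
  w1 <- make_windows(start = 100, end = -100, width = 200, step = 200)
  tr2 <- difference_track(profile_group(a, w1), profile_group(b, w1),
                          mode = "freq_neg", min_probes = 3)
  expect_true(all(is.na(tr2$delta)))
  expect_error(difference_track(profile_group(a, w1),
                                profile_group(b, make_windows(90, -110,
                                                              200, 200))),
               "window lists")
})

test_that("opposed sign groups give a unit freq-neg difference and a tiny p", {
  w <- make_windows(start = 100, end = -100, width = 200, step = 200)
  a <- fake_stats(tss_offset = rep(0, 10), sign = rep("negative", 10))
  b <- fake_stats(tss_offset = rep(0, 10), sign = rep("positive", 10))
  tr <- difference_track(profile_group(a, w), profile_group(b, w),
                         mode = "freq_neg")
  expect_equal(tr$delta, 1)
  # same comparison through the scalar Mann-Whitney on -1/+1 indicators
  ref <- mw_probe_test(rep(-1, 10), rep(1, 10))
  expect_equal(tr$p_value, ref, tolerance = 1e-10)
  expect_lt(tr$p_value, 1e-4)
})

test_that("vectorised indicator Mann-Whitney agrees with wilcox.test", {
  set.seed(35)
  for (i in 1:40) {
    na_neg <- sample(0:12, 1); na_pos <- sample(0:12, 1)
    nb_neg <- sample(0:12, 1); nb_pos <- sample(0:12, 1)
    if (na_neg + na_pos < 2 || nb_neg + nb_pos < 2) next
    x <- rep(c(-1, 1), c(na_neg, na_pos))
    y <- rep(c(-1, 1), c(nb_neg, nb_pos))
    expect_equal(methscan:::mw_indicator_p(na_neg, na_pos, nb_neg, nb_pos),
                 mw_probe_test(x, y), tolerance = 1e-10)
  }
})

test_that("two-proportion alternative matches the Pearson 2x2 formula", {
  set.seed(36)
  for (i in 1:20) {
    k <- sample(3:30, 4, replace = TRUE)
    tab <- matrix(k, 2, 2)
    expect_equal(methscan:::prop_chisq_p(k[1], k[2], k[3], k[4]),
                 stats::pchisq(pearson_chi2(tab), 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("significant runs are extracted in order of length", {
  tr <- data.frame(window_id = 10:1,
                   delta = c(1, 1, NA, 1, 1, 1, -1, 1, 1, 1) * 0.5,
                   p_value = c(0.01, 0.01, NA, 0.2, 0.01, 0.01,
                               0.01, 0.3, 0.04, 0.2),
                   n_a = 5, n_b = 5)
  runs <- significant_runs(tr)
  expect_equal(runs$n_windows[1], 3)
  expect_equal(runs$from[1], 6)
  expect_equal(runs$to[1], 4)
  pos_runs <- significant_runs(tr, sign = "positive")
  expect_false(any(pos_runs$from == 4))  # the negative-delta window drops out
})
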