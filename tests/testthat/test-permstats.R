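# Group-level permutation inference, FDR, effect sizes, and the
# directional-sampling summaries.

test_that("the exhaustive sign-flip test enumerates all 2^n assignments", {
  set.seed(1)
  v <- rnorm(10) + 1
  res <- signflip_ttest(v, tail = "one", n_boot = 0)
  expect_true(res$exhaustive)
  expect_equal(res$n_perms, 1024)
  # with all values positive the identity assignment is the unique maximum
  expect_equal(res$p, 1 / 1024, tolerance = 1e-12)
  expect_equal(res$p, 0.000977, tolerance = 1e-3)
})

test_that("small groups hit their exact enumeration floor", {
  res <- signflip_ttest(c(0.5, 1.2, 0.9), tail = "one", n_boot = 0)
  expect_equal(res$n_perms, 8)
  expect_equal(res$p, 1 / 8)
})

test_that("sign-flip p agrees with brute-force enumeration", {
  v <- c(1.4, -0.3, 0.8, 2.1, -0.2)
  res <- signflip_ttest(v, tail = "one", n_boot = 0)
  S <- as.matrix(expand.grid(rep(list(c(1, -1)), 5)))
  ts <- apply(S, 1, function(s) {
    x <- s * v
    mean(x) / (sd(x) / sqrt(5))
  })
  t_obs <- mean(v) / (sd(v) / sqrt(5))
  expect_equal(res$statistic, t_obs, tolerance = 1e-12)
  expect_equal(res$p, mean(ts >= t_obs - 1e-12), tolerance = 1e-12)
  res2 <- signflip_ttest(v, tail = "two", n_boot = 0)
  expect_equal(res2$p, mean(abs(ts) >= abs(t_obs) - 1e-12), tolerance = 1e-12)
})

test_that("a sign-symmetric null gives large p for centered data", {
  set.seed(2)
  v <- rnorm(12)
  v <- v - mean(v)  # exactly centered
  res <- signflip_ttest(v, tail = "one", n_boot = 0)
  expect_gte(res$p, 0.4)
})

test_that("the sampled sign-flip regime includes the identity", {
  set.seed(3)
  v <- rnorm(20) + 2
  res <- signflip_ttest(v, tail = "one", k = 500, n_boot = 0, seed = 4)
  expect_false(res$exhaustive)
  expect_equal(res$n_perms, 500)
  expect_gte(res$p, 1 / 500)
  res_b <- signflip_ttest(v, tail = "one", k = 500, n_boot = 0, seed = 4)
  expect_equal(res$p, res_b$p)
})

test_that("degenerate sign-flip inputs are handled explicitly", {
  expect_error(signflip_ttest(rep(0, 10)), "all values are zero")
  expect_error(signflip_ttest(3), "at least 2")
  # constant non-zero values: p at the floor, infinite standardized effect
  res <- signflip_ttest(rep(1, 10), tail = "one", n_boot = 0)
  expect_equal(res$p, 1 / 1024)
  expect_equal(res$effect_d, Inf)
})

test_that("the unpaired permutation t test separates shifted groups", {
  set.seed(5)
  a <- rnorm(15) + 2
  b <- rnorm(15)
  res <- perm_ttest2(a, b, k = 2000, n_boot = 0, seed = 6)
  expect_lte(res$p, 0.01)
  expect_gte(res$p, 1 / 2000)  # the observed labeling is in the null
  expect_gt(res$statistic, 3)
  same <- perm_ttest2(rnorm(15), rnorm(15), k = 1000, n_boot = 0, seed = 7)
  expect_gt(same$p, 0.05)
})

test_that("the unpaired test statistic matches t.test's pooled t", {
  set.seed(8)
  a <- rnorm(10); b <- rnorm(12) + 0.5
  res <- perm_ttest2(a, b, k = 100, n_boot = 0, seed = 1)
  expect_equal(res$statistic,
               unname(t.test(a, b, var.equal = TRUE)$statistic),
               tolerance = 1e-12)
})

test_that("the paired test sign-flips the differences", {
  set.seed(9)
  base <- rnorm(10)
  a <- base + 1 + rnorm(10, sd = 0.2)
  b <- base
  res <- perm_ttest2(a, b, paired = TRUE, tail = "one", n_boot = 0)
  ref <- signflip_ttest(a - b, tail = "one", n_boot = 0)
  expect_equal(res$p, ref$p)
  expect_equal(res$statistic, ref$statistic)
  # identical pairs: no evidence, by convention t = 0 and p = 1
  same <- perm_ttest2(b + 1, b + 1, paired = TRUE, n_boot = 0)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_error(perm_ttest2(1:3, 1:4, paired = TRUE), "equal lengths")
  expect_error(perm_ttest2(numeric(0), 1:3), "empty group")
})

test_that("perm_rankcorr enumerates small n and matches a hand-built null", {
  x <- c(1, 2, 3, 4)
  y <- c(1.1, 1.9, 3.2, 4.5)
  res <- perm_rankcorr(x, y)
  expect_true(res$exhaustive)
  expect_equal(res$n_perms, 24)
  expect_equal(res$rho, 1)
  # hand enumeration: both rank vectors are 1:4
  P <- pracma::perms(1:4)
  rho_null <- apply(P, 1, function(p) cor(1:4, p, method = "spearman"))
  expect_equal(res$p, mean(abs(rho_null) >= 1 - 1e-12))
})

test_that("perm_rankcorr is monotone-invariant and validated", {
  set.seed(10)
  x <- rnorm(9)
  y <- exp(x)  # monotone transform: rho exactly 1
  res <- perm_rankcorr(x, y, k = 2000, seed = 11)
  expect_equal(res$rho, 1)
  expect_lte(res$p, 0.01)
  expect_error(perm_rankcorr(1:5, rep(2, 5)), "constant")
  expect_error(perm_rankcorr(1:2, 1:2), "length >= 3")
})

test_that("perm_rankcorr p-values are calibrated under independence", {
  set.seed(12)
  ps <- replicate(200, perm_rankcorr(rnorm(6), rnorm(6))$p)
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.65)
  expect_gt(min(ps), 0)
})

test_that("bh_fdr reproduces the step-up procedure by hand", {
  p <- c(0.001, 0.008, 0.012, 0.015, 0.02, 0.3, 0.4, 0.5, 0.6, 0.7)
  res <- bh_fdr(p, q = 0.05)
  # hand step-up: largest i with p_(i) <= i/m * q; here i = 5
  # (p_(5) = 0.02 <= 5/10 * 0.05 = 0.025, p_(6) = 0.3 > 0.03)
  expect_equal(res$significant, c(rep(TRUE, 5), rep(FALSE, 5)))
  # adjusted values match the hand-computed cumulative minimum
  m <- length(p)
  ord <- order(p)
  adj_hand <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  expect_equal(res$adjusted[ord], pmin(adj_hand, 1))
  expect_error(bh_fdr(c(0.2, 1.3)), "\\[0, 1\\]")
})

test_that("bh_fdr is order-invariant and monotone in q", {
  set.seed(13)
  p <- runif(20)^2
  perm <- sample(20)
  res <- bh_fdr(p)
  res_perm <- bh_fdr(p[perm])
  expect_equal(res_perm$significant, res$significant[perm])
  expect_true(all(bh_fdr(p, q = 0.01)$significant <= res$significant))
})

test_that("Cohen's d has unit scale invariance and sane intervals", {
  set.seed(14)
  a <- rnorm(30, mean = 1)
  d1 <- cohens_d_ci(a, n_boot = 0)
  expect_equal(d1$d, mean(a) / sd(a), tolerance = 1e-12)
  d2 <- cohens_d_ci(a * 7, n_boot = 0)
  expect_equal(d2$d, d1$d, tolerance = 1e-12)
  # two-sample: equal groups have d = 0 and a CI covering 0
  b1 <- rnorm(40); b2 <- rnorm(40)
  dd <- cohens_d_ci(b1, b2, n_boot = 500, seed = 15)
  expect_lt(dd$ci[1], 0)
  expect_gt(dd$ci[2], 0)
  expect_lt(abs(dd$d), 0.5)
  # exact two-sample value against the pooled-SD formula
  ref <- (mean(b1) - mean(b2)) /
    sqrt(((39) * var(b1) + (39) * var(b2)) / 78)
  expect_equal(dd$d, ref, tolerance = 1e-12)
  expect_error(cohens_d_ci(rep(2, 5), n_boot = 0), "zero standard deviation")
})

test_that("bootstrap intervals are reproducible and bracket the estimate", {
  set.seed(16)
  a <- rnorm(25, 0.8)
  ci1 <- cohens_d_ci(a, n_boot = 400, seed = 17)$ci
  ci2 <- cohens_d_ci(a, n_boot = 400, seed = 17)$ci
  expect_equal(ci1, ci2)
  d <- cohens_d_ci(a, n_boot = 0)$d
  expect_lt(ci1[1], d)
  expect_gt(ci1[2], d)
})

test_that("directional sampling percentages are well-formed", {
  log <- small_log()
  h <- directional_sampling(log)
  expect_equal(length(h), 36)
  expect_equal(sum(h), 100, tolerance = 1e-9)
  expect_true(all(h >= 0))
  expect_equal(names(h)[1:3], c("0", "10", "20"))
  expect_error(directional_sampling(log, bin_width = 7), "divide 360")
})

test_that("directional sampling respects state restriction and constant traces", {
  log <- small_log()
  labels <- label_states(log)
  h_l <- directional_sampling(log, state_labels = labels, state = "locomotion")
  h_s <- directional_sampling(log, state_labels = labels, state = "stationary")
  expect_equal(sum(h_l), 100, tolerance = 1e-9)
  expect_equal(sum(h_s), 100, tolerance = 1e-9)
  # a synthetic constant trace puts all mass into one bin
  fake <- log
  fake$samples$vhd <- rep(222, nrow(log$samples))
  h <- directional_sampling(fake)
  expect_equal(unname(h[["220"]]), 100)
  expect_equal(sum(h != 0), 1)
})

test_that("within-TR histograms align their modal bin at position one", {
  log <- small_log()
  al <- within_tr_alignment(log)
  expect_s3_class(al, "aligned_histogram")
  expect_equal(length(al$bins), 36)
  expect_equal(sum(al$bins), 100, tolerance = 1e-9)
  # by construction the first aligned bin is the per-TR maximum
  expect_equal(unname(al$bins[1]), max(al$bins))
  expect_equal(al$predominant_fraction, unname(al$bins[1]))
  expect_true(all(al$modal_direction %in% seq(0, 350, by = 10)))
  # directions are sticky within a TR: the predominant bin dominates
  expect_gt(al$predominant_fraction, 100 / 36)
})

test_that("a constant trace concentrates all within-TR mass at 100 percent", {
  log <- small_log()
  fake <- log
  fake$samples$vhd <- rep(90, nrow(log$samples))
  al <- within_tr_alignment(fake)
  expect_equal(unname(al$bins[1]), 100)
  expect_equal(sum(al$bins[-1]), 0)
  expect_true(all(al$modal_direction == 90))
  expect_equal(al$n_skipped, 0)
})

test_that("TRs without samples are skipped with a warning", {
  log <- small_log()
  fake <- log
  # drop every sample of the first TR
  keep <- fake$samples$t >= fake$tr
  fake$samples <- fake$samples[keep, ]
  expect_warning(al <- within_tr_alignment(fake), "skipped")
  expect_equal(al$n_skipped, 1)
  expect_equal(sum(al$bins), 100, tolerance = 1e-9)
})
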