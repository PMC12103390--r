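# Statistical layer: Wilcoxon signed-rank, Spearman, ROC cutpoint,
# Kaplan-Meier, log-rank, dichotomized survival.

test_that("all-equal pairs give a degenerate Wilcoxon with p = 1", {
  res <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
  expect_equal(res$n, 0L)
})

test_that("six uniformly positive differences give exact p = 2/2^6", {
  res <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6, 7), c(1, 2, 3, 4, 5, 6))
  expect_equal(res$p_value, 2 / 2^6)
  expect_equal(res$statistic, 21)
})

test_that("exact Wilcoxon p equals full 2^n enumeration for n <= 12", {
  set.seed(5)
  for (rep in 1:30) {
    n <- sample(3:12, 1)
    d <- round(rnorm(n), sample(0:1, 1))  # rounding induces ties/zeros
    if (all(d == 0)) d[1] <- 1
    res <- wilcoxon_signed_rank(d)
    expect_equal(res$p_value, oracle_signed_rank_p(d), tolerance = 1e-12)
  }
})

test_that("exact Wilcoxon agrees with stats::wilcox.test when tie-free", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(6:20, 1)
    d <- rnorm(n)
    res <- wilcoxon_signed_rank(d)
    ref <- wilcox.test(d, exact = TRUE)
    expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(res$statistic, unname(ref$statistic))
  }
})

test_that("the large-sample Wilcoxon approximation tracks the exact p", {
  set.seed(2)
  d <- rnorm(40, mean = 0.3)
  approx_p <- wilcoxon_signed_rank(d)$p_value     # n > 25 -> normal path
  exact_p <- wilcoxon_signed_rank(d, exact_max = 64)$p_value
  expect_equal(approx_p, exact_p, tolerance = 0.15)
})

test_that("Spearman rho hits the monotone extremes", {
  x <- c(1, 2, 5, 9, 12)
  expect_equal(spearman_test(x, x^3)$statistic, 1)
  expect_equal(spearman_test(x, -2 * x)$statistic, -1)
  expect_error(spearman_test(1:3, 1:3), "at least 4")
})

test_that("Spearman equals rank-then-Pearson with ties, p matches cor.test", {
  set.seed(8)
  for (rep in 1:20) {
    n <- sample(6:40, 1)
    x <- round(rnorm(n), 1); y <- round(rnorm(n), 1)  # many ties
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    res <- spearman_test(x, y)
    expect_equal(res$statistic, cor(rank(x), rank(y)), tolerance = 1e-12)
    ref <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
    expect_equal(res$statistic, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-9)
  }
})

test_that("a perfectly separating feature gives Youden J = 1", {
  cp <- roc_cutpoint(c(1, 2, 8, 9), c(0, 0, 1, 1))
  expect_equal(cp$youden_j, 1)
  expect_gt(cp$cutoff, 2)
  expect_lt(cp$cutoff, 8)
  expect_error(roc_cutpoint(c(1, 2), c(1, 1)), "both outcome classes")
  expect_error(roc_cutpoint(c(3, 3, 3), c(0, 1, 0)), "constant")
})

test_that("cutpoint search equals exhaustive enumeration on small inputs", {
  set.seed(12)
  for (rep in 1:40) {
    n <- sample(6:20, 1)
    v <- round(runif(n, 0, 10), 1)
    o <- rbinom(n, 1, 0.5)
    if (length(unique(o)) < 2 || length(unique(v)) < 2) next
    cp <- roc_cutpoint(v, o)
    or <- oracle_cutpoint(v, o)
    expect_equal(cp$cutoff, or$cut)
    expect_equal(cp$youden_j, or$j, tolerance = 1e-12)
  }
})

test_that("an outcome-independent feature has Youden J near zero", {
  set.seed(99)
  js <- replicate(200, {
    v <- rnorm(100); o <- rbinom(100, 1, 0.5)
    roc_cutpoint(v, o)$youden_j
  })
  # optimized J is biased upward but must stay small for n = 100
  expect_lt(mean(js), 0.25)
  expect_gt(mean(js), 0)
})

test_that("KM without censoring equals the empirical survival function", {
  set.seed(44)
  for (rep in 1:10) {
    tt <- round(rexp(sample(5:60, 1), 0.1), 2)
    km <- km_estimate(tt, rep(1, length(tt)))
    for (k in seq_along(km$time)) {
      expect_equal(km$surv[k], mean(tt > km$time[k]), tolerance = 1e-12)
    }
  }
})

test_that("KM median follows the S(t) <= 0.5 convention, NR when never reached", {
  km <- km_estimate(1:10, rep(1, 10))
  expect_equal(km$median, 5)                   # S(5) = 0.5 exactly
  km2 <- km_estimate(1:10, rep(0, 10))
  expect_true(is.na(km2$median))               # all censored -> not reached
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "survival times")
})

test_that("KM median recovers the exponential closed form ln2/hazard", {
  set.seed(100)
  tt <- rexp(5000, rate = 0.1)
  km <- km_estimate(tt, rep(1, 5000))
  expect_lt(abs(km$median - log(2) / 0.1), 0.2)
})

test_that("log-rank on identical groups is null and hand example matches", {
  tt <- c(1, 2, 3, 4); ev <- c(1, 1, 1, 1)
  res <- log_rank_test(c(tt, tt), c(ev, ev), rep(c("a", "b"), each = 4))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1, tolerance = 1e-12)

  # hand-computed O-E tables: groups {1, 3} and {2} events, all observed.
  # risk sets: t=1: (2,1); t=2: (1,1); t=3: (1,0)
  # E_a = 2/3 + 1/2 + 1 = 13/6; V = 2/9 + 1/4 = 17/36
  # chisq = (2 - 13/6)^2 / (17/36) = (1/36) / (17/36) = 1/17
  res2 <- log_rank_test(c(1, 3, 2), c(1, 1, 1), c("a", "a", "b"))
  expect_equal(res2$statistic, 1 / 17, tolerance = 1e-12)

  # invariance to time-scale multiplication
  set.seed(3)
  t3 <- rexp(30); e3 <- rbinom(30, 1, 0.8); g3 <- rep(c("a", "b"), 15)
  expect_equal(log_rank_test(t3, e3, g3)$statistic,
               log_rank_test(t3 * 12.7, e3, g3)$statistic, tolerance = 1e-12)
  expect_error(log_rank_test(t3, e3, rep("a", 30)), "two")
})

test_that("dichotomized survival flags degenerate features and recovers effects", {
  # constant feature -> flagged, no test
  out <- dichotomized_survival(rep(1, 10), rexp(10), rbinom(10, 1, 0.5))
  expect_true(out$degenerate)
  expect_match(out$reason, "constant")

  # strong binary effect: groups recovered, log-rank significant
  set.seed(55)
  n <- 120
  f <- c(rnorm(n / 2, 0), rnorm(n / 2, 5))
  h <- ifelse(f > 2.5, 0.02, 0.1)
  tt <- rexp(n, h); ev <- as.integer(tt <= 60); tt <- pmin(tt, 60)
  out2 <- dichotomized_survival(f, tt, ev, n_perm = 200, seed = 9)
  expect_false(out2$degenerate)
  expect_lt(out2$test$p_value, 0.01)
  expect_lt(out2$p_permutation, 0.05)
  expect_gt(out2$median_high, out2$median_low)
})

test_that("permutation calibration controls cutpoint optimism under the null", {
  set.seed(77)
  n_rep <- 60
  raw <- numeric(n_rep); cal <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    n <- 40
    f <- rnorm(n)
    tt <- rexp(n, 0.08); ev <- as.integer(tt <= 40); tt <- pmin(tt, 40)
    out <- dichotomized_survival(f, tt, ev, n_perm = 60, seed = r)
    if (out$degenerate) { raw[r] <- NA; cal[r] <- NA; next }
    raw[r] <- out$test$p_value
    cal[r] <- out$p_permutation
  }
  raw <- raw[!is.na(raw)]; cal <- cal[!is.na(cal)]
  # optimized-cutpoint raw p is anti-conservative; the permutation p must
  # be closer to nominal (and not smaller than the raw rejection rate)
  expect_gte(mean(raw < 0.05), mean(cal < 0.05))
  expect_lt(mean(cal < 0.05), 0.15)
})
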