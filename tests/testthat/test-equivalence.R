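test_that("one-sample TOST matches hand-computed normal tails", {
  # symmetric null estimate with a tight SE: both arms reject
  r <- tost_meta(0, 0.04, bound = 0.1)
  expect_equal(r$p_lower, pnorm(-2.5))
  expect_equal(r$p_upper, pnorm(-2.5))
  expect_equal(r$p_tost, pnorm(-2.5), tolerance = 1e-6)
  expect_equal(r$p_tost, 0.00621, tolerance = 1e-3)
  expect_true(r$equivalent)

  # estimate sitting exactly on the bound: upper arm is a coin flip
  r2 <- tost_meta(0.2, 0.1, bound = 0.2)
  expect_equal(r2$p_upper, 0.5)
  expect_false(r2$equivalent)

  # small but non-equivalent summary effect
  r3 <- tost_meta(0.14, 0.05, bound = 0.1)
  expect_equal(r3$p_upper, pnorm(0.8))
  expect_equal(r3$p_upper, 0.788, tolerance = 1e-3)
  expect_equal(c(r3$ci_tost_low, r3$ci_tost_high), c(0.0578, 0.2222),
               tolerance = 1e-3)
  expect_false(r3$equivalent)

  expect_error(tost_meta(0.1, 0.05, bound = -0.1), "bound")
  expect_error(tost_meta(0.1, 0, bound = 0.1), "se")
})

test_that("TOST decision and 90% CI-within-bounds criterion agree", {
  set.seed(23)
  n <- 2000
  smd <- rnorm(n, 0, 0.3)
  se <- runif(n, 0.01, 0.5)
  bound <- runif(n, 0.05, 0.5)
  r <- tost_meta(smd, se, bound)
  ci_inside <- r$ci_tost_low > -r$bound & r$ci_tost_high < r$bound
  expect_identical(r$equivalent, ci_inside)
})

test_that("widening the SESOI never destroys equivalence", {
  set.seed(29)
  smd <- rnorm(200, 0, 0.2)
  se <- runif(200, 0.01, 0.3)
  p1 <- tost_meta(smd, se, 0.1)$p_tost
  p2 <- tost_meta(smd, se, 0.2)$p_tost
  p3 <- tost_meta(smd, se, 0.3)$p_tost
  expect_true(all(p2 <= p1) && all(p3 <= p2))
})

test_that("upper TOST arm rejects at the nominal rate when truth is at +bound", {
  set.seed(31)
  reps <- 1e5
  se <- 0.12
  bound <- 0.2
  hat <- rnorm(reps, bound, se) # true effect exactly on the upper bound
  rej <- mean(pnorm((hat - bound) / se) <= 0.05)
  expect_lt(abs(rej - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("welch_t agrees with stats::t.test on raw data", {
  set.seed(37)
  for (i in 1:10) {
    x <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1), sd = runif(1, .5, 3))
    y <- rnorm(sample(5:40, 1), mean = runif(1, -1, 1), sd = runif(1, .5, 3))
    ref <- t.test(x, y)
    got <- welch_t(length(x), mean(x), sd(x), length(y), mean(y), sd(y))
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(got$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("welch_t reproduces the Satterthwaite df of the dosing contrast", {
  # multiple-dose vs single-dose clinical subgroups, from summary statistics
  w <- welch_t(30, 14.6, 18.9, 38, 10.3, 6.4)
  expect_equal(round(w$df, 1), 34.3)
  expect_equal(w$t, 1.19, tolerance = 0.01)
})

test_that("welch_t on identical groups reduces to the pooled t", {
  w <- welch_t(15, 2.3, 1.1, 15, 2.3, 1.1)
  expect_equal(w$t, 0)
  expect_equal(w$df, 28)
  expect_equal(w$p, 1)
  expect_error(welch_t(1, 0, 1, 10, 0, 1), "at least 2")
  expect_error(welch_t(10, 0, 0, 10, 0, 1), "Standard deviations")
})

test_that("two-sample TOST converts the d bound and tests on Welch df", {
  # equal means, large groups: easily equivalent at d = 0.2
  r <- tost_two_sample(1000, 0, 1, 1000, 0, 1, d_bound = 0.2)
  expect_equal(r$bound_raw, 0.2)
  expect_equal(r$t_lower, 0.2 / sqrt(2 / 1000), tolerance = 1e-10)
  expect_true(r$equivalent)
  expect_lt(r$p_tost, 0.05)

  # mean difference exactly at the raw bound: p_tost = 0.5
  r2 <- tost_two_sample(20, 1.2, 1, 25, 1.0, 1, d_bound = 0.2)
  expect_equal(r2$p_upper, 0.5)
  expect_equal(r2$p_tost, 0.5)
  expect_false(r2$equivalent)

  # the dosing-contrast summaries are far from equivalent at d = 0.2
  r3 <- tost_two_sample(30, 14.6, 18.9, 38, 10.3, 6.4, d_bound = 0.2)
  expect_false(r3$equivalent)
  expect_gt(r3$p_tost, 0.05)
  expect_equal(r3$df, welch_t(30, 14.6, 18.9, 38, 10.3, 6.4)$df)
})

test_that("equivalence screen separates NHST-significant metas and matches a row-wise oracle", {
  corp <- generate_corpus(generator_config(n_metas = 20, seed = 43))
  scr <- equivalence_screen(corp, bounds = c(0.1, 0.3))
  expect_equal(nrow(scr), 40)

  # oracle: plain per-row recomputation from the metas table
  for (i in seq_len(nrow(scr))) {
    m <- corp$metas[corp$metas$meta_id == scr$meta_id[i], ]
    expect_identical(scr$nhst_significant[i],
                     abs(m$smd) / m$se > qnorm(0.975))
    p_up <- pnorm((m$smd - scr$bound[i]) / m$se)
    p_lo <- 1 - pnorm((m$smd + scr$bound[i]) / m$se)
    expect_equal(scr$p_tost[i], max(p_up, p_lo), tolerance = 1e-12)
    expect_identical(scr$equivalent[i], max(p_up, p_lo) <= 0.05)
  }

  # a strongly significant meta is never counted as equivalent-nonsignificant
  strong <- scr[scr$nhst_significant, ]
  if (nrow(strong)) expect_true(all(strong$nhst_significant))
})
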