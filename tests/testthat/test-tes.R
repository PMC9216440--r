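test_that("study significance is the two-sided z criterion", {
  expect_true(study_significant(0.4, 0.1))
  expect_false(study_significant(0.1, 0.1))
  expect_true(study_significant(1.959965 * 0.2, 0.2))   # just over
  expect_false(study_significant(1.959963 * 0.2, 0.2))  # just under
  expect_error(study_significant(0.2, 0), "se")
})

test_that("exact Poisson-binomial tail matches full enumeration", {
  set.seed(47)
  for (i in 1:15) {
    n <- sample(2:10, 1)
    p <- runif(n)
    k <- sample(0:n, 1)
    expect_equal(poweraudit:::poisson_binomial_tail(p, k),
                 enumerate_pb_tail(p, k), tolerance = 1e-12)
  }
  expect_equal(poweraudit:::poisson_binomial_tail(c(0.2, 0.8), 0), 1)
  expect_equal(poweraudit:::poisson_binomial_tail(c(0.2, 0.8), 3), 0)
})

test_that("tes computes O, E and both test forms correctly", {
  # ten studies whose powers at theta_ref are known through wald_power;
  # 9 significant by construction
  se <- rep(0.102, 10)
  smd <- c(rep(0.5, 9), 0.01) # |z| > 1.96 for 9, far under for 1
  studies <- tibble::tibble(study_id = sprintf("s%d", 1:10),
                            smd = smd, se = se)
  theta <- 0.2
  r <- tes(studies, theta_ref = theta, form = "chisq")
  E <- sum(wald_power(theta, se))
  expect_equal(r$n, 10)
  expect_equal(r$O, 9)
  expect_equal(r$E, E, tolerance = 1e-12)
  A <- (9 - E)^2 / E + (9 - E)^2 / (10 - E)
  expect_equal(r$A, A, tolerance = 1e-12)
  expect_equal(r$p, pchisq(A, 1, lower.tail = FALSE) / 2, tolerance = 1e-12)
  expect_true(r$flagged)

  # near-half powers: the frozen Ioannidis-Trikalinos reference case
  expect_equal(E, 5, tolerance = 0.01)
  expect_equal(A, 6.4, tolerance = 0.05)

  rx <- tes(studies, theta_ref = theta, form = "exact")
  expect_equal(rx$p, enumerate_pb_tail(wald_power(theta, se), 9),
               tolerance = 1e-10)
  expect_equal(rx$p, 0.0107, tolerance = 0.02) # ~ binomial(10, .5) tail at 9
  expect_true(rx$flagged)
})

test_that("tes never flags without an excess (O <= E)", {
  se <- rep(0.1, 8)
  studies <- tibble::tibble(study_id = sprintf("s%d", 1:8),
                            smd = rep(0.05, 8), se = se) # none significant
  r <- tes(studies, theta_ref = 0.5, form = "chisq")
  expect_equal(r$O, 0)
  expect_gt(r$E, 0)
  expect_false(r$flagged)
  expect_gt(r$p, 0.5) # deficit direction

  # O == E (near-integer case): A ~ 0, not flagged
  studies2 <- tibble::tibble(study_id = sprintf("s%d", 1:4),
                             smd = c(0.5, 0.5, 0.01, 0.01),
                             se = rep(0.102, 4))
  r2 <- tes(studies2, theta_ref = 0.2, form = "chisq")
  expect_equal(r2$O, 2)
  expect_lt(abs(r2$A), 0.01)
  expect_false(r2$flagged)
})

test_that("degenerate expected counts fall back to the exact form", {
  # powers ~ 1 and all studies significant: no excess is possible
  studies <- tibble::tibble(study_id = sprintf("s%d", 1:5),
                            smd = rep(2, 5), se = rep(0.1, 5))
  expect_warning(r <- tes(studies, theta_ref = 2, form = "chisq"),
                 "degenerate")
  expect_equal(r$form, "exact")
  expect_equal(r$O, 5)
  expect_false(r$flagged)
  expect_error(tes(studies[1, ], 0.2), "at least 2")
})

test_that("multi-outcome studies contribute median power and median-|z| significance", {
  studies <- tibble::tibble(
    study_id = c("a", "a", "a", "b", "b"),
    smd = c(0.5, 0.30, 0.01, 0.4, 0.01),
    se = c(0.1, 0.12, 0.30, 0.1, 0.1))
  r <- tes(studies, theta_ref = 0.3, form = "exact")
  expect_equal(r$n, 2)
  # study a: median |z| of (5, 2.5, 0.033) is 2.5 -> significant
  # study b: median |z| of (4, 0.1) is 2.05 -> significant
  expect_equal(r$O, 2)
  expect_equal(r$E,
               median(wald_power(0.3, c(0.1, 0.12, 0.30))) +
                 median(wald_power(0.3, c(0.1, 0.1))),
               tolerance = 1e-12)
  # the any-outcome rule can only increase O
  r_any <- tes(studies, theta_ref = 0.3, form = "exact",
               outcome_rule = "any")
  expect_gte(r_any$O, r$O)
})

test_that("tes_screen covers univariate metas only and warns when none exist", {
  corp <- generate_corpus(generator_config(n_metas = 15, seed = 53))
  scr <- tes_screen(corp, form = "exact")
  uni <- corp$metas$meta_id[corp$metas$design == "univariate"]
  expect_setequal(scr$meta_id, uni)

  corp$metas$design <- "multivariate"
  expect_warning(empty <- tes_screen(corp), "No univariate")
  expect_equal(nrow(empty), 0)
})

test_that("chi-square and exact forms mostly agree on flag decisions", {
  set.seed(59)
  agree <- 0
  trials <- 60
  for (i in seq_len(trials)) {
    n <- sample(10:16, 1)
    powers <- runif(n, 0.2, 0.8)
    O <- rbinom(1, n, mean(powers))
    E <- sum(powers)
    A <- (O - E)^2 / E + (O - E)^2 / (n - E)
    p_chi <- pchisq(A, 1, lower.tail = FALSE) / 2
    p_chi <- if (O > E) p_chi else 1 - p_chi
    p_ex <- poweraudit:::poisson_binomial_tail(powers, O)
    f_chi <- p_chi < 0.05 && O > E
    f_ex <- p_ex < 0.05 && O > E
    agree <- agree + (f_chi == f_ex)
  }
  expect_gte(agree / trials, 0.95)
})
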