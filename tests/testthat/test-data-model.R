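test_that("se_from_ci recovers the SE of a symmetric normal interval", {
  # width of 2 * z_{0.975} has SE exactly 1
  expect_equal(se_from_ci(-1.959964, 1.959964), 1.0, tolerance = 1e-6)
  expect_equal(se_from_ci(0.05, 0.45), 0.4 / (2 * qnorm(0.975)),
               tolerance = 1e-12)
  expect_equal(se_from_ci(0.05, 0.45), 0.10204, tolerance = 1e-4)
  # other levels use the matching quantile
  expect_equal(se_from_ci(-1, 1, level = 0.9), 1 / qnorm(0.95))
})

test_that("se_from_ci rejects degenerate or non-finite intervals", {
  expect_error(se_from_ci(0, 0), "Inverted or degenerate")
  expect_error(se_from_ci(0.3, 0.1), "Inverted or degenerate")
  expect_error(se_from_ci(NA_real_, 1), "Non-finite")
  expect_error(se_from_ci(-1, 1, level = 1.2), "level")
})

test_that("CI -> SE -> CI round trip is the identity for midpoint estimates", {
  set.seed(41)
  for (i in 1:50) {
    mid <- rnorm(1)
    half <- runif(1, 0.01, 2)
    se <- se_from_ci(mid - half, mid + half)
    z <- qnorm(0.975)
    expect_equal(c(mid - z * se, mid + z * se), c(mid - half, mid + half),
                 tolerance = 1e-9)
  }
})

test_that("resolve_se fills missing SEs from CIs and names unresolvable rows", {
  df <- tibble::tibble(
    meta_id = "m1", study_id = c("a", "b"),
    smd = c(0.2, 0.25), se = c(0.1, NA),
    ci_low = c(NA, 0.05), ci_high = c(NA, 0.45))
  out <- resolve_se(df)
  expect_equal(out$se, c(0.1, se_from_ci(0.05, 0.45)))
  expect_identical(attr(out, "n_se_from_ci"), 1L)

  df$ci_low[2] <- NA
  expect_error(resolve_se(df), "m1/b")
})

test_that("sign convention negates flagged metas, swaps CI bounds, keeps SEs", {
  corp <- tiny_corpus()
  corp$metas$reverse_sign[1] <- TRUE
  corp$metas$ci_low <- corp$metas$smd - 0.2
  corp$metas$ci_high <- corp$metas$smd + 0.1
  out <- apply_sign_convention(corp)
  expect_equal(out$metas$smd, c(-0.10, 0.50))
  expect_equal(out$metas$ci_low[1], -(corp$metas$ci_high[1]))
  expect_equal(out$metas$ci_high[1], -(corp$metas$ci_low[1]))
  expect_lt(out$metas$ci_low[1], out$metas$ci_high[1])
  expect_equal(out$metas$se, corp$metas$se)
  # member outcomes of the flagged meta are negated; the other meta untouched
  expect_equal(out$studies$smd[out$studies$meta_id == "mA"],
               -corp$studies$smd[corp$studies$meta_id == "mA"])
  expect_equal(out$studies$smd[out$studies$meta_id == "mB"],
               corp$studies$smd[corp$studies$meta_id == "mB"])
  # involution: applying twice restores every numeric field
  twice <- apply_sign_convention(out)
  expect_equal(twice$metas, corp$metas)
  expect_equal(twice$studies, corp$studies)
})

test_that("read_corpus ingests the fixture schema and reports conversions", {
  paths <- write_tmp_corpus(tiny_corpus())
  expect_message(corp <- read_corpus(paths[1], paths[2]),
                 "2 meta-analyses / 3 unique studies")
  cnt <- corpus_counts(corp)
  expect_equal(cnt$n_metas, 2L)
  expect_equal(cnt$n_unique_studies, 3L)
  expect_equal(cnt$n_outcome_rows, 4L)

  # blank an SE but keep the CI: resolved via the conversion
  studies <- readr::read_csv(paths[2], show_col_types = FALSE)
  studies$se[1] <- NA
  studies$ci_low[1] <- 0.05 - 1.959964 * 0.2
  studies$ci_high[1] <- 0.05 + 1.959964 * 0.2
  readr::write_csv(studies, paths[2], na = "")
  corp2 <- read_corpus(paths[1], paths[2], quiet = TRUE)
  expect_equal(corp2$studies$se[1], 0.2, tolerance = 1e-6)
  expect_equal(attr(corp2, "load_report")$n_se_from_ci, 1)

  # blank both: error naming the row
  studies$ci_low[1] <- NA
  readr::write_csv(studies, paths[2], na = "")
  expect_error(read_corpus(paths[1], paths[2], quiet = TRUE), "s1")
})

test_that("read_corpus rejects schema violations", {
  paths <- write_tmp_corpus(tiny_corpus())
  metas <- readr::read_csv(paths[1], show_col_types = FALSE)
  readr::write_csv(metas[, setdiff(names(metas), "design")], paths[1])
  # readr also warns about the absent named column; only the error matters
  suppressWarnings(
    expect_error(read_corpus(paths[1], paths[2], quiet = TRUE), "design"))
})

test_that("write/read round trip reproduces the corpus field-for-field", {
  corp <- tiny_corpus()
  corp$metas$reverse_sign[2] <- TRUE
  corp <- apply_sign_convention(corp) # normalized in-memory form
  paths <- write_tmp_corpus(corp)
  back <- read_corpus(paths[1], paths[2], quiet = TRUE)
  expect_equal(back$metas, corp$metas)
  expect_equal(back$studies, corp$studies)
})

test_that("corpus validation catches structural errors", {
  corp <- tiny_corpus()
  expect_error(meta_corpus(corp$metas[1, ], corp$studies), "unknown meta_id")
  expect_error(meta_corpus(corp$metas, corp$studies[-4, ]),
               "no member studies")
  expect_error(
    meta_corpus(dplyr::bind_rows(corp$metas, corp$metas[1, ]), corp$studies),
    "Duplicated meta_id")
  corp$studies$year[1] <- 1890L
  expect_warning(meta_corpus(corp$metas, corp$studies), "Implausible")
})
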