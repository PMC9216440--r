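# small corpora built in code for the unit tests

# two meta-analyses (one univariate, one multivariate, one sign-reversed),
# three unique studies, one shared across both metas, one multi-outcome
tiny_corpus <- function() {
  metas <- tibble::tibble(
    meta_id = c("mA", "mB"),
    label = c("attention", "social cognition"),
    smd = c(0.10, 0.50),
    se = c(0.08, 0.10),
    ci_low = NA_real_, ci_high = NA_real_,
    reverse_sign = c(FALSE, FALSE),
    design = c("univariate", "multivariate"))
  studies <- tibble::tibble(
    meta_id = c("mA", "mA", "mA", "mB"),
    study_id = c("s1", "s2", "s2", "s3"),
    year = c(2012L, 2015L, 2015L, 2016L),
    smd = c(0.05, 0.30, 0.10, 0.60),
    se = c(0.20, 0.25, 0.30, 0.15),
    ci_low = NA_real_, ci_high = NA_real_,
    population = c("clinical", "healthy", "healthy", "clinical"),
    dosing = c("single", "single", "single", "multiple"))
  meta_corpus(metas, studies)
}

# write a corpus in the text schema under a temp dir; returns c(meta, study)
write_tmp_corpus <- function(corpus, dir = withr::local_tempdir(
                               .local_envir = parent.frame())) {
  paths <- c(file.path(dir, "metas.csv"), file.path(dir, "studies.csv"))
  write_corpus(corpus, paths[1], paths[2])
  paths
}

# brute-force Poisson-binomial upper tail by enumerating all 2^n outcomes
enumerate_pb_tail <- function(p, k) {
  n <- length(p)
  total <- 0
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask)[seq_len(n)])
    if (sum(bits) >= k) {
      total <- total + prod(ifelse(bits == 1, p, 1 - p))
    }
  }
  total
}

expect_tbl_equal <- function(a, b, tol = 1e-9) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tol)
}
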