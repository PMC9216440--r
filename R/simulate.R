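#' Configuration for the synthetic corpus generator
#'
#' Parameters of the generative model behind [generate_corpus()]. The
#' defaults emulate the statistical skeleton of the published oxytocin
#' administration literature: about 35 meta-analyses with a few studies each,
#' small true effects centred near 0.14 with modest heterogeneity, and
#' per-group sample sizes (10–40) that put typical study power in the single
#' digits at effects of that size.
#'
#' @param n_metas Number of meta-analyses.
#' @param studies_per_meta Integer range `c(lo, hi)` of studies per
#'   meta-analysis.
#' @param mu Grand mean true SMD across meta-analyses.
#' @param tau Between-meta SD of true effects (non-negative).
#' @param within_tau Between-study SD of true effects within a meta-analysis
#'   (non-negative).
#' @param n_per_group Integer range of per-group sample sizes (two equal
#'   groups per study), each >= 5.
#' @param censor_prob Probability that a non-significant study is dropped
#'   from the published record — the publication-bias knob. 0 disables
#'   censoring.
#' @param multi_outcome_prob Probability a study reports several outcomes.
#' @param outcomes_per_study Integer range of outcome counts for
#'   multi-outcome studies.
#' @param year_range Integer range of publication years.
#' @param clinical_prob Probability a study is in a clinical population.
#' @param multiple_dose_prob Probability a study uses multiple doses.
#' @param univariate_prob Probability a meta-analysis is univariate (the only
#'   kind screened by the Test of Excess Significance).
#' @param reverse_prob Probability a meta-analysis coded benefit as negative
#'   and so carries the `reverse_sign` flag.
#' @param summary_method `"FE"` (fixed-effect inverse variance, default) or
#'   `"DL"` (DerSimonian–Laird random effects) for the generator's summary
#'   estimates.
#' @param seed Integer RNG seed; the corpus is fully reproducible from it.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_metas = 35,
                             studies_per_meta = c(2, 5),
                             mu = 0.14,
                             tau = 0.1,
                             within_tau = 0.1,
                             n_per_group = c(10, 40),
                             censor_prob = 0,
                             multi_outcome_prob = 0.3,
                             outcomes_per_study = c(2, 3),
                             year_range = c(2010, 2017),
                             clinical_prob = 0.64,
                             multiple_dose_prob = 0.44,
                             univariate_prob = 18 / 35,
                             reverse_prob = 8 / 35,
                             summary_method = c("FE", "DL"),
                             seed = 1L) {
  cfg <- list(
    n_metas = as.integer(n_metas), studies_per_meta = as.integer(studies_per_meta),
    mu = mu, tau = tau, within_tau = within_tau,
    n_per_group = as.integer(n_per_group), censor_prob = censor_prob,
    multi_outcome_prob = multi_outcome_prob,
    outcomes_per_study = as.integer(outcomes_per_study),
    year_range = as.integer(year_range), clinical_prob = clinical_prob,
    multiple_dose_prob = multiple_dose_prob,
    univariate_prob = univariate_prob, reverse_prob = reverse_prob,
    summary_method = match.arg(summary_method), seed = as.integer(seed))
  probs <- c(cfg$censor_prob, cfg$multi_outcome_prob, cfg$clinical_prob,
             cfg$multiple_dose_prob, cfg$univariate_prob, cfg$reverse_prob)
  stopifnot(
    cfg$n_metas >= 1,
    length(cfg$studies_per_meta) == 2,
    cfg$studies_per_meta[1] >= 1,
    cfg$studies_per_meta[1] <= cfg$studies_per_meta[2],
    cfg$tau >= 0, cfg$within_tau >= 0,
    length(cfg$n_per_group) == 2, cfg$n_per_group[1] >= 5,
    cfg$n_per_group[1] <= cfg$n_per_group[2],
    all(probs >= 0 & probs <= 1),
    length(cfg$outcomes_per_study) == 2,
    cfg$outcomes_per_study[1] >= 1,
    cfg$outcomes_per_study[1] <= cfg$outcomes_per_study[2],
    length(cfg$year_range) == 2, cfg$year_range[1] <= cfg$year_range[2],
    is.finite(cfg$seed))
  structure(cfg, class = "generator_config")
}

# large-sample sampling SD of an SMD from two equal groups of size n
smd_se <- function(d, n) sqrt(2 / n + d^2 / (4 * n))

rand_int <- function(k, range) {
  if (range[1] == range[2]) rep(range[1], k)
  else sample(seq(range[1], range[2]), k, replace = TRUE)
}

# inverse-variance pooling; DL adds a method-of-moments tau^2 to the weights
pool_summary <- function(d, se, method = "FE") {
  w <- 1 / se^2
  if (method == "DL" && length(d) > 1) {
    mu_fe <- sum(w * d) / sum(w)
    q <- sum(w * (d - mu_fe)^2)
    tau2 <- max(0, (q - (length(d) - 1)) / (sum(w) - sum(w^2) / sum(w)))
    w <- 1 / (se^2 + tau2)
  }
  c(smd = sum(w * d) / sum(w), se = sqrt(1 / sum(w)))
}

#' Generate a synthetic meta-analysis corpus
#'
#' Simulates a corpus under a nested random-effects model: meta-analysis true
#' effects `theta_k ~ N(mu, tau^2)`, study true effects
#' `theta_ki ~ N(theta_k, within_tau^2)`, and observed SMDs drawn with the
#' large-sample sampling SD `sqrt(2/n + d^2/(4n))` implied by two equal
#' groups of size `n`. With `censor_prob > 0`, a study whose (median-|z|)
#' outcome is non-significant is dropped from the record with that
#' probability, mimicking publication bias; a meta-analysis losing all its
#' studies is regenerated (up to 100 attempts). Summary estimates are pooled
#' from the surviving outcomes by inverse variance. One RNG stream is seeded
#' from the config, with per-meta sub-seeds, so corpora are byte-identical
#' across runs of the same config.
#'
#' @param config A [generator_config()].
#' @return A normalized `meta_corpus`; meta-analyses drawn as sign-reversed
#'   carry `reverse_sign = TRUE` and are written back in the publication
#'   direction by [write_corpus()]/[write_fixture()].
#' @export
generate_corpus <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, config$n_metas)

  one_meta <- function(k) {
    set.seed(sub_seeds[k])
    design <- if (stats::runif(1) < config$univariate_prob) "univariate" else "multivariate"
    reverse <- stats::runif(1) < config$reverse_prob
    theta_k <- stats::rnorm(1, config$mu, config$tau)
    n_studies <- rand_int(1, config$studies_per_meta)

    for (attempt in seq_len(100)) {
      rows <- purrr::map(seq_len(n_studies), function(j) {
        theta_kj <- stats::rnorm(1, theta_k, config$within_tau)
        n <- rand_int(1, config$n_per_group)
        n_out <- if (stats::runif(1) < config$multi_outcome_prob) {
          rand_int(1, config$outcomes_per_study)
        } else 1L
        d <- stats::rnorm(n_out, theta_kj, smd_se(theta_kj, n))
        se <- smd_se(d, n)
        tibble::tibble(
          study_id = sprintf("s%02d.%02d", k, j),
          year = rand_int(1, config$year_range),
          smd = d, se = se,
          population = if (stats::runif(1) < config$clinical_prob) "clinical" else "healthy",
          dosing = if (stats::runif(1) < config$multiple_dose_prob) "multiple" else "single")
      }) |> purrr::list_rbind()

      if (config$censor_prob > 0) {
        sig <- rows |>
          dplyr::summarise(
            sig = stats::median(abs(.data$smd) / .data$se) > z_crit(0.05),
            .by = "study_id")
        u <- stats::runif(nrow(sig))
        drop <- sig$study_id[!sig$sig & u < config$censor_prob]
        rows <- rows[!rows$study_id %in% drop, ]
      }
      if (nrow(rows) > 0) break
      if (attempt == 100) {
        abort(sprintf("Meta-analysis %d: no studies survived censoring after 100 attempts.", k))
      }
    }

    sm <- pool_summary(rows$smd, rows$se, config$summary_method)
    rows$meta_id <- sprintf("meta%02d", k)
    rows$ci_low <- rows$smd - z_crit(0.05) * rows$se
    rows$ci_high <- rows$smd + z_crit(0.05) * rows$se
    meta <- tibble::tibble(
      meta_id = sprintf("meta%02d", k),
      label = sprintf("synthetic meta-analysis %02d", k),
      smd = sm[["smd"]], se = sm[["se"]],
      ci_low = sm[["smd"]] - z_crit(0.05) * sm[["se"]],
      ci_high = sm[["smd"]] + z_crit(0.05) * sm[["se"]],
      reverse_sign = reverse, design = design)
    list(meta = meta, studies = rows[, study_cols])
  }

  parts <- purrr::map(seq_len(config$n_metas), one_meta)
  corpus <- meta_corpus(purrr::list_rbind(purrr::map(parts, "meta")),
                        purrr::list_rbind(purrr::map(parts, "studies")))
  attr(corpus, "config") <- config
  corpus
}

#' Write a synthetic fixture to disk
#'
#' Generates a corpus from `config` and writes it in the [read_corpus()]
#' schema (meta and study tables, publication direction) together with a JSON
#' manifest recording the full configuration, so the fixture is auditable and
#' regenerable.
#'
#' @param config A [generator_config()].
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"tsv"`.
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_fixture <- function(config = generator_config(), dir,
                          format = c("csv", "tsv")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  corpus <- generate_corpus(config)
  paths <- c(metas = file.path(dir, paste0("metas.", format)),
             studies = file.path(dir, paste0("studies.", format)),
             manifest = file.path(dir, "manifest.json"))
  write_corpus(corpus, paths[["metas"]], paths[["studies"]])
  jsonlite::write_json(unclass(config), paths[["manifest"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}
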