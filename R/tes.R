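#' Two-sided significance of a single effect estimate
#'
#' A study outcome counts as statistically significant when `|smd| / se`
#' exceeds the two-sided normal critical value at level `alpha`.
#'
#' @param smd Effect estimate(s).
#' @param se Standard error(s), > 0.
#' @param alpha Two-sided level. Default 0.05.
#' @return Logical vector.
#' @export
study_significant <- function(smd, se, alpha = 0.05) {
  if (any(!is.finite(se) | se <= 0)) abort("`se` must be finite and > 0.")
  abs(smd) / se > z_crit(alpha)
}

# exact Poisson-binomial upper tail P(X >= k) for independent Bernoulli
# trials with success probabilities p, by direct convolution of the pmf
poisson_binomial_tail <- function(p, k) {
  if (any(p < 0 | p > 1)) abort("Probabilities must lie in [0, 1].")
  if (k <= 0) return(1)
  n <- length(p)
  if (k > n) return(0)
  pmf <- 1
  for (pi in p) pmf <- c(pmf * (1 - pi), 0) + c(0, pmf * pi)
  sum(pmf[(k + 1):(n + 1)])
}

#' Test of Excess Significance for one meta-analysis
#'
#' Compares the observed number of statistically significant constituent
#' studies, O, with the number expected from their individual powers,
#' `E = sum(power_i)`, where each study's power is the two-sided Wald power
#' at a reference true effect (by default the meta-analysis summary
#' estimate). A study with several outcomes contributes the median of its
#' outcome powers to E, and counts as significant when its median-|z| outcome
#' is significant (set `outcome_rule = "any"` for the any-outcome rule).
#'
#' Two test forms are available. The chi-square form uses the
#' Ioannidis–Trikalinos statistic `A = (O-E)^2/E + (O-E)^2/(n-E)` with a
#' one-sided p (half the chi-square(1) tail, assigned to the excess
#' direction). The exact form is the one-sided Poisson-binomial tail
#' `P(X >= O)` under the per-study powers; it is also the automatic fallback
#' when E is degenerate (0 or n). A meta-analysis is flagged when `p <
#' threshold` *and* O > E — an excess, not any misfit.
#'
#' @param studies Data frame of the meta-analysis's outcome rows, with
#'   columns `study_id`, `smd`, `se`.
#' @param theta_ref Reference true effect used for the expected powers;
#'   typically the meta-analysis summary estimate.
#' @param alpha Two-sided significance level defining a "significant study"
#'   and used in the power computation. Default 0.05.
#' @param form `"chisq"` (default) or `"exact"`.
#' @param threshold One-sided flagging threshold. Default 0.05.
#' @param outcome_rule `"median_z"` (default) or `"any"`: how a multi-outcome
#'   study's significance status is collapsed.
#' @return A one-row tibble: `n`, `O`, `E`, `A` (NA for the exact form),
#'   `p`, `form`, `flagged`.
#' @export
tes <- function(studies, theta_ref, alpha = 0.05,
                form = c("chisq", "exact"), threshold = 0.05,
                outcome_rule = c("median_z", "any")) {
  form <- match.arg(form)
  outcome_rule <- match.arg(outcome_rule)
  if (dplyr::n_distinct(studies$study_id) < 2) {
    abort("Test of Excess Significance needs at least 2 studies.")
  }
  if (!is.finite(theta_ref)) abort("`theta_ref` must be finite.")

  per_study <- studies |>
    dplyr::summarise(
      power = dedup_power(wald_power(theta_ref, .data$se, alpha)),
      significant = if (outcome_rule == "any") {
        any(study_significant(.data$smd, .data$se, alpha))
      } else {
        # the outcome whose |z| is the study's median |z| decides
        stats::median(abs(.data$smd) / .data$se) > z_crit(alpha)
      },
      .by = "study_id")

  n <- nrow(per_study)
  O <- sum(per_study$significant)
  E <- sum(per_study$power)
  degenerate <- E <= 0 || E >= n
  if (degenerate && form == "chisq") {
    warn("Expected count E is degenerate (0 or n); using the exact form.")
    form <- "exact"
  }
  if (form == "chisq") {
    A <- (O - E)^2 / E + (O - E)^2 / (n - E)
    half <- stats::pchisq(A, df = 1, lower.tail = FALSE) / 2
    p <- if (O > E) half else 1 - half
  } else {
    A <- NA_real_
    p <- poisson_binomial_tail(per_study$power, O)
  }
  tibble::tibble(n = n, O = O, E = E, A = A, p = p, form = form,
                 flagged = p < threshold & O > E)
}

#' Test of Excess Significance across a corpus
#'
#' Runs [tes()] for every univariate meta-analysis in the corpus
#' (multivariate meta-analyses are skipped: their constituent estimates are
#' not independent significance tests of one effect). The reference effect is
#' each meta-analysis's own summary estimate by default, or a fixed user
#' value.
#'
#' @param corpus A `meta_corpus`.
#' @param reference `"summary"` (default) or a single numeric SMD used for
#'   every meta-analysis.
#' @inheritParams tes
#' @return A tibble with one row per univariate meta-analysis with >= 2
#'   studies: `meta_id`, `n`, `O`, `E`, `A`, `p`, `form`, `flagged`. Empty
#'   (with a warning) when the corpus has no univariate meta-analyses.
#' @export
tes_screen <- function(corpus, reference = "summary", alpha = 0.05,
                       form = c("chisq", "exact"), threshold = 0.05,
                       outcome_rule = c("median_z", "any")) {
  stopifnot(inherits(corpus, "meta_corpus"))
  form <- match.arg(form)
  outcome_rule <- match.arg(outcome_rule)
  uni <- corpus$metas[corpus$metas$design == "univariate", ]
  if (nrow(uni) == 0) {
    warn("No univariate meta-analyses in the corpus; empty TES table.")
    return(tibble::tibble(meta_id = character(), n = integer(),
                          O = integer(), E = double(), A = double(),
                          p = double(), form = character(),
                          flagged = logical()))
  }
  purrr::map(seq_len(nrow(uni)), function(i) {
    rows <- corpus$studies[corpus$studies$meta_id == uni$meta_id[i], ]
    if (dplyr::n_distinct(rows$study_id) < 2) return(NULL)
    theta <- if (identical(reference, "summary")) uni$smd[i] else reference
    dplyr::bind_cols(tibble::tibble(meta_id = uni$meta_id[i]),
                     tes(rows, theta, alpha, form, threshold, outcome_rule))
  }) |>
    purrr::list_rbind()
}
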