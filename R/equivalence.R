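#' One-sample TOST equivalence test for a summary effect
#'
#' Two one-sided z-tests of a summary SMD with known standard error against
#' the equivalence bounds (-bound, +bound): the upper test rejects effects at
#' or above `+bound` with `p_upper = pnorm((smd - bound)/se)`, the lower test
#' rejects effects at or below `-bound` with
#' `p_lower = 1 - pnorm((smd + bound)/se)`. Equivalence is declared when both
#' reject, i.e. `p_tost = max(p_lower, p_upper) <= alpha`, which is the same
#' as the `(1 - 2*alpha)` confidence interval lying strictly inside the
#' bounds. Tests are z-based because the input is an estimate with a standard
#' error; no degrees of freedom are available from a meta-analytic summary.
#'
#' @param smd Summary standardized mean difference (vectorized).
#' @param se Standard error(s), > 0.
#' @param bound Smallest effect size of interest (SESOI) on the SMD scale
#'   (positive); the equivalence bounds are `-bound` and `+bound`.
#' @param alpha One-sided level of each test. Default 0.05, giving a 90% TOST
#'   interval and a 95% NHST interval.
#' @return A tibble, one row per input: `smd`, `se`, `bound`, `p_lower`,
#'   `p_upper`, `p_tost`, `ci_tost_low`/`ci_tost_high` (the `(1-2*alpha)`
#'   interval), `ci_nhst_low`/`ci_nhst_high` (the `(1-alpha)` interval), and
#'   `equivalent`.
#' @examples
#' tost_meta(0, 0.04, bound = 0.1)    # clearly equivalent: p = pnorm(-2.5)
#' tost_meta(0.14, 0.05, bound = 0.1) # not equivalent
#' @export
tost_meta <- function(smd, se, bound, alpha = 0.05) {
  if (any(!is.finite(bound) | bound <= 0)) abort("`bound` must be > 0.")
  if (any(!is.finite(se) | se <= 0)) abort("`se` must be finite and > 0.")
  n <- max(length(smd), length(se), length(bound))
  smd <- rep_len(smd, n); se <- rep_len(se, n); bound <- rep_len(bound, n)
  p_upper <- stats::pnorm((smd - bound) / se)
  p_lower <- stats::pnorm((smd + bound) / se, lower.tail = FALSE)
  p_tost <- pmax(p_lower, p_upper)
  z1 <- stats::qnorm(1 - alpha)
  z2 <- z_crit(alpha)
  tibble::tibble(
    smd = smd, se = se, bound = bound,
    p_lower = p_lower, p_upper = p_upper, p_tost = p_tost,
    ci_tost_low = smd - z1 * se, ci_tost_high = smd + z1 * se,
    ci_nhst_low = smd - z2 * se, ci_nhst_high = smd + z2 * se,
    equivalent = p_tost <= alpha)
}

#' Equivalence screen of every meta-analysis in a corpus
#'
#' For each meta-analysis: its null-hypothesis significance status
#' (`|smd|/se` against the two-sided z criterion), then a TOST result at
#' every requested SESOI bound. Equivalence counts are conventionally read
#' among the non-significant meta-analyses — those are the ones for which
#' "no effect" and "not enough data" must be told apart.
#'
#' @param corpus A `meta_corpus`.
#' @param bounds Vector of SESOI bounds. Default `c(0.1, 0.2, 0.3)`.
#' @param alpha Significance level (one-sided per TOST arm, two-sided for the
#'   NHST column).
#' @return A tibble with one row per meta-analysis per bound: `meta_id`,
#'   `nhst_significant`, then the [tost_meta()] columns.
#' @export
equivalence_screen <- function(corpus, bounds = c(0.1, 0.2, 0.3),
                               alpha = 0.05) {
  stopifnot(inherits(corpus, "meta_corpus"))
  if (length(bounds) < 1) abort("`bounds` must be non-empty.")
  m <- corpus$metas
  sig <- abs(m$smd) / m$se > z_crit(alpha)
  purrr::map(sort(bounds), function(b) {
    dplyr::bind_cols(
      tibble::tibble(meta_id = m$meta_id, nhst_significant = sig),
      tost_meta(m$smd, m$se, b, alpha))
  }) |>
    purrr::list_rbind() |>
    dplyr::arrange(.data$meta_id, .data$bound)
}

#' Welch two-sample t-test from summary statistics
#'
#' The unequal-variance t-test computed from group sizes, means and standard
#' deviations, with Welch–Satterthwaite degrees of freedom.
#'
#' @param n1,n2 Group sizes, >= 2.
#' @param mean1,mean2 Group means.
#' @param sd1,sd2 Group standard deviations, > 0.
#' @return A one-row tibble: `t`, `df`, `p` (two-sided), `mean_diff`,
#'   `se_diff`, and the echoed group summaries.
#' @examples
#' welch_t(30, 14.6, 18.9, 38, 10.3, 6.4) # df 34.3
#' @export
welch_t <- function(n1, mean1, sd1, n2, mean2, sd2) {
  if (n1 < 2 || n2 < 2) abort("Group sizes must be at least 2.")
  if (!is.finite(sd1) || !is.finite(sd2) || sd1 <= 0 || sd2 <= 0) {
    abort("Standard deviations must be finite and > 0.")
  }
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  se <- sqrt(v1 + v2)
  t <- (mean1 - mean2) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble::tibble(
    t = t, df = df, p = 2 * stats::pt(-abs(t), df),
    mean_diff = mean1 - mean2, se_diff = se,
    n1 = n1, mean1 = mean1, sd1 = sd1, n2 = n2, mean2 = mean2, sd2 = sd2)
}

#' Two-sample TOST equivalence test from summary statistics
#'
#' Welch-based two one-sided tests of a mean difference against equivalence
#' bounds given as a Cohen's-d SESOI. The d bound is put on the raw scale by
#' `d_bound * sqrt((sd1^2 + sd2^2) / 2)`; each one-sided test uses the Welch
#' standard error and Welch–Satterthwaite degrees of freedom.
#'
#' @inheritParams welch_t
#' @param d_bound SESOI on the Cohen's-d scale, > 0.
#' @param alpha One-sided level of each test. Default 0.05.
#' @return A one-row tibble: `bound_raw`, `t_lower`, `t_upper`, `p_lower`,
#'   `p_upper`, `p_tost`, `df`, `equivalent`.
#' @export
tost_two_sample <- function(n1, mean1, sd1, n2, mean2, sd2, d_bound,
                            alpha = 0.05) {
  if (!is.finite(d_bound) || d_bound <= 0) abort("`d_bound` must be > 0.")
  w <- welch_t(n1, mean1, sd1, n2, mean2, sd2)
  bound_raw <- d_bound * sqrt((sd1^2 + sd2^2) / 2)
  t_upper <- (w$mean_diff - bound_raw) / w$se_diff
  t_lower <- (w$mean_diff + bound_raw) / w$se_diff
  p_upper <- stats::pt(t_upper, w$df)
  p_lower <- stats::pt(t_lower, w$df, lower.tail = FALSE)
  p_tost <- pmax(p_lower, p_upper)
  tibble::tibble(
    bound_raw = bound_raw, t_lower = t_lower, t_upper = t_upper,
    p_lower = p_lower, p_upper = p_upper, p_tost = p_tost, df = w$df,
    equivalent = p_tost <= alpha)
}
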