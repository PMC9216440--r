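#' Year-by-year power profile
#'
#' Median per-study power by publication year at each assumed true effect in
#' the grid (and at the observed summary estimate when `at_observed = TRUE`).
#' Duplicate studies are collapsed to one power per study per condition
#' before the yearly median; undated studies are excluded with a logged
#' count.
#'
#' @param corpus A `meta_corpus`.
#' @param grid Assumed true effects. Default 0.1 to 1.0 by 0.1.
#' @param alpha Two-sided significance level.
#' @param at_observed Include the observed-summary condition.
#' @param quiet Suppress the undated-studies message.
#' @return A tibble `(year, ref, delta_star, median_power, n_studies)`,
#'   years ascending, with the per-study flat rows in attribute
#'   `"per_study"`.
#' @export
trend_table <- function(corpus, grid = seq(0.1, 1, by = 0.1), alpha = 0.05,
                        at_observed = TRUE, quiet = FALSE) {
  sp <- study_power(corpus, grid, alpha, at_observed)
  undated <- unique(sp$study_id[!is.finite(sp$year)])
  if (length(undated) && !quiet) {
    inform(sprintf("Excluding %d undated studies from the trend table.",
                   length(undated)))
  }
  per_study <- sp |>
    dplyr::filter(is.finite(.data$year)) |>
    dplyr::summarise(power = stats::median(.data$power),
                     year = .data$year[1],
                     .by = c("study_id", "ref", "delta_star"))
  if (nrow(per_study) == 0) abort("No dated studies in the corpus.")
  out <- per_study |>
    dplyr::summarise(median_power = stats::median(.data$power),
                     n_studies = dplyr::n(),
                     .by = c("year", "ref", "delta_star")) |>
    dplyr::arrange(.data$year, .data$ref, .data$delta_star)
  attr(out, "per_study") <- per_study
  out
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA of `values` over the levels of
#' `groups` (fitted with [stats::lm()]). The degenerate all-identical input
#' returns F = 0, p = 1 with a warning; zero within-group variance with
#' differing means returns an infinite F and p = 0, also with a warning.
#'
#' @param values Numeric response, e.g. per-study power.
#' @param groups Group labels, e.g. publication year; coerced to factor.
#' @return A one-row tibble: `F`, `df_between`, `df_within`, `p`,
#'   `ss_between`, `ss_within`, `ss_total`.
#' @export
oneway_anova <- function(values, groups) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  if (nlevels(groups) < 2) abort("Need at least 2 groups.")
  if (!any(tabulate(groups) >= 2)) {
    abort("Need at least one group with 2 or more values.")
  }
  df_b <- nlevels(groups) - 1L
  df_w <- length(values) - nlevels(groups)
  if (stats::var(values) == 0) {
    warn("All values identical; returning F = 0, p = 1.")
    return(tibble::tibble(F = 0, df_between = df_b, df_within = df_w, p = 1,
                          ss_between = 0, ss_within = 0, ss_total = 0))
  }
  # lm warns on an essentially perfect fit; the degenerate case is reported
  # through our own explicit warning below instead
  tab <- suppressWarnings(stats::anova(stats::lm(values ~ groups)))
  ss_b <- tab$`Sum Sq`[1]
  ss_w <- tab$`Sum Sq`[2]
  f <- tab$`F value`[1]
  p <- tab$`Pr(>F)`[1]
  if (ss_w <= .Machine$double.eps * ss_b) {
    warn("Zero within-group variance with differing means; F is infinite.")
    f <- Inf
    p <- 0
  }
  tibble::tibble(F = f, df_between = df_b, df_within = df_w, p = p,
                 ss_between = ss_b, ss_within = ss_w,
                 ss_total = ss_b + ss_w)
}

#' ANOVA for change in study power over publication years
#'
#' Tests whether per-study statistical power differs across publication
#' years, using each study's power at its parent meta-analysis's observed
#' summary estimate by default (or at a fixed assumed effect), with duplicate
#' studies collapsed by the median.
#'
#' @param corpus A `meta_corpus`.
#' @param at `"observed"` (default) or a single numeric assumed true SMD.
#' @param alpha Two-sided significance level for the power computation.
#' @return A one-row tibble from [oneway_anova()], with the per-study data in
#'   attribute `"per_study"`.
#' @export
power_trend_anova <- function(corpus, at = "observed", alpha = 0.05) {
  if (identical(at, "observed")) {
    sp <- study_power(corpus, grid = numeric(0), alpha = alpha,
                      at_observed = TRUE)
  } else {
    stopifnot(is.numeric(at), length(at) == 1)
    sp <- study_power(corpus, grid = at, alpha = alpha, at_observed = FALSE)
  }
  per_study <- sp |>
    dplyr::filter(is.finite(.data$year)) |>
    dplyr::summarise(power = stats::median(.data$power),
                     year = .data$year[1], .by = "study_id")
  out <- oneway_anova(per_study$power, per_study$year)
  attr(out, "per_study") <- per_study
  out
}
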