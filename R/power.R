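#' Two-sided Wald-test power for a standardized mean difference
#'
#' Probability that a two-sided z-test of an estimate with standard error
#' `se` rejects at level `alpha`, when the true effect is `delta`:
#' `power = 1 - pnorm(c - delta/se) + pnorm(-c - delta/se)` with
#' `c = qnorm(1 - alpha/2)`. Normal-theory throughout — no small-sample
#' degrees-of-freedom correction — and symmetric in the sign of `delta`.
#' At `delta = 0` the power equals `alpha` exactly; as `se` shrinks the power
#' climbs to 1 for any nonzero `delta`.
#'
#' @param delta Assumed true SMD (vectorized).
#' @param se Standard error(s) of the estimate, > 0.
#' @param alpha Two-sided significance level, in (0, 1). Default 0.05.
#' @return Power in `[alpha, 1]`, recycled over the inputs.
#' @examples
#' wald_power(0, 0.2)          # exactly 0.05
#' wald_power(0.8, sqrt(2/25)) # about 0.807: d = 0.8 with 25 per group
#' @export
wald_power <- function(delta, se, alpha = 0.05) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be a single number in (0, 1).")
  }
  if (any(!is.finite(se) | se <= 0)) {
    abort("`se` must be finite and > 0.")
  }
  z <- delta / se
  crit <- z_crit(alpha)
  stats::pnorm(z - crit) + stats::pnorm(-z - crit)
}

#' Collapse multiple outcome powers from one study to a single value
#'
#' A study reporting several tests contributes its median power (the midpoint
#' of the two central values for an even count), so that multi-outcome studies
#' do not dominate corpus summaries.
#'
#' @param powers Numeric vector of per-outcome powers, length >= 1.
#' @return The median power.
#' @export
dedup_power <- function(powers) {
  if (length(powers) < 1) abort("`powers` must contain at least one value.")
  if (any(!is.finite(powers))) abort("`powers` must be finite.")
  stats::median(powers)
}

#' Per-study power profiles over a grid of assumed true effects
#'
#' For every constituent study, computes two-sided Wald power at each assumed
#' true effect in `grid` and (optionally) at the parent meta-analysis's
#' observed summary estimate. Per-outcome powers are collapsed to one value
#' per study per condition by the median rule ([dedup_power()]).
#'
#' @param corpus A `meta_corpus`.
#' @param grid Ascending vector of assumed true SMDs. Default 0.1 to 1.0 by
#'   0.1.
#' @param alpha Two-sided significance level.
#' @param at_observed Also compute power taking each meta-analysis's summary
#'   estimate as the true effect (rows with `ref = "observed"`).
#' @return A tibble with one row per study, per meta-analysis membership, per
#'   condition: `meta_id`, `study_id`, `year`, `population`, `dosing`, `ref`
#'   (`"grid"` or `"observed"`), `delta_star` (the assumed true effect used),
#'   `power`.
#' @export
study_power <- function(corpus, grid = seq(0.1, 1, by = 0.1), alpha = 0.05,
                        at_observed = TRUE) {
  stopifnot(inherits(corpus, "meta_corpus"))
  if (length(grid) < 1 && !at_observed) {
    abort("Empty `grid` with `at_observed = FALSE`: nothing to compute.")
  }
  if (length(grid) && is.unsorted(grid)) grid <- sort(grid)

  conds <- tibble::tibble(meta_id = character(), ref = character(),
                          delta_star = double())
  if (length(grid)) {
    conds <- tidyr::expand_grid(
      meta_id = corpus$metas$meta_id, ref = "grid", delta_star = grid)
  }
  if (at_observed) {
    conds <- dplyr::bind_rows(
      conds,
      tibble::tibble(meta_id = corpus$metas$meta_id, ref = "observed",
                     delta_star = corpus$metas$smd))
  }

  corpus$studies |>
    dplyr::inner_join(conds, by = "meta_id",
                      relationship = "many-to-many") |>
    dplyr::mutate(power = wald_power(.data$delta_star, .data$se, alpha)) |>
    dplyr::summarise(
      power = dedup_power(.data$power),
      year = .data$year[1], population = .data$population[1],
      dosing = .data$dosing[1],
      .by = c("meta_id", "study_id", "ref", "delta_star")) |>
    dplyr::select("meta_id", "study_id", "year", "population", "dosing",
                  "ref", "delta_star", "power") |>
    dplyr::arrange(.data$meta_id, .data$study_id, .data$ref,
                   .data$delta_star)
}

#' Summarize study powers to median/mean/min/max percentages
#'
#' Aggregates a [study_power()] table (or any tibble with `study_id`,
#' `power`) to power summaries in percent, rounded half-away-from-zero to one
#' decimal. With `unique_studies = TRUE` a study appearing in several
#' meta-analyses is first collapsed to one value per condition by the median,
#' so corpus-level summaries count each study once.
#'
#' @param power_tbl A tibble of per-study powers, e.g. from [study_power()].
#' @param by Optional character vector of grouping columns (e.g.
#'   `"population"`, `"meta_id"`, `"year"`). Conditions (`ref`, `delta_star`)
#'   are always kept separate when present.
#' @param unique_studies Collapse duplicate `study_id`s across meta-analyses
#'   before summarizing (ignored when grouping by `meta_id`).
#' @return A tibble with the grouping columns plus `n` (studies summarized),
#'   `median_pct`, `mean_pct`, `min_pct`, `max_pct`.
#' @export
summarize_power <- function(power_tbl, by = NULL, unique_studies = TRUE) {
  if (nrow(power_tbl) == 0) abort("Empty power table: nothing to summarize.")
  cond <- intersect(c("ref", "delta_star"), names(power_tbl))
  keys <- unique(c(by, cond))
  if (unique_studies && !"meta_id" %in% by) {
    power_tbl <- power_tbl |>
      dplyr::summarise(power = stats::median(.data$power),
                       .by = dplyr::all_of(unique(c("study_id", keys))))
  }
  power_tbl |>
    dplyr::summarise(
      n = dplyr::n_distinct(.data$study_id),
      median_pct = round_half_away(100 * stats::median(.data$power)),
      mean_pct = round_half_away(100 * mean(.data$power)),
      min_pct = round_half_away(100 * min(.data$power)),
      max_pct = round_half_away(100 * max(.data$power)),
      .by = dplyr::all_of(keys))
}
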