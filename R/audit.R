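#' Run the full meta-analysis audit
#'
#' Orchestrates the whole pipeline on a corpus: power profiles and summaries
#' (overall, per meta-analysis, and the clinical/healthy and single/multiple
#' dose subgroups with Welch and two-sample TOST contrasts), the TOST
#' equivalence screen of every summary estimate at each SESOI bound, the Test
#' of Excess Significance over the univariate meta-analyses, and the
#' year-by-year power trend with its one-way ANOVA.
#'
#' @param x A `meta_corpus`, a [generator_config()] (the corpus is generated
#'   first), or a length-2 character vector `c(meta_file, study_file)` of
#'   paths in the [read_corpus()] schema.
#' @param grid Assumed-true-effect grid for power profiling.
#' @param bounds SESOI bounds for the equivalence screen.
#' @param alpha Significance level used throughout.
#' @param contrast_bound Cohen's-d SESOI for the subgroup equivalence
#'   contrasts. Default 0.2.
#' @param tes_form Test form for the excess-significance screen.
#' @param quiet Suppress per-stage log messages.
#' @return A `meta_audit` object: a list with elements `counts`,
#'   `power` (per-study profiles), `power_summary` (overall + per-meta +
#'   subgroup summaries), `contrasts`, `equivalence` (per-meta per-bound),
#'   `equivalence_counts`, `tes`, `trend`, `anova`, and a `provenance` block
#'   (parameters, seed where known, package version).
#' @export
run_audit <- function(x, grid = seq(0.1, 1, by = 0.1),
                      bounds = c(0.1, 0.2, 0.3), alpha = 0.05,
                      contrast_bound = 0.2,
                      tes_form = c("chisq", "exact"), quiet = FALSE) {
  tes_form <- match.arg(tes_form)
  config <- NULL
  if (inherits(x, "generator_config")) {
    config <- x
    x <- generate_corpus(x)
  } else if (is.character(x) && length(x) == 2) {
    x <- read_corpus(x[1], x[2], quiet = quiet)
  }
  stopifnot(inherits(x, "meta_corpus"))
  config <- config %||% attr(x, "config")
  say <- function(...) if (!quiet) inform(sprintf(...))

  counts <- corpus_counts(x)
  say("[power] profiling %d studies over %d grid points",
      counts$n_unique_studies, length(grid))
  sp <- study_power(x, grid, alpha, at_observed = TRUE)
  # delta_star under ref == "observed" is each meta's own summary, so it is
  # dropped before summarizing or it would split the groups
  obs <- dplyr::filter(sp, .data$ref == "observed") |>
    dplyr::select(-"delta_star")
  power_summary <- dplyr::bind_rows(
    dplyr::mutate(summarize_power(obs), scope = "corpus", group = "all"),
    dplyr::mutate(summarize_power(obs, by = "meta_id"), scope = "per_meta",
                  group = .data$meta_id),
    obs |> dplyr::filter(.data$population %in% c("clinical", "healthy")) |>
      summarize_power(by = "population") |>
      dplyr::mutate(scope = "population", group = .data$population),
    obs |> dplyr::filter(.data$population == "clinical",
                         .data$dosing %in% c("single", "multiple")) |>
      summarize_power(by = "dosing") |>
      dplyr::mutate(scope = "dosing_clinical", group = .data$dosing))

  contrasts <- audit_contrasts(obs, contrast_bound, alpha)
  say("[equivalence] screening %d meta-analyses at bounds {%s}",
      counts$n_metas, paste(bounds, collapse = ", "))
  eq <- equivalence_screen(x, bounds, alpha)
  eq_counts <- eq |>
    dplyr::summarise(
      n_metas = dplyr::n(),
      n_nonsignificant = sum(!.data$nhst_significant),
      n_equivalent_nonsig = sum(.data$equivalent & !.data$nhst_significant),
      .by = "bound")

  say("[tes] screening univariate meta-analyses (%s form)", tes_form)
  tes_tbl <- tes_screen(x, alpha = alpha, form = tes_form)

  say("[trend] yearly power profile and ANOVA")
  trend <- trend_table(x, grid, alpha, quiet = quiet)
  anova <- power_trend_anova(x, at = "observed", alpha = alpha)

  structure(list(
    counts = counts,
    power = sp,
    power_summary = power_summary,
    contrasts = contrasts,
    equivalence = eq,
    equivalence_counts = eq_counts,
    tes = tes_tbl,
    trend = trend,
    anova = anova,
    provenance = list(
      grid = grid, bounds = bounds, alpha = alpha,
      contrast_bound = contrast_bound, tes_form = tes_form,
      generator = if (!is.null(config)) unclass(config),
      package_version = as.character(utils::packageVersion("poweraudit")),
      schema_version = "1")
  ), class = "meta_audit")
}

# Welch + two-sample TOST contrasts of power (percent scale) between the
# clinical/healthy and, within clinical, single/multiple-dose subgroups
audit_contrasts <- function(obs, contrast_bound, alpha) {
  per_study <- obs |>
    dplyr::summarise(power = stats::median(.data$power),
                     population = .data$population[1],
                     dosing = .data$dosing[1], .by = "study_id") |>
    dplyr::mutate(pct = 100 * .data$power)
  one <- function(a, b, name) {
    if (length(a) < 2 || length(b) < 2 ||
        stats::sd(a) == 0 || stats::sd(b) == 0) {
      return(NULL)
    }
    w <- welch_t(length(a), mean(a), stats::sd(a),
                 length(b), mean(b), stats::sd(b))
    tq <- tost_two_sample(length(a), mean(a), stats::sd(a),
                          length(b), mean(b), stats::sd(b),
                          d_bound = contrast_bound, alpha = alpha)
    tibble::tibble(contrast = name, t = w$t, df = w$df, p = w$p,
                   n1 = w$n1, mean1 = w$mean1, sd1 = w$sd1,
                   n2 = w$n2, mean2 = w$mean2, sd2 = w$sd2,
                   tost_p = tq$p_tost, tost_equivalent = tq$equivalent)
  }
  clin <- per_study$pct[per_study$population == "clinical"]
  heal <- per_study$pct[per_study$population == "healthy"]
  multi <- per_study$pct[per_study$population == "clinical" &
                           per_study$dosing == "multiple"]
  single <- per_study$pct[per_study$population == "clinical" &
                            per_study$dosing == "single"]
  dplyr::bind_rows(one(clin, heal, "clinical_vs_healthy"),
                   one(multi, single, "multiple_vs_single_dose_clinical"))
}

#' @export
print.meta_audit <- function(x, ...) {
  cat("<meta_audit>\n")
  cat(sprintf("  corpus: %d meta-analyses (%d univariate), %d unique studies\n",
              x$counts$n_metas, x$counts$n_univariate,
              x$counts$n_unique_studies))
  overall <- x$power_summary[x$power_summary$scope == "corpus", ]
  cat(sprintf("  power at observed summary: median %.1f%%, mean %.1f%% (min %.1f%%, max %.1f%%) over %d unique studies\n",
              overall$median_pct, overall$mean_pct, overall$min_pct,
              overall$max_pct, overall$n))
  for (i in seq_len(nrow(x$equivalence_counts))) {
    e <- x$equivalence_counts[i, ]
    cat(sprintf("  SESOI %.2g: %d of %d non-significant meta-analyses equivalent\n",
                e$bound, e$n_equivalent_nonsig, e$n_nonsignificant))
  }
  if (nrow(x$tes)) {
    cat(sprintf("  excess significance: %d of %d univariate meta-analyses flagged\n",
                sum(x$tes$flagged), nrow(x$tes)))
  }
  cat(sprintf("  power over time: F(%d,%d) = %.3g, p = %.3g\n",
              x$anova$df_between, x$anova$df_within, x$anova$F, x$anova$p))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-meta-analysis audit results
#'
#' One row per meta-analysis per SESOI bound: significance status, TOST
#' p-value and 90% interval, equivalence flag, median constituent-study power
#' at the observed summary, and the excess-significance result where the
#' meta-analysis is univariate.
#'
#' @param x A `meta_audit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.meta_audit <- function(x, ...) {
  per_meta <- x$power_summary |>
    dplyr::filter(.data$scope == "per_meta") |>
    dplyr::select(meta_id = "group", n_studies = "n",
                  median_power_pct = "median_pct")
  tes_cols <- dplyr::select(x$tes, "meta_id", tes_p = "p",
                            tes_flagged = "flagged")
  x$equivalence |>
    dplyr::select("meta_id", "nhst_significant", "bound", "p_tost",
                  "ci_tost_low", "ci_tost_high", "equivalent") |>
    dplyr::left_join(per_meta, by = "meta_id") |>
    dplyr::left_join(tes_cols, by = "meta_id")
}

#' One-row summary of a meta-analysis audit
#'
#' @param x A `meta_audit`.
#' @param ... Unused.
#' @return A one-row tibble: corpus counts, median/mean power (percent, at
#'   the observed summary), median summary SMD, count of NHST-significant
#'   meta-analyses, equivalent counts per bound, TES flags, and the trend
#'   ANOVA p-value.
#' @export
glance.meta_audit <- function(x, ...) {
  overall <- x$power_summary[x$power_summary$scope == "corpus", ]
  eq <- x$equivalence |>
    dplyr::distinct(.data$meta_id, .data$smd, .data$nhst_significant)
  wide <- x$equivalence_counts
  out <- tibble::tibble(
    n_metas = x$counts$n_metas,
    n_unique_studies = x$counts$n_unique_studies,
    median_power_pct = overall$median_pct,
    mean_power_pct = overall$mean_pct,
    median_summary_smd = stats::median(eq$smd),
    n_significant_metas = sum(eq$nhst_significant),
    n_tes_screened = nrow(x$tes),
    n_tes_flagged = if (nrow(x$tes)) sum(x$tes$flagged) else 0L,
    anova_F = x$anova$F,
    anova_p = x$anova$p)
  for (i in seq_len(nrow(wide))) {
    out[[sprintf("n_equivalent_d%02.0f", 100 * wide$bound[i])]] <-
      wide$n_equivalent_nonsig[i]
  }
  out
}

#' Write the audit's tables and report to a directory
#'
#' Emits every result table as delimited text with fixed 6-significant-digit
#' number formatting (so repeated runs on the same input are byte-identical)
#' plus a single JSON report mirroring the `meta_audit` object.
#'
#' @param audit A `meta_audit`.
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"tsv"`.
#' @return Named vector of written paths, invisibly.
#' @export
write_audit_tables <- function(audit, dir, format = c("csv", "tsv")) {
  stopifnot(inherits(audit, "meta_audit"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- list(power = audit$power, power_summary = audit$power_summary,
                 contrasts = audit$contrasts, equivalence = audit$equivalence,
                 equivalence_counts = audit$equivalence_counts,
                 tes = audit$tes, trend = audit$trend, anova = audit$anova)
  paths <- character(0)
  for (nm in names(tables)) {
    df <- tables[[nm]]
    if (is.null(df) || nrow(df) == 0) next
    df <- tibble::as_tibble(df)
    num <- vapply(df, is.double, logical(1))
    df[num] <- lapply(df[num], format_num)
    path <- file.path(dir, paste0(nm, ".", format))
    readr::write_delim(df, path, delim = delim_for_path(path), na = "")
    paths[nm] <- path
  }
  report <- c(list(counts = audit$counts,
                   equivalence_counts = audit$equivalence_counts,
                   anova = audit$anova, provenance = audit$provenance))
  paths["report"] <- file.path(dir, "report.json")
  jsonlite::write_json(report, paths[["report"]], auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  invisible(paths)
}
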