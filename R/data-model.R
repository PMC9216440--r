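#' Standard error of an SMD from its confidence interval
#'
#' Recovers the standard error of a standardized mean difference from a
#' symmetric normal-theory confidence interval:
#' `SE = (ci_high - ci_low) / (2 * z)`, where `z` is the normal quantile for
#' the interval level (1.959964 for 95%).
#'
#' @param ci_low,ci_high Lower and upper confidence bounds (vectorized).
#' @param level Confidence level of the interval, in (0, 1). Default 0.95.
#' @return A numeric vector of standard errors.
#' @examples
#' se_from_ci(-1.959964, 1.959964)        # exactly 1
#' se_from_ci(0.05, 0.45)                 # 0.10204
#' @export
se_from_ci <- function(ci_low, ci_high, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    abort("`level` must be a single number in (0, 1).")
  }
  bad <- !is.finite(ci_low) | !is.finite(ci_high)
  if (any(bad)) {
    abort(paste0("Non-finite confidence bounds at position(s): ",
                 paste(which(bad), collapse = ", ")))
  }
  inv <- ci_low >= ci_high
  if (any(inv)) {
    abort(paste0("Inverted or degenerate confidence interval at position(s): ",
                 paste(which(inv), collapse = ", ")))
  }
  (ci_high - ci_low) / (2 * stats::qnorm((1 + level) / 2))
}

#' Resolve effect estimates to standard-error form
#'
#' Fills missing `se` values from `ci_low`/`ci_high` where available. Rows
#' with neither a standard error nor a complete confidence interval are an
#' error: every downstream computation needs a resolved SE.
#'
#' @param data A data frame with columns `smd`, `se`, `ci_low`, `ci_high`.
#' @param level Confidence level used for the CI-to-SE conversion.
#' @param id_cols Character vector of columns used to name offending rows in
#'   error messages.
#' @return `data` as a tibble with `se` populated for every row, and an
#'   integer attribute `n_se_from_ci` counting the conversions.
#' @export
resolve_se <- function(data, level = 0.95, id_cols = intersect(
                         c("meta_id", "study_id"), names(data))) {
  data <- tibble::as_tibble(data)
  has_se <- is.finite(data$se) & data$se > 0
  has_ci <- is.finite(data$ci_low) & is.finite(data$ci_high)
  need <- !has_se
  unresolvable <- need & !has_ci
  if (any(unresolvable)) {
    who <- apply(data[unresolvable, id_cols, drop = FALSE], 1L,
                 paste, collapse = "/")
    abort(paste0("Rows with neither SE nor CI: ",
                 paste(unique(who), collapse = ", ")))
  }
  if (any(need)) {
    data$se[need] <- se_from_ci(data$ci_low[need], data$ci_high[need], level)
  }
  nonpos <- !is.finite(data$se) | data$se <= 0
  if (any(nonpos)) {
    who <- apply(data[nonpos, id_cols, drop = FALSE], 1L, paste, collapse = "/")
    abort(paste0("Non-positive SE after resolution: ",
                 paste(unique(who), collapse = ", ")))
  }
  attr(data, "n_se_from_ci") <- sum(need)
  data
}

# negate effect columns in place; CI bounds swap so low < high is preserved
flip_effect <- function(data) {
  lo <- data$ci_low
  data$ci_low <- -data$ci_high
  data$ci_high <- -lo
  data$smd <- -data$smd
  data
}

#' Apply the sign-reversal convention to a corpus
#'
#' Meta-analyses that coded a beneficial outcome as a negative effect carry
#' `reverse_sign = TRUE`; this negates their summary effect and every member
#' outcome (CI bounds swapped, SEs untouched) so that all effects point in the
#' same direction. The operation is an involution on the numeric fields:
#' applying it twice returns the original values.
#'
#' @param corpus A `meta_corpus` object.
#' @return The corpus with flagged meta-analyses negated.
#' @export
apply_sign_convention <- function(corpus) {
  stopifnot(inherits(corpus, "meta_corpus"))
  rev_ids <- corpus$metas$meta_id[corpus$metas$reverse_sign]
  if (length(rev_ids)) {
    hit_m <- corpus$metas$meta_id %in% rev_ids
    corpus$metas[hit_m, ] <- flip_effect(corpus$metas[hit_m, ])
    hit_s <- corpus$studies$meta_id %in% rev_ids
    corpus$studies[hit_s, ] <- flip_effect(corpus$studies[hit_s, ])
  }
  corpus
}

meta_cols <- c("meta_id", "label", "smd", "se", "ci_low", "ci_high",
               "reverse_sign", "design")
study_cols <- c("meta_id", "study_id", "year", "smd", "se", "ci_low",
                "ci_high", "population", "dosing")

#' Construct a meta-analysis corpus
#'
#' Bundles the meta-analysis summary table and the constituent-study outcome
#' table into a validated `meta_corpus`. The study table holds one row per
#' outcome; a study contributing several outcomes, or appearing in several
#' meta-analyses, has several rows under the same `study_id`.
#'
#' @param metas Data frame with columns `meta_id`, `label`, `smd`, `se`,
#'   `ci_low`, `ci_high`, `reverse_sign`, `design` (`"univariate"` or
#'   `"multivariate"`).
#' @param studies Data frame with columns `meta_id`, `study_id`, `year`,
#'   `smd`, `se`, `ci_low`, `ci_high`, `population` (`"clinical"`,
#'   `"healthy"`, `"unknown"`), `dosing` (`"single"`, `"multiple"`,
#'   `"unknown"`).
#' @return A `meta_corpus`: a list with tibbles `metas` and `studies`.
#' @export
meta_corpus <- function(metas, studies) {
  metas <- tibble::as_tibble(metas)
  studies <- tibble::as_tibble(studies)
  miss_m <- setdiff(meta_cols, names(metas))
  miss_s <- setdiff(study_cols, names(studies))
  if (length(miss_m)) {
    abort(paste0("Meta table is missing column(s): ",
                 paste(miss_m, collapse = ", ")))
  }
  if (length(miss_s)) {
    abort(paste0("Study table is missing column(s): ",
                 paste(miss_s, collapse = ", ")))
  }
  if (anyDuplicated(metas$meta_id)) {
    abort("Duplicated meta_id in the meta table.")
  }
  orphans <- setdiff(metas$meta_id, studies$meta_id)
  if (length(orphans)) {
    abort(paste0("Meta-analyses with no member studies: ",
                 paste(orphans, collapse = ", ")))
  }
  unknown <- setdiff(studies$meta_id, metas$meta_id)
  if (length(unknown)) {
    abort(paste0("Study rows reference unknown meta_id: ",
                 paste(unknown, collapse = ", ")))
  }
  yr <- studies$year
  odd_year <- is.finite(yr) & (yr < 1950 | yr > 2100)
  if (any(odd_year)) {
    warn(paste0("Implausible publication year for study row(s): ",
                paste(unique(studies$study_id[odd_year]), collapse = ", ")))
  }
  structure(list(metas = metas, studies = studies), class = "meta_corpus")
}

#' @export
print.meta_corpus <- function(x, ...) {
  cnt <- corpus_counts(x)
  cat("<meta_corpus> ", cnt$n_metas, " meta-analyses (",
      cnt$n_univariate, " univariate), ",
      cnt$n_unique_studies, " unique studies, ",
      cnt$n_outcome_rows, " outcome rows\n", sep = "")
  invisible(x)
}

#' Corpus size summary
#'
#' @param corpus A `meta_corpus`.
#' @return A one-row tibble: number of meta-analyses, univariate
#'   meta-analyses, unique studies, and outcome rows.
#' @export
corpus_counts <- function(corpus) {
  stopifnot(inherits(corpus, "meta_corpus"))
  tibble::tibble(
    n_metas = nrow(corpus$metas),
    n_univariate = sum(corpus$metas$design == "univariate", na.rm = TRUE),
    n_unique_studies = dplyr::n_distinct(corpus$studies$study_id),
    n_outcome_rows = nrow(corpus$studies)
  )
}

#' Read a meta-analysis corpus from delimited text
#'
#' Reads the two-table schema (meta summaries + per-outcome study rows),
#' resolves every estimate to SE form (converting from confidence intervals
#' where the SE is absent), applies the sign-reversal convention, and checks
#' that a `study_id` shared across meta-analyses carries consistent labels.
#' The delimiter is taken from the extension: `.csv` is comma, anything else
#' tab.
#'
#' @param meta_file,study_file Paths to the meta table and the study table.
#' @param level Confidence level assumed for CI-to-SE conversion.
#' @param quiet Suppress the load-report message.
#' @return A normalized `meta_corpus` with a `load_report` attribute (a list
#'   of counts: rows read, SE conversions, sign reversals).
#' @export
read_corpus <- function(meta_file, study_file, level = 0.95, quiet = FALSE) {
  metas <- readr::read_delim(
    meta_file, delim = delim_for_path(meta_file), show_col_types = FALSE,
    col_types = readr::cols(
      meta_id = "c", label = "c", smd = "d", se = "d", ci_low = "d",
      ci_high = "d", reverse_sign = "l", design = "c"))
  studies <- readr::read_delim(
    study_file, delim = delim_for_path(study_file), show_col_types = FALSE,
    col_types = readr::cols(
      meta_id = "c", study_id = "c", year = "i", smd = "d", se = "d",
      ci_low = "d", ci_high = "d", population = "c", dosing = "c"))
  metas$reverse_sign[is.na(metas$reverse_sign)] <- FALSE
  metas <- resolve_se(metas, level, id_cols = "meta_id")
  studies <- resolve_se(studies, level, id_cols = c("meta_id", "study_id"))
  n_conv <- attr(metas, "n_se_from_ci") + attr(studies, "n_se_from_ci")
  attr(metas, "n_se_from_ci") <- NULL
  attr(studies, "n_se_from_ci") <- NULL

  corpus <- meta_corpus(metas, studies)
  corpus <- apply_sign_convention(corpus)

  # a study_id appearing in several meta-analyses must be one study
  lab <- dplyr::distinct(corpus$studies, .data$study_id, .data$year,
                         .data$population, .data$dosing)
  clash <- lab$study_id[duplicated(lab$study_id)]
  if (length(clash)) {
    warn(paste0("Inconsistent year/population/dosing for shared study_id: ",
                paste(unique(clash), collapse = ", ")))
  }

  report <- list(
    n_metas = nrow(corpus$metas),
    n_unique_studies = dplyr::n_distinct(corpus$studies$study_id),
    n_outcome_rows = nrow(corpus$studies),
    n_se_from_ci = n_conv,
    n_sign_reversed = sum(corpus$metas$reverse_sign)
  )
  attr(corpus, "load_report") <- report
  if (!quiet) {
    inform(sprintf(
      "Read %d meta-analyses / %d unique studies (%d outcome rows); %d SEs from CIs; %d meta-analyses sign-reversed.",
      report$n_metas, report$n_unique_studies, report$n_outcome_rows,
      report$n_se_from_ci, report$n_sign_reversed))
  }
  corpus
}

#' Write a corpus back to the delimited-text schema
#'
#' Emits the same two-table schema that [read_corpus()] ingests, in the
#' publication direction: meta-analyses flagged `reverse_sign` are negated on
#' the way out, so reading the files back reproduces the in-memory corpus
#' exactly (write/read round trip is the identity).
#'
#' @param corpus A `meta_corpus`.
#' @param meta_file,study_file Output paths; extension selects the delimiter.
#' @return The corpus, invisibly.
#' @export
write_corpus <- function(corpus, meta_file, study_file) {
  stopifnot(inherits(corpus, "meta_corpus"))
  raw <- apply_sign_convention(corpus) # undo normalization for flagged metas
  write_one <- function(df, cols, path) {
    df <- df[, cols]
    num <- vapply(df, is.numeric, logical(1)) & names(df) != "year"
    # 17 significant digits: doubles survive the write/read round trip exactly
    df[num] <- lapply(df[num], function(x) {
      out <- trimws(formatC(x, digits = 17, format = "g"))
      out[is.na(x)] <- ""
      out
    })
    readr::write_delim(df, path, delim = delim_for_path(path), na = "")
  }
  write_one(raw$metas, meta_cols, meta_file)
  write_one(raw$studies, study_cols, study_file)
  invisible(corpus)
}
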