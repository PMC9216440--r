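#' @importFrom rlang .data abort warn inform %||%
#' @importFrom stats qnorm pnorm pt pchisq median
NULL

# two-sided critical value on the z scale
z_crit <- function(alpha) stats::qnorm(1 - alpha / 2)

# round half away from zero (not banker's rounding) to `digits` decimals
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# delimiter from file extension: .csv -> comma, anything else -> tab
delim_for_path <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

# locale-independent fixed formatting (6 significant digits) so emitted
# tables are byte-stable across runs
format_num <- function(x) {
  out <- trimws(formatC(x, digits = 6, format = "g"))
  out[is.na(x)] <- ""
  out
}

`%||%` <- rlang::`%||%`
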