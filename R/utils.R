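#' Round half away from zero
#'
#' Rounding used wherever percentages are printed: exact halves round up
#' (`round_half_up(0.15, 1)` is `0.2`), unlike base R's banker's rounding.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded to `digits` decimals, ties away from zero.
#' @examples
#' round_half_up(100 * 47 / 76, 1) # 61.8
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # 1e-9 guard absorbs binary-representation error just below a true half
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# ordered impact levels shared by the generator and the flag assigner
impact_levels <- function() c("modifier", "low", "moderate", "high")

impact_flag <- function(impact) {
  c(modifier = "I0", low = "I1", moderate = "I2", high = "I3")[impact]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}
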