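#' @importFrom rlang abort %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter arrange select bind_rows group_by summarise n
#' @importFrom stats median quantile coef resid rnorm runif setNames
NULL

# consistent error classes so callers can condition on failure kind
stop_invalid <- function(msg, ...) {
  abort(msg, class = "pharmera_invalid_parameter", ...)
}

stop_no_data <- function(msg, ...) {
  abort(msg, class = "pharmera_no_data", ...)
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_invalid(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (positive && x <= 0) {
    stop_invalid(sprintf("`%s` must be strictly positive (got %g).", name, x))
  }
  if (nonneg && x < 0) {
    stop_invalid(sprintf("`%s` must be non-negative (got %g).", name, x))
  }
  invisible(x)
}

check_fraction <- function(x, name) {
  check_number(x, name)
  if (x < 0 || x > 1) {
    stop_invalid(sprintf("`%s` must lie in [0, 1] (got %g).", name, x))
  }
  invisible(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(
      sprintf(
        "%s is missing required column(s): %s.",
        what, paste(missing, collapse = ", ")
      ),
      class = "pharmera_schema_error"
    )
  }
  invisible(df)
}

geometric_mean <- function(x) exp(mean(log(x)))

#' Round a value to a number of significant figures, always downward
#'
#' Used by the acceptable-daily-exposure rounding policies, where a protective
#' (never upward) rounding is required.
#'
#' @param x positive number.
#' @param digits significant figures to keep.
#' @return `x` truncated downward to `digits` significant figures.
#' @keywords internal
round_down_signif <- function(x, digits = 1L) {
  if (x == 0) return(0)
  mag <- floor(log10(abs(x))) - (digits - 1L)
  floor(x / 10^mag) * 10^mag
}
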