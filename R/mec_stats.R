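#' Build a censored measured-concentration table
#'
#' Measured environmental concentrations (MECs) are frequently reported as
#' "below the limit of quantitation": left-censored observations. The standard
#' table has one row per measurement with columns
#' `value_ugL` (numeric, `NA` for a nondetect), `loq_ugL` (> 0), `detected`
#' (logical), and optional `matrix`, `site`, `source`. Trace detects reported
#' below their own LOQ are kept as detects.
#'
#' `censored_samples()` validates such a table and fills `detected` from
#' `value_ugL` when absent.
#'
#' @param samples data frame as described above.
#' @return validated tibble.
#' @export
censored_samples <- function(samples) {
  check_columns(samples, c("value_ugL", "loq_ugL"), "MEC table")
  samples <- as_tibble(samples)
  if (!"detected" %in% names(samples)) {
    samples$detected <- !is.na(samples$value_ugL)
  }
  if (!nrow(samples)) stop_no_data("empty MEC table.")
  if (any(samples$loq_ugL <= 0, na.rm = TRUE) || anyNA(samples$loq_ugL)) {
    stop_invalid("`loq_ugL` must be present and > 0 for every sample.")
  }
  if (any(samples$detected & (is.na(samples$value_ugL) | samples$value_ugL <= 0))) {
    stop_invalid("detected samples must carry a positive `value_ugL`.")
  }
  samples
}

#' Percent-rank a censored concentration dataset
#'
#' Orders a mixed detect/nondetect dataset for percent-ranked risk plots:
#' nondetects occupy the lowest ranks (ordered among themselves by their LOQ),
#' detects follow in ascending order. Quantiles use the nearest-rank (ceiling)
#' convention on this censored ordering: percentile `p` is the value at rank
#' `ceiling(p * n / 100)`; when that rank is a nondetect the quantile is
#' censored ("<LOQ") and reported as `NA` with `censored = TRUE`.
#'
#' @param samples censored MEC table (see [censored_samples()]).
#' @param percentiles percentiles (in percent) to evaluate, default
#'   `c(25, 50, 75, 90, 95, 99)`.
#' @return an object of class `ranked_distribution`: a list with `ordered`
#'   (tibble: `rank`, `percent_rank`, `value_ugL`, `censored`, `loq_ugL`),
#'   `percentile_of` (tibble: `percentile`, `value_ugL`, `censored`),
#'   `n_total`, `n_nondetect`.
#' @examples
#' m <- tibble::tibble(value_ugL = c(NA, NA, 0.002, 0.01), loq_ugL = 0.001)
#' percent_rank_mecs(censored_samples(m))
#' @export
percent_rank_mecs <- function(samples, percentiles = c(25, 50, 75, 90, 95, 99)) {
  samples <- censored_samples(samples)
  nd <- samples |> filter(!.data$detected) |> arrange(.data$loq_ugL)
  det <- samples |> filter(.data$detected) |> arrange(.data$value_ugL)
  ordered <- tibble(
    value_ugL = c(rep(NA_real_, nrow(nd)), det$value_ugL),
    censored = c(rep(TRUE, nrow(nd)), rep(FALSE, nrow(det))),
    loq_ugL = c(nd$loq_ugL, det$loq_ugL)
  ) |>
    mutate(
      rank = dplyr::row_number(),
      percent_rank = 100 * .data$rank / dplyr::n()
    ) |>
    select("rank", "percent_rank", "value_ugL", "censored", "loq_ugL")
  n <- nrow(ordered)
  idx <- pmin(pmax(ceiling(percentiles * n / 100), 1L), n)
  structure(
    list(
      ordered = ordered,
      percentile_of = tibble(
        percentile = percentiles,
        value_ugL = ordered$value_ugL[idx],
        censored = ordered$censored[idx],
        loq_ugL = ordered$loq_ugL[idx]
      ),
      n_total = n,
      n_nondetect = nrow(nd)
    ),
    class = "ranked_distribution"
  )
}

#' @export
print.ranked_distribution <- function(x, ...) {
  cat(sprintf(
    "<ranked_distribution> %d values (%d nondetects, %.1f%%)\n",
    x$n_total, x$n_nondetect, 100 * x$n_nondetect / x$n_total
  ))
  print(x$percentile_of)
  invisible(x)
}

#' @export
tidy.ranked_distribution <- function(x, ...) x$ordered

#' @export
glance.ranked_distribution <- function(x, ...) {
  tibble(
    n_total = x$n_total,
    n_nondetect = x$n_nondetect,
    detection_fraction = 1 - x$n_nondetect / x$n_total,
    max_ugL = suppressWarnings(max(x$ordered$value_ugL, na.rm = TRUE))
  )
}

#' Quantile of a ranked censored distribution
#'
#' @param x a `ranked_distribution` from [percent_rank_mecs()].
#' @param p percentile in percent (vectorised).
#' @return tibble with `percentile`, `value_ugL` (`NA` when censored) and
#'   `censored`.
#' @export
mec_quantile <- function(x, p) {
  stopifnot(inherits(x, "ranked_distribution"))
  idx <- pmin(pmax(ceiling(p * x$n_total / 100), 1L), x$n_total)
  tibble(
    percentile = p,
    value_ugL = x$ordered$value_ugL[idx],
    censored = x$ordered$censored[idx]
  )
}

#' Mean of a censored dataset by substitution
#'
#' Arithmetic mean with every nondetect replaced according to the substitution
#' rule: half its LOQ (the conventional choice), its full LOQ (an upper bound)
#' or zero (a lower bound).
#'
#' @param samples censored MEC table (see [censored_samples()]).
#' @param substitution `"half_loq"`, `"loq"` or `"zero"`.
#' @return the substituted mean, ug/L.
#' @examples
#' m <- tibble::tibble(value_ugL = c(0.9, NA), loq_ugL = 0.001)
#' censored_mean(m) # (0.9 + 0.0005) / 2
#' @export
censored_mean <- function(samples, substitution = c("half_loq", "loq", "zero")) {
  substitution <- match.arg(substitution)
  samples <- censored_samples(samples)
  sub <- switch(substitution,
    half_loq = samples$loq_ugL / 2,
    loq = samples$loq_ugL,
    zero = 0
  )
  mean(ifelse(samples$detected, samples$value_ugL, sub))
}

#' Fraction of a censored dataset above a threshold
#'
#' Counts measurements exceeding a threshold (e.g. a PNEC). A nondetect counts
#' as below the threshold only when its LOQ does not exceed the threshold;
#' a nondetect whose LOQ is above the threshold could lie on either side, so
#' the comparison is indeterminate and an error is raised.
#'
#' @param samples censored MEC table (see [censored_samples()]).
#' @param threshold concentration threshold, ug/L, > 0. A `pnec_result` is
#'   also accepted.
#' @return tibble with `count`, `n`, `fraction`.
#' @examples
#' m <- tibble::tibble(value_ugL = c(0.2, 0.7, NA), loq_ugL = 0.001)
#' fraction_above(m, 0.58) # 1 of 3
#' @export
fraction_above <- function(samples, threshold) {
  if (inherits(threshold, "pnec_result")) threshold <- threshold$value
  check_number(threshold, "threshold", positive = TRUE)
  samples <- censored_samples(samples)
  bad <- !samples$detected & samples$loq_ugL > threshold
  if (any(bad)) {
    abort(
      sprintf(
        "%d nondetect(s) have LOQ > threshold (%g ug/L): exceedance is indeterminate.",
        sum(bad), threshold
      ),
      class = "pharmera_indeterminate_censoring"
    )
  }
  above <- samples$detected & samples$value_ugL > threshold
  tibble(count = sum(above), n = nrow(samples), fraction = sum(above) / nrow(samples))
}
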