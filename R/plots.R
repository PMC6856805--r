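#' Percent-ranked risk plot for a censored MEC distribution
#'
#' The standard exposure-versus-threshold figure: each measurement plotted at
#' its percent rank against concentration on a log axis, nondetects shown at
#' half their LOQ with an open symbol, and PNEC lines drawn vertically so that
#' points to the right of a line are at potential risk for that threshold.
#'
#' @param object a `ranked_distribution` from [percent_rank_mecs()].
#' @param pnecs named numeric vector of thresholds (ug/L) to draw, e.g.
#'   `c(PNEC_NOEC = 0.132, PNEC_EC10 = 0.58)`; `pnec_result` objects are also
#'   accepted in a list.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.ranked_distribution <- function(object, pnecs = NULL, ...) {
  df <- object$ordered |>
    mutate(
      plotted_ugL = ifelse(.data$censored, .data$loq_ugL / 2, .data$value_ugL),
      status = ifelse(.data$censored, "nondetect (at LOQ/2)", "detect")
    )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$plotted_ugL, y = .data$percent_rank)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$status), colour = "steelblue") +
    ggplot2::scale_shape_manual(values = c("detect" = 16, "nondetect (at LOQ/2)" = 1)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "concentration (µg/L)", y = "percent rank (%)",
      shape = NULL,
      title = "Percent-ranked concentration distribution"
    ) +
    ggplot2::theme_minimal()
  p + pnec_vlines(pnecs)
}

pnec_vlines <- function(pnecs) {
  if (is.null(pnecs)) return(NULL)
  if (is.list(pnecs)) {
    vals <- vapply(pnecs, function(p) if (inherits(p, "pnec_result")) p$value else p,
                   numeric(1))
  } else {
    vals <- pnecs
  }
  list(
    ggplot2::geom_vline(xintercept = vals, colour = "red", linetype = "dashed"),
    if (!is.null(names(vals))) {
      ggplot2::annotate("text", x = vals, y = 5, label = names(vals),
                        angle = 90, vjust = -0.4, size = 3, colour = "red")
    }
  )
}

#' Percentile-distribution plot for simulated catchment PECs
#'
#' Plots per-segment PECs of one or more flow scenarios as percent-ranked
#' curves (values below the reporting floor are dropped, so curves start where
#' concentrations become reportable), with optional PNEC lines.
#'
#' @param object a `segment_pec_field` from [propagate()], or a named list of
#'   them (names become the legend, e.g. `list(mean = ..., low = ...)`).
#' @inheritParams autoplot.ranked_distribution
#' @param floor reporting floor in ug/L.
#' @return a ggplot.
#' @export
autoplot.segment_pec_field <- function(object, pnecs = NULL, floor = 0.0005, ...) {
  plot_pec_field(object, pnecs = pnecs, floor = floor)
}

#' @rdname autoplot.segment_pec_field
#' @param fields a `segment_pec_field` or named list of them.
#' @export
plot_pec_field <- function(fields, pnecs = NULL, floor = 0.0005) {
  if (inherits(fields, "segment_pec_field")) {
    fields <- setNames(list(fields), attr(fields, "flow_scenario") %||% "mean")
  }
  df <- bind_rows(lapply(names(fields), function(nm) {
    x <- sort(fields[[nm]]$pec_ugL)
    tibble(
      scenario = nm,
      pec_ugL = x,
      percent_rank = 100 * seq_along(x) / length(x)
    )
  })) |>
    filter(.data$pec_ugL >= floor)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pec_ugL, y = .data$percent_rank,
                                   colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "PEC (µg/L)", y = "percent rank (%)", colour = "flow scenario",
      title = "Simulated catchment PEC distribution"
    ) +
    ggplot2::theme_minimal() +
    pnec_vlines(pnecs)
}
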