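#' Define an exposure scenario
#'
#' The four parameters that turn a per-capita daily use into a surface-water
#' predicted environmental concentration (PEC): per-capita wastewater (or
#' water-use) volume, the fraction of wastewater that passes a sewage treatment
#' plant (STP), the removal fraction achieved in the STP, and the dilution
#' factor of the effluent in the receiving water. The regulatory screening
#' default is 200 L/person/day of wastewater with a dilution factor of 10, no
#' removal, and all wastewater treated.
#'
#' @param wastewater_per_capita L/person/day, > 0.
#' @param treated_fraction fraction of mass routed through STPs, in \[0, 1\].
#' @param stp_removal fraction removed during treatment, in \[0, 1\].
#' @param dilution_factor effluent dilution in the receiving water, >= 1.
#' @return an object of class `exposure_scenario`.
#' @examples
#' exposure_scenario() # regulatory screening defaults
#' exposure_scenario(treated_fraction = 0.8, stp_removal = 0.12, dilution_factor = 18)
#' @export
exposure_scenario <- function(wastewater_per_capita = 200,
                              treated_fraction = 1,
                              stp_removal = 0,
                              dilution_factor = 10) {
  check_number(wastewater_per_capita, "wastewater_per_capita", positive = TRUE)
  check_fraction(treated_fraction, "treated_fraction")
  check_fraction(stp_removal, "stp_removal")
  check_number(dilution_factor, "dilution_factor")
  if (dilution_factor < 1) stop_invalid("`dilution_factor` must be >= 1.")
  structure(
    list(
      wastewater_per_capita = wastewater_per_capita,
      treated_fraction = treated_fraction,
      stp_removal = stp_removal,
      dilution_factor = dilution_factor
    ),
    class = "exposure_scenario"
  )
}

#' @export
print.exposure_scenario <- function(x, ...) {
  cat(sprintf(
    "<exposure_scenario> %g L/p/d wastewater, %.0f%% treated, %.1f%% STP removal, dilution %g\n",
    x$wastewater_per_capita, 100 * x$treated_fraction, 100 * x$stp_removal,
    x$dilution_factor
  ))
  invisible(x)
}

#' Per-capita daily use from an annual sales table
#'
#' Converts annual sold masses of the active substance and (optionally) its
#' prodrug into a daily per-capita use in micrograms of active moiety, the
#' quantity all downstream PEC derivations start from. The prodrug mass is
#' converted stoichiometrically with [prodrug_to_active()]; the year basis is
#' fixed at 365 days.
#'
#' @param use_table data frame with columns `country`, `year`, `mpa_kg`
#'   (active sold, kg/yr), `mpm_kg` (prodrug sold, kg/yr) and `population`.
#' @param mw_active,mw_prodrug molecular weights (g/mol). `mw_prodrug` may be
#'   `NULL` when every `mpm_kg` is zero.
#' @return the input as a tibble with an added column `use_ug_person_day`.
#' @examples
#' tbl <- tibble::tibble(
#'   country = "XX", year = 2017, mpa_kg = 1000, mpm_kg = 0, population = 1e7
#' )
#' per_capita_daily_use(tbl, mw_active = 320.34, mw_prodrug = 433.5)
#' @export
per_capita_daily_use <- function(use_table, mw_active, mw_prodrug = NULL) {
  check_columns(use_table, c("country", "year", "mpa_kg", "mpm_kg", "population"),
                "use table")
  if (any(use_table$population <= 0, na.rm = TRUE)) {
    stop_invalid("`population` must be strictly positive in every row.")
  }
  if (any(use_table$mpa_kg < 0 | use_table$mpm_kg < 0, na.rm = TRUE)) {
    stop_invalid("sold masses must be non-negative.")
  }
  active_kg <- use_table$mpa_kg
  if (any(use_table$mpm_kg > 0)) {
    if (is.null(mw_prodrug)) {
      stop_invalid("`mw_prodrug` is required when prodrug sales are non-zero.")
    }
    active_kg <- active_kg + prodrug_to_active(use_table$mpm_kg, mw_active, mw_prodrug)
  }
  as_tibble(use_table) |>
    mutate(use_ug_person_day = active_kg * 1e9 / (.data$population * 365))
}

#' Sewage-treatment-plant influent PEC
#'
#' Divides a daily per-capita use by the per-capita wastewater volume. With the
#' 200 L/person/day screening default this is the initial regulatory STP PEC;
#' with a country-specific water use it is the refined STP PEC.
#'
#' @param use daily per-capita use (ug/person/day). Vectorised.
#' @param wastewater_per_capita wastewater volume (L/person/day), > 0.
#' @return STP influent PEC in ug/L.
#' @examples
#' pec_stp(598, 200) # -> 2.99 ug/L
#' @export
pec_stp <- function(use, wastewater_per_capita = 200) {
  check_number(wastewater_per_capita, "wastewater_per_capita", positive = TRUE)
  if (any(use < 0, na.rm = TRUE)) stop_invalid("`use` must be non-negative.")
  use / wastewater_per_capita
}

#' Surface-water PEC from an STP influent PEC
#'
#' Applies treatment and dilution: the treated fraction of the load is reduced
#' by the STP removal, the untreated fraction passes unchanged, and the blended
#' effluent is diluted in the receiving water:
#' `pec_surface = pec_stp * (f_t * (1 - R) + (1 - f_t)) / D`.
#'
#' @param stp_pec STP influent PEC (ug/L). Vectorised.
#' @param scenario an [exposure_scenario()].
#' @return surface-water PEC in ug/L.
#' @examples
#' pec_surface(2.99, exposure_scenario()) # screening default -> 0.299
#' @export
pec_surface <- function(stp_pec, scenario = exposure_scenario()) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  if (any(stp_pec < 0, na.rm = TRUE)) stop_invalid("`stp_pec` must be non-negative.")
  f_t <- scenario$treated_fraction
  passed <- f_t * (1 - scenario$stp_removal) + (1 - f_t)
  stp_pec * passed / scenario$dilution_factor
}

#' Derive STP and surface-water PECs for a use table
#'
#' Data-frame verb combining [per_capita_daily_use()], [pec_stp()] and
#' [pec_surface()]. Scenario parameters may be constants or per-row columns of
#' `use_table` (`wastewater_per_capita`, `treated_fraction`, `stp_removal`,
#' `dilution_factor`), allowing country-specific water use and dilution.
#'
#' @inheritParams per_capita_daily_use
#' @param scenario an [exposure_scenario()] supplying defaults for parameters
#'   not present as columns.
#' @param highest_per_country if `TRUE`, keep only each country's highest
#'   per-capita-use year before deriving PECs (the usual worst-case basis).
#' @return tibble with one row per country (or per country-year) and columns
#'   `use_ug_person_day`, `stp_pec_ugL`, `sw_pec_ugL`.
#' @export
derive_pec <- function(use_table, mw_active, mw_prodrug = NULL,
                       scenario = exposure_scenario(),
                       highest_per_country = TRUE) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  tbl <- per_capita_daily_use(use_table, mw_active, mw_prodrug)
  if (highest_per_country) {
    tbl <- tbl |>
      group_by(.data$country) |>
      filter(.data$use_ug_person_day == max(.data$use_ug_person_day)) |>
      dplyr::slice(1L) |>
      dplyr::ungroup()
  }
  pull_param <- function(col, default) {
    if (col %in% names(tbl)) tbl[[col]] else rep(default, nrow(tbl))
  }
  ww <- pull_param("wastewater_per_capita", scenario$wastewater_per_capita)
  ft <- pull_param("treated_fraction", scenario$treated_fraction)
  rm_ <- pull_param("stp_removal", scenario$stp_removal)
  dil <- pull_param("dilution_factor", scenario$dilution_factor)
  tbl |>
    mutate(
      stp_pec_ugL = .data$use_ug_person_day / ww,
      sw_pec_ugL = .data$stp_pec_ugL * (ft * (1 - rm_) + (1 - ft)) / dil
    )
}

#' Population-weighted summary of per-country PECs
#'
#' Weighted mean, lower weighted median (smallest value whose cumulative weight
#' reaches 50%), minimum and maximum of a set of country PECs weighted by
#' population.
#'
#' @param pec_table data frame with a value column and a weight column.
#' @param value,weight column names (strings) holding the PECs and weights;
#'   default `"sw_pec_ugL"` and `"population"`.
#' @return one-row tibble with `weighted_mean`, `weighted_median`, `min`,
#'   `max` and `n`.
#' @examples
#' weighted_summary(
#'   tibble::tibble(sw_pec_ugL = c(1, 3), population = c(1, 1))
#' )
#' @export
weighted_summary <- function(pec_table, value = "sw_pec_ugL", weight = "population") {
  check_columns(pec_table, c(value, weight), "PEC table")
  x <- pec_table[[value]]
  w <- pec_table[[weight]]
  if (!length(x)) stop_no_data("empty PEC table.")
  if (any(w <= 0, na.rm = TRUE)) stop_invalid("weights must be strictly positive.")
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  cum <- cumsum(w) / sum(w)
  tibble(
    weighted_mean = sum(x * w) / sum(w),
    weighted_median = x[which(cum >= 0.5)[1L]],
    min = min(x),
    max = max(x),
    n = length(x)
  )
}
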