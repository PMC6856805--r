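#' Risk quotient of an exposure concentration against a PNEC
#'
#' `RQ = exposure / PNEC`; a quotient strictly greater than one flags potential
#' risk, a quotient of one or below means no significant risk.
#'
#' @param exposure PEC or MEC, ug/L (vectorised, >= 0).
#' @param pnec a `pnec_result` or a positive number (ug/L).
#' @param label optional label(s) for the exposure source.
#' @return tibble with `exposure_ugL`, `pnec_ugL`, `quotient`, `verdict`
#'   (`"no_significant_risk"` / `"potential_risk"`), and `label` when given.
#' @examples
#' risk_quotient(0.299, 0.58) # 0.516, no significant risk
#' @export
risk_quotient <- function(exposure, pnec, label = NULL) {
  method <- NULL
  if (inherits(pnec, "pnec_result")) {
    method <- pnec$method
    pnec <- pnec$value
  }
  check_number(pnec, "pnec", positive = TRUE)
  if (any(exposure < 0, na.rm = TRUE)) stop_invalid("`exposure` must be non-negative.")
  out <- tibble(
    exposure_ugL = exposure,
    pnec_ugL = pnec,
    quotient = exposure / pnec,
    verdict = ifelse(exposure / pnec > 1, "potential_risk", "no_significant_risk")
  )
  if (!is.null(label)) out <- mutate(out, label = label, .before = 1)
  if (!is.null(method)) out$pnec_method <- method
  out
}

#' Exceedance summary of an exposure distribution against a PNEC
#'
#' Fraction of a set of concentrations at potential risk (above the PNEC) and
#' its complement. Accepts a plain numeric vector of PECs, a censored MEC
#' table, or a `ranked_distribution`; censored handling follows
#' [fraction_above()].
#'
#' @param x numeric PECs, a censored MEC table, or a `ranked_distribution`.
#' @param pnec a `pnec_result` or positive number (ug/L).
#' @return tibble with `n`, `count_at_risk`, `fraction_at_risk`,
#'   `fraction_safe`.
#' @export
exceedance_summary <- function(x, pnec) {
  if (inherits(pnec, "pnec_result")) pnec <- pnec$value
  check_number(pnec, "pnec", positive = TRUE)
  if (inherits(x, "ranked_distribution")) {
    x <- x$ordered |>
      select(value_ugL = "value_ugL", loq_ugL = "loq_ugL") |>
      mutate(detected = !is.na(.data$value_ugL))
  }
  if (is.numeric(x)) {
    if (!length(x)) stop_no_data("empty exposure set.")
    x <- tibble(value_ugL = x, loq_ugL = pnec, detected = TRUE)
  }
  fa <- fraction_above(x, pnec)
  tibble(
    n = fa$n,
    count_at_risk = fa$count,
    fraction_at_risk = fa$fraction,
    fraction_safe = 1 - fa$fraction
  )
}

#' Define an acceptable-daily-exposure (ADE) derivation
#'
#' An ADE derivation is a point of departure from mammalian toxicology (a
#' NOAEL, NOEL or LOAEL in mg/kg body weight/day), a default consumer body
#' weight, and an ordered chain of adjustment factors, each with a rationale
#' (interspecies extrapolation, intraspecies variability, study duration,
#' severity, point-of-departure quality, ...). The unrounded ADE is
#' `pod * body_weight / prod(factors)`.
#'
#' @param point_of_departure mg/kg body weight/day, > 0.
#' @param pod_kind `"NOAEL"`, `"NOEL"` or `"LOAEL"`.
#' @param body_weight consumer body weight, kg (default 60, adult human).
#' @param factors data frame with columns `value` (>= 1) and `rationale`
#'   (non-empty), or a named numeric vector (names become rationales).
#' @param label optional label for the derivation.
#' @return an object of class `ade_derivation`.
#' @examples
#' ade_derivation(2, "NOAEL", 60, c(
#'   interspecies_rat_to_human = 6.2, intraspecies_variability = 10,
#'   study_duration = 1, severity_systemic_toxicity = 5, noael_not_noel = 3
#' ))
#' @export
ade_derivation <- function(point_of_departure,
                           pod_kind = c("NOAEL", "NOEL", "LOAEL"),
                           body_weight = 60,
                           factors,
                           label = NULL) {
  pod_kind <- match.arg(pod_kind)
  check_number(point_of_departure, "point_of_departure", positive = TRUE)
  check_number(body_weight, "body_weight", positive = TRUE)
  if (is.numeric(factors)) {
    if (is.null(names(factors)) || any(names(factors) == "")) {
      stop_invalid("every adjustment factor needs a rationale (use a named vector).")
    }
    factors <- tibble(value = as.numeric(factors), rationale = names(factors))
  }
  check_columns(factors, c("value", "rationale"), "factor table")
  if (!nrow(factors)) stop_invalid("the adjustment-factor chain must not be empty.")
  if (any(factors$value < 1)) stop_invalid("adjustment factors must be >= 1.")
  if (any(!nzchar(factors$rationale))) stop_invalid("factor rationales must be non-empty.")
  structure(
    list(
      point_of_departure = point_of_departure,
      pod_kind = pod_kind,
      body_weight = body_weight,
      factors = as_tibble(factors),
      label = label
    ),
    class = "ade_derivation"
  )
}

#' @export
print.ade_derivation <- function(x, ...) {
  cat(sprintf(
    "<ade_derivation>%s %s %g mg/kg/d x %g kg / %s\n",
    if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
    x$pod_kind, x$point_of_departure, x$body_weight,
    paste(x$factors$value, collapse = " x ")
  ))
  invisible(x)
}

#' @export
tidy.ade_derivation <- function(x, ...) x$factors

#' Compute an ADE from a derivation, with an explicit rounding policy
#'
#' The unrounded ADE is `pod * body_weight / prod(factors)` (mg/person/day).
#' Rounding policies are named because derivations published in safety
#' assessments apply different conventions: `"two_decimals"` rounds to two
#' decimal places, `"down_1sf"` truncates downward to one significant figure
#' (never upward, hence always protective), `"none"` leaves the value as is.
#'
#' @param derivation an [ade_derivation()].
#' @param rounding `"none"`, `"two_decimals"` or `"down_1sf"`.
#' @return tibble with `label`, `pod_kind`, `unrounded_mg_d`, `ade_mg_d`,
#'   `rounding`.
#' @examples
#' d <- ade_derivation(2, "NOEL", 60, c(
#'   interspecies = 6.2, intraspecies = 10, duration = 1,
#'   teratogenicity_without_maternal_toxicity = 10, noel_quality = 1
#' ))
#' derive_ade(d, "two_decimals") # 0.19355 -> 0.19 mg/person/d
#' @export
derive_ade <- function(derivation, rounding = c("none", "two_decimals", "down_1sf")) {
  stopifnot(inherits(derivation, "ade_derivation"))
  rounding <- match.arg(rounding)
  unrounded <- derivation$point_of_departure * derivation$body_weight /
    prod(derivation$factors$value)
  ade <- switch(rounding,
    none = unrounded,
    two_decimals = round(unrounded, 2),
    down_1sf = round_down_signif(unrounded, 1L)
  )
  tibble(
    label = derivation$label %||% NA_character_,
    pod_kind = derivation$pod_kind,
    unrounded_mg_d = unrounded,
    ade_mg_d = ade,
    rounding = rounding
  )
}

#' Select the protective ADE among candidate derivations
#'
#' The lowest candidate ADE is protective of all others and is selected.
#'
#' @param ades tibble of [derive_ade()] rows (bind rows of candidates).
#' @return the selected row.
#' @export
select_ade <- function(ades) {
  check_columns(ades, "ade_mg_d", "ADE table")
  if (!nrow(ades)) stop_no_data("no candidate ADEs.")
  ades |> arrange(.data$ade_mg_d) |> dplyr::slice(1L)
}

#' Scale an intake limit between consumers of different body weight
#'
#' Linear body-weight scaling, e.g. from a 60-kg human ADE to a 10-kg otter
#' maximum tolerable daily intake (MTDI).
#'
#' @param ade intake limit (mass/day; any unit). Vectorised.
#' @param reference_bw body weight the limit was derived for (kg).
#' @param target_bw body weight of the target consumer (kg).
#' @return scaled limit, `ade * target_bw / reference_bw`.
#' @examples
#' mtdi_scale(75, 60, 10) # 12.5 ug/d for a 10-kg otter
#' @export
mtdi_scale <- function(ade, reference_bw, target_bw) {
  check_number(reference_bw, "reference_bw", positive = TRUE)
  check_number(target_bw, "target_bw", positive = TRUE)
  ade * target_bw / reference_bw
}

#' Fish tissue concentration from water concentration and BCF
#'
#' Steady-state bioconcentration: `c_fish (ug/kg) = c_water (ug/L) * BCF`.
#'
#' @param water_pec water concentration, ug/L (vectorised, >= 0).
#' @param bcf bioconcentration factor (L/kg, >= 0); a `bcf_selection` is also
#'   accepted.
#' @return fish tissue concentration, ug/kg wet weight.
#' @examples
#' fish_tissue_concentration(0.671, 6.22) # 4.17 ug/kg
#' @export
fish_tissue_concentration <- function(water_pec, bcf) {
  if (inherits(bcf, "bcf_selection")) bcf <- bcf$selected_bcf
  check_number(bcf, "bcf", nonneg = TRUE)
  if (any(water_pec < 0, na.rm = TRUE)) stop_invalid("`water_pec` must be non-negative.")
  water_pec * bcf
}

#' Define a secondary-poisoning intake scenario
#'
#' Daily fish and drinking-water intake of a consumer (top predator or human),
#' with the water and fish-tissue concentrations they are exposed to. Default
#' consumers: an otter (10 kg, 1 kg fish/d, 0.79 L water/d) and a human
#' (60 kg, 115 g fish/d, 2 L water/d).
#'
#' @param consumer `"top_predator"` or `"human"`.
#' @param body_weight kg.
#' @param fish_intake kg fish/day.
#' @param water_intake L water/day.
#' @param water_concentration ug/L.
#' @param fish_tissue_conc ug/kg; computed with [fish_tissue_concentration()]
#'   when a `bcf` is given instead.
#' @param bcf optional BCF used to derive `fish_tissue_conc` from
#'   `water_concentration` (ignored when `fish_tissue_conc` is supplied).
#' @return an object of class `intake_scenario`.
#' @export
intake_scenario <- function(consumer = c("top_predator", "human"),
                            body_weight = if (consumer == "human") 60 else 10,
                            fish_intake = if (consumer == "human") 0.115 else 1,
                            water_intake = if (consumer == "human") 2 else 0.79,
                            water_concentration,
                            fish_tissue_conc = NULL,
                            bcf = NULL) {
  consumer <- match.arg(consumer)
  for (nm in c("body_weight")) check_number(get(nm), nm, positive = TRUE)
  for (nm in c("fish_intake", "water_intake", "water_concentration")) {
    check_number(get(nm), nm, nonneg = TRUE)
  }
  if (is.null(fish_tissue_conc)) {
    if (is.null(bcf)) stop_invalid("supply either `fish_tissue_conc` or `bcf`.")
    fish_tissue_conc <- fish_tissue_concentration(water_concentration, bcf)
  }
  check_number(fish_tissue_conc, "fish_tissue_conc", nonneg = TRUE)
  structure(
    list(
      consumer = consumer,
      body_weight = body_weight,
      fish_intake = fish_intake,
      water_intake = water_intake,
      water_concentration = water_concentration,
      fish_tissue_conc = fish_tissue_conc
    ),
    class = "intake_scenario"
  )
}

#' Combined daily intake through fish and drinking water
#'
#' `intake (ug/d) = fish_intake * c_fish + water_intake * c_water`.
#'
#' @param scenario an [intake_scenario()].
#' @return total daily intake, ug/day.
#' @examples
#' otter <- intake_scenario("top_predator", water_concentration = 0.671, bcf = 6.22)
#' daily_intake(otter) # 4.7 ug/d
#' @export
daily_intake <- function(scenario) {
  stopifnot(inherits(scenario, "intake_scenario"))
  scenario$fish_intake * scenario$fish_tissue_conc +
    scenario$water_intake * scenario$water_concentration
}

#' Secondary-poisoning risk quotient
#'
#' Daily intake divided by the intake limit (ADE for humans, MTDI for
#' wildlife); a quotient above one flags potential risk.
#'
#' @param intake daily intake (ug/day, >= 0), or an [intake_scenario()] whose
#'   [daily_intake()] is used.
#' @param limit intake limit (ug/day, > 0).
#' @return tibble with `intake_ug_d`, `limit_ug_d`, `quotient`, `verdict`.
#' @examples
#' secondary_poisoning_rq(4.7, 12.5) # 0.376, no significant risk
#' @export
secondary_poisoning_rq <- function(intake, limit) {
  if (inherits(intake, "intake_scenario")) intake <- daily_intake(intake)
  check_number(limit, "limit", positive = TRUE)
  if (any(intake < 0, na.rm = TRUE)) stop_invalid("`intake` must be non-negative.")
  tibble(
    intake_ug_d = intake,
    limit_ug_d = limit,
    quotient = intake / limit,
    verdict = ifelse(intake / limit > 1, "potential_risk", "no_significant_risk")
  )
}
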