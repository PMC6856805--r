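#' Construct a substance profile
#'
#' A substance profile collects the physicochemical and fate constants that the
#' exposure, effects and secondary-poisoning tiers consume: molecular weights of
#' the active moiety and (optionally) its prodrug, acid dissociation constants,
#' pH-dependent octanol/water distribution coefficients, solubilities and
#' bioconcentration factors (BCFs), vapor pressure, and screening-level
#' hydrolysis/photolysis observations. The screening hydrolysis and photolysis
#' entries are stored as inert data; no kinetics are derived from them unless a
#' caller opts in (e.g. as a decay rate for the catchment simulator).
#'
#' pH-indexed maps are given as named numeric vectors whose names are pH values,
#' e.g. `c("5" = 161, "6" = 23.2)`. Duplicate pH keys are rejected rather than
#' silently collapsed.
#'
#' @param name substance name.
#' @param molecular_weight molecular weight of the active moiety (g/mol).
#' @param prodrug_molecular_weight molecular weight of the prodrug (g/mol), or
#'   `NULL` when the substance is administered directly.
#' @param pka_values numeric vector of acid dissociation constants.
#' @param log_dow_by_ph named numeric vector, pH -> log D_OW (dimensionless).
#' @param water_solubility_by_ph named numeric vector, pH -> solubility (mg/L).
#' @param bcf_by_ph named numeric vector, pH -> wet-weight fish BCF (L/kg).
#' @param vapor_pressure vapor pressure (hPa).
#' @param hydrolysis_loss_by_ph named numeric vector, pH -> percent substance
#'   loss in a screening hydrolysis test (data only).
#' @param photolysis_rate_by_condition named numeric vector, condition label ->
#'   photodegradation rate constant (1/min; data only).
#' @param cmr is the substance carcinogenic, mutagenic or reprotoxic? Feeds the
#'   toxicity arm of [pbt_screen()].
#' @return an object of class `substance_profile`.
#' @seealso [select_bcf()], [prodrug_to_active()], [mpa_profile()]
#' @export
substance_profile <- function(name,
                              molecular_weight,
                              prodrug_molecular_weight = NULL,
                              pka_values = numeric(),
                              log_dow_by_ph = NULL,
                              water_solubility_by_ph = NULL,
                              bcf_by_ph = NULL,
                              vapor_pressure = NULL,
                              hydrolysis_loss_by_ph = NULL,
                              photolysis_rate_by_condition = NULL,
                              cmr = FALSE) {
  stopifnot(is.character(name), length(name) == 1L)
  check_number(molecular_weight, "molecular_weight", positive = TRUE)
  if (!is.null(prodrug_molecular_weight)) {
    check_number(prodrug_molecular_weight, "prodrug_molecular_weight", positive = TRUE)
  }
  check_ph_map <- function(map, what, positive = TRUE) {
    if (is.null(map)) return(NULL)
    if (is.null(names(map)) || any(names(map) == "")) {
      stop_invalid(sprintf("`%s` must be a named vector (names are pH values).", what))
    }
    ph <- as.numeric(names(map))
    if (anyNA(ph) || any(ph < 0) || any(ph > 14)) {
      stop_invalid(sprintf("`%s` pH keys must be numbers in [0, 14].", what))
    }
    if (anyDuplicated(ph)) {
      stop_invalid(sprintf("`%s` has duplicate pH keys; duplicates are rejected.", what))
    }
    if (positive && any(map <= 0)) {
      stop_invalid(sprintf("`%s` values must be strictly positive.", what))
    }
    map[order(ph)]
  }
  out <- structure(
    list(
      name = name,
      molecular_weight = molecular_weight,
      prodrug_molecular_weight = prodrug_molecular_weight,
      pka_values = as.numeric(pka_values),
      log_dow_by_ph = check_ph_map(log_dow_by_ph, "log_dow_by_ph", positive = FALSE),
      water_solubility_by_ph = check_ph_map(water_solubility_by_ph, "water_solubility_by_ph"),
      bcf_by_ph = check_ph_map(bcf_by_ph, "bcf_by_ph"),
      vapor_pressure = vapor_pressure,
      hydrolysis_loss_by_ph = check_ph_map(hydrolysis_loss_by_ph, "hydrolysis_loss_by_ph"),
      photolysis_rate_by_condition = photolysis_rate_by_condition,
      cmr = isTRUE(cmr)
    ),
    class = "substance_profile"
  )
  if (!is.null(out$vapor_pressure)) check_number(out$vapor_pressure, "vapor_pressure", positive = TRUE)
  out
}

#' @export
print.substance_profile <- function(x, ...) {
  cat("<substance_profile> ", x$name, "\n", sep = "")
  cat("  MW active:", x$molecular_weight, "g/mol")
  if (!is.null(x$prodrug_molecular_weight)) {
    cat("; MW prodrug:", x$prodrug_molecular_weight, "g/mol")
  }
  cat("\n")
  if (!is.null(x$bcf_by_ph)) {
    cat("  BCF by pH:", paste(names(x$bcf_by_ph), x$bcf_by_ph, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Stoichiometric prodrug-to-active-moiety mass conversion
#'
#' Converts a mass of prodrug to the equivalent mass of active moiety by the
#' ratio of molecular weights, assuming complete cleavage of the prodrug (the
#' standard assumption for an ester prodrug that is fully hydrolysed in vivo).
#'
#' @param mass_prodrug mass of prodrug (any mass unit; the result is in the
#'   same unit). Vectorised.
#' @param mw_active molecular weight of the active moiety (g/mol).
#' @param mw_prodrug molecular weight of the prodrug (g/mol).
#' @return mass of active moiety, `mass_prodrug * mw_active / mw_prodrug`.
#' @examples
#' prodrug_to_active(0.1, 320.34, 433.5) # 0.1 mg MPM -> 0.0739 mg MPA
#' @export
prodrug_to_active <- function(mass_prodrug, mw_active, mw_prodrug) {
  check_number(mw_active, "mw_active", positive = TRUE)
  check_number(mw_prodrug, "mw_prodrug", positive = TRUE)
  if (any(mass_prodrug < 0, na.rm = TRUE)) {
    stop_invalid("`mass_prodrug` must be non-negative.")
  }
  mass_prodrug * mw_active / mw_prodrug
}

#' Select a bioconcentration factor over an environmentally relevant pH window
#'
#' Takes the geometric mean of all tabulated BCFs whose pH lies inside the
#' closed interval `[ph_low, ph_high]`. Environmental assessments conventionally
#' use pH 5 to 9 as the relevant surface-water range.
#'
#' @param bcf_by_ph named numeric vector, pH -> BCF, or a
#'   [substance_profile()] (whose `bcf_by_ph` slot is used).
#' @param ph_low,ph_high closed interval endpoints (inclusive).
#' @return an object of class `bcf_selection` with fields `ph_range`,
#'   `values_used` (in pH order) and `selected_bcf`.
#' @examples
#' select_bcf(c("5" = 161, "6" = 23.2, "7" = 2.49, "8" = 1, "9" = 1, "10" = 1), 5, 9)
#' @export
select_bcf <- function(bcf_by_ph, ph_low = 5, ph_high = 9) {
  if (inherits(bcf_by_ph, "substance_profile")) bcf_by_ph <- bcf_by_ph$bcf_by_ph
  if (is.null(bcf_by_ph) || !length(bcf_by_ph)) {
    stop_no_data("no BCF values supplied.")
  }
  ph <- as.numeric(names(bcf_by_ph))
  if (anyNA(ph)) stop_invalid("`bcf_by_ph` must be named by numeric pH values.")
  if (anyDuplicated(ph)) stop_invalid("duplicate pH keys in `bcf_by_ph` are rejected.")
  check_number(ph_low, "ph_low")
  check_number(ph_high, "ph_high")
  keep <- ph >= ph_low & ph <= ph_high
  if (!any(keep)) {
    stop_no_data(sprintf("no BCF values tabulated inside pH [%g, %g].", ph_low, ph_high))
  }
  used <- bcf_by_ph[keep][order(ph[keep])]
  structure(
    list(
      ph_range = c(ph_low, ph_high),
      values_used = used,
      selected_bcf = geometric_mean(used)
    ),
    class = "bcf_selection"
  )
}

#' @export
print.bcf_selection <- function(x, ...) {
  cat(sprintf(
    "<bcf_selection> geometric mean BCF %.3g over pH [%g, %g] (%d values)\n",
    x$selected_bcf, x$ph_range[1], x$ph_range[2], length(x$values_used)
  ))
  invisible(x)
}

#' @rdname select_bcf
#' @param x a `bcf_selection`.
#' @param ... unused.
#' @export
tidy.bcf_selection <- function(x, ...) {
  tibble(
    ph = as.numeric(names(x$values_used)),
    bcf = as.numeric(x$values_used),
    selected_bcf = x$selected_bcf
  )
}

#' Read or write a substance profile as JSON
#'
#' The on-disk representation stores the pH-indexed maps as JSON objects keyed
#' by pH. [mpa_profile()] reproduces the bundled mycophenolic-acid fixture.
#'
#' @param path file path.
#' @return [read_substance_profile()] returns a [substance_profile()];
#'   [write_substance_profile()] returns `path` invisibly.
#' @export
read_substance_profile <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("profile file not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_map <- function(x) if (is.null(x) || !length(x)) NULL else unlist(x)
  substance_profile(
    name = raw$name,
    molecular_weight = raw$molecular_weight,
    prodrug_molecular_weight = raw$prodrug_molecular_weight,
    pka_values = raw$pka_values %||% numeric(),
    log_dow_by_ph = as_map(raw$log_dow_by_ph),
    water_solubility_by_ph = as_map(raw$water_solubility_by_ph),
    bcf_by_ph = as_map(raw$bcf_by_ph),
    vapor_pressure = raw$vapor_pressure,
    hydrolysis_loss_by_ph = as_map(raw$hydrolysis_loss_by_ph),
    photolysis_rate_by_condition = as_map(raw$photolysis_rate_by_condition),
    cmr = isTRUE(raw$cmr)
  )
}

#' @rdname read_substance_profile
#' @param profile a [substance_profile()].
#' @export
write_substance_profile <- function(profile, path) {
  stopifnot(inherits(profile, "substance_profile"))
  x <- unclass(profile)
  x <- x[!vapply(x, is.null, logical(1))]
  # pH-indexed maps serialise as JSON objects keyed by pH, not bare arrays
  x <- lapply(x, function(el) {
    if (is.numeric(el) && !is.null(names(el))) as.list(el) else el
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
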