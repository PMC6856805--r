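pnec_result <- function(value, basis, assessment_factor, method, extra = list()) {
  structure(
    c(list(
      value = value,
      basis = basis,
      assessment_factor = assessment_factor,
      method = method
    ), extra),
    class = "pnec_result"
  )
}

#' @export
print.pnec_result <- function(x, ...) {
  cat(sprintf("<pnec_result> %.4g ug/L [%s]\n", x$value, x$method))
  if (!is.null(x$basis)) {
    cat("  basis:", paste(unlist(x$basis), collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
tidy.pnec_result <- function(x, ...) {
  tibble(
    method = x$method,
    pnec_ugL = x$value,
    assessment_factor = x$assessment_factor,
    basis = paste(unlist(x$basis), collapse = " "),
    raw_ugL = x$raw_value %||% x$value
  )
}

aquatic_taxa <- c("fish", "daphnid", "green_alga", "cyanobacterium")

#' Aquatic PNEC from chronic ecotoxicity endpoints
#'
#' Divides the lowest chronic endpoint of the requested kind (NOEC or EC10)
#' among the standard aquatic taxa (fish, daphnids, green algae,
#' cyanobacteria) by an assessment factor; the default factor of 10 is the
#' regulatory convention when chronic endpoints from three trophic levels are
#' available.
#'
#' @param endpoints data frame with columns `taxon_group`, `endpoint_kind`,
#'   `value_ugL` (> 0); extra columns (duration, basis) are carried through to
#'   the recorded basis.
#' @param kind `"NOEC"` or `"EC10"`.
#' @param assessment_factor dimensionless, >= 1.
#' @return a `pnec_result` whose `basis` records the driving endpoint.
#' @examples
#' ep <- tibble::tibble(
#'   taxon_group = c("cyanobacterium", "green_alga", "daphnid", "fish"),
#'   endpoint_kind = "NOEC", value_ugL = c(83.9, 9, 630, 1.32)
#' )
#' pnec_aquatic(ep, "NOEC") # 0.132 ug/L, fish-driven
#' @export
pnec_aquatic <- function(endpoints, kind = c("NOEC", "EC10"), assessment_factor = 10) {
  kind <- match.arg(kind)
  check_columns(endpoints, c("taxon_group", "endpoint_kind", "value_ugL"), "endpoint table")
  check_number(assessment_factor, "assessment_factor", positive = TRUE)
  if (assessment_factor < 1) stop_invalid("`assessment_factor` must be >= 1.")
  sel <- endpoints |>
    filter(.data$endpoint_kind == kind, .data$taxon_group %in% aquatic_taxa)
  if (!nrow(sel)) {
    stop_no_data(sprintf("no aquatic %s endpoints available.", kind))
  }
  if (any(sel$value_ugL <= 0)) stop_invalid("endpoint values must be > 0.")
  lowest <- sel |> arrange(.data$value_ugL) |> dplyr::slice(1L)
  pnec_result(
    value = lowest$value_ugL / assessment_factor,
    basis = list(taxon_group = lowest$taxon_group, endpoint_kind = kind,
                 value_ugL = lowest$value_ugL),
    assessment_factor = assessment_factor,
    method = paste0("aquatic_", tolower(kind))
  )
}

#' PNEC for sewage-treatment-plant microorganisms
#'
#' Divides the activated-sludge respiration-inhibition EC10 by an assessment
#' factor (default 10).
#'
#' @param ec10_sludge sludge-microorganism EC10 in ug/L, > 0.
#' @param assessment_factor dimensionless, >= 1.
#' @return a `pnec_result`.
#' @examples
#' pnec_stp(69000) # 69 mg/L EC10 -> 6900 ug/L
#' @export
pnec_stp <- function(ec10_sludge, assessment_factor = 10) {
  check_number(ec10_sludge, "ec10_sludge", positive = TRUE)
  check_number(assessment_factor, "assessment_factor", positive = TRUE)
  pnec_result(
    value = ec10_sludge / assessment_factor,
    basis = list(taxon_group = "sludge_microorganisms", endpoint_kind = "EC10",
                 value_ugL = ec10_sludge),
    assessment_factor = assessment_factor,
    method = "stp"
  )
}

check_mic_table <- function(mics) {
  check_columns(mics, c("species", "mic_mgL"), "MIC table")
  if (!nrow(mics)) stop_no_data("empty MIC table.")
  if (any(mics$mic_mgL <= 0)) stop_invalid("MICs must be > 0.")
  invisible(mics)
}

#' Antibiotic-resistance PNEC: lowest MIC over a fixed factor
#'
#' The simplest provisional PNEC for selection or maintenance of antibiotic
#' resistance: the lowest bacterial minimum inhibitory concentration divided by
#' a fixed assessment factor (default 100). MICs are supplied in mg/L; the
#' result is in ug/L.
#'
#' @param mics data frame with columns `species`, `mic_mgL` (> 0); a `strain`
#'   column is optional.
#' @param factor assessment factor, >= 1.
#' @return a `pnec_result`.
#' @examples
#' pnec_abr_lowest_mic(tibble::tibble(species = "S. aureus", mic_mgL = 31.25))
#' @export
pnec_abr_lowest_mic <- function(mics, factor = 100) {
  check_mic_table(mics)
  check_number(factor, "factor", positive = TRUE)
  lowest <- mics |> arrange(.data$mic_mgL) |> dplyr::slice(1L)
  pnec_result(
    value = lowest$mic_mgL * 1000 / factor,
    basis = list(species = lowest$species, mic_mgL = lowest$mic_mgL),
    assessment_factor = factor,
    method = "abr_lowest_mic"
  )
}

# standard two-fold antimicrobial dilution series: ..., 0.25, 0.5, 1, 2, 4, ...
# i.e. integer powers of two in ug/L
round_down_mic_series <- function(x) 2^floor(log2(x))

#' Antibiotic-resistance PNEC: species-filtered lowest-percentile method
#'
#' The MIC-distribution-based method: only species with at least
#' `min_obs_per_species` MIC observations are eligible (to avoid conclusions
#' from sparse data); one value, the lowest MIC, is taken per eligible species;
#' an uncertainty factor for small datasets scales the result by the number of
#' eligible species over 41 (the species count of the reference MIC
#' compilation); and a general assessment factor of 10 is applied:
#' `PNEC_raw = lowest_MIC * (n_species / 41) / 10`. The raw value is finally
#' rounded down to the nearest concentration of the standard two-fold MIC test
#' dilution series (..., 16, 32, 64, 128 ug/L).
#'
#' @inheritParams pnec_abr_lowest_mic
#' @param min_obs_per_species minimum MIC observations for a species to be
#'   eligible (default 10).
#' @param reference_species_count denominator of the small-dataset uncertainty
#'   factor (default 41).
#' @param general_factor general assessment factor (default 10).
#' @return a `pnec_result` whose `value` is the rounded PNEC and which also
#'   carries `raw_value` (before rounding) and `n_species`.
#' @examples
#' mics <- tibble::tibble(species = "S. aureus", mic_mgL = rep(31.25, 12))
#' pnec_abr_percentile(mics) # raw 76.2 -> rounded 64 ug/L
#' @export
pnec_abr_percentile <- function(mics, min_obs_per_species = 10,
                                reference_species_count = 41,
                                general_factor = 10) {
  check_mic_table(mics)
  eligible <- mics |>
    group_by(.data$species) |>
    summarise(lowest_mic_mgL = min(.data$mic_mgL), n_obs = n()) |>
    filter(.data$n_obs >= min_obs_per_species)
  if (!nrow(eligible)) {
    stop_no_data(sprintf(
      "no species has >= %d MIC observations; cannot derive a distribution-based resistance PNEC.",
      min_obs_per_species
    ))
  }
  n_species <- nrow(eligible)
  lowest <- min(eligible$lowest_mic_mgL) * 1000 # ug/L
  raw <- lowest * (n_species / reference_species_count) / general_factor
  pnec_result(
    value = round_down_mic_series(raw),
    basis = list(
      species = eligible$species[which.min(eligible$lowest_mic_mgL)],
      lowest_mic_ugL = lowest
    ),
    assessment_factor = general_factor * reference_species_count / n_species,
    method = "abr_percentile",
    extra = list(raw_value = raw, n_species = n_species)
  )
}

#' Final antibiotic-resistance PNEC
#'
#' Derives both provisional resistance PNECs ([pnec_abr_lowest_mic()] and
#' [pnec_abr_percentile()]) and selects the lower. If the distribution-based
#' method has no eligible species, the lowest-MIC method alone is returned.
#'
#' @inheritParams pnec_abr_percentile
#' @param factor fixed factor for the lowest-MIC method.
#' @return the selected `pnec_result`.
#' @export
pnec_abr <- function(mics, factor = 100, min_obs_per_species = 10) {
  a <- pnec_abr_lowest_mic(mics, factor = factor)
  b <- tryCatch(
    pnec_abr_percentile(mics, min_obs_per_species = min_obs_per_species),
    pharmera_no_data = function(e) NULL
  )
  if (is.null(b) || a$value <= b$value) a else b
}

#' Persistence / bioaccumulation / toxicity (PBT) screen
#'
#' Screening-level hazard classification. Persistence is an evidence flag
#' supplied by the caller (degradation simulation tests are weighed by expert
#' judgment, not by a numeric trigger here). Bioaccumulation uses the screening
#' triggers BCF >= 2000 or maximum log D_OW >= 4.5. Toxicity triggers when any
#' chronic NOEC is below 10 ug/L or when the substance carries a CMR
#' (carcinogenic/mutagenic/reprotoxic) classification. Missing inputs yield an
#' explicit `"undetermined"` verdict for that arm rather than a guess.
#'
#' @param profile a [substance_profile()] (supplies BCFs, log D_OW, CMR flag).
#' @param degradable `TRUE`/`FALSE` evidence flag from degradation simulation
#'   tests, or `NA` if unknown.
#' @param endpoints chronic endpoint table as in [pnec_aquatic()], or `NULL`.
#' @param bcf_threshold,logd_threshold,noec_threshold_ugL screening triggers.
#' @return tibble with columns `criterion` (`persistent`, `bioaccumulative`,
#'   `toxic`), `verdict` (`"yes"`, `"no"`, `"undetermined"`), `rationale`.
#' @export
pbt_screen <- function(profile, degradable = NA, endpoints = NULL,
                       bcf_threshold = 2000, logd_threshold = 4.5,
                       noec_threshold_ugL = 10) {
  stopifnot(inherits(profile, "substance_profile"))

  p_verdict <- if (is.na(degradable)) "undetermined" else if (degradable) "no" else "yes"
  p_rat <- switch(p_verdict,
    no = "degradation evidence flag set: substance degraded in simulation tests",
    yes = "degradation evidence flag unset: no relevant degradation observed",
    undetermined = "no degradation evidence supplied"
  )

  max_bcf <- if (!is.null(profile$bcf_by_ph)) max(profile$bcf_by_ph) else NA_real_
  max_logd <- if (!is.null(profile$log_dow_by_ph)) max(profile$log_dow_by_ph) else NA_real_
  if (is.na(max_bcf) && is.na(max_logd)) {
    b_verdict <- "undetermined"
    b_rat <- "no BCF or log D_OW data supplied"
  } else if ((!is.na(max_bcf) && max_bcf >= bcf_threshold) ||
             (!is.na(max_logd) && max_logd >= logd_threshold)) {
    b_verdict <- "yes"
    b_rat <- sprintf(
      "screening trigger crossed (max BCF %.3g vs %.3g; max log D %.3g vs %.3g)",
      max_bcf, bcf_threshold, max_logd, logd_threshold
    )
  } else {
    b_verdict <- "no"
    b_rat <- sprintf(
      "max BCF %.3g < %.3g and max log D %.3g < %.3g",
      max_bcf, bcf_threshold, max_logd, logd_threshold
    )
  }

  noecs <- if (!is.null(endpoints)) {
    check_columns(endpoints, c("taxon_group", "endpoint_kind", "value_ugL"), "endpoint table")
    endpoints$value_ugL[endpoints$endpoint_kind == "NOEC"]
  } else {
    numeric()
  }
  if (isTRUE(profile$cmr)) {
    t_verdict <- "yes"
    t_rat <- "carcinogenic/mutagenic/reprotoxic classification"
    if (length(noecs) && min(noecs) < noec_threshold_ugL) {
      t_rat <- sprintf("%s; chronic NOEC %.3g ug/L < %.3g ug/L", t_rat,
                       min(noecs), noec_threshold_ugL)
    }
  } else if (length(noecs)) {
    if (min(noecs) < noec_threshold_ugL) {
      t_verdict <- "yes"
      t_rat <- sprintf("chronic NOEC %.3g ug/L < %.3g ug/L", min(noecs), noec_threshold_ugL)
    } else {
      t_verdict <- "no"
      t_rat <- sprintf("lowest chronic NOEC %.3g ug/L >= %.3g ug/L and no CMR classification",
                       min(noecs), noec_threshold_ugL)
    }
  } else {
    t_verdict <- "undetermined"
    t_rat <- "no chronic endpoints and no CMR classification supplied"
  }

  tibble(
    criterion = c("persistent", "bioaccumulative", "toxic"),
    verdict = c(p_verdict, b_verdict, t_verdict),
    rationale = c(p_rat, b_rat, t_rat)
  )
}
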