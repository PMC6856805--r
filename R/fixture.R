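#' Physicochemical profile of mycophenolic acid (MPA)
#'
#' The bundled worked example: the published physicochemical and fate
#' constants for mycophenolic acid and its prodrug mycophenolate mofetil
#' (MPM). Values: MW 320.34 / 433.5 g/mol; pKa 4.58 (carboxylic acid) and
#' 8.045 (phenolic); solubility 45 mg/L (pH 5) and 710 mg/L (pH 7);
#' log D_OW 2.28 / 0.48 / -1.54 at pH 5 / 7 / 9; vapor pressure 4.27e-7 hPa;
#' modelled wet-weight fish BCFs 161, 23.2, 2.49, 1.0, 1.0, 1.0 at pH 5-10;
#' screening hydrolysis losses 46.15 / 29.03 / 36.67 percent at pH 5 / 7 / 9;
#' photodegradation rate constants per minute by season/pH plus literature
#' UV-C and artificial-sunlight rates. MPA is classified
#' carcinogenic/mutagenic/reprotoxic (CMR), which feeds the toxicity arm of
#' [pbt_screen()].
#'
#' @return a [substance_profile()].
#' @export
mpa_profile <- function() {
  substance_profile(
    name = "mycophenolic acid",
    molecular_weight = 320.34,
    prodrug_molecular_weight = 433.5,
    pka_values = c(4.58, 8.045),
    log_dow_by_ph = c("5" = 2.28, "7" = 0.48, "9" = -1.54),
    water_solubility_by_ph = c("5" = 45, "7" = 710),
    bcf_by_ph = c("5" = 161, "6" = 23.2, "7" = 2.49, "8" = 1, "9" = 1, "10" = 1),
    vapor_pressure = 4.27e-7,
    hydrolysis_loss_by_ph = c("5" = 46.15, "7" = 29.03, "9" = 36.67),
    photolysis_rate_by_condition = c(
      ph5_winter = 0.0017, ph5_summer = 0.0059,
      ph7_winter = 0.0049, ph7_summer = 0.018,
      ph9_winter = 0.0087, ph9_summer = 0.031,
      uvc = 0.0284, solar_box = 0.004
    ),
    cmr = TRUE
  )
}

#' Bundled mycophenolic-acid assessment fixture
#'
#' All constants needed to run the full tiered assessment for MPA/MPM from
#' code: the substance profile, the chronic ecotoxicity endpoint table, the
#' bacterial MIC table, the biodegradation and sorption constants, the
#' STP-removal scenarios, exposure scenario defaults, the two
#' acceptable-daily-exposure derivations, the secondary-poisoning intake
#' defaults, and the reference exposure concentrations used in the worked
#' risk characterisation.
#'
#' Published values are carried verbatim. Two kinds of entries are synthetic
#' stand-ins, flagged in `$synthetic_notes`: the individual MIC values other
#' than the minima (only the ranges 31.25-125 and 125-500 mg/L are published;
#' the within-range spread here is invented, and only the minimum and the
#' per-species observation counts enter any derivation), and the per-country
#' water-use/dilution factors used by examples (the underlying country
#' dataset is not reproduced).
#'
#' @return a named list; see Details.
#' @examples
#' fx <- mpa_fixture()
#' pnec_aquatic(fx$endpoints, "NOEC")$value # 0.132
#' @export
mpa_fixture <- function() {
  endpoints <- tibble(
    taxon_group = rep(c("cyanobacterium", "green_alga", "daphnid", "fish"), 2),
    endpoint_kind = rep(c("NOEC", "EC10"), each = 4),
    value_ugL = c(83.9, 9, 630, 1.32, 155, 12, 929, 5.8),
    basis = c(
      "growth rate and yield", "growth rate", "reproduction", "F1 length and wet weight",
      "growth rate", "growth rate", "reproduction", "posthatch survival"
    )
  )
  # 23 bacterial MICs; only the reported minima (31.25 for S. aureus, 125 for
  # the rest) and the counts are load-bearing; the within-range spread is a
  # synthetic stand-in
  mics <- dplyr::bind_rows(
    tibble(
      species = "Staphylococcus aureus",
      strain = sprintf("sa_%02d", 1:12),
      mic_mgL = c(31.25, 31.25, 62.5, 62.5, 62.5, 62.5, 125, 125, 125, 125, 125, 125)
    ),
    tibble(
      species = c(
        "Staphylococcus epidermidis",
        rep(c("Shigella flexneri", "Proteus vulgaris", "Escherichia coli",
              "Pseudomonas aeruginosa", "Salmonella enteritidis"), each = 2)
      ),
      strain = c("se_01", sprintf("other_%02d", 1:10)),
      mic_mgL = c(125, 125, 250, 250, 500, 250, 500, 250, 500, 250, 500)
    )
  )
  ade_chains <- list(
    systemic = ade_derivation(
      point_of_departure = 2, pod_kind = "NOAEL", body_weight = 60,
      factors = c(
        interspecies_rat_to_human = 6.2,
        intraspecies_variability = 10,
        study_duration_1yr_rodent = 1,
        severity_systemic_toxicity = 5,
        noael_instead_of_noel = 3
      ),
      label = "systemic (12-month rat oral)"
    ),
    teratology = ade_derivation(
      point_of_departure = 2, pod_kind = "NOEL", body_weight = 60,
      factors = c(
        interspecies_rat_to_human = 6.2,
        intraspecies_variability = 10,
        full_organogenesis_covered = 1,
        teratogenicity_without_maternal_toxicity = 10,
        established_noel = 1
      ),
      label = "teratology (rat)"
    )
  )
  list(
    profile = mpa_profile(),
    endpoints = endpoints,
    ec10_sludge_ugL = 69000, # activated sludge respiration inhibition EC10, 69 mg/L
    mics = mics,
    k_biodeg = rate_constant(0.0174, "per_hour"),
    k_biodeg_scenarios = list(
      low = rate_constant(0.0174, "per_hour"),
      mid = rate_constant(0.0017, "per_minute"),
      high = rate_constant(0.006, "per_minute")
    ),
    mineralization_plateau_percent = 82.2,
    stp_removals = c(low = 0.12, mid = 0.436, high = 0.731),
    kd_soil_Lkg = c(2.2, 2.8, 5.0),
    kd_sludge_Lkg = c(9.3, 13),
    koc_max_Lkg = 37,
    dt50_sediment_d = 14,
    scenario_initial = exposure_scenario(
      wastewater_per_capita = 200, treated_fraction = 1,
      stp_removal = 0, dilution_factor = 10
    ),
    treated_fraction_refined = 0.8,
    reference = list(
      highest_stp_pec_ugL = 8.83,   # highest refined per-country STP PEC
      highest_effluent_mec_ugL = 4.19,
      highest_sw_pec_ugL = 0.671,   # catchment-model 99th-percentile surface PEC
      highest_sw_mec_ugL = 0.656,
      initial_stp_pec_ugL = 2.99,
      loq_ugL = 0.001,
      n_mecs = 110,
      n_mec_detects = 61
    ),
    ade_chains = ade_chains,
    intake_defaults = list(
      top_predator = list(body_weight = 10, fish_intake = 1, water_intake = 0.79),
      human = list(body_weight = 60, fish_intake = 0.115, water_intake = 2)
    ),
    synthetic_notes = c(
      "MIC within-range spread is synthetic; only minima and counts are published",
      "per-country water-use and dilution factors are not reproduced; examples use synthetic values"
    )
  )
}
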