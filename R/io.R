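table_schemas <- list(
  use = list(
    cols = c(country = "character", year = "integer", mpa_kg = "double",
             mpm_kg = "double", population = "double")
  ),
  mec = list(
    cols = c(value_ugL = "double", loq_ugL = "double", detected = "logical",
             matrix = "character", site = "character", source = "character"),
    optional = c("matrix", "site", "source", "detected")
  ),
  endpoint = list(
    cols = c(taxon_group = "character", endpoint_kind = "character",
             value_ugL = "double", duration = "character", basis = "character"),
    optional = c("duration", "basis")
  ),
  mic = list(
    cols = c(species = "character", strain = "character", mic_mgL = "double"),
    optional = "strain"
  ),
  segment = list(
    cols = c(id = "integer", downstream_id = "integer", flow_mean_m3s = "double",
             flow_min_m3s = "double", flow_max_m3s = "double",
             travel_time_h = "double")
  ),
  stp = list(
    cols = c(segment_id = "integer", population = "double",
             per_capita_use_ug_d = "double", wastewater_per_capita_L_d = "double",
             removal = "double")
  )
)

#' Read a schema-validated input table
#'
#' Reads one of the pipeline's CSV dialects (comma-separated, UTF-8, `.`
#' decimal) and validates it against the named schema. Missing required
#' columns raise a schema error; rows that fail a type conversion are reported
#' with their row numbers. A header-only file yields an empty (zero-row)
#' tibble, not an error.
#'
#' Schemas: `"use"` (`country,year,mpa_kg,mpm_kg,population`), `"mec"`
#' (`value_ugL,loq_ugL,detected,matrix,site,source`; `value_ugL` empty for a
#' nondetect), `"endpoint"` (`taxon_group,endpoint_kind,value_ugL,duration,
#' basis`), `"mic"` (`species,strain,mic_mgL`), `"segment"` and `"stp"` (river
#' network halves).
#'
#' @param path CSV file path.
#' @param schema one of `"use"`, `"mec"`, `"endpoint"`, `"mic"`, `"segment"`,
#'   `"stp"`.
#' @return validated tibble.
#' @export
read_table <- function(path, schema = names(table_schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop_invalid(sprintf("file not found: %s", path))
  spec <- table_schemas[[schema]]
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  required <- setdiff(names(spec$cols), spec$optional %||% character())
  check_columns(raw, required, sprintf("%s (schema '%s')", path, schema))
  if (!nrow(raw)) {
    out <- lapply(spec$cols, function(type) vector(
      switch(type, integer = "integer", double = "double",
             logical = "logical", "character"), 0L))
    return(as_tibble(out)[intersect(names(spec$cols), c(names(raw), required))])
  }
  out <- raw
  for (col in intersect(names(spec$cols), names(raw))) {
    type <- spec$cols[[col]]
    if (type == "character") next
    parsed <- switch(type,
      integer = suppressWarnings(as.integer(raw[[col]])),
      double = suppressWarnings(as.numeric(raw[[col]])),
      logical = suppressWarnings(as.logical(raw[[col]]))
    )
    bad <- which(!is.na(raw[[col]]) & raw[[col]] != "" & is.na(parsed))
    if (length(bad)) {
      abort(
        sprintf("%s: column `%s` fails %s conversion at row(s) %s.",
                path, col, type, paste(utils::head(bad, 5L), collapse = ", ")),
        class = "pharmera_parse_error"
      )
    }
    out[[col]] <- parsed
  }
  if (schema == "mec" && !"detected" %in% names(out)) {
    out$detected <- !is.na(out$value_ugL)
  }
  out
}

#' Run the full tiered assessment from a configuration
#'
#' Orchestrates the assessment in the conventional order: exposure (initial
#' and refined PECs from the use table) -> effect thresholds (aquatic, STP and
#' antibiotic-resistance PNECs) -> risk quotients -> measured-concentration
#' statistics -> secondary poisoning -> PBT screen. Outputs are deterministic
#' for a fixed configuration and are written as `pec.csv`, `pnec.json`,
#' `risk.csv`, `mec_summary.json`, `ade_audit.json` and `summary.md` under
#' `out_dir`.
#'
#' @param config a named list, or path to a YAML/JSON file containing one,
#'   with elements:
#' \describe{
#'   \item{profile}{a [substance_profile()], or a path to a profile JSON.}
#'   \item{use_table}{data frame or CSV path (schema `"use"`).}
#'   \item{endpoints}{data frame or CSV path (schema `"endpoint"`).}
#'   \item{ec10_sludge_ugL}{sludge EC10 for the STP PNEC (optional).}
#'   \item{mics}{data frame or CSV path (schema `"mic"`; optional).}
#'   \item{mecs}{data frame or CSV path (schema `"mec"`; optional).}
#'   \item{scenario}{list of [exposure_scenario()] fields (optional).}
#'   \item{ade_chains}{list of [ade_derivation()] objects (optional).}
#'   \item{intake}{list with `water_concentration_ugL` and optionally
#'     `mec_water_concentration_ugL` for the mixed measured/predicted human
#'     scenario (optional).}
#' }
#' @param out_dir output directory, created if needed; `NULL` writes nothing.
#' @return a list of the computed pieces (`pec`, `pec_summary`, `pnec`,
#'   `risk`, `mec`, `ade`, `secondary_poisoning`, `pbt`), invisibly when
#'   `out_dir` is set.
#' @export
run_era <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  stopifnot(is.list(config))
  profile <- config$profile
  if (is.character(profile)) profile <- read_substance_profile(profile)
  if (!inherits(profile, "substance_profile")) {
    stop_invalid("`config$profile` must be a substance profile or a path to one.")
  }
  load_tbl <- function(x, schema) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) read_table(x, schema) else as_tibble(x)
  }
  use_table <- load_tbl(config$use_table, "use")
  endpoints <- load_tbl(config$endpoints, "endpoint")
  mics <- load_tbl(config$mics, "mic")
  mecs <- load_tbl(config$mecs, "mec")
  if (!is.null(mecs) && !nrow(mecs)) {
    stop_no_data("the MEC table is empty; remove it from the config or supply data.")
  }
  scen_args <- config$scenario %||% list()
  scenario <- do.call(exposure_scenario, scen_args)

  out <- list()

  if (!is.null(use_table)) {
    if (!nrow(use_table)) stop_no_data("the use table is empty.")
    pec <- derive_pec(use_table, profile$molecular_weight,
                      profile$prodrug_molecular_weight, scenario)
    out$pec <- pec
    out$pec_summary <- weighted_summary(pec)
  }

  pnecs <- list()
  if (!is.null(endpoints)) {
    pnecs$aquatic_noec <- tryCatch(pnec_aquatic(endpoints, "NOEC"),
                                   pharmera_no_data = function(e) NULL)
    pnecs$aquatic_ec10 <- tryCatch(pnec_aquatic(endpoints, "EC10"),
                                   pharmera_no_data = function(e) NULL)
  }
  if (!is.null(config$ec10_sludge_ugL)) {
    pnecs$stp <- pnec_stp(config$ec10_sludge_ugL)
  }
  if (!is.null(mics) && nrow(mics)) {
    pnecs$abr <- pnec_abr(mics)
  }
  pnecs <- pnecs[!vapply(pnecs, is.null, logical(1))]
  out$pnec <- pnecs

  if (length(pnecs)) {
    risk_rows <- list()
    expo <- list()
    if (!is.null(out$pec)) {
      expo$highest_refined_sw_pec <- max(out$pec$sw_pec_ugL)
      expo$weighted_median_sw_pec <- out$pec_summary$weighted_median
      expo$highest_refined_stp_pec <- max(out$pec$stp_pec_ugL)
    }
    for (nm in names(expo)) {
      for (pn in names(pnecs)) {
        target_stp <- pn %in% c("stp", "abr")
        is_stp_exposure <- grepl("stp", nm)
        if (target_stp != is_stp_exposure && pn != "abr") next
        risk_rows[[paste(nm, pn, sep = "_vs_")]] <-
          risk_quotient(expo[[nm]], pnecs[[pn]],
                        label = paste(nm, "vs", pn))
      }
    }
    out$risk <- bind_rows(risk_rows)
  }

  if (!is.null(mecs)) {
    ranked <- percent_rank_mecs(mecs)
    out$mec <- list(
      ranked = ranked,
      mean_half_loq = censored_mean(mecs),
      exceedance = lapply(pnecs[names(pnecs) %in% c("aquatic_noec", "aquatic_ec10")],
                          function(p) exceedance_summary(mecs, p))
    )
  }

  if (!is.null(config$ade_chains)) {
    cand <- bind_rows(
      derive_ade(config$ade_chains[[1]], "down_1sf"),
      if (length(config$ade_chains) > 1) {
        bind_rows(lapply(config$ade_chains[-1], derive_ade, rounding = "two_decimals"))
      }
    )
    selected <- select_ade(cand)
    ade_active_mg_d <- if (!is.null(profile$prodrug_molecular_weight)) {
      prodrug_to_active(selected$ade_mg_d, profile$molecular_weight,
                        profile$prodrug_molecular_weight)
    } else {
      selected$ade_mg_d
    }
    out$ade <- list(candidates = cand, selected = selected,
                    ade_active_mg_d = ade_active_mg_d)

    if (!is.null(config$intake)) {
      cw <- config$intake$water_concentration_ugL
      bcf <- select_bcf(profile)$selected_bcf
      # daily intake limits are conventionally quoted to the nearest 5 ug
      ade_ug_d <- round(ade_active_mg_d * 200) / 200 * 1000
      mtdi <- mtdi_scale(ade_ug_d, 60, 10)
      otter <- intake_scenario("top_predator", water_concentration = cw, bcf = bcf)
      human_cw <- config$intake$mec_water_concentration_ugL %||% cw
      human <- intake_scenario(
        "human", water_concentration = human_cw,
        fish_tissue_conc = fish_tissue_concentration(cw, bcf)
      )
      out$secondary_poisoning <- bind_rows(
        mutate(secondary_poisoning_rq(daily_intake(otter), mtdi),
               consumer = "top_predator", .before = 1),
        mutate(secondary_poisoning_rq(daily_intake(human), ade_ug_d),
               consumer = "human", .before = 1)
      )
    }
  }

  out$pbt <- pbt_screen(profile, degradable = config$degradable %||% NA,
                        endpoints = endpoints)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(out$pec)) {
      readr::write_csv(out$pec, file.path(out_dir, "pec.csv"))
    }
    jsonlite::write_json(
      lapply(pnecs, function(p) as.list(tidy(p))),
      file.path(out_dir, "pnec.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    if (!is.null(out$risk)) {
      readr::write_csv(out$risk, file.path(out_dir, "risk.csv"))
    }
    if (!is.null(out$mec)) {
      jsonlite::write_json(
        list(
          n_total = out$mec$ranked$n_total,
          n_nondetect = out$mec$ranked$n_nondetect,
          mean_half_loq_ugL = out$mec$mean_half_loq,
          percentiles = out$mec$ranked$percentile_of
        ),
        file.path(out_dir, "mec_summary.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
      )
    }
    if (!is.null(out$ade)) {
      jsonlite::write_json(
        list(
          candidates = out$ade$candidates,
          selected = out$ade$selected,
          ade_active_mg_d = out$ade$ade_active_mg_d,
          chains = lapply(config$ade_chains, function(d) {
            list(point_of_departure = d$point_of_departure, pod_kind = d$pod_kind,
                 body_weight = d$body_weight, factors = d$factors, label = d$label)
          })
        ),
        file.path(out_dir, "ade_audit.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
      )
    }
    writeLines(era_summary_md(out, profile), file.path(out_dir, "summary.md"))
    return(invisible(out))
  }
  out
}

read_run_config <- function(path) {
  if (!file.exists(path)) stop_invalid(sprintf("config file not found: %s", path))
  if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

era_summary_md <- function(out, profile) {
  lines <- c(
    sprintf("# Tiered environmental risk assessment: %s", profile$name),
    ""
  )
  if (!is.null(out$pec_summary)) {
    s <- out$pec_summary
    lines <- c(lines,
      "## Exposure",
      sprintf(
        "- refined surface-water PECs: weighted mean %.3g, weighted median %.3g, range %.3g-%.3g ug/L (n = %d countries)",
        s$weighted_mean, s$weighted_median, s$min, s$max, s$n
      ),
      ""
    )
  }
  if (length(out$pnec)) {
    lines <- c(lines, "## Effect thresholds",
      vapply(out$pnec, function(p) {
        sprintf("- %s: %.4g ug/L", p$method, p$value)
      }, character(1)),
      ""
    )
  }
  if (!is.null(out$risk)) {
    lines <- c(lines, "## Risk quotients",
      sprintf("- %s: %.3g (%s)", out$risk$label, signif(out$risk$quotient, 3),
              out$risk$verdict),
      ""
    )
  }
  if (!is.null(out$secondary_poisoning)) {
    sp <- out$secondary_poisoning
    lines <- c(lines, "## Secondary poisoning",
      sprintf("- %s: intake %.3g ug/d vs limit %.3g ug/d, RQ %.3g (%s)",
              sp$consumer, sp$intake_ug_d, sp$limit_ug_d,
              signif(sp$quotient, 3), sp$verdict),
      ""
    )
  }
  if (!is.null(out$pbt)) {
    lines <- c(lines, "## PBT screen",
      sprintf("- %s: %s (%s)", out$pbt$criterion, out$pbt$verdict, out$pbt$rationale))
  }
  lines
}
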