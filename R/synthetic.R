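#' Seeded generator: country-by-year pharmaceutical sales table
#'
#' Emulates a proprietary country-by-year API sales panel. Per-capita daily use
#' is drawn lognormally per country-year (so the implied sold mass scales with
#' population), populations are drawn log-uniformly from a stated range, and a
#' configurable fraction of the active-moiety mass is sold as prodrug. Every
#' draw is fixed by `seed`.
#'
#' @param n_countries number of countries.
#' @param years integer vector of years.
#' @param use_log_mean,use_log_sd meanlog/sdlog of the per-capita daily use
#'   distribution (ug/person/day); defaults centre on ~300 ug/person/day.
#' @param pop_range population range (log-uniform draw).
#' @param prodrug_fraction fraction of active-moiety mass sold as prodrug.
#' @param mw_active,mw_prodrug molecular weights used to convert the prodrug
#'   share back to sold prodrug mass.
#' @param seed integer seed.
#' @return tibble with columns `country`, `year`, `mpa_kg`, `mpm_kg`,
#'   `population`.
#' @export
gen_use_table <- function(n_countries = 24, years = 2004:2017,
                          use_log_mean = log(300), use_log_sd = 0.6,
                          pop_range = c(5e5, 8e7),
                          prodrug_fraction = 0.9,
                          mw_active = 320.34, mw_prodrug = 433.5,
                          seed = 1) {
  stopifnot(n_countries >= 1, length(years) >= 1)
  check_fraction(prodrug_fraction, "prodrug_fraction")
  if (use_log_sd < 0) stop_invalid("`use_log_sd` must be >= 0.")
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  countries <- sprintf("C%02d", seq_len(n_countries))
  pop <- exp(runif(n_countries, log(pop_range[1]), log(pop_range[2])))
  grid <- tidyr::expand_grid(country = countries, year = as.integer(years))
  grid$population <- rep(round(pop), each = length(years))
  use <- stats::rlnorm(nrow(grid), use_log_mean, use_log_sd) # ug/person/d
  total_kg <- use * grid$population * 365 / 1e9
  active_share_kg <- total_kg * (1 - prodrug_fraction)
  prodrug_kg <- total_kg * prodrug_fraction * mw_prodrug / mw_active
  grid |>
    mutate(mpa_kg = active_share_kg, mpm_kg = prodrug_kg) |>
    select("country", "year", "mpa_kg", "mpm_kg", "population")
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Seeded generator: censored surface-water concentration dataset
#'
#' Draws lognormal concentrations and censors every value below the LOQ as a
#' nondetect. The lognormal location is placed so that the expected detection
#' fraction equals `detection_fraction`:
#' `meanlog = log(loq) - qnorm(1 - detection_fraction) * sdlog`.
#'
#' @param n number of measurements.
#' @param loq limit of quantitation, ug/L.
#' @param detection_fraction expected fraction of detects, in (0, 1\].
#' @param sdlog lognormal sdlog of the concentration distribution.
#' @param matrix sample matrix label.
#' @param seed integer seed.
#' @return censored MEC tibble (`value_ugL`, `loq_ugL`, `detected`, `matrix`,
#'   `site`, `source`).
#' @export
gen_mec_dataset <- function(n = 110, loq = 0.001, detection_fraction = 0.55,
                            sdlog = 1.5, matrix = "surface_water", seed = 1) {
  stopifnot(n >= 1)
  check_number(loq, "loq", positive = TRUE)
  if (detection_fraction <= 0 || detection_fraction > 1) {
    stop_invalid("`detection_fraction` must be in (0, 1].")
  }
  if (sdlog < 0) stop_invalid("`sdlog` must be >= 0.")
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  meanlog <- log(loq) - stats::qnorm(1 - detection_fraction) * sdlog
  conc <- stats::rlnorm(n, meanlog, sdlog)
  detected <- conc >= loq
  tibble(
    value_ugL = ifelse(detected, conc, NA_real_),
    loq_ugL = loq,
    detected = detected,
    matrix = matrix,
    site = sprintf("site_%03d", seq_len(n)),
    source = "synthetic"
  )
}

#' Seeded generator: cumulative mineralization curve
#'
#' First-order-to-plateau curve `plateau * (1 - exp(-k t))` sampled at the
#' given times, optionally with additive Gaussian noise, for parameter-recovery
#' testing of [fit_first_order()].
#'
#' @param k first-order rate constant, 1/h.
#' @param plateau plateau mineralization, percent.
#' @param times_h sampling times in hours (default days 1,2,4,7,14,28).
#' @param noise_sd additive Gaussian noise standard deviation (percent
#'   points), >= 0.
#' @param relative_noise if `TRUE`, `noise_sd` is a relative (fractional)
#'   noise level applied to each curve value.
#' @param seed integer seed.
#' @return tibble with `time_h`, `percent` (clipped to \[0, 110\]).
#' @export
gen_mineralization_curve <- function(k = 0.0174, plateau = 82.2,
                                     times_h = c(1, 2, 4, 7, 14, 28) * 24,
                                     noise_sd = 0, relative_noise = FALSE,
                                     seed = 1) {
  check_number(k, "k", nonneg = TRUE)
  check_number(plateau, "plateau", positive = TRUE)
  if (noise_sd < 0) stop_invalid("`noise_sd` must be >= 0.")
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  mu <- plateau * (1 - exp(-k * times_h))
  eps <- if (noise_sd > 0) {
    if (relative_noise) rnorm(length(mu), 0, noise_sd) * mu else rnorm(length(mu), 0, noise_sd)
  } else {
    0
  }
  tibble(time_h = times_h, percent = pmin(pmax(mu + eps, 0), 110))
}

#' Seeded generator: tree-shaped river network with STP nodes
#'
#' Grows a random forest of river segments (each new segment attaches
#' downstream of a uniformly chosen earlier segment, or starts a new headwater
#' with probability `1 - branching`), draws per-segment flows log-uniformly
#' with `flow_min <= flow_mean <= flow_max`, and places STPs on distinct
#' random segments.
#'
#' @param n_segments number of river segments.
#' @param n_stps number of STP nodes (must be <= `n_segments`).
#' @param branching probability a new segment attaches to the existing tree
#'   (0 gives a single chain from a single root).
#' @param flow_range range of mean flows, m3/s (log-uniform draw).
#' @param flow_cv spread factor: `flow_min = flow_mean / (1 + cv)`,
#'   `flow_max = flow_mean * (1 + cv)` with per-segment jitter.
#' @param population_range STP population range (log-uniform draw).
#' @param per_capita_use_ug_d per-capita daily use discharged, ug/person/day.
#' @param removal STP removal fraction applied at every STP.
#' @param seed integer seed.
#' @return a validated [river_network()].
#' @export
gen_network <- function(n_segments = 50, n_stps = 10, branching = 0.7,
                        flow_range = c(0.5, 200), flow_cv = 1.5,
                        population_range = c(1e4, 2e6),
                        per_capita_use_ug_d = 300, removal = 0.12,
                        seed = 1) {
  stopifnot(n_segments >= 1, n_stps >= 0, n_stps <= n_segments)
  check_fraction(branching, "branching")
  check_fraction(removal, "removal")
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  # grow from the outlet upstream: segment 1 is the outlet; each later segment
  # drains into an earlier one (tree), or becomes a new outlet (forest)
  downstream <- rep(NA_integer_, n_segments)
  for (i in seq_len(n_segments)[-1]) {
    if (runif(1) < branching || branching == 0) {
      downstream[i] <- if (branching == 0) i - 1L else sample.int(i - 1L, 1L)
    }
  }
  flow_mean <- exp(runif(n_segments, log(flow_range[1]), log(flow_range[2])))
  spread_lo <- 1 + flow_cv * runif(n_segments)
  spread_hi <- 1 + flow_cv * runif(n_segments)
  segments <- tibble(
    id = seq_len(n_segments),
    downstream_id = downstream,
    flow_mean_m3s = flow_mean,
    flow_min_m3s = flow_mean / spread_lo,
    flow_max_m3s = flow_mean * spread_hi,
    travel_time_h = runif(n_segments, 1, 48)
  )
  stps <- if (n_stps > 0) {
    tibble(
      segment_id = sample(segments$id, n_stps),
      population = round(exp(runif(n_stps, log(population_range[1]),
                                   log(population_range[2])))),
      per_capita_use_ug_d = per_capita_use_ug_d,
      wastewater_per_capita_L_d = 200,
      removal = removal
    )
  } else {
    tibble(
      segment_id = integer(), population = numeric(),
      per_capita_use_ug_d = numeric(), wastewater_per_capita_L_d = numeric(),
      removal = numeric()
    )
  }
  river_network(segments, stps)
}
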