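use_row <- function(mpa = 0, mpm = 0, pop = 1e7) {
  tibble::tibble(country = "XX", year = 2017L, mpa_kg = mpa, mpm_kg = mpm,
                 population = pop)
}

test_that("per-capita daily use converts kg/yr to ug/person/day", {
  expect_equal(
    per_capita_daily_use(use_row(mpa = 1000), 320.34, 433.5)$use_ug_person_day,
    1e12 / (1e7 * 365), # 273.97
    tolerance = 1e-10
  )
  expect_equal(per_capita_daily_use(use_row(), 320.34, 433.5)$use_ug_person_day, 0)
  # prodrug-only sales are converted stoichiometrically
  expect_equal(
    per_capita_daily_use(use_row(mpm = 1000), 320.34, 433.5)$use_ug_person_day,
    (1e12 / (1e7 * 365)) * 320.34 / 433.5, # 202.45
    tolerance = 1e-10
  )
  expect_error(
    per_capita_daily_use(use_row(pop = 0), 320.34, 433.5),
    class = "pharmera_invalid_parameter"
  )
})

test_that("STP and surface-water PECs follow the screening arithmetic", {
  expect_equal(pec_stp(598, 200), 2.99)
  expect_equal(pec_stp(0, 200), 0)
  expect_equal(pec_stp(200, 200), 1)
  expect_error(pec_stp(10, 0), class = "pharmera_invalid_parameter")

  # default scenario: all treated, no removal, dilution 10
  expect_equal(pec_surface(2.99, exposure_scenario()), 0.299)
  # complete removal of a fully treated stream
  full <- exposure_scenario(treated_fraction = 1, stp_removal = 1, dilution_factor = 3)
  expect_equal(pec_surface(123, full), 0)
  # refined scenario back-solved from the published removal-scenario pair
  sc <- exposure_scenario(treated_fraction = 0.8, stp_removal = 0.436,
                          dilution_factor = 15.0)
  expect_equal(pec_surface(8.83, sc), 0.383, tolerance = 0.001 / 0.383)
})

test_that("surface PEC is monotone in removal and dilution, linear in input", {
  set.seed(21)
  for (i in 1:25) {
    stp <- runif(1, 0.1, 10)
    ft <- runif(1)
    r1 <- runif(1); r2 <- runif(1)
    d1 <- runif(1, 1, 50); d2 <- d1 * runif(1, 1, 4)
    lo_r <- min(r1, r2); hi_r <- max(r1, r2)
    expect_gte(
      pec_surface(stp, exposure_scenario(200, ft, lo_r, d1)),
      pec_surface(stp, exposure_scenario(200, ft, hi_r, d1))
    )
    expect_gte(
      pec_surface(stp, exposure_scenario(200, ft, r1, d1)),
      pec_surface(stp, exposure_scenario(200, ft, r1, d2))
    )
    expect_equal(
      pec_surface(2 * stp, exposure_scenario(200, ft, r1, d1)),
      2 * pec_surface(stp, exposure_scenario(200, ft, r1, d1))
    )
  }
})

test_that("removal-scenario PEC ratios are independent of dilution", {
  # the scaling identity behind published removal-scenario triplets
  set.seed(31)
  for (i in 1:20) {
    stp <- runif(1, 0.5, 10)
    ft <- runif(1)
    r1 <- runif(1); r2 <- runif(1)
    dA <- runif(1, 1, 40); dB <- runif(1, 1, 40)
    ratio <- function(d) {
      pec_surface(stp, exposure_scenario(200, ft, r2, d)) /
        pec_surface(stp, exposure_scenario(200, ft, r1, d))
    }
    expected <- (ft * (1 - r2) + 1 - ft) / (ft * (1 - r1) + 1 - ft)
    expect_equal(ratio(dA), expected, tolerance = 1e-12)
    expect_equal(ratio(dB), expected, tolerance = 1e-12)
  }
})

test_that("weighted summary uses population weights and the lower weighted median", {
  tbl <- tibble::tibble(sw_pec_ugL = c(1, 3), population = c(1, 1))
  expect_equal(weighted_summary(tbl)$weighted_mean, 2)
  dom <- tibble::tibble(sw_pec_ugL = c(1, 100), population = c(99, 1))
  expect_equal(weighted_summary(dom)$weighted_median, 1)
  mix <- tibble::tibble(sw_pec_ugL = c(0.1, 0.2, 0.4), population = c(2, 1, 1))
  expect_equal(weighted_summary(mix)$weighted_mean, 0.2)
  expect_error(
    weighted_summary(tibble::tibble(sw_pec_ugL = numeric(), population = numeric())),
    class = "pharmera_no_data"
  )
})

test_that("derive_pec keeps each country's highest-use year and honours per-row scenarios", {
  tbl <- tibble::tibble(
    country = c("A", "A", "B"),
    year = c(2016L, 2017L, 2017L),
    mpa_kg = c(100, 500, 200),
    mpm_kg = 0,
    population = c(1e6, 1e6, 2e6),
    dilution_factor = c(10, 10, 2)
  )
  pec <- derive_pec(tbl, 320.34, 433.5,
                    scenario = exposure_scenario(treated_fraction = 0.8,
                                                 stp_removal = 0.12))
  expect_equal(nrow(pec), 2)
  expect_equal(pec$year[pec$country == "A"], 2017L)
  # per-row dilution column overrides the scenario default
  b <- pec[pec$country == "B", ]
  expect_equal(b$sw_pec_ugL, b$stp_pec_ugL * (0.8 * 0.88 + 0.2) / 2)
})
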