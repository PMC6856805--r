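test_that("aquatic PNEC is the lowest endpoint of the requested kind over the AF", {
  noec <- pnec_aquatic(fx$endpoints, "NOEC")
  expect_equal(noec$value, 0.132)
  expect_equal(noec$basis$taxon_group, "fish")
  ec10 <- pnec_aquatic(fx$endpoints, "EC10")
  expect_equal(ec10$value, 0.58)
  expect_equal(ec10$basis$taxon_group, "fish")
  single <- tibble::tibble(taxon_group = "fish", endpoint_kind = "NOEC", value_ugL = 10)
  expect_equal(pnec_aquatic(single, "NOEC", assessment_factor = 1)$value, 10)
  expect_error(pnec_aquatic(single, "EC10"), class = "pharmera_no_data")
})

test_that("AF-based PNECs scale inversely with the factor and never exceed the basis", {
  set.seed(51)
  for (i in 1:15) {
    n <- sample(2:6, 1)
    ep <- tibble::tibble(
      taxon_group = sample(c("fish", "daphnid", "green_alga", "cyanobacterium"),
                           n, replace = TRUE),
      endpoint_kind = "NOEC",
      value_ugL = stats::rlnorm(n, 2, 1.5)
    )
    af <- runif(1, 1, 100)
    p <- pnec_aquatic(ep, "NOEC", assessment_factor = af)
    expect_equal(p$value, min(ep$value_ugL) / af)
    expect_lte(p$value, min(ep$value_ugL))
    expect_equal(pnec_aquatic(ep, "NOEC", assessment_factor = 2 * af)$value,
                 p$value / 2)
  }
})

test_that("STP PNEC divides the sludge EC10 by the assessment factor", {
  expect_equal(pnec_stp(69000)$value, 6900)
  expect_equal(pnec_stp(100, assessment_factor = 1)$value, 100)
  expect_equal(pnec_stp(100)$value, 10)
  expect_error(pnec_stp(0), class = "pharmera_invalid_parameter")
})

test_that("lowest-MIC resistance PNEC converts mg/L to ug/L over the factor", {
  expect_equal(pnec_abr_lowest_mic(fx$mics)$value, 312.5)
  one <- tibble::tibble(species = "X", mic_mgL = 100)
  expect_equal(pnec_abr_lowest_mic(one)$value, 1000)
  two <- tibble::tibble(species = c("X", "Y"), mic_mgL = c(50, 500))
  expect_equal(pnec_abr_lowest_mic(two)$value, 500)
  expect_error(pnec_abr_lowest_mic(tibble::tibble(species = character(),
                                                  mic_mgL = numeric())),
               class = "pharmera_no_data")
})

test_that("distribution-based resistance PNEC filters species, scales and rounds down", {
  res <- pnec_abr_percentile(fx$mics)
  expect_equal(res$raw_value, 31250 * (1 / 41) / 10, tolerance = 1e-12) # 76.2
  expect_equal(res$value, 64)
  expect_equal(res$n_species, 1) # only the 12-observation species is eligible
  expect_lte(res$value, res$raw_value)
  expect_gt(res$value, 0)

  # nine observations are not enough for eligibility
  nine <- tibble::tibble(species = "X", mic_mgL = rep(31.25, 9))
  expect_error(pnec_abr_percentile(nine), class = "pharmera_no_data")
  expect_error(pnec_abr_percentile(nine), "10")

  # two eligible species: lowest MIC 41 mg/L, n = 2 -> raw 200 ug/L
  two <- tibble::tibble(
    species = rep(c("X", "Y"), each = 10),
    mic_mgL = c(rep(41, 10), rep(100, 10))
  )
  expect_equal(pnec_abr_percentile(two)$raw_value, 41000 * 2 / 41 / 10)
})

test_that("round-down to the two-fold dilution series hits series members exactly", {
  expect_equal(pharmera:::round_down_mic_series(76.2), 64)
  expect_equal(pharmera:::round_down_mic_series(64), 64)
  expect_equal(pharmera:::round_down_mic_series(63.9), 32)
  expect_equal(pharmera:::round_down_mic_series(0.3), 0.25)
})

test_that("the final resistance PNEC is the lower of the two methods", {
  sel <- pnec_abr(fx$mics)
  expect_equal(sel$value, 64)
  expect_equal(sel$method, "abr_percentile")
  expect_equal(
    sel$value,
    min(pnec_abr_lowest_mic(fx$mics)$value, pnec_abr_percentile(fx$mics)$value)
  )
  # with no eligible species the lowest-MIC method stands alone
  sparse <- tibble::tibble(species = c("X", "Y"), mic_mgL = c(50, 80))
  expect_equal(pnec_abr(sparse)$method, "abr_lowest_mic")
})

test_that("PBT screen reproduces the worked verdict and its edge cases", {
  verdict <- pbt_screen(fx$profile, degradable = TRUE, endpoints = fx$endpoints)
  expect_equal(verdict$verdict, c("no", "no", "yes"))
  expect_true(all(nzchar(verdict$rationale)))

  high_bcf <- substance_profile("hypothetical", 300, bcf_by_ph = c("7" = 5000))
  expect_equal(pbt_screen(high_bcf, TRUE)$verdict[2], "yes")

  bare <- substance_profile("bare", 300)
  v <- pbt_screen(bare)
  expect_equal(v$verdict, c("undetermined", "undetermined", "undetermined"))
})
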