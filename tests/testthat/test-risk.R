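test_that("risk quotients divide exposure by threshold with the verdict boundary at 1", {
  rq <- risk_quotient(0.299, 0.58)
  expect_equal(rq$quotient, 0.516, tolerance = 1e-3)
  expect_equal(rq$verdict, "no_significant_risk")
  expect_equal(risk_quotient(8.83, 6900)$quotient, 0.00128, tolerance = 1e-3)
  # a quotient of exactly 1 is not potential risk
  boundary <- risk_quotient(0.58, 0.58)
  expect_equal(boundary$quotient, 1)
  expect_equal(boundary$verdict, "no_significant_risk")
  expect_equal(risk_quotient(0.59, 0.58)$verdict, "potential_risk")
  # linear in exposure
  expect_equal(risk_quotient(2 * 0.299, 0.58)$quotient, 2 * rq$quotient)
  expect_error(risk_quotient(1, 0), class = "pharmera_invalid_parameter")
})

test_that("exceedance summaries count values above the PNEC", {
  set.seed(71)
  pecs <- c(runif(105, 0, 0.1), runif(5, 0.2, 0.5))
  es <- exceedance_summary(pecs, 0.132)
  expect_equal(es$count_at_risk, 5)
  expect_equal(es$fraction_at_risk, 5 / 110)
  expect_equal(es$fraction_at_risk + es$fraction_safe, 1)
  expect_equal(exceedance_summary(c(0.01, 0.02), 0.132)$fraction_at_risk, 0)
  expect_equal(exceedance_summary(c(1, 2), 0.132)$fraction_at_risk, 1)
  # ranked censored distributions propagate indeterminate censoring
  rd <- percent_rank_mecs(mixed_mecs)
  expect_error(exceedance_summary(rd, 0.5),
               class = "pharmera_indeterminate_censoring")
  expect_equal(exceedance_summary(rd, 4.5)$count_at_risk, 2)
})

test_that("ADE derivations follow pod x bw / factors with named rounding policies", {
  a_ter <- derive_ade(fx$ade_chains$teratology, "two_decimals")
  expect_equal(a_ter$unrounded_mg_d, 2 * 60 / (6.2 * 10 * 1 * 10 * 1)) # 0.19355
  expect_equal(a_ter$ade_mg_d, 0.19)
  a_sys <- derive_ade(fx$ade_chains$systemic, "down_1sf")
  expect_equal(a_sys$unrounded_mg_d, 2 * 60 / (6.2 * 10 * 1 * 5 * 3), tolerance = 1e-12)
  expect_equal(a_sys$ade_mg_d, 0.1)
  flat <- ade_derivation(2, "NOAEL", 60, c(a = 1, b = 1))
  expect_equal(derive_ade(flat)$ade_mg_d, 120)
  expect_error(ade_derivation(2, "NOAEL", 60, tibble::tibble(value = numeric(),
                                                             rationale = character())),
               class = "pharmera_invalid_parameter")
  expect_error(ade_derivation(2, "NOAEL", 60, c(6.2, 10)),
               class = "pharmera_invalid_parameter")
})

test_that("unrounded ADE is invariant under factor reordering; selection takes the minimum", {
  f <- c(interspecies = 6.2, intraspecies = 10, duration = 1, severity = 5, pod = 3)
  base <- derive_ade(ade_derivation(2, "NOAEL", 60, f))$unrounded_mg_d
  set.seed(81)
  for (i in 1:5) {
    perm <- sample(length(f))
    expect_equal(derive_ade(ade_derivation(2, "NOAEL", 60, f[perm]))$unrounded_mg_d,
                 base)
  }
  cand <- dplyr::bind_rows(
    derive_ade(fx$ade_chains$systemic, "down_1sf"),
    derive_ade(fx$ade_chains$teratology, "two_decimals")
  )
  expect_equal(select_ade(cand)$ade_mg_d, 0.1)
})

test_that("MTDI body-weight scaling is linear", {
  expect_equal(mtdi_scale(75, 60, 10), 12.5)
  expect_equal(mtdi_scale(75, 60, 60), 75)
  expect_equal(mtdi_scale(75, 60, 30), 37.5)
})

test_that("fish tissue concentration and combined intake follow the worked chain", {
  expect_equal(fish_tissue_concentration(0.671, 6.22), 4.17, tolerance = 1e-3)
  expect_equal(fish_tissue_concentration(0, 6.22), 0)
  expect_equal(fish_tissue_concentration(1, 1), 1)

  otter <- intake_scenario("top_predator", water_concentration = 0.671, bcf = 6.22)
  expect_equal(otter$body_weight, 10)
  expect_equal(daily_intake(otter), 4.7, tolerance = 1e-2 / 4.7)

  human <- intake_scenario("human", water_concentration = 0.656,
                           fish_tissue_conc = fish_tissue_concentration(0.671, 6.22))
  expect_equal(daily_intake(human), 1.792, tolerance = 1e-3 / 1.792)

  nothing <- intake_scenario("human", water_concentration = 0,
                             fish_tissue_conc = 0)
  expect_equal(daily_intake(nothing), 0)
})

test_that("secondary-poisoning quotients reproduce the worked values", {
  expect_equal(secondary_poisoning_rq(4.7, 12.5)$quotient, 0.376)
  expect_equal(secondary_poisoning_rq(1.792, 75)$quotient, 0.024, tolerance = 1e-2)
  at_limit <- secondary_poisoning_rq(12.5, 12.5)
  expect_equal(at_limit$quotient, 1)
  expect_equal(at_limit$verdict, "no_significant_risk")
})

test_that("the full fixture chain reproduces every published step from constants alone", {
  profile <- fx$profile
  cand <- dplyr::bind_rows(
    derive_ade(fx$ade_chains$systemic, "down_1sf"),
    derive_ade(fx$ade_chains$teratology, "two_decimals")
  )
  sel <- select_ade(cand)
  ade_mpa_mg <- prodrug_to_active(sel$ade_mg_d, profile$molecular_weight,
                                  profile$prodrug_molecular_weight)
  expect_equal(ade_mpa_mg, 0.0739, tolerance = 1e-3)
  ade_ug <- round(ade_mpa_mg * 200) / 200 * 1000 # nearest 5 ug
  expect_equal(ade_ug, 75)
  mtdi <- mtdi_scale(ade_ug, 60, 10)
  expect_equal(mtdi, 12.5)
  bcf <- select_bcf(profile)$selected_bcf
  otter <- intake_scenario("top_predator",
                           water_concentration = fx$reference$highest_sw_pec_ugL,
                           bcf = bcf)
  expect_equal(daily_intake(otter), 4.7, tolerance = 1e-2 / 4.7)
  expect_equal(secondary_poisoning_rq(daily_intake(otter), mtdi)$quotient,
               0.376, tolerance = 1e-2 / 3.76)
  human <- intake_scenario("human",
                           water_concentration = fx$reference$highest_sw_mec_ugL,
                           fish_tissue_conc = fish_tissue_concentration(
                             fx$reference$highest_sw_pec_ugL, bcf))
  expect_equal(daily_intake(human), 1.792, tolerance = 1e-3 / 1.792)
  expect_equal(secondary_poisoning_rq(daily_intake(human), ade_ug)$quotient,
               0.024, tolerance = 1e-2)
})
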