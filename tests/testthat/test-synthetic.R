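test_that("generators are deterministic per seed and vary across seeds", {
  expect_identical(gen_use_table(seed = 4), gen_use_table(seed = 4))
  expect_false(identical(gen_use_table(seed = 4), gen_use_table(seed = 5)))
  expect_identical(gen_mec_dataset(seed = 4), gen_mec_dataset(seed = 4))
  expect_false(identical(gen_mec_dataset(seed = 4)$value_ugL,
                         gen_mec_dataset(seed = 5)$value_ugL))
  n1 <- gen_network(seed = 4)
  n2 <- gen_network(seed = 4)
  expect_identical(n1$segments, n2$segments)
  expect_identical(n1$stps, n2$stps)
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_mec_dataset(seed = 99))
  expect_identical(.Random.seed, before)
})

test_that("use table has the configured shape and satisfies exposure invariants", {
  tbl <- gen_use_table(n_countries = 24, years = 2004:2017, seed = 1)
  expect_equal(nrow(tbl), 24 * 14)
  expect_true(all(tbl$population > 0))
  expect_true(all(tbl$mpa_kg >= 0 & tbl$mpm_kg >= 0))
  # zero spread -> identical per-capita use everywhere
  flat <- gen_use_table(n_countries = 5, years = 2017, use_log_sd = 0, seed = 2)
  use <- per_capita_daily_use(flat, 320.34, 433.5)$use_ug_person_day
  expect_equal(max(use) - min(use), 0, tolerance = 1e-9)
  # law of large numbers: configured median use recovered within 5% at n large
  big <- gen_use_table(n_countries = 10, years = 1:100,
                       use_log_mean = log(300), use_log_sd = 0.6, seed = 3)
  med <- stats::median(per_capita_daily_use(big, 320.34, 433.5)$use_ug_person_day)
  expect_equal(med, 300, tolerance = 0.05)
})

test_that("MEC generator realises the detection fraction and type invariants", {
  m <- gen_mec_dataset(n = 110, detection_fraction = 0.55, seed = 7)
  expect_equal(nrow(m), 110)
  # binomial expectation ~50 nondetects, allow 3 sd
  expect_lt(abs(sum(!m$detected) - 110 * 0.45), 3 * sqrt(110 * 0.55 * 0.45))
  expect_true(all(is.na(m$value_ugL[!m$detected])))
  expect_true(all(m$value_ugL[m$detected] >= m$loq_ugL[m$detected]))
  expect_true(all(gen_mec_dataset(n = 50, detection_fraction = 1, seed = 8)$detected))
  # substituted mean is at least the detect share of the detect mean
  dm <- mean(m$value_ugL[m$detected])
  expect_gte(censored_mean(m), dm * sum(m$detected) / nrow(m))
  expect_error(gen_mec_dataset(detection_fraction = 0), class = "pharmera_invalid_parameter")
})

test_that("mineralization-curve generator is exact at zero noise and guards inputs", {
  c0 <- gen_mineralization_curve(k = 0.0174, plateau = 82.2, noise_sd = 0)
  expect_equal(c0$percent, 82.2 * (1 - exp(-0.0174 * c0$time_h)))
  expect_error(gen_mineralization_curve(noise_sd = -1),
               class = "pharmera_invalid_parameter")
})

test_that("generated networks validate and honour their structure options", {
  net <- gen_network(n_segments = 50, n_stps = 10, seed = 3)
  expect_s3_class(net, "river_network")
  expect_true(all(net$segments$flow_min_m3s <= net$segments$flow_mean_m3s))
  expect_true(all(net$segments$flow_mean_m3s <= net$segments$flow_max_m3s))
  # branching 0 -> one chain: ids 2..n drain to the previous id
  chain <- gen_network(n_segments = 10, n_stps = 2, branching = 0, seed = 4)
  expect_equal(chain$segments$downstream_id[-1], 1:9)
  expect_equal(sum(is.na(chain$segments$downstream_id)), 1)
})

test_that("the bundled fixture is positive, typed and drives the pipeline end to end", {
  expect_s3_class(fx$profile, "substance_profile")
  expect_true(all(fx$endpoints$value_ugL > 0))
  expect_true(all(fx$mics$mic_mgL > 0))
  expect_equal(nrow(fx$mics), 23)
  expect_equal(min(fx$mics$mic_mgL), 31.25)
  expect_equal(sum(fx$mics$species == "Staphylococcus aureus"), 12)
  expect_true(all(fx$stp_removals > 0 & fx$stp_removals < 1))
  # every generator output satisfies its consumer's validation
  expect_no_error(per_capita_daily_use(gen_use_table(seed = 1), 320.34, 433.5))
  expect_no_error(censored_samples(gen_mec_dataset(seed = 1)))
  expect_no_error(fit_first_order(gen_mineralization_curve(seed = 1)))
  expect_no_error(propagate(gen_network(seed = 1), "mean"))
})
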