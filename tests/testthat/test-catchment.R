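single_stp_net <- function(use = 86.4, removal = 0, flow = 1) {
  river_network(
    tibble::tibble(
      id = 1:2, downstream_id = c(NA, 1L),
      flow_mean_m3s = flow, flow_min_m3s = flow / 2, flow_max_m3s = flow * 2,
      travel_time_h = 10
    ),
    tibble::tibble(
      segment_id = 2L, population = 1e6, per_capita_use_ug_d = use,
      wastewater_per_capita_L_d = 200, removal = removal
    )
  )
}

test_that("a single STP load over a 1 m3/s flow gives the hand-computed PEC", {
  # 1e6 p x 86.4 ug/p/d = 8.64e7 ug/d over 8.64e7 L/d = 1 ug/L
  field <- propagate(single_stp_net(), "mean")
  expect_equal(field$pec_ugL[field$id == 2], 1.0)
  # downstream segment carries the same load in the same flow
  expect_equal(field$pec_ugL[field$id == 1], 1.0)
})

test_that("zero decay conserves mass: outlet load equals total discharged load", {
  for (seed in 1:4) {
    net <- gen_network(n_segments = 40, n_stps = 8, branching = 1, seed = seed)
    field <- propagate(net, "mean", decay_rate = 0)
    discharged <- sum(net$stps$population * net$stps$per_capita_use_ug_d *
                        (1 - net$stps$removal))
    outlets <- field$id[is.na(field$downstream_id)]
    expect_equal(sum(field$load_ug_d[field$id %in% outlets]), discharged)
  }
})

test_that("confluent branch loads add; complete removal zeroes the field", {
  net <- river_network(
    tibble::tibble(
      id = 1:3, downstream_id = c(NA, 1L, 1L),
      flow_mean_m3s = c(2, 1, 1), flow_min_m3s = 0.5, flow_max_m3s = 4,
      travel_time_h = 5
    ),
    tibble::tibble(
      segment_id = c(2L, 3L), population = c(1e5, 3e5),
      per_capita_use_ug_d = 100, wastewater_per_capita_L_d = 200, removal = 0
    )
  )
  field <- propagate(net, "mean")
  expect_equal(field$load_ug_d[field$id == 1],
               sum(field$load_ug_d[field$id %in% 2:3]))

  all_removed <- river_network(net$segments,
                               dplyr::mutate(net$stps, removal = 1))
  expect_true(all(propagate(all_removed, "mean")$pec_ugL == 0))
})

test_that("segments with no STP upstream have exactly zero PEC", {
  net <- gen_network(n_segments = 60, n_stps = 5, seed = 9)
  field <- propagate(net, "mean")
  has_stp <- net$segments$id %in% net$stps$segment_id
  # walk each zero segment: no STP may sit on it or upstream of it
  down <- setNames(net$segments$downstream_id, net$segments$id)
  reaches <- function(from) { # ids reachable downstream from `from`, inclusive
    path <- from
    while (!is.na(down[[as.character(from)]])) {
      from <- down[[as.character(from)]]
      path <- c(path, from)
    }
    path
  }
  touched <- unique(unlist(lapply(net$stps$segment_id, reaches)))
  expect_true(all(field$pec_ugL[!field$id %in% touched] == 0))
  expect_true(all(field$pec_ugL[field$id %in% net$stps$segment_id] > 0))
})

test_that("PEC field scales linearly with use and is monotone across flow scenarios", {
  net1 <- gen_network(n_segments = 30, n_stps = 6, per_capita_use_ug_d = 100, seed = 3)
  net2 <- gen_network(n_segments = 30, n_stps = 6, per_capita_use_ug_d = 300, seed = 3)
  f1 <- propagate(net1, "mean")
  f2 <- propagate(net2, "mean")
  expect_equal(f2$pec_ugL, 3 * f1$pec_ugL)

  f_low <- propagate(net1, "low")
  f_high <- propagate(net1, "high")
  expect_true(all(f_low$pec_ugL >= f1$pec_ugL))
  expect_true(all(f1$pec_ugL >= f_high$pec_ugL))
})

test_that("first-order in-stream decay attenuates downstream loads", {
  field0 <- propagate(single_stp_net(), "mean", decay_rate = 0)
  field1 <- propagate(single_stp_net(), "mean", decay_rate = 0.05)
  expect_equal(field1$load_ug_d[field1$id == 2], field0$load_ug_d[field0$id == 2])
  expect_equal(
    field1$load_ug_d[field1$id == 1],
    field0$load_ug_d[field0$id == 1] * exp(-0.05 * 10)
  )
})

test_that("cyclic topologies are rejected", {
  segs <- tibble::tibble(
    id = 1:2, downstream_id = c(2L, 1L),
    flow_mean_m3s = 1, flow_min_m3s = 1, flow_max_m3s = 1, travel_time_h = 1
  )
  stps <- tibble::tibble(segment_id = 1L, population = 10,
                         per_capita_use_ug_d = 1,
                         wastewater_per_capita_L_d = 200, removal = 0)
  expect_error(river_network(segs, stps), class = "pharmera_invalid_network")
  self <- dplyr::mutate(segs, downstream_id = c(1L, NA))
  expect_error(river_network(self, stps), class = "pharmera_invalid_network")
})

test_that("field percentiles use nearest rank, include zeros and apply the floor", {
  pp <- pec_percentiles(c(0, 0, 1, 2), percentiles = c(50, 99))
  expect_true(pp$below_floor[pp$percentile == 50])
  expect_true(is.na(pp$pec_ugL[pp$percentile == 50]))
  expect_equal(pp$pec_ugL[pp$percentile == 99], 2)

  all_zero <- pec_percentiles(rep(0, 10))
  expect_true(all(all_zero$below_floor))

  # percentile curves are non-decreasing, and low flow dominates mean flow
  net <- gen_network(n_segments = 50, n_stps = 10, seed = 13)
  p_mean <- pec_percentiles(propagate(net, "mean"), percentiles = c(25, 50, 75, 90, 99))
  p_low <- pec_percentiles(propagate(net, "low"), percentiles = c(25, 50, 75, 90, 99))
  vals <- function(p) ifelse(p$below_floor, 0, p$pec_ugL)
  expect_true(all(diff(vals(p_mean)) >= 0))
  expect_true(all(vals(p_low) >= vals(p_mean)))
})
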