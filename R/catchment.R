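#' Assemble and validate a river network
#'
#' A simplified river-catchment representation for distributional PEC
#' simulation: river segments form a forest draining to one or more outlets
#' (`downstream_id = NA`), each segment carries mean/low/high flows and a
#' travel time, and sewage-treatment plants (STPs) discharge into named
#' segments with a connected population, per-capita use, and removal fraction.
#' This is an emulation of georeferenced catchment exposure models for testing
#' distributional risk summaries; it is not a hydrological model.
#'
#' @param segments data frame with columns `id`, `downstream_id` (`NA` for an
#'   outlet), `flow_mean_m3s`, `flow_min_m3s`, `flow_max_m3s` (> 0, with
#'   `flow_min <= flow_mean <= flow_max`), `travel_time_h` (>= 0).
#' @param stps data frame with columns `segment_id`, `population` (> 0),
#'   `per_capita_use_ug_d`, `wastewater_per_capita_L_d`, `removal` (in
#'   \[0, 1\]); may have zero rows.
#' @return an object of class `river_network`.
#' @seealso [propagate()], [gen_network()]
#' @export
river_network <- function(segments, stps) {
  check_columns(segments,
                c("id", "downstream_id", "flow_mean_m3s", "flow_min_m3s",
                  "flow_max_m3s", "travel_time_h"),
                "segment table")
  check_columns(stps,
                c("segment_id", "population", "per_capita_use_ug_d",
                  "wastewater_per_capita_L_d", "removal"),
                "STP table")
  segments <- as_tibble(segments)
  stps <- as_tibble(stps)
  if (anyDuplicated(segments$id)) stop_invalid("segment ids must be unique.")
  flows <- c(segments$flow_mean_m3s, segments$flow_min_m3s, segments$flow_max_m3s)
  if (any(flows <= 0, na.rm = TRUE) || anyNA(flows)) {
    stop_invalid("all segment flows must be strictly positive.")
  }
  if (any(segments$flow_min_m3s > segments$flow_mean_m3s |
          segments$flow_mean_m3s > segments$flow_max_m3s)) {
    stop_invalid("each segment needs flow_min <= flow_mean <= flow_max.")
  }
  if (any(segments$travel_time_h < 0)) stop_invalid("travel times must be >= 0.")
  down <- segments$downstream_id
  bad_down <- !is.na(down) & !(down %in% segments$id)
  if (any(bad_down)) {
    stop_invalid("some downstream_id values reference unknown segments.")
  }
  if (any(!is.na(down) & down == segments$id)) {
    abort("self-referencing segment (id == downstream_id): cyclic topology.",
          class = "pharmera_invalid_network")
  }
  if (nrow(stps) && !all(stps$segment_id %in% segments$id)) {
    stop_invalid("some STPs discharge into unknown segments.")
  }
  if (nrow(stps)) {
    if (any(stps$population <= 0)) stop_invalid("STP populations must be > 0.")
    if (any(stps$removal < 0 | stps$removal > 1)) {
      stop_invalid("STP removal fractions must lie in [0, 1].")
    }
  }
  # each segment has at most one downstream edge, so acyclicity == DAG check
  edges <- segments |> filter(!is.na(.data$downstream_id))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges$id), to = as.character(edges$downstream_id)),
    directed = TRUE,
    vertices = data.frame(name = as.character(segments$id))
  )
  if (!igraph::is_dag(g)) {
    abort("river network contains a cycle; topology must be a forest draining to outlets.",
          class = "pharmera_invalid_network")
  }
  structure(list(segments = segments, stps = stps, graph = g),
            class = "river_network")
}

#' @export
print.river_network <- function(x, ...) {
  cat(sprintf(
    "<river_network> %d segments (%d outlets), %d STPs\n",
    nrow(x$segments), sum(is.na(x$segments$downstream_id)), nrow(x$stps)
  ))
  invisible(x)
}

#' Propagate STP loads through a river network
#'
#' Mass-balance pass in topological (upstream-to-downstream) order. Each
#' segment's load is the sum of its upstream loads, each attenuated by
#' first-order decay over the upstream segment's travel time, plus the local
#' STP load `population * per_capita_use * (1 - removal)`. The segment PEC is
#' `load / flow` under the chosen flow scenario; effluent volume is neglected
#' relative to river flow (the dilution-factor convention). Segments with no
#' STP anywhere upstream have PEC exactly zero.
#'
#' @param network a [river_network()].
#' @param flow_scenario `"mean"`, `"low"` or `"high"`.
#' @param decay_rate first-order in-stream decay rate (1/h), >= 0; default 0
#'   (conservative transport).
#' @return a tibble of class `segment_pec_field` with one row per segment:
#'   `id`, `load_ug_d`, `flow_m3s`, `pec_ugL`, plus attributes `flow_scenario`
#'   and `decay_rate`.
#' @examples
#' net <- gen_network(n_segments = 20, n_stps = 4, seed = 1)
#' propagate(net, "mean")
#' @export
propagate <- function(network, flow_scenario = c("mean", "low", "high"),
                      decay_rate = 0) {
  stopifnot(inherits(network, "river_network"))
  flow_scenario <- match.arg(flow_scenario)
  check_number(decay_rate, "decay_rate", nonneg = TRUE)
  seg <- network$segments
  flow_col <- switch(flow_scenario,
    mean = "flow_mean_m3s", low = "flow_min_m3s", high = "flow_max_m3s"
  )
  order_ids <- names(igraph::topo_sort(network$graph, mode = "out"))
  idx <- match(order_ids, as.character(seg$id))

  local_load <- setNames(numeric(nrow(seg)), as.character(seg$id))
  if (nrow(network$stps)) {
    by_seg <- network$stps |>
      group_by(.data$segment_id) |>
      summarise(load = sum(.data$population * .data$per_capita_use_ug_d *
                             (1 - .data$removal)))
    local_load[as.character(by_seg$segment_id)] <- by_seg$load
  }

  load <- local_load
  down <- setNames(as.character(seg$downstream_id), as.character(seg$id))
  travel <- setNames(seg$travel_time_h, as.character(seg$id))
  for (id in as.character(seg$id)[idx]) {
    d <- down[[id]]
    if (!is.na(d)) {
      load[[d]] <- load[[d]] + load[[id]] * exp(-decay_rate * travel[[id]])
    }
  }

  flow_Ld <- seg[[flow_col]] * 86400 * 1000 # m3/s -> L/d
  out <- seg |>
    mutate(
      load_ug_d = unname(load[as.character(.data$id)]),
      flow_m3s = .data[[flow_col]],
      pec_ugL = .data$load_ug_d / flow_Ld
    ) |>
    select("id", "downstream_id", "load_ug_d", "flow_m3s", "pec_ugL")
  attr(out, "flow_scenario") <- flow_scenario
  attr(out, "decay_rate") <- decay_rate
  class(out) <- c("segment_pec_field", class(out))
  out
}

#' Percentiles of a per-segment PEC field
#'
#' Nearest-rank percentiles over all segments, zeros included (headwater
#' stretches upstream of the uppermost STP legitimately carry zero predicted
#' concentration). Values below the reporting floor are flagged rather than
#' printed, mirroring how distributional PEC figures cut off at a fraction of
#' the analytical LOQ.
#'
#' @param field a `segment_pec_field` from [propagate()], or a numeric vector
#'   of PECs.
#' @param percentiles percentiles in percent, default `c(1, 25, 50, 75, 90, 99)`.
#' @param floor reporting floor in ug/L (default 0.0005, half a typical LOQ).
#' @return tibble with `percentile`, `pec_ugL`, `below_floor` (when
#'   `below_floor` is `TRUE`, `pec_ugL` is `NA` and the value is reported only
#'   as "< floor").
#' @export
pec_percentiles <- function(field, percentiles = c(1, 25, 50, 75, 90, 99),
                            floor = 0.0005) {
  x <- if (is.numeric(field)) field else field$pec_ugL
  if (!length(x)) stop_no_data("empty PEC field.")
  check_number(floor, "floor", nonneg = TRUE)
  xs <- sort(x)
  n <- length(xs)
  idx <- pmin(pmax(ceiling(percentiles * n / 100), 1L), n)
  val <- xs[idx]
  below <- val < floor
  tibble(
    percentile = percentiles,
    pec_ugL = ifelse(below, NA_real_, val),
    below_floor = below
  )
}
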