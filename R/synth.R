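# Synthetic fixtures: patient location sets and usage logs with the
# statistical structure of real service logs, so the whole pipeline is
# testable without any external dataset.

#' Parameters of the synthetic-data generator
#'
#' Patients per request follow a log-normal capped at the 300-location upload
#' limit, tuned to a median of about 17 and mean of about 30 (the two moments
#' the service's real usage exhibits); requested cluster sizes follow a
#' discrete bell over 3..25 with its mode at 10. Patient locations are drawn
#' from a Gaussian mixture around a handful of UK town centres. Request
#' timestamps follow a mixture of five campaign waves, echoing the dose and
#' booster waves of a vaccination campaign. A configurable fraction of
#' requests are re-emissions of an earlier patient set within the repeat
#' window, emulating users experimenting with parameters.
#'
#' @param seed Integer master seed.
#' @param n_requests Number of requests to simulate.
#' @param size_meanlog,size_sdlog Log-normal parameters of patients per
#'   request (defaults give median 17, mean 30 before capping).
#' @param max_patients Upload cap, default 300.
#' @param cluster_size_mode,cluster_size_sd Centre and width of the discrete
#'   cluster-size distribution over 3..25.
#' @param repeat_fraction Fraction of requests injected as within-window
#'   repeats of an earlier request.
#' @param co_location_prob Probability that a patient duplicates a previous
#'   patient's exact address within the same request.
#' @param town_centres `data.frame` with `lat`, `lon`, `weight`.
#' @param spread_km Gaussian spread of patients around their town centre.
#' @param campaign_waves `data.frame` with `peak` (Date) and `width_days`.
#' @param walk_fraction Fraction of requests in walking mode.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(seed = 1L,
                         n_requests = 200L,
                         size_meanlog = log(17),
                         size_sdlog = sqrt(2 * log(30 / 17)),
                         max_patients = 300L,
                         cluster_size_mode = 10,
                         cluster_size_sd = 4,
                         repeat_fraction = 0.1,
                         co_location_prob = 0.05,
                         town_centres = NULL,
                         spread_km = 5,
                         campaign_waves = NULL,
                         walk_fraction = 0.2) {
  if (is.null(town_centres)) {
    town_centres <- data.frame(
      name = c("London", "Birmingham", "Manchester", "Leeds", "Cardiff",
               "Newcastle", "Norwich", "Plymouth"),
      lat = c(51.51, 52.48, 53.48, 53.80, 51.48, 54.98, 52.63, 50.38),
      lon = c(-0.13, -1.90, -2.24, -1.55, -3.18, -1.61, 1.30, -4.14),
      weight = c(4, 2, 2, 1.5, 1, 1, 0.8, 0.7)
    )
  }
  if (is.null(campaign_waves)) {
    campaign_waves <- data.frame(
      peak = as.Date(c("2021-02-01", "2021-04-15", "2021-11-01",
                       "2022-05-01", "2022-10-01")),
      width_days = c(20, 20, 25, 25, 25)
    )
  }
  structure(list(
    seed = check_count(seed, "seed", lower = 0L),
    n_requests = check_count(n_requests, "n_requests"),
    size_meanlog = check_number(size_meanlog, "size_meanlog"),
    size_sdlog = check_number(size_sdlog, "size_sdlog", lower = 0),
    max_patients = check_count(max_patients, "max_patients"),
    cluster_size_mode = check_number(cluster_size_mode, "cluster_size_mode",
                                     lower = 3, upper = 25),
    cluster_size_sd = check_number(cluster_size_sd, "cluster_size_sd", lower = 0),
    repeat_fraction = check_number(repeat_fraction, "repeat_fraction", 0, 1),
    co_location_prob = check_number(co_location_prob, "co_location_prob", 0, 1),
    town_centres = town_centres,
    spread_km = check_number(spread_km, "spread_km", lower = 0),
    campaign_waves = campaign_waves,
    walk_fraction = check_number(walk_fraction, "walk_fraction", 0, 1)
  ), class = "synth_params")
}

#' Sample request sizes (patients per request)
#'
#' @param n Number of draws.
#' @param params A [synth_params()].
#' @param seed Integer seed.
#' @return Integer vector in `[1, max_patients]`.
#' @export
sample_request_sizes <- function(n, params = synth_params(), seed = params$seed) {
  withr::with_seed(seed, {
    raw <- stats::rlnorm(n, params$size_meanlog, params$size_sdlog)
    pmin(pmax(1L, as.integer(round(raw))), params$max_patients)
  })
}

sample_cluster_sizes <- function(n, params) {
  support <- 3:25
  w <- stats::dnorm(support, params$cluster_size_mode, params$cluster_size_sd)
  sample(support, n, replace = TRUE, prob = w)
}

sample_timestamps <- function(n, params) {
  wave <- sample.int(nrow(params$campaign_waves), n, replace = TRUE)
  day <- round(stats::rnorm(n, 0, params$campaign_waves$width_days[wave]))
  date <- params$campaign_waves$peak[wave] + day
  secs <- round(stats::runif(n, 8 * 3600, 18 * 3600))  # working hours
  as.POSIXct(as.numeric(as.POSIXct(date, tz = "UTC")) + secs,
             tz = "UTC", origin = "1970-01-01")
}

#' Generate a synthetic patient location set
#'
#' Draws `n` home locations from a weighted Gaussian mixture around the
#' configured town centres; with probability `co_location_prob` a patient
#' duplicates a previously drawn address exactly (several patients in one
#' household). All points are clamped to the UK bounding box.
#'
#' @param n Number of patients, in `[1, max_patients]`.
#' @param params A [synth_params()].
#' @param seed Integer seed; the output is deterministic given it.
#' @return A [geo_points()] table with `n` rows.
#' @export
generate_patient_set <- function(n, params = synth_params(), seed = params$seed) {
  n <- check_count(n, "n")
  if (n > params$max_patients)
    stop_validation("n must be in [1, %d]", params$max_patients)
  withr::with_seed(seed, {
    town <- sample.int(nrow(params$town_centres), 1L,
                       prob = params$town_centres$weight)
    base_lat <- params$town_centres$lat[town]
    base_lon <- params$town_centres$lon[town]
    sd_lat <- params$spread_km / 111
    sd_lon <- params$spread_km / (111 * cos(base_lat * pi / 180))
    lat <- stats::rnorm(n, base_lat, sd_lat)
    lon <- stats::rnorm(n, base_lon, sd_lon)
    dup <- stats::runif(n) < params$co_location_prob
    for (i in seq_len(n)[-1]) {
      if (dup[i]) {
        j <- sample.int(i - 1L, 1L)
        lat[i] <- lat[j]; lon[i] <- lon[j]
      }
    }
    if (n == 1L) dup[1L] <- FALSE
    geo_points(
      pmin(pmax(lat, UK_BBOX$lat_min), UK_BBOX$lat_max),
      pmin(pmax(lon, UK_BBOX$lon_min), UK_BBOX$lon_max)
    )
  })
}

#' Generate a synthetic usage log
#'
#' For each simulated request: sample a patient count, cluster size, mode and
#' campaign-wave timestamp; generate patients; run the planner (fixed-size
#' clustering plus open-route optimisation) to obtain cluster labels and
#' visit orders; and store the coordinates in centroid-anonymised relative
#' form. A configured fraction of extra requests re-emit an earlier patient
#' set 1--20 days later, as injected within-window repeats.
#'
#' @param params A [synth_params()].
#' @param path Optional CSV path; when given the log is also written via
#'   [write_usage_log()].
#' @param n_restarts,max_iter,exact_threshold Planner effort used when
#'   generating labels and orders (lighter than interactive defaults).
#' @return A list of [usage_record()] objects, sorted by timestamp, with
#'   attribute `repeat_truth`: the logical ground-truth repeat flag per
#'   record.
#' @export
generate_usage_log <- function(params = synth_params(), path = NULL,
                               n_restarts = 1L, max_iter = 20L,
                               exact_threshold = 8L) {
  n_req <- params$n_requests
  sizes <- sample_request_sizes(n_req, params, seed = params$seed)
  draws <- withr::with_seed(params$seed + 1L, list(
    D = sample_cluster_sizes(n_req, params),
    mode = ifelse(stats::runif(n_req) < params$walk_fraction, "walk", "drive"),
    ts = sample_timestamps(n_req, params)
  ))
  records <- vector("list", n_req)
  for (i in seq_len(n_req)) {
    pts <- generate_patient_set(sizes[i], params, seed = params$seed + 13L * i)
    records[[i]] <- plan_to_usage_record(
      pts, draws$D[i], draws$mode[i], draws$ts[i],
      seed = params$seed + 17L * i, n_restarts = n_restarts,
      max_iter = max_iter, exact_threshold = exact_threshold)
  }
  truth <- rep(FALSE, n_req)
  n_rep <- round(params$repeat_fraction * n_req)
  if (n_rep > 0L) {
    rep_draws <- withr::with_seed(params$seed + 2L, list(
      src = sample.int(n_req, n_rep, replace = TRUE),
      delay = stats::runif(n_rep, 1, 20)
    ))
    for (k in seq_len(n_rep)) {
      src <- records[[rep_draws$src[k]]]
      dup <- src
      dup$timestamp <- src$timestamp + rep_draws$delay[k] * 86400
      records[[n_req + k]] <- dup
      truth[n_req + k] <- TRUE
    }
  }
  ts <- do.call(c, lapply(records, `[[`, "timestamp"))
  ord <- order(ts)
  records <- records[ord]
  truth <- truth[ord]
  attr(records, "repeat_truth") <- truth
  if (!is.null(path)) write_usage_log(records, path)
  records
}

# Run the planner on a patient set and package the result as a usage record
# with centroid-anonymised coordinates.
plan_to_usage_record <- function(pts, D, mode, timestamp, seed,
                                 n_restarts = 1L, max_iter = 20L,
                                 exact_threshold = 8L) {
  cp <- cluster_params(D = D, seed = seed, max_iter = max_iter,
                       n_restarts = n_restarts)
  plan <- plan_routes(pts, cp, mode = if (mode == "walk") "walk" else "drive",
                      exact_threshold = exact_threshold)
  rel <- cbind(pts$lat - mean(pts$lat), pts$lon - mean(pts$lon))
  usage_record(
    timestamp = timestamp, n_patients = nrow(pts), cluster_size = D,
    mode = mode, rel_coords = rel, labels = plan$assignment$labels,
    orders = lapply(plan$routes, `[[`, "order")
  )
}

#' Generate a deterministic synthetic geocoder table
#'
#' Maps each distinct postcode to a stable pseudo-random UK point via the
#' synthetic geocoder; duplicates collapse to one row.
#'
#' @param postcodes Character vector of postcode text.
#' @param seed Integer seed for the underlying hash.
#' @param path Optional CSV path (`postcode,lat,lon`).
#' @return A `data.frame` with columns `postcode`, `lat`, `lon`.
#' @export
generate_geocoder_table <- function(postcodes, seed = 0L, path = NULL) {
  norm <- unique(normalize_postcode(postcodes)$normalized)
  pts <- geocoder_synthetic(seed)(norm)
  tab <- data.frame(postcode = norm, lat = pts$lat, lon = pts$lon)
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  tab
}
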