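# Usage-log analysis: estimates the planning-time, driving-distance and cost
# savings produced by automated route planning, from anonymised request logs.
#
# Each logged request keeps only relative patient coordinates (shifted so the
# centroid sits at the origin), the clustering, the visit orders and request
# metadata. The analysis (i) removes repeat requests -- the same patient set
# re-uploaded within a short window, interpreted as user experimentation;
# (ii) reconstructs route lengths by translating the offsets to the UK
# mid-point, projecting to Web Mercator and summing legs along the recorded
# orders; (iii) models manual planning time as a per-location lookup cost
# plus a per-location routing cost, less a per-request upload penalty; and
# (iv) models the extra distance of human-planned routes with a saturating
# exponential penalty p(n) = A (1 - exp(-n/B)).

#' Parameters of the savings analysis
#'
#' Defaults are the model constants of the analysis: survey-derived manual
#' planning coefficients (36.4 s/location lookup, 4.8 s/location routing,
#' less a 30 s upload penalty per request), a 21-day repeat window, a detour
#' index of 1.4, a 50 km/h mean driving speed and a 40 h work week. The cost
#' conversion uses a configurable blend of annual salaries divided by working
#' hours per year.
#'
#' @param lookup_s_per_loc Manual map-lookup time, seconds per location.
#' @param routing_s_per_loc Manual route-planning time, seconds per location.
#' @param upload_penalty_s Time to upload and parameterise one request, s.
#' @param repeat_window_days Repeat-detection window, days.
#' @param detour_index Road-to-straight-line distance ratio.
#' @param speed_kmh Mean driving speed for distance-to-time conversion.
#' @param workweek_h Hours per working week.
#' @param uk_shift Degrees (lat, lon) added to relative coordinates before
#'   projection; the approximate UK mid-point.
#' @param salary_rates Named annual salaries (GBP) blended into an hourly
#'   rate for the cost estimate.
#' @param work_hours_per_year Divisor converting annual salary to an hourly
#'   rate; default 52 weeks x 40 h.
#' @param repeat_tol Rounding (degrees) applied to relative coordinates when
#'   comparing patient sets for repeat detection.
#' @return An object of class `savings_params`.
#' @export
savings_params <- function(lookup_s_per_loc = 36.4,
                           routing_s_per_loc = 4.8,
                           upload_penalty_s = 30,
                           repeat_window_days = 21,
                           detour_index = 1.4,
                           speed_kmh = 50,
                           workweek_h = 40,
                           uk_shift = c(53, -1.2),
                           salary_rates = c(practice_manager = 38000,
                                            community_nurse = 32000),
                           work_hours_per_year = 52 * 40,
                           repeat_tol = 1e-6) {
  fields <- list(
    lookup_s_per_loc = lookup_s_per_loc, routing_s_per_loc = routing_s_per_loc,
    upload_penalty_s = upload_penalty_s, repeat_window_days = repeat_window_days,
    detour_index = detour_index, speed_kmh = speed_kmh, workweek_h = workweek_h,
    uk_shift = uk_shift, salary_rates = salary_rates,
    work_hours_per_year = work_hours_per_year, repeat_tol = repeat_tol)
  for (nm in setdiff(names(fields), c("uk_shift", "salary_rates")))
    check_number(fields[[nm]], nm, lower = 0)
  if (length(uk_shift) != 2L) stop_validation("'uk_shift' must be length 2")
  structure(fields, class = "savings_params")
}

#' Saturating model of human route-planning performance
#'
#' Human tours are near-optimal for small problems and degrade with size;
#' the fractional excess length over the optimal route is modelled as
#' `p(n) = A * (1 - exp(-n / B))`: zero at n = 0, monotone increasing, and
#' saturating at the asymptote A.
#'
#' The shipped defaults (A = 0.15, B = 70) are a calibration chosen so that
#' the penalty stays below 5% for routes of up to 25 locations and below 10%
#' up to about 60 locations, matching the published behaviour of human
#' solvers; they are a configuration, not fitted constants.
#'
#' @param A Asymptotic penalty fraction, > 0.
#' @param B Scale in locations, > 0.
#' @return An object of class `penalty_model`.
#' @seealso [human_penalty()], [fit_penalty_model()]
#' @export
penalty_model <- function(A = 0.15, B = 70) {
  check_number(A, "A"); check_number(B, "B")
  if (A <= 0 || B <= 0) stop_validation("A and B must be positive")
  structure(list(A = A, B = B), class = "penalty_model")
}

#' Evaluate the human-performance penalty
#'
#' @param n Problem sizes (number of locations), >= 0.
#' @param model A [penalty_model()].
#' @return Fractional excess length of a human solution, `A*(1 - exp(-n/B))`.
#' @examples
#' human_penalty(25, penalty_model(A = 0.1, B = 50))
#' @export
human_penalty <- function(n, model = penalty_model()) {
  if (any(!is.finite(n)) || any(n < 0))
    stop_validation("'n' must be non-negative")
  model$A * (1 - exp(-n / model$B))
}

#' Fit the penalty model to observed (size, penalty) pairs
#'
#' Positivity-constrained nonlinear least squares of
#' `p ~ A * (1 - exp(-n/B))` via Levenberg-Marquardt.
#'
#' @param n Problem sizes, >= 0.
#' @param p Observed fractional penalties, >= 0.
#' @return A [penalty_model()] with attribute `residual_norm`.
#' @export
fit_penalty_model <- function(n, p) {
  if (length(n) != length(p)) stop_validation("'n' and 'p' must match in length")
  if (length(n) < 3L) stop_validation("need at least 3 observations")
  if (any(n < 0) || any(p < 0)) stop_validation("observations must be non-negative")
  if (length(unique(n)) < 2L)
    stop_validation("degenerate data: all problem sizes are equal")
  df <- data.frame(n = n, p = p)
  start <- list(A = max(max(p), 1e-3), B = max(stats::median(n), 1))
  fit <- tryCatch(
    minpack.lm::nlsLM(p ~ A * (1 - exp(-n / B)), data = df, start = start,
                      lower = c(A = 1e-9, B = 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop_validation("penalty fit failed: %s",
                                        conditionMessage(e))
  )
  co <- stats::coef(fit)
  out <- penalty_model(A = co[["A"]], B = co[["B"]])
  attr(out, "residual_norm") <- sqrt(sum(stats::resid(fit)^2))
  out
}

#' Construct a validated usage record
#'
#' One historical planning request: the unit of the savings analysis.
#'
#' @param timestamp A `POSIXct` scalar.
#' @param n_patients Number of uploaded locations.
#' @param cluster_size Requested cluster size D.
#' @param mode `"drive"` or `"walk"`.
#' @param rel_coords n x 2 matrix of (lat, lon) offsets in degrees, centroid
#'   at the origin (anonymised).
#' @param labels Cluster label per patient, in `1:G` with
#'   `G = ceiling(n / D)`.
#' @param orders List of G integer vectors: the visit order of each cluster
#'   as global patient indices; together a permutation of `1:n` partitioned
#'   by `labels`.
#' @param districts Optional named integer vector of postal-district counts.
#' @return An object of class `usage_record`.
#' @export
usage_record <- function(timestamp, n_patients, cluster_size, mode,
                         rel_coords, labels, orders, districts = NULL) {
  n_patients <- check_count(n_patients, "n_patients")
  cluster_size <- check_count(cluster_size, "cluster_size")
  if (!inherits(timestamp, "POSIXct") || length(timestamp) != 1L)
    stop_validation("'timestamp' must be a POSIXct scalar")
  if (!mode %in% c("drive", "walk"))
    stop_validation("'mode' must be 'drive' or 'walk'")
  rel_coords <- as.matrix(rel_coords)
  if (nrow(rel_coords) != n_patients || ncol(rel_coords) != 2L)
    stop_validation("'rel_coords' must be an n_patients x 2 matrix")
  G <- as.integer(ceiling(n_patients / cluster_size))
  labels <- as.integer(labels)
  if (length(labels) != n_patients || any(labels < 1L) || any(labels > G))
    stop_validation("cluster labels must lie in 1..G = 1..%d", G)
  if (!is.list(orders) || length(orders) != G)
    stop_validation("'orders' must be a list of G = %d visit orders", G)
  for (g in seq_len(G)) {
    members <- which(labels == g)
    if (!setequal(orders[[g]], members) ||
        length(orders[[g]]) != length(members))
      stop_validation("visit order of cluster %d is not a permutation of its members", g)
  }
  structure(list(
    timestamp = timestamp, n_patients = n_patients,
    cluster_size = cluster_size, mode = mode, rel_coords = rel_coords,
    labels = labels, orders = lapply(orders, as.integer),
    districts = districts
  ), class = "usage_record")
}

# --- usage-log CSV serialisation -------------------------------------------
# One row per request. Coordinate lists and orders are delimited sub-fields:
#   rel_coords    "lat:lon;lat:lon;..."     degrees, full precision
#   cluster_labels "0;1;0;..."              0-based on disk
#   visit_orders  "0,2,1|3,4"               clusters split by '|', 0-based
#   districts     "OX1:3;CB2:1"             optional, may be empty
USAGE_LOG_COLUMNS <- c("timestamp", "n_patients", "cluster_size", "mode",
                       "rel_coords", "cluster_labels", "visit_orders",
                       "districts")

fmt_num <- function(x) formatC(x, format = "g", digits = 12)

#' Write usage records to a log CSV
#'
#' @param records A list of [usage_record()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_usage_log <- function(records, path) {
  rows <- lapply(records, function(r) {
    data.frame(
      timestamp = format(r$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
      n_patients = r$n_patients,
      cluster_size = r$cluster_size,
      mode = r$mode,
      rel_coords = paste(paste(fmt_num(r$rel_coords[, 1]),
                               fmt_num(r$rel_coords[, 2]), sep = ":"),
                         collapse = ";"),
      cluster_labels = paste(r$labels - 1L, collapse = ";"),
      visit_orders = paste(vapply(r$orders, function(o)
        paste(o - 1L, collapse = ","), character(1)), collapse = "|"),
      districts = if (is.null(r$districts)) "" else
        paste(names(r$districts), r$districts, sep = ":", collapse = ";")
    )
  })
  if (length(rows)) {
    df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(USAGE_LOG_COLUMNS)), USAGE_LOG_COLUMNS))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Parse a usage-log CSV
#'
#' Validates every row; malformed rows are reported with their line numbers
#' (line 1 is the header) and abort the parse.
#'
#' @param path Path to a CSV with the documented usage-log schema.
#' @return A list of [usage_record()] objects (empty, with a warning, for a
#'   log with no data rows).
#' @export
parse_usage_log <- function(path) {
  if (!file.exists(path)) stop_io("usage log not found: %s", path)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop_format("cannot parse usage log: %s",
                                    conditionMessage(e)))
  if (!all(USAGE_LOG_COLUMNS[1:7] %in% names(df)))
    stop_format("usage log must have columns: %s",
                paste(USAGE_LOG_COLUMNS[1:7], collapse = ", "))
  if (nrow(df) == 0L) {
    warning("usage log has no data rows")
    return(list())
  }
  records <- vector("list", nrow(df))
  problems <- character(0)
  for (i in seq_len(nrow(df))) {
    rec <- tryCatch(parse_usage_row(df[i, ]), error = function(e)
      conditionMessage(e))
    if (is.character(rec)) {
      problems <- c(problems, sprintf("line %d: %s", i + 1L, rec))
    } else {
      records[[i]] <- rec
    }
  }
  if (length(problems))
    stop_format("malformed usage log rows:\n%s",
                paste(problems, collapse = "\n"))
  records
}

parse_usage_row <- function(row) {
  ts <- as.POSIXct(row$timestamp, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (is.na(ts)) stop("unparseable timestamp ", sQuote(row$timestamp))
  n <- suppressWarnings(as.integer(row$n_patients))
  D <- suppressWarnings(as.integer(row$cluster_size))
  if (is.na(n) || is.na(D)) stop("non-integer n_patients / cluster_size")
  coords <- strsplit(row$rel_coords, ";", fixed = TRUE)[[1]]
  parts <- strsplit(coords, ":", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("malformed rel_coords field")
  rel <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                ncol = 2, byrow = TRUE)
  if (any(!is.finite(rel))) stop("non-numeric rel_coords")
  labels0 <- suppressWarnings(
    as.integer(strsplit(row$cluster_labels, ";", fixed = TRUE)[[1]]))
  if (any(is.na(labels0))) stop("non-integer cluster labels")
  G <- as.integer(ceiling(n / D))
  if (any(labels0 < 0L) || any(labels0 >= G))
    stop(sprintf("cluster label outside [0, %d)", G))
  orders0 <- lapply(strsplit(row$visit_orders, "|", fixed = TRUE)[[1]],
                    function(s) suppressWarnings(
                      as.integer(strsplit(s, ",", fixed = TRUE)[[1]])))
  if (any(vapply(orders0, anyNA, logical(1)))) stop("non-integer visit order")
  districts <- NULL
  if (!is.null(row$districts) && !is.na(row$districts) && nzchar(row$districts)) {
    dparts <- strsplit(strsplit(row$districts, ";", fixed = TRUE)[[1]],
                       ":", fixed = TRUE)
    districts <- stats::setNames(
      vapply(dparts, function(x) as.integer(x[2]), integer(1)),
      vapply(dparts, `[`, character(1), 1))
  }
  usage_record(ts, n, D, row$mode, rel, labels0 + 1L,
               lapply(orders0, function(o) o + 1L), districts)
}

#' Flag repeat requests
#'
#' A request is a repeat when an earlier request with an identical patient
#' set (the multiset of relative coordinates, rounded to `tol` degrees)
#' exists strictly less than `window_days` earlier. Re-uploads inside the
#' window are interpreted as user experimentation; identical uploads farther
#' apart are kept as genuine repeat visits.
#'
#' @param records List of [usage_record()] objects.
#' @param window_days Window in days, default 21.
#' @param tol Coordinate rounding used for set identity, degrees.
#' @return Logical vector parallel to `records`.
#' @export
detect_repeats <- function(records, window_days = 21, tol = 1e-6) {
  if (!length(records)) return(logical(0))
  digits <- max(0L, round(-log10(tol)))
  sig <- vapply(records, function(r) {
    paste(sort(paste(round(r$rel_coords[, 1], digits),
                     round(r$rel_coords[, 2], digits), sep = ":")),
          collapse = ";")
  }, character(1))
  times <- as.numeric(do.call(c, lapply(records, `[[`, "timestamp")))
  flags <- logical(length(records))
  for (group in split(seq_along(records), sig)) {
    if (length(group) < 2L) next
    group <- group[order(times[group])]
    gaps <- diff(times[group]) / 86400
    flags[group[-1L]] <- gaps < window_days
  }
  flags
}

#' Reconstruct the total closed route length of a request
#'
#' Relative coordinates are translated onto the UK mid-point, projected to
#' Web Mercator, and pairwise plane distances computed. For each cluster the
#' legs along its recorded visit order are summed together with the closing
#' leg back to the first patient; a single-patient cluster contributes zero.
#' The total over clusters is inflated by the detour index.
#'
#' Note the projected-plane distances carry the Mercator scale inflation at
#' UK latitudes (about 1.66x at 53 N); this is deliberate, reproducing the
#' reconstruction procedure exactly. Pass `distance = "haversine"` for
#' great-circle distances instead (not the reference procedure).
#'
#' @param record A [usage_record()].
#' @param params A [savings_params()].
#' @param distance `"mercator"` (reference) or `"haversine"`.
#' @return Detour-adjusted total closed route length, metres.
#' @export
reconstruct_route_length <- function(record, params = savings_params(),
                                     distance = c("mercator", "haversine")) {
  distance <- match.arg(distance)
  pts <- recenter_relative(record$rel_coords, shift = params$uk_shift)
  dmat <- if (distance == "mercator") {
    pairwise_distances(project_web_mercator(pts))
  } else {
    haversine_distances(pts)
  }
  total <- 0
  for (ord in record$orders) {
    if (length(ord) < 2L) next
    total <- total + route_length(dmat, c(ord, ord[1L]))
  }
  total * params$detour_index
}

#' Manual planning time for one request of n locations
#'
#' @param n Number of locations.
#' @param params A [savings_params()].
#' @return A list with `lookup_s`, `routing_s` and `total_s` (their sum);
#'   e.g. a 5-site route costs 182 s of lookup and 24 s of routing, 206 s.
#' @export
manual_planning_time <- function(n, params = savings_params()) {
  check_number(n, "n", lower = 0)
  lookup <- n * params$lookup_s_per_loc
  routing <- n * params$routing_s_per_loc
  list(lookup_s = lookup, routing_s = routing, total_s = lookup + routing)
}

#' Total planning-time savings over a usage log
#'
#' Sums the manual lookup and routing time for every request (repeats
#' included: users are assumed to have had reasonable cause for them), less
#' the upload penalty per request.
#'
#' @param records List of [usage_record()] objects.
#' @param params A [savings_params()].
#' @return Net savings in seconds.
#' @seealso [planning_time_from_totals()] for the closed-form equivalent.
#' @export
planning_time_savings <- function(records, params = savings_params()) {
  if (!length(records)) return(0)
  n <- vapply(records, `[[`, numeric(1), "n_patients")
  planning_time_from_totals(sum(n), length(records), params)
}

#' Planning-time savings from aggregate totals
#'
#' Closed form of [planning_time_savings()]:
#' `patients * (lookup + routing) - requests * upload_penalty` seconds.
#'
#' @param n_patients Total locations across all requests.
#' @param n_requests Number of requests.
#' @param params A [savings_params()].
#' @return Net savings in seconds.
#' @export
planning_time_from_totals <- function(n_patients, n_requests,
                                      params = savings_params()) {
  n_patients * (params$lookup_s_per_loc + params$routing_s_per_loc) -
    n_requests * params$upload_penalty_s
}

#' Driving-distance and driving-time savings over a usage log
#'
#' For each (non-repeat) request the human route is modelled as
#' `(1 + p(n))` times the reconstructed route length, so the distance saved
#' is `L * p(n)`; time savings follow at the assumed mean driving speed.
#'
#' @param records List of [usage_record()] objects (pass the non-repeat
#'   subset; repeats were likely never driven).
#' @param model A [penalty_model()].
#' @param params A [savings_params()].
#' @return A list with `distance_m`, `time_s`, and per-record vectors
#'   `route_length_m` and `saved_m`.
#' @export
driving_savings <- function(records, model = penalty_model(),
                            params = savings_params()) {
  if (!length(records))
    return(list(distance_m = 0, time_s = 0,
                route_length_m = numeric(0), saved_m = numeric(0)))
  lvm <- vapply(records, reconstruct_route_length, numeric(1), params = params)
  n <- vapply(records, `[[`, numeric(1), "n_patients")
  saved <- lvm * human_penalty(n, model)
  list(distance_m = sum(saved),
       time_s = sum(saved) / (params$speed_kmh / 3.6),
       route_length_m = lvm, saved_m = saved)
}

#' Aggregate savings report
#'
#' Combines planning-time savings (computed over the full log, repeats
#' included) and driving savings (over the non-repeat subset) into total
#' practitioner hours, work weeks and an approximate cost, using an hourly
#' rate blended from the configured annual salaries.
#'
#' @param records List of [usage_record()] objects.
#' @param model A [penalty_model()].
#' @param params A [savings_params()].
#' @return An object of class `savings_report`.
#' @export
aggregate_report <- function(records, model = penalty_model(),
                             params = savings_params()) {
  repeats <- detect_repeats(records, params$repeat_window_days,
                            params$repeat_tol)
  kept <- records[!repeats]
  n_all <- vapply(records, `[[`, numeric(1), "n_patients")
  planning_s <- planning_time_savings(records, params)
  driving <- driving_savings(kept, model, params)
  planning_h <- planning_s / 3600
  driving_h <- driving$time_s / 3600
  total_h <- planning_h + driving_h
  hourly <- mean(params$salary_rates) / params$work_hours_per_year
  structure(list(
    n_requests = length(records),
    n_patients = sum(n_all),
    n_repeats = sum(repeats),
    n_requests_excl_repeats = length(kept),
    n_patients_excl_repeats = sum(n_all[!repeats]),
    planning_hours = planning_h,
    distance_saved_km = driving$distance_m / 1000,
    driving_hours = driving_h,
    total_hours = total_h,
    total_weeks = total_h / params$workweek_h,
    cost_estimate = total_h * hourly,
    repeat_flags = repeats,
    model = model,
    params = params
  ), class = "savings_report")
}

#' @export
print.savings_report <- function(x, ...) {
  cat("Savings report\n")
  cat(sprintf("  requests: %d (%d repeats; %d kept covering %d patients of %d)\n",
              x$n_requests, x$n_repeats, x$n_requests_excl_repeats,
              x$n_patients_excl_repeats, x$n_patients))
  cat(sprintf("  planning time saved: %.1f h\n", x$planning_hours))
  cat(sprintf("  distance saved:      %.1f km (%.1f h at %.0f km/h)\n",
              x$distance_saved_km, x$driving_hours, x$params$speed_kmh))
  cat(sprintf("  total:               %.1f h = %.1f weeks at %.0f h/week\n",
              x$total_hours, x$total_weeks, x$params$workweek_h))
  cat(sprintf("  approximate cost:    GBP %.0f\n", x$cost_estimate))
  invisible(x)
}

#' Summary tables of usage-log characteristics
#'
#' Histogram tables of patients per request, requested cluster size and
#' generated cluster count; daily request/patient totals with a trailing
#' 30-day moving average; and, when any record carries postal-district
#' counts, a per-district patient total.
#'
#' @param records List of [usage_record()] objects.
#' @return A list with `patients` (summary + table), `cluster_size`,
#'   `clusters_generated`, `daily` (data.frame with `ma30` column),
#'   `districts` (or `NULL`).
#' @export
summarize_usage <- function(records) {
  if (!length(records))
    return(list(patients = NULL, cluster_size = NULL,
                clusters_generated = NULL, daily = NULL, districts = NULL))
  n <- vapply(records, `[[`, numeric(1), "n_patients")
  D <- vapply(records, `[[`, numeric(1), "cluster_size")
  G <- ceiling(n / D)
  dates <- as.Date(do.call(c, lapply(records, `[[`, "timestamp")))
  all_days <- seq(min(dates), max(dates), by = "day")
  per_day_req <- as.numeric(table(factor(dates, levels = as.character(all_days))))
  pat_by_day <- tapply(n, factor(dates, levels = as.character(all_days)), sum)
  pat_by_day[is.na(pat_by_day)] <- 0
  x <- as.numeric(pat_by_day)
  ma30 <- rep(NA_real_, length(x))  # defined once a full 30-day window exists
  if (length(x) >= 30L) {
    cs <- c(0, cumsum(x))
    idx <- 30:length(x)
    ma30[idx] <- (cs[idx + 1L] - cs[idx - 29L]) / 30
  }
  daily <- data.frame(date = all_days, requests = per_day_req,
                      patients = as.numeric(pat_by_day), ma30 = ma30)
  dist_tabs <- Filter(Negate(is.null), lapply(records, `[[`, "districts"))
  districts <- NULL
  if (length(dist_tabs)) {
    all_d <- unlist(dist_tabs)
    districts <- sort(tapply(all_d, names(all_d), sum), decreasing = TRUE)
  }
  list(
    patients = list(median = stats::median(n), mean = mean(n), table = table(n)),
    cluster_size = list(median = stats::median(D), mean = mean(D), table = table(D)),
    clusters_generated = list(median = stats::median(G), mean = mean(G),
                              table = table(G)),
    daily = daily,
    districts = districts
  )
}
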