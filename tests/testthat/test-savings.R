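test_that("savings parameter defaults carry the analysis constants", {
  p <- savings_params()
  expect_equal(p$lookup_s_per_loc, 36.4)
  expect_equal(p$routing_s_per_loc, 4.8)
  expect_equal(p$upload_penalty_s, 30)
  expect_equal(p$repeat_window_days, 21)
  expect_equal(p$detour_index, 1.4)
  expect_equal(p$speed_kmh, 50)
  expect_equal(p$workweek_h, 40)
  expect_equal(unname(p$uk_shift), c(53, -1.2))
})

test_that("the human-performance penalty is zero at 0, monotone and saturates at A", {
  m <- penalty_model(A = 0.1, B = 50)
  expect_equal(human_penalty(0, m), 0)
  expect_equal(human_penalty(25, m), 0.1 * (1 - exp(-0.5)))
  expect_equal(human_penalty(25, m), 0.03935, tolerance = 1e-4)

  n <- 0:300
  p <- human_penalty(n, m)
  expect_true(all(diff(p) > 0))
  expect_lt(max(p), m$A)
  expect_equal(human_penalty(1e6, m), m$A, tolerance = 1e-9)

  # shipped defaults stay below 5% at 25 locations and 10% at 60
  expect_lte(human_penalty(25, penalty_model()), 0.05)
  expect_lte(human_penalty(60, penalty_model()), 0.10)

  expect_error(human_penalty(-1, m), class = "vialroute_validation_error")
  expect_error(penalty_model(A = 0), class = "vialroute_validation_error")
})

test_that("penalty fitting recovers parameters and rejects degenerate data", {
  n <- seq(2, 120, by = 2)
  p <- 0.12 * (1 - exp(-n / 40))
  fit <- fit_penalty_model(n, p)
  expect_equal(fit$A, 0.12, tolerance = 1e-6)
  expect_equal(fit$B, 40, tolerance = 1e-5)

  # noisy recovery: |A_hat - A| < 0.02 across seeded trials
  errs <- vapply(1:100, function(trial) {
    withr::with_seed(trial, {
      nn <- sample(2:120, 50, replace = TRUE)
      pp <- pmax(0, 0.12 * (1 - exp(-nn / 40)) + rnorm(50, 0, 0.005))
    })
    abs(fit_penalty_model(nn, pp)$A - 0.12)
  }, numeric(1))
  expect_lt(max(errs), 0.02)

  expect_error(fit_penalty_model(c(5, 5), c(0.1, 0.1)),
               class = "vialroute_validation_error")
  expect_error(fit_penalty_model(c(5, 5, 5), c(0.1, 0.1, 0.2)),
               class = "vialroute_validation_error")
})

test_that("usage logs round-trip losslessly through write/parse", {
  recs <- generate_usage_log(synth_params(seed = 5, n_requests = 30))
  path <- tempfile(fileext = ".csv")
  write_usage_log(recs, path)
  back <- parse_usage_log(path)
  expect_length(back, length(recs))
  for (i in seq_along(recs)) {
    expect_equal(back[[i]]$timestamp, recs[[i]]$timestamp)
    expect_equal(back[[i]]$n_patients, recs[[i]]$n_patients)
    expect_equal(back[[i]]$cluster_size, recs[[i]]$cluster_size)
    expect_equal(back[[i]]$mode, recs[[i]]$mode)
    expect_equal(back[[i]]$rel_coords, recs[[i]]$rel_coords,
                 tolerance = 1e-10, ignore_attr = TRUE)
    expect_identical(back[[i]]$labels, recs[[i]]$labels)
    expect_identical(back[[i]]$orders, recs[[i]]$orders)
  }
})

test_that("malformed usage-log rows are rejected with line numbers", {
  recs <- generate_usage_log(synth_params(seed = 6, n_requests = 3))
  path <- tempfile(fileext = ".csv")
  write_usage_log(recs, path)
  # corrupt the cluster labels of the second data row to be outside [0, G)
  df <- utils::read.csv(path, colClasses = "character")
  df$cluster_labels[2] <- gsub("[0-9]+", "99", df$cluster_labels[2])
  utils::write.csv(df, path, row.names = FALSE)
  err <- tryCatch(parse_usage_log(path), error = function(e) e)
  expect_s3_class(err, "vialroute_format_error")
  expect_match(conditionMessage(err), "line 3")

  # an empty log parses to an empty list with a warning
  empty <- tempfile(fileext = ".csv")
  write_usage_log(list(), empty)
  expect_warning(out <- parse_usage_log(empty), "no data rows")
  expect_length(out, 0L)
})

test_that("repeat detection uses the 21-day window and is order-independent", {
  rel_a <- rel_two_points(1000)
  rel_b <- rel_two_points(2000)
  t0 <- as.POSIXct("2021-02-01 09:00:00", tz = "UTC")
  day <- 86400

  # same set at day 0 and day 10: the second is a repeat
  recs <- list(simple_record(rel_a, t0), simple_record(rel_a, t0 + 10 * day))
  expect_equal(detect_repeats(recs), c(FALSE, TRUE))

  # same set 30 days apart: a genuine repeat visit, not flagged
  recs <- list(simple_record(rel_a, t0), simple_record(rel_a, t0 + 30 * day))
  expect_equal(detect_repeats(recs), c(FALSE, FALSE))

  # chains: day 0, day 30 (kept), day 35 (within 21 d of day 30 -> repeat)
  recs <- list(simple_record(rel_a, t0), simple_record(rel_a, t0 + 30 * day),
               simple_record(rel_a, t0 + 35 * day), simple_record(rel_b, t0))
  expect_equal(detect_repeats(recs), c(FALSE, FALSE, TRUE, FALSE))

  # order independence for distinct timestamps, and idempotence
  perm <- c(3, 1, 4, 2)
  expect_equal(detect_repeats(recs[perm]),
               detect_repeats(recs)[perm])
  expect_equal(detect_repeats(recs), detect_repeats(recs))
})

test_that("route-length reconstruction follows the recentre-project-sum procedure", {
  # two patients 1000 m apart in the projected plane, one closed 2-cycle:
  # L = 2 * 1000 * 1.4 = 2800 m
  rec <- simple_record(rel_two_points(1000))
  expect_equal(reconstruct_route_length(rec), 2800, tolerance = 1e-6)

  # co-located patients contribute nothing
  rec0 <- simple_record(matrix(0, 4, 2), D = 4)
  expect_equal(reconstruct_route_length(rec0), 0)

  # single-patient clusters contribute zero length
  rec1 <- simple_record(matrix(0, 1, 2), D = 3)
  expect_equal(reconstruct_route_length(rec1), 0)

  # translating the offsets before the centroid shift changes nothing
  rel <- rel_two_points(5000)
  rec_a <- simple_record(rel)
  rec_b <- simple_record(rel + 0.01)
  expect_equal(reconstruct_route_length(rec_b),
               reconstruct_route_length(rec_a), tolerance = 1e-6)

  # non-negative always
  withr::with_seed(61, {
    for (i in 1:10) {
      n <- sample(2:20, 1)
      rel <- cbind(rnorm(n, 0, 0.05), rnorm(n, 0, 0.05))
      rel <- sweep(rel, 2, colMeans(rel))
      expect_gte(reconstruct_route_length(simple_record(rel, D = max(3, n))), 0)
    }
  })
})

test_that("manual planning time follows the per-location coefficients", {
  # the 5-site worked example: 182 s lookup + 24 s routing = 206 s
  m <- manual_planning_time(5)
  expect_equal(m$lookup_s, 182)
  expect_equal(m$routing_s, 24)
  expect_equal(m$total_s, 206)

  # net of the upload penalty a single 5-site request saves 176 s
  rec <- simple_record(rel_two_points(1000))
  rec$n_patients <- 5L  # bypass full construction for the arithmetic check
  expect_equal(planning_time_savings(list(rec)), 5 * 41.2 - 30)
  expect_equal(planning_time_savings(list()), 0)

  # linear in patients and requests: additive over log concatenation
  recs <- generate_usage_log(synth_params(seed = 9, n_requests = 20))
  mid <- length(recs) %/% 2
  half1 <- recs[seq_len(mid)]; half2 <- recs[(mid + 1):length(recs)]
  expect_equal(planning_time_savings(recs),
               planning_time_savings(half1) + planning_time_savings(half2))
})

test_that("planning savings from printed aggregate totals reproduce the headline hours", {
  s <- planning_time_from_totals(432856, 14359)
  expect_equal(s, 432856 * 41.2 - 14359 * 30)
  expect_equal(s / 3600, 4834, tolerance = 1 / 4834)  # 4834 h to within 1 h
})

test_that("driving savings scale with the penalty and the speed", {
  # a 100 km reconstructed route with p(n) = 0.05 saves 5 km = 360 s at 50 km/h
  rec <- simple_record(rel_two_points(1e5 / 2 / 1.4))
  m_const <- penalty_model(A = 0.05, B = 1e-9)  # p(n) ~ A for n >= 1
  ds <- driving_savings(list(rec), m_const)
  expect_equal(ds$route_length_m, 1e5, tolerance = 1e-6)
  expect_equal(ds$distance_m, 5000, tolerance = 1e-6)
  expect_equal(ds$time_s, 360, tolerance = 1e-6)

  # monotone in A; vanishing with A
  recs <- generate_usage_log(synth_params(seed = 10, n_requests = 10))
  saved <- vapply(c(1e-9, 0.05, 0.1, 0.2), function(A)
    driving_savings(recs, penalty_model(A = A, B = 70))$distance_m, numeric(1))
  expect_true(all(diff(saved) > 0))
  expect_lt(saved[1], 1)  # metres: vanishes as A -> 0
  expect_equal(driving_savings(list())$distance_m, 0)
})

test_that("per-record driving savings stay below 5% of route length for vial-sized requests", {
  # with any conforming penalty model (p(25) <= 0.05) the distance saved on a
  # request of at most 25 patients is at most 5% of its reconstructed length
  model <- penalty_model()
  expect_lte(human_penalty(25, model), 0.05)
  recs <- generate_usage_log(synth_params(seed = 12, n_requests = 30))
  small <- Filter(function(r) r$n_patients <= 25, recs)
  ds <- driving_savings(small, model)
  expect_true(all(ds$saved_m <= 0.05 * ds$route_length_m + 1e-9))
})

test_that("the aggregate report matches an independent spreadsheet-style recomputation", {
  expect_equal(aggregate_report(list())$total_hours, 0)

  recs <- generate_usage_log(synth_params(seed = 13, n_requests = 10,
                                          repeat_fraction = 0.2))
  rep <- aggregate_report(recs)

  # independent recomputation with plain arithmetic
  n <- vapply(recs, `[[`, numeric(1), "n_patients")
  planning_h <- (sum(n) * (36.4 + 4.8) - length(recs) * 30) / 3600
  flags <- attr(recs, "repeat_truth")
  saved_km <- 0
  R <- 6378137
  for (r in recs[!flags]) {
    lat <- r$rel_coords[, 1] + 53
    lon <- r$rel_coords[, 2] - 1.2
    x <- R * lon * pi / 180
    y <- R * log(tan(pi / 4 + lat * pi / 360))
    lvm <- 0
    for (ord in r$orders) {
      if (length(ord) < 2) next
      loop <- c(ord, ord[1])
      lvm <- lvm + sum(sqrt(diff(x[loop])^2 + diff(y[loop])^2))
    }
    saved_km <- saved_km + lvm * 1.4 * 0.15 * (1 - exp(-r$n_patients / 70)) / 1000
  }
  driving_h <- saved_km / 50

  expect_equal(rep$n_repeats, sum(flags))
  expect_equal(rep$planning_hours, planning_h, tolerance = 1e-9)
  expect_equal(rep$distance_saved_km, saved_km, tolerance = 1e-3)
  expect_equal(rep$driving_hours, driving_h, tolerance = 1e-3)
  expect_equal(rep$total_hours, rep$planning_hours + rep$driving_hours)
  expect_equal(rep$total_weeks, rep$total_hours / 40)
  expect_equal(rep$cost_estimate,
               rep$total_hours * mean(c(38000, 32000)) / 2080, tolerance = 1e-9)
})

test_that("usage summaries report histograms, daily totals and moving averages", {
  t0 <- as.POSIXct("2021-02-01 09:00:00", tz = "UTC")
  rel17 <- cbind(seq(-0.08, 0.08, length.out = 17), rep(0, 17))
  rel17 <- sweep(rel17, 2, colMeans(rel17))
  rec <- usage_record(t0, 17L, 10L, "drive", rel17,
                      labels = rep(1:2, c(10, 7)),
                      orders = list(1:10, 11:17))
  s <- summarize_usage(list(rec))
  expect_equal(as.integer(names(s$patients$table)), 17L)
  expect_equal(as.integer(names(s$cluster_size$table)), 10L)
  expect_equal(as.integer(names(s$clusters_generated$table)), 2L)

  # a constant 10 patients/day series has a trailing 30-day mean of 10
  day <- 86400
  recs <- lapply(0:59, function(k) {
    r <- simple_record(rel_two_points(1000), ts = t0 + k * day)
    r$n_patients <- 10L
    r
  })
  s <- summarize_usage(recs)
  expect_equal(nrow(s$daily), 60L)
  expect_true(all(abs(s$daily$ma30[30:60] - 10) < 1e-9))

  # district counts aggregate across the records that carry them
  r1 <- simple_record(rel_two_points(1000)); r1$districts <- c(OX1 = 3L, CB2 = 1L)
  r2 <- simple_record(rel_two_points(2000)); r2$districts <- c(OX1 = 2L)
  s <- summarize_usage(list(r1, r2))
  expect_equal(s$districts[["OX1"]], 5L)
  expect_equal(s$districts[["CB2"]], 1L)
})
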