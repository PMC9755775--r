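test_that("postcode normalisation uppercases, collapses whitespace and extracts the district", {
  rec <- normalize_postcode(" ox1  2jd ")
  expect_equal(rec$normalized, "OX1 2JD")
  expect_equal(rec$district, "OX1")

  rec <- normalize_postcode("OX1 2JD")
  expect_equal(rec$normalized, "OX1 2JD")
  expect_equal(rec$district, "OX1")

  # no-space form: district is everything before the 3-character inward code
  expect_equal(normalize_postcode("OX12JD")$district, "OX1")
  expect_equal(normalize_postcode("sw1a1aa")$district, "SW1A")

  expect_error(normalize_postcode(""), class = "vialroute_validation_error")
  expect_error(normalize_postcode("   "), class = "vialroute_validation_error")
})

test_that("geocoding is deterministic, order-preserving and reports failures", {
  backend <- geocoder_synthetic()
  res <- geocode_batch(c("OX1 2JD", "OX1 2JD"), backend)
  expect_equal(res$records$lat[1], res$records$lat[2])
  expect_equal(res$records$lon[1], res$records$lon[2])
  expect_equal(nrow(res$failures), 0L)

  # synthetic backend stays inside the UK bounding box, stably
  pcs <- fake_postcodes(50, seed = 3)
  p1 <- backend(pcs); p2 <- backend(pcs)
  expect_identical(p1, p2)
  expect_true(all(p1$lat >= 49.9 & p1$lat <= 60.9))
  expect_true(all(p1$lon >= -8.2 & p1$lon <= 1.8))

  # table backend: missing key lands in the failure list, order preserved
  tab <- data.frame(postcode = c("OX1 2JD", "CB2 1TN"),
                    lat = c(51.75, 52.2), lon = c(-1.26, 0.12))
  res <- geocode_batch(c("CB2 1TN", "ZZ9 9ZZ", "OX1 2JD"), geocoder_table(tab))
  expect_equal(res$failures$normalized, "ZZ9 9ZZ")
  expect_equal(res$failures$index, 2L)
  expect_equal(res$records$lat, c(52.2, NA, 51.75))
})

test_that("Web-Mercator projection matches the closed-form spherical equations", {
  expect_equal(as.numeric(project_web_mercator(geo_points(0, 0))), c(0, 0))

  # x at the antimeridian is pi * R
  p <- project_web_mercator(geo_points(0, 180))
  expect_equal(p$x, 20037508.34, tolerance = 1e-8)
  expect_equal(p$y, 0, tolerance = 1e-6)

  # independent formulation: y = R * atanh(sin(lat))
  oracle <- function(lat, lon) {
    R <- 6378137
    cbind(R * lon * pi / 180, R * atanh(sin(lat * pi / 180)))
  }
  p <- project_web_mercator(geo_points(53, -1.2))
  expect_equal(c(p$x, p$y), as.numeric(oracle(53, -1.2)), tolerance = 1e-12)

  withr::with_seed(42, {
    lat <- runif(1000, -85, 85)
    lon <- runif(1000, -180, 180)
  })
  got <- as.matrix(project_web_mercator(geo_points(lat, lon)))
  want <- oracle(lat, lon)
  rel <- abs(got - want) / pmax(abs(want), 1)
  expect_lt(max(rel), 1e-6)

  expect_error(project_web_mercator(geo_points(86, 0)),
               class = "vialroute_validation_error")
})

test_that("UK recentring is a componentwise shift and is invertible by centroid subtraction", {
  p <- recenter_relative(rbind(c(0, 0)))
  expect_equal(c(p$lat, p$lon), c(53, -1.2))

  p <- recenter_relative(rbind(c(1, 1), c(-1, -1)))
  expect_equal(p$lat, c(54, 52))
  expect_equal(p$lon, c(-0.2, -2.2))

  withr::with_seed(7, offsets <- cbind(rnorm(40, 0, 0.05), rnorm(40, 0, 0.05)))
  offsets <- sweep(offsets, 2, colMeans(offsets))  # exact centroid at origin
  out <- recenter_relative(offsets)
  # linearity: shifted mean equals the shift plus the input mean
  expect_equal(unname(colMeans(as.matrix(out))), c(53, -1.2), tolerance = 1e-12)
  # centroid subtraction recovers the offsets
  back <- sweep(as.matrix(out), 2, colMeans(as.matrix(out)))
  expect_equal(unname(back), unname(offsets), tolerance = 1e-9)
})

test_that("pairwise distances are Euclidean, symmetric and rigid-motion invariant", {
  d <- pairwise_distances(data.frame(x = c(0, 3), y = c(0, 4)))
  expect_equal(d[1, 2], 5)

  expect_equal(pairwise_distances(data.frame(x = 1, y = 2)),
               matrix(0, 1, 1, dimnames = list("1", "1")),
               ignore_attr = TRUE)

  withr::with_seed(11, xy <- matrix(runif(20) * 1000, ncol = 2))
  d <- pairwise_distances(data.frame(x = xy[, 1], y = xy[, 2]))
  expect_equal(unname(d), naive_distances(xy), tolerance = 1e-12)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))

  # translation + rotation leave the matrix unchanged
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  xy2 <- sweep(xy %*% rot, 2, c(-1234, 567), "+")
  d2 <- pairwise_distances(data.frame(x = xy2[, 1], y = xy2[, 2]))
  expect_equal(unname(d2), unname(d), tolerance = 1e-9)
})

test_that("patient files read from CSV and XLSX preserving count and order", {
  # CSV with a postcode column
  pcs <- fake_postcodes(24, seed = 5)
  csv <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(postcode = pcs), csv, row.names = FALSE)
  rec <- read_patient_file(csv)
  expect_equal(nrow(rec), 24L)
  expect_equal(rec$normalized, normalize_postcode(pcs)$normalized)

  # CSV with lat/lon columns needs no geocoding
  csv2 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(lat = c(51.5, 53.4), lon = c(-0.1, -2.2)),
                   csv2, row.names = FALSE)
  pts <- read_patient_file(csv2)
  expect_equal(pts$lat, c(51.5, 53.4))

  # XLSX: first column of first sheet, file order preserved
  xlsx <- tempfile(fileext = ".xlsx")
  write_xlsx_column(pcs, xlsx)
  rec2 <- read_patient_file(xlsx)
  expect_equal(rec2$normalized, rec$normalized)

  # the 300-patient cap is enforced
  csv3 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(postcode = fake_postcodes(301, seed = 6)),
                   csv3, row.names = FALSE)
  expect_error(read_patient_file(csv3), class = "vialroute_limit_error")

  # unusable CSV is a format error
  csv4 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(foo = 1:3), csv4, row.names = FALSE)
  expect_error(read_patient_file(csv4), class = "vialroute_format_error")
})

test_that("GeoJSON export has one LineString per cluster, one Point per patient, and round-trips visit orders", {
  withr::with_seed(2, pts <- geo_points(53 + runif(24, 0, 0.1),
                                        -1.2 + runif(24, 0, 0.1)))
  plan <- plan_routes(pts, cluster_params(D = 8, seed = 4, n_restarts = 2))
  path <- tempfile(fileext = ".geojson")
  write_routes_geojson(plan, path)

  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  expect_equal(gj$type, "FeatureCollection")
  types <- vapply(gj$features, function(f) f$geometry$type, character(1))
  expect_equal(sum(types == "LineString"), 3L)
  expect_equal(sum(types == "Point"), 24L)

  # re-parsed visit orders are identical to the plan's
  lines <- gj$features[types == "LineString"]
  for (f in lines) {
    g <- f$properties$cluster
    coords <- do.call(rbind, lapply(f$geometry$coordinates, unlist))
    want <- plan$routes[[g]]$order
    expect_equal(coords[, 1], pts$lon[want])
    expect_equal(coords[, 2], pts$lat[want])
  }

  expect_error(write_routes_geojson(list(), tempfile()),
               class = "vialroute_validation_error")
})
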