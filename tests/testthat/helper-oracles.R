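# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately naive (enumeration, double loops) so it
# stays independent of the package's optimised code paths.

# all permutations of a vector (n! rows) -- fine for n <= 8
all_perms <- function(v) {
  n <- length(v)
  if (n <= 1L) return(matrix(v, nrow = 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- all_perms(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# brute-force optimal fixed-endpoint path length (start == end: closed tour)
brute_force_route_length <- function(dmat, start, end) {
  n <- nrow(dmat)
  inner <- setdiff(seq_len(n), unique(c(start, end)))
  if (!length(inner)) {
    ords <- matrix(integer(0), nrow = 1, ncol = 0)
  } else {
    ords <- all_perms(inner)
  }
  best <- Inf
  for (r in seq_len(nrow(ords))) {
    ord <- c(start, ords[r, ], end)
    len <- sum(dmat[cbind(ord[-length(ord)], ord[-1])])
    best <- min(best, len)
  }
  best
}

# naive double-loop Euclidean distance matrix
naive_distances <- function(xy) {
  n <- nrow(xy)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sqrt(sum((xy[i, ] - xy[j, ])^2))
  d
}

# within-cluster sum of squares of a labelled point set
partition_ssq <- function(xy, labels) {
  total <- 0
  for (g in unique(labels)) {
    m <- xy[labels == g, , drop = FALSE]
    total <- total + sum(sweep(m, 2, colMeans(m))^2)
  }
  total
}

# exhaustive optimal balanced 2-partition (n points into two groups of n/2)
best_balanced_2partition <- function(xy) {
  n <- nrow(xy)
  half <- n / 2
  combos <- utils::combn(n, half)
  best <- NULL; best_obj <- Inf
  for (c_ in seq_len(ncol(combos))) {
    labels <- rep(2L, n)
    labels[combos[, c_]] <- 1L
    obj <- partition_ssq(xy, labels)
    if (obj < best_obj) { best_obj <- obj; best <- labels }
  }
  list(labels = best, objective = best_obj)
}

# G well-separated Gaussian blobs of exactly D points each (projected metres)
make_blobs <- function(G, D, sep = 50000, radius = 500, seed = 1) {
  withr::with_seed(seed, {
    centres <- cbind(runif(G, 0, 10) * sep, runif(G, 0, 10) * sep)
    while (min(dist(centres)) < 10 * radius) {
      centres <- cbind(runif(G, 0, 10) * sep, runif(G, 0, 10) * sep)
    }
    xy <- do.call(rbind, lapply(seq_len(G), function(g)
      cbind(rnorm(D, centres[g, 1], radius), rnorm(D, centres[g, 2], radius))))
    list(xy = xy, labels = rep(seq_len(G), each = D))
  })
}

# relative (lat, lon) offsets of two patients a given projected distance
# apart at the UK mid-point latitude (same latitude, so the projected
# separation is purely in x and exact)
rel_two_points <- function(dist_m) {
  half_lon <- (dist_m / 2) / 6378137 * 180 / pi
  rbind(c(0, -half_lon), c(0, half_lon))
}

# minimal single-cluster usage record
simple_record <- function(rel, ts = as.POSIXct("2021-02-01 09:00:00", tz = "UTC"),
                          D = max(3L, nrow(rel)), mode = "drive",
                          order = seq_len(nrow(rel))) {
  usage_record(ts, nrow(rel), D, mode, rel,
               labels = rep(1L, nrow(rel)), orders = list(order))
}

# write an XLSX file with one column of values via openpyxl (field-standard
# spreadsheet upload format; R has no writer installed, Python does)
write_xlsx_column <- function(values, path) {
  py <- sprintf(
    "import openpyxl, json, sys\nwb = openpyxl.Workbook()\nws = wb.active\nfor v in json.load(open(sys.argv[1])):\n    ws.append([v])\nwb.save(sys.argv[2])\n")
  json_path <- tempfile(fileext = ".json")
  script <- tempfile(fileext = ".py")
  jsonlite::write_json(values, json_path)
  writeLines(py, script)
  status <- system2("python", c(script, json_path, path),
                    stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0)
  path
}

# deterministic fake UK-style postcodes for fixtures
fake_postcodes <- function(n, seed = 1) {
  withr::with_seed(seed, {
    sprintf("%s%d %d%s%s",
            sample(c("OX", "CB", "LS", "M", "NE", "PL"), n, replace = TRUE),
            sample(1:20, n, replace = TRUE),
            sample(1:9, n, replace = TRUE),
            sample(LETTERS, n, replace = TRUE),
            sample(LETTERS, n, replace = TRUE))
  })
}
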