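# Within-cluster visit-order optimisation. Both route modes reduce to a
# fixed-endpoint Hamiltonian path over the cluster members:
#   closed -- the route starts and ends at a depot (e.g. the GP surgery),
#             a conventional travelling-salesman tour;
#   open   -- no depot; the endpoints are the two members farthest apart, on
#             the heuristic that the others lie roughly on the line between
#             them (an open vehicle-routing route).
# Small instances are solved exactly by Held-Karp dynamic programming;
# larger ones by nearest-neighbour construction plus 2-opt local search.

#' Index pair of the two locations farthest apart
#'
#' @param dmat Symmetric distance matrix, n >= 2.
#' @return Integer vector `c(i, j)` with `i < j` maximising `dmat[i, j]`;
#'   ties resolved to the lexicographically smallest pair.
#' @export
farthest_pair_endpoints <- function(dmat) {
  n <- nrow(dmat)
  if (is.null(n) || n < 2L) stop_validation("need at least two locations")
  m <- dmat
  m[lower.tri(m, diag = TRUE)] <- -Inf
  hits <- which(m == max(m), arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  as.integer(unname(hits[1, ]))
}

#' Total length of a route order
#'
#' @param dmat Distance matrix.
#' @param order Integer sequence of visited indices (consecutive legs are
#'   summed; repeat the first index at the end for a closed tour).
#' @return Length in the units of `dmat`.
#' @export
route_length <- function(dmat, order) {
  if (length(order) < 2L) return(0)
  sum(dmat[cbind(order[-length(order)], order[-1L])])
}

#' Exact fixed-endpoint route by Held-Karp dynamic programming
#'
#' Finds the minimum-length path from `start` to `end` visiting every index
#' of `dmat` exactly once (except that `start == end` gives a closed tour).
#' Complexity is O(2^n n^2), so a threshold guards against oversized calls.
#'
#' @param dmat Symmetric distance matrix.
#' @param start,end Endpoint indices; equal for a closed tour.
#' @param exact_threshold Refuse instances with more members than this.
#' @return Integer visit order including both endpoints.
#' @export
exact_route <- function(dmat, start, end, exact_threshold = 12L) {
  n <- nrow(dmat)
  if (n > exact_threshold)
    stop_validation("instance size %d exceeds exact threshold %d", n, exact_threshold)
  closed <- start == end
  inner <- setdiff(seq_len(n), if (closed) start else c(start, end))
  k <- length(inner)
  if (k == 0L) return(if (closed) c(start, start) else c(start, end))
  # dp[S + 1, j]: shortest path start -> inner[j] visiting exactly the inner
  # subset encoded by bitmask S (which must contain j)
  dp <- matrix(Inf, nrow = 2^k, ncol = k)
  parent <- matrix(0L, nrow = 2^k, ncol = k)
  bit <- as.integer(2^(seq_len(k) - 1L))
  for (j in seq_len(k)) dp[bit[j] + 1L, j] <- dmat[start, inner[j]]
  if (k > 1L) {
    for (S in seq_len(2^k - 1L)) {
      members <- which(bitwAnd(S, bit) > 0L)
      if (length(members) < 2L) next
      for (j in members) {
        prevS <- S - bit[j]
        ks <- members[members != j]
        cand <- dp[prevS + 1L, ks] + dmat[inner[ks], inner[j]]
        b <- which.min(cand)
        dp[S + 1L, j] <- cand[b]
        parent[S + 1L, j] <- ks[b]
      }
    }
  }
  full <- 2^k - 1L
  totals <- dp[full + 1L, ] + dmat[inner, end]
  j <- which.min(totals)
  path <- integer(k)
  S <- full
  while (j > 0L) {
    path[sum(bitwAnd(S, bit) > 0L)] <- inner[j]
    nj <- parent[S + 1L, j]
    S <- S - bit[j]
    j <- nj
  }
  c(start, path, end)
}

#' Heuristic fixed-endpoint route (nearest neighbour + 2-opt + or-opt)
#'
#' Builds nearest-neighbour paths from both endpoints (keeping the opposite
#' endpoint for last), then improves each with alternating 2-opt segment
#' reversals and single-node relocations (or-opt) that respect the fixed
#' endpoints, until no move shortens the route; the shorter result wins.
#' The result is never longer than the nearest-neighbour path.
#'
#' @inheritParams exact_route
#' @return Integer visit order including both endpoints.
#' @export
heuristic_route <- function(dmat, start, end) {
  n <- nrow(dmat)
  if (n < 2L) stop_validation("need at least two locations")
  a <- local_search(dmat, nn_path(dmat, start, end))
  if (start == end) return(a)
  b <- rev(local_search(dmat, nn_path(dmat, end, start)))
  if (route_length(dmat, b) < route_length(dmat, a)) b else a
}

nn_path <- function(dmat, start, end) {
  n <- nrow(dmat)
  closed <- start == end
  left <- setdiff(seq_len(n), if (closed) start else c(start, end))
  path <- integer(0)
  cur <- start
  while (length(left)) {
    nxt <- left[which.min(dmat[cur, left])]
    path <- c(path, nxt)
    left <- left[left != nxt]
    cur <- nxt
  }
  c(start, path, end)
}

local_search <- function(dmat, order) {
  repeat {
    improved <- FALSE
    new <- two_opt(dmat, order)
    if (route_length(dmat, new) < route_length(dmat, order) - 1e-9) {
      order <- new; improved <- TRUE
    }
    new <- or_opt(dmat, order)
    if (route_length(dmat, new) < route_length(dmat, order) - 1e-9) {
      order <- new; improved <- TRUE
    }
    if (!improved) break
  }
  order
}

# or-opt: relocate one interior node to its best alternative slot; repeat
# until no relocation shortens the route (endpoints stay fixed)
or_opt <- function(dmat, order) {
  m <- length(order)
  if (m < 4L) return(order)
  repeat {
    improved <- FALSE
    for (i in 2:(m - 1L)) {
      v <- order[i]
      rem_gain <- dmat[order[i - 1L], v] + dmat[v, order[i + 1L]] -
        dmat[order[i - 1L], order[i + 1L]]
      if (rem_gain <= 1e-9) next
      rest <- order[-i]
      ins_cost <- dmat[rest[-length(rest)], v] + dmat[v, rest[-1L]] -
        dmat[cbind(rest[-length(rest)], rest[-1L])]
      j <- which.min(ins_cost)
      if (ins_cost[j] < rem_gain - 1e-9) {
        order <- append(rest, v, after = j)
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  order
}

# 2-opt with fixed first and last positions: reverse order[i..j] whenever it
# strictly shortens the route; first-improvement sweeps until none applies.
two_opt <- function(dmat, order) {
  m <- length(order)
  if (m < 4L) return(order)
  repeat {
    improved <- FALSE
    for (i in 2:(m - 2L)) {
      for (j in (i + 1L):(m - 1L)) {
        a <- order[i - 1L]; b <- order[i]
        c_ <- order[j]; d <- order[j + 1L]
        delta <- (dmat[a, c_] + dmat[b, d]) - (dmat[a, b] + dmat[c_, d])
        if (delta < -1e-9) {
          order[i:j] <- rev(order[i:j])
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  order
}

#' Solve the visit order for one cluster
#'
#' Dispatches to the exact Held-Karp solver when the instance is small
#' enough, otherwise to the nearest-neighbour/2-opt heuristic. In closed
#' mode the route starts and ends at the depot index; in open mode the
#' endpoints are the farthest-apart pair of members. The travel-time
#' estimate inflates the straight-line length by a detour index (ratio of
#' road to straight-line distance) and divides by the mode speed.
#'
#' @param dmat Symmetric distance matrix in metres over cluster members
#'   (including the depot, for closed mode).
#' @param mode `"open"` or `"closed"`.
#' @param depot Index of the depot row in `dmat` (closed mode only).
#' @param detour_index Road-to-straight-line distance ratio, default 1.4.
#' @param speed_kmh Assumed mean travel speed, default 50 km/h.
#' @param exact_threshold Largest instance solved exactly, default 12.
#' @return A list of class `vialroute_route`: `order` (indices into `dmat`),
#'   `length_m` (straight-line), `travel_time_s` (detour-adjusted), `closed`.
#' @export
solve_route <- function(dmat, mode = c("open", "closed"), depot = NULL,
                        detour_index = 1.4, speed_kmh = 50,
                        exact_threshold = 12L) {
  mode <- match.arg(mode)
  dmat <- as.matrix(dmat)
  n <- nrow(dmat)
  if (n < 1L) stop_validation("empty distance matrix")
  if (mode == "closed") {
    if (is.null(depot)) stop_validation("closed mode requires a depot index")
    start <- end <- depot
  } else if (n == 1L) {
    res <- list(order = 1L, length_m = 0, travel_time_s = 0, closed = FALSE)
    return(structure(res, class = "vialroute_route"))
  } else {
    ep <- farthest_pair_endpoints(dmat)
    start <- ep[1L]; end <- ep[2L]
  }
  order <- if (n <= exact_threshold + (mode == "closed")) {
    exact_route(dmat, start, end, exact_threshold = exact_threshold +
                  (mode == "closed"))
  } else {
    heuristic_route(dmat, start, end)
  }
  len <- route_length(dmat, order)
  structure(list(
    order = order,
    length_m = len,
    travel_time_s = len * detour_index / (speed_kmh / 3.6),
    closed = mode == "closed"
  ), class = "vialroute_route")
}

#' Plan vial-sized visit routes for a set of patients
#'
#' The full two-stage pipeline: cluster patients into groups of a fixed size,
#' then compute the visit order within each group. Without a depot every
#' route is open (endpoints at the farthest-apart pair); with a depot every
#' route is a closed tour from and back to it.
#'
#' @param patients A [geo_points()] table of patient locations (lat/lon), or
#'   an n x 2 matrix / `x`-`y` data.frame of projected coordinates in metres.
#' @param params A [cluster_params()] object.
#' @param depot Optional depot as a one-row [geo_points()] table (or length-2
#'   `c(lat, lon)`).
#' @param mode `"drive"` or `"walk"`; selects the travel speed.
#' @param detour_index Road-to-straight-line ratio, default 1.4.
#' @param drive_kmh,walk_kmh Mode speeds, defaults 50 and 5 km/h.
#' @param exact_threshold Largest cluster routed exactly, default 12.
#' @param distance `"mercator"` reproduces projected-plane distances;
#'   `"haversine"` uses great-circle distances instead (only meaningful for
#'   lat/lon input).
#' @return A list of class `vialroute_plan`: `patients` (lat/lon table when
#'   available), `assignment` (the `cluster_assignment`), `routes` (one per
#'   cluster, with `order` as global patient indices, 0 marking the depot),
#'   `depot`, `mode`, `summary` (per-cluster data.frame).
#' @examples
#' pts <- geo_points(53 + runif(24, 0, 0.1), -1.2 + runif(24, 0, 0.1))
#' p <- plan_routes(pts, cluster_params(D = 8, seed = 1))
#' p$summary
#' @export
plan_routes <- function(patients, params, depot = NULL,
                        mode = c("drive", "walk"), detour_index = 1.4,
                        drive_kmh = 50, walk_kmh = 5, exact_threshold = 12L,
                        distance = c("mercator", "haversine")) {
  mode <- match.arg(mode)
  distance <- match.arg(distance)
  speed <- if (mode == "drive") drive_kmh else walk_kmh
  is_geo <- is.data.frame(patients) && all(c("lat", "lon") %in% names(patients))
  if (is_geo) {
    pts <- geo_points(patients$lat, patients$lon)
    xy <- as.matrix(project_web_mercator(pts))
  } else {
    pts <- NULL
    xy <- as.matrix(patients)
    if (distance == "haversine")
      stop_validation("haversine distances require lat/lon input")
  }
  if (!is.null(depot)) {
    if (is.numeric(depot) && length(depot) == 2L)
      depot <- geo_points(depot[1L], depot[2L])
    if (!is_geo) stop_validation("a depot requires lat/lon patient input")
  }
  assignment <- cluster_fixed_size(xy, params)
  dist_fun <- function(idx, with_depot) {
    if (distance == "haversine") {
      g <- pts[idx, , drop = FALSE]
      if (with_depot) g <- rbind(g, depot)
      haversine_distances(g)
    } else {
      p <- xy[idx, , drop = FALSE]
      if (with_depot) p <- rbind(p, as.matrix(project_web_mercator(depot)))
      as.matrix(stats::dist(p))
    }
  }
  routes <- vector("list", assignment$G)
  for (g in seq_len(assignment$G)) {
    members <- which(assignment$labels == g)
    with_depot <- !is.null(depot)
    dmat <- dist_fun(members, with_depot)
    if (with_depot) {
      r <- solve_route(dmat, "closed", depot = length(members) + 1L,
                       detour_index = detour_index, speed_kmh = speed,
                       exact_threshold = exact_threshold)
      # map back to global indices; 0 marks the depot
      global <- c(members, 0L)[r$order]
    } else if (length(members) == 1L) {
      r <- solve_route(dmat, "open", detour_index = detour_index,
                       speed_kmh = speed, exact_threshold = exact_threshold)
      global <- members
    } else {
      r <- solve_route(dmat, "open", detour_index = detour_index,
                       speed_kmh = speed, exact_threshold = exact_threshold)
      global <- members[r$order]
    }
    routes[[g]] <- list(cluster = g, order = global, length_m = r$length_m,
                        travel_time_s = r$travel_time_s, closed = r$closed)
  }
  summary <- data.frame(
    cluster = seq_len(assignment$G),
    size = assignment$sizes,
    length_m = vapply(routes, `[[`, numeric(1), "length_m"),
    travel_time_s = vapply(routes, `[[`, numeric(1), "travel_time_s")
  )
  structure(list(
    patients = pts, xy = xy, assignment = assignment, routes = routes,
    depot = depot, mode = mode, summary = summary
  ), class = "vialroute_plan")
}

#' @export
print.vialroute_plan <- function(x, ...) {
  n <- length(x$assignment$labels)
  cat(sprintf("Visit plan: %d patients, %d clusters (D = %d), %s mode, %s routes\n",
              n, x$assignment$G, x$assignment$D, x$mode,
              if (is.null(x$depot)) "open" else "closed"))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
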