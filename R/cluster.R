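# Fixed-size clustering: partition N locations into G = ceiling(N/D) groups
# so that exactly one group may be smaller than the requested size D and all
# others have size exactly D (each group then consumes one vaccine vial).
#
# The algorithm is a capacity-constrained variant of iterative k-means:
# seeded farthest-first initialisation, priority-ordered greedy assignment
# (locations whose best and second-best centroids differ most are placed
# first; locations near the middle of the distribution, which could join any
# cluster cheaply, are placed last), then a best-improvement swap local
# search that preserves the size constraint at every step.

#' Clustering parameters
#'
#' @param D Target cluster size (vial size); an integer in \[3, 25\].
#' @param max_patients Upload cap, default 300 locations.
#' @param seed Integer seed; the whole procedure is deterministic given it.
#' @param max_iter Maximum refinement passes per restart.
#' @param n_restarts Independent seeded restarts; the lowest-objective result
#'   is kept.
#' @return An object of class `cluster_params`.
#' @export
cluster_params <- function(D, max_patients = 300L, seed = 1L,
                           max_iter = 100L, n_restarts = 8L) {
  D <- check_count(D, "D")
  if (D < 3L || D > 25L)
    stop_validation("cluster size D must be between 3 and 25, got %d", D)
  structure(list(
    D = D,
    max_patients = check_count(max_patients, "max_patients"),
    seed = check_count(seed, "seed", lower = 0L),
    max_iter = check_count(max_iter, "max_iter"),
    n_restarts = check_count(n_restarts, "n_restarts")
  ), class = "cluster_params")
}

#' Number of clusters for N locations at target size D
#'
#' `G = ceiling(N / D)`; when D does not divide N exactly one cluster is
#' smaller than D, so at most one vial per plan is incompletely used.
#'
#' @param N Number of locations.
#' @param D Target cluster size.
#' @return Integer cluster count.
#' @examples
#' num_clusters(24, 8)  # 3
#' num_clusters(30, 8)  # 4
#' @export
num_clusters <- function(N, D) {
  N <- check_count(N, "N")
  D <- check_count(D, "D")
  as.integer(ceiling(N / D))
}

# squared Euclidean distances from each point (rows of xy) to each centroid
dist2_to_centroids <- function(xy, centroids) {
  cross <- xy %*% t(centroids)
  sweep(sweep(-2 * cross, 1, rowSums(xy^2), "+"), 2, rowSums(centroids^2), "+")
}

#' Seeded farthest-first centroid initialisation
#'
#' The first centroid is a seeded random point; each subsequent centroid is
#' the point farthest from all centroids chosen so far (ties by lowest
#' index). With `G = N` every point becomes a centroid.
#'
#' @param xy Numeric matrix (n x 2) of projected coordinates, metres.
#' @param G Number of centroids.
#' @param seed Integer seed.
#' @return A G x 2 matrix of starting centroids.
#' @export
init_centroids <- function(xy, G, seed = 1L) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  G <- check_count(G, "G")
  if (n < G) stop_validation("need at least G = %d points, got %d", G, n)
  first <- withr::with_seed(seed, sample.int(n, 1L))
  chosen <- integer(G)
  chosen[1L] <- first
  if (G > 1L) {
    mind <- colSums((t(xy) - xy[first, ])^2)
    for (g in 2:G) {
      nxt <- which.max(mind)  # first index on ties
      chosen[g] <- nxt
      mind <- pmin(mind, colSums((t(xy) - xy[nxt, ])^2))
    }
  }
  xy[chosen, , drop = FALSE]
}

#' Priority order for capacity-constrained assignment
#'
#' Ranks locations by descending assignment regret: the distance to the
#' second-nearest centroid minus the distance to the nearest. A location far
#' from all centroids but one must be placed early to get its only good
#' cluster; a location equidistant from all centroids can be placed last at
#' little cost. Ties break by descending distance from the global centroid,
#' then by index.
#'
#' @param xy Numeric matrix (n x 2), projected metres.
#' @param centroids G x 2 matrix.
#' @return A permutation of `1:n`, highest priority first.
#' @export
priority_order <- function(xy, centroids) {
  xy <- as.matrix(xy)
  centroids <- as.matrix(centroids)
  d <- sqrt(pmax(dist2_to_centroids(xy, centroids), 0))
  if (ncol(d) == 1L) {
    regret <- rep(0, nrow(xy))
  } else {
    sorted <- t(apply(d, 1, sort))
    regret <- sorted[, 2] - sorted[, 1]
  }
  gc_dist <- sqrt(colSums((t(xy) - colMeans(xy))^2))
  order(-regret, -gc_dist, seq_len(nrow(xy)))
}

#' Greedy capacity-constrained assignment
#'
#' Visits locations in priority order and gives each its nearest centroid
#' that still has free capacity, subject to the whole assignment remaining
#' completable with at most one undersized cluster. Every cluster has
#' capacity D; the undersized cluster (when D does not divide N) is not
#' pre-designated -- it is whichever cluster is left with unfilled capacity
#' when assignment ends.
#'
#' A choice is feasible when the locations still to be placed can fill every
#' cluster except the one with the most free slots: with m locations left
#' and free capacities f, this requires `m >= sum(f) - max(f)`. Assigning
#' greedily among feasible clusters guarantees the final size multiset is
#' exactly `{D, ..., D, N - (G-1)*D}`.
#'
#' @param xy Numeric matrix (n x 2).
#' @param centroids G x 2 matrix.
#' @param ord Permutation of `1:n` from [priority_order()].
#' @param D Target cluster size.
#' @return Integer vector of cluster labels in `1:G`.
#' @export
assign_with_capacity <- function(xy, centroids, ord, D) {
  xy <- as.matrix(xy)
  centroids <- as.matrix(centroids)
  n <- nrow(xy)
  G <- nrow(centroids)
  if (G * D < n) stop_validation("capacity G*D = %d below n = %d", G * D, n)
  d2 <- dist2_to_centroids(xy, centroids)
  free <- rep.int(D, G)
  labels <- integer(n)
  remaining <- n
  for (i in ord) {
    remaining <- remaining - 1L  # locations still to place after this one
    open <- which(free > 0L)
    open <- open[order(d2[i, open])]
    for (g in open) {
      f <- free
      f[g] <- f[g] - 1L
      if (remaining >= sum(f) - max(f)) { labels[i] <- g; break }
    }
    if (labels[i] == 0L)  # unreachable: a feasible cluster always exists
      stop_validation("capacity assignment became infeasible")
    free[labels[i]] <- free[labels[i]] - 1L
  }
  labels
}

cluster_objective <- function(xy, labels, centroids) {
  sum((xy - centroids[labels, , drop = FALSE])^2)
}

centroids_of <- function(xy, labels, G) {
  cx <- tapply(xy[, 1], factor(labels, levels = 1:G), mean)
  cy <- tapply(xy[, 2], factor(labels, levels = 1:G), mean)
  cbind(as.numeric(cx), as.numeric(cy))
}

#' Swap-based refinement of a capacity-feasible assignment
#'
#' Best-improvement local search: repeatedly applies the pairwise label swap
#' that most reduces the within-cluster sum of squares, recomputing centroids
#' after each pass, until no strictly improving swap exists or `max_iter`
#' passes have run. When the undersized cluster is one short of full
#' (`N mod D == D - 1`) a single move that relabels one location into it --
#' which then makes the donor the undersized cluster -- is also considered.
#' Cluster sizes are preserved exactly at every step and the objective never
#' increases.
#'
#' @param xy Numeric matrix (n x 2).
#' @param labels Integer labels in `1:G`, capacity-feasible.
#' @param D Target cluster size.
#' @param max_iter Maximum passes.
#' @return A list with `labels`, `centroids`, `objective`.
#' @export
refine_swaps <- function(xy, labels, D, max_iter = 100L) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  G <- max(labels)
  sizes <- tabulate(labels, nbins = G)
  short <- which(sizes < D)  # at most one by construction
  for (pass in seq_len(max_iter)) {
    centroids <- centroids_of(xy, labels, G)
    d2 <- dist2_to_centroids(xy, centroids)
    improved <- FALSE
    repeat {
      cur <- d2[cbind(seq_len(n), labels)]
      # gain[i, j] > 0 when swapping labels of i and j lowers the (fixed-
      # centroid) objective; same-cluster pairs have gain 0 by symmetry
      cross <- d2[, labels, drop = FALSE]          # cross[i, j] = d2(i, cl(j))
      gain <- outer(cur, cur, "+") - cross - t(cross)
      best <- arrayInd(which.max(gain), dim(gain))
      best_gain <- gain[best]
      # size-preserving single move into the undersized cluster: only legal
      # when it leaves the donor exactly as undersized as the target was
      move_i <- 0L
      move_gain <- -Inf
      if (length(short) == 1L && sizes[short] == D - 1L) {
        cand_gain <- cur - d2[, short]
        cand_gain[labels == short] <- -Inf
        move_i <- which.max(cand_gain)
        move_gain <- cand_gain[move_i]
      }
      eps <- 1e-9 * max(1, mean(cur))
      if (best_gain <= eps && move_gain <= eps) break
      if (best_gain >= move_gain) {
        i <- best[1L]; j <- best[2L]
        tmp <- labels[i]; labels[i] <- labels[j]; labels[j] <- tmp
      } else {
        donor <- labels[move_i]
        labels[move_i] <- short
        sizes[short] <- D
        sizes[donor] <- sizes[donor] - 1L
        short <- donor
      }
      improved <- TRUE
    }
    if (!improved) break
  }
  centroids <- centroids_of(xy, labels, G)
  list(labels = labels, centroids = centroids,
       objective = cluster_objective(xy, labels, centroids))
}

#' Partition locations into fixed-size clusters
#'
#' Runs the full pipeline -- farthest-first initialisation, priority-ordered
#' capacity assignment, swap refinement -- over `n_restarts` seeded restarts
#' and keeps the lowest-objective result. Deterministic given `params$seed`.
#'
#' Co-located patients (identical coordinates) are counted as distinct
#' locations, so the size constraint holds even when several patients share
#' an address.
#'
#' @param xy An n x 2 matrix or a `data.frame` with `x`/`y` columns of
#'   projected coordinates in metres.
#' @param params A [cluster_params()] object.
#' @return A list of class `cluster_assignment`: `labels` (in `1:G`),
#'   `centroids`, `sizes`, `objective` (metres^2), `G`, `D`.
#' @examples
#' xy <- cbind(runif(24) * 1000, runif(24) * 1000)
#' fit <- cluster_fixed_size(xy, cluster_params(D = 8, seed = 42))
#' fit$sizes  # 8 8 8
#' @export
cluster_fixed_size <- function(xy, params) {
  if (!inherits(params, "cluster_params"))
    stop_validation("'params' must be a cluster_params object")
  if (is.data.frame(xy)) xy <- as.matrix(xy[, c("x", "y")])
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (n < 1L) stop_validation("need at least one location")
  if (n > params$max_patients)
    stop_limit("%d locations exceed the configured maximum of %d patients",
               n, params$max_patients)
  G <- num_clusters(n, params$D)
  best <- NULL
  for (r in seq_len(params$n_restarts)) {
    cen0 <- init_centroids(xy, G, seed = params$seed + (r - 1L) * 1009L)
    ord <- priority_order(xy, cen0)
    labels0 <- assign_with_capacity(xy, cen0, ord, params$D)
    fit <- refine_swaps(xy, labels0, params$D, max_iter = params$max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  structure(list(
    labels = best$labels,
    centroids = best$centroids,
    sizes = tabulate(best$labels, nbins = G),
    objective = best$objective,
    G = G, D = params$D
  ), class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("Fixed-size clustering: %d locations in %d clusters (D = %d)\n",
              length(x$labels), x$G, x$D))
  cat("sizes:", paste(x$sizes, collapse = ", "), "\n")
  cat(sprintf("within-cluster sum of squares: %.1f m^2\n", x$objective))
  invisible(x)
}
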