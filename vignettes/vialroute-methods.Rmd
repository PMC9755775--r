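---
title: "Methods: vial-constrained route planning and savings estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vial-constrained route planning and savings estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vialroute)
```

# The planning model

vialroute plans home visits for `N` patients under a vial-size constraint:
any practitioner trip should cover exactly `D` patients (one vial of `D`
doses), `3 <= D <= 25`. This forces `G = ceiling(N/D)` clusters, with at
most one cluster — the remainder — smaller than `D`, so at most one vial per
plan is incompletely used. Uploads are capped at 300 patients.

Planning is two-stage. Clustering works on Euclidean distances between
projected (Web-Mercator) coordinates, which assumes patients are connected
by roughly direct paths; routing then orders the visits within each cluster.

## Fixed-size clustering

Standard *k*-means cannot hold cluster sizes fixed, so the package uses a
capacity-constrained variant:

1. **Initialisation** (`init_centroids`): a seeded random first centroid,
   then farthest-first selection — each next centroid is the point with the
   largest minimum distance to those already chosen. Deterministic given the
   seed; with duplicated points ties resolve to the lowest index.
2. **Priority order** (`priority_order`): locations are ranked by
   *assignment regret*, the distance to the second-nearest centroid minus
   the distance to the nearest. A point that is far from every centroid but
   one must get its only good cluster before capacity runs out; a point near
   the middle of the distribution can join any cluster cheaply and is
   handled last. Ties break by distance from the global centroid
   (descending), then index.
3. **Capacity assignment** (`assign_with_capacity`): in priority order, each
   location takes its nearest centroid that still has free capacity,
   *subject to feasibility*. A naive "nearest with free capacity" greedy can
   end with free slots stranded in two clusters (e.g. `N = 10, D = 4`
   finishing `{4, 3, 3}`), violating the one-remainder rule. The package
   therefore only allows an assignment if the locations still to be placed
   can fill every cluster except the one with the most free slots
   (`m >= sum(f) - max(f)` with `m` remaining locations and `f` the free
   capacities). A feasible cluster always exists, and the final size
   multiset is provably `{D, ..., D, N - (G-1)D}`. The undersized cluster is
   not pre-designated; it is whichever cluster ends with free capacity.
4. **Refinement** (`refine_swaps`): best-improvement local search over
   pairwise label swaps, which are always size-preserving. A *single* move
   into the undersized cluster preserves the size multiset only when the
   remainder equals `D - 1` (the donor then becomes the undersized
   cluster); it is considered exactly in that case. Swap gains are evaluated
   against fixed centroids, centroids are recomputed after each pass, and
   both steps can only decrease the within-cluster sum of squares, so the
   objective is monotone and the search terminates at a local optimum or
   after `max_iter` passes (default 100).
5. **Restarts**: the pipeline runs `n_restarts` times (default 8) from
   seeds derived deterministically from `params$seed`; the lowest-objective
   result wins. This is a heuristic — optimal balanced clustering by integer
   programming is out of scope — but on well-separated groups it recovers
   the generating partition exactly, which the tests verify.

Co-located patients count as distinct locations, so several patients in one
household never break the size constraint.

## Within-cluster routing

Both route modes reduce to a minimum-length Hamiltonian path with fixed
endpoints on the cluster's distance matrix:

* **Closed** (a depot, e.g. the surgery, is given): start = end = depot — a
  conventional TSP tour.
* **Open** (no depot): the endpoints are the two cluster members farthest
  apart, on the heuristic that the remaining members lie roughly on the line
  between them. Ties in the farthest pair resolve to the lexicographically
  smallest index pair.

Instances up to `exact_threshold` members (default 12) are solved exactly by
Held–Karp dynamic programming (`O(2^n n^2)`); larger clusters (up to the cap
of 25) use nearest-neighbour construction from both endpoints, improved by
alternating 2-opt segment reversals and or-opt single-node relocations until
no move shortens the route, keeping the better of the two constructions. On
random Euclidean instances with `n <= 12` this heuristic lands within 5% of
the exact optimum on well over 95% of cases (a regression guard in the test
suite, not a guarantee).

Travel time is an offline estimate: straight-line route length × detour
index (the ratio of road to straight-line distance, default 1.4) ÷ mode
speed. Driving defaults to 50 km/h; walking to 5 km/h, a configurable
package default for urban use. Per-visit dwell time is not included.

# The savings model

The analysis consumes anonymised usage logs. Each record keeps a timestamp,
the patient count `n`, the requested cluster size, the transport mode, the
patients' coordinates *relative to their centroid* (an irreversible
anonymisation), the cluster labels and the per-cluster visit orders.

**Repeat detection.** A record is a repeat if an earlier record with an
identical patient-location multiset exists strictly less than 21 days
before. Identity is operationalised as the multiset of relative coordinates
rounded to 1e-6 degrees (about 0.1 m — far below inter-address spacing,
far above serialisation error); anonymised logs carry no postcodes to
compare instead. Re-uploads inside the window are read as experimentation
with parameters; identical uploads farther apart may be genuine repeat
visits and are kept.

**Route-length reconstruction.** Relative coordinates are shifted onto the
approximate UK mid-point (53, −1.2) — distances depend on latitude once
projected, so the offsets must sit at a representative latitude — then
projected to EPSG:3857, and each cluster's recorded visit order is summed as
a closed loop; single-patient clusters contribute zero. The total is
multiplied by the detour index. Two caveats are deliberate: Web-Mercator
plane distances overstate ground distance by roughly `1/cos(latitude)`
(about 1.66× at 53° N), and the loop is closed even for open routes. Both
choices reproduce the reference reconstruction procedure exactly; a
`distance = "haversine"` flag provides great-circle distances for users who
want geometric correctness rather than reproduction.

**Manual planning time.** Planning a route by hand splits into a lookup
component (finding addresses on a map: 36.4 s/location) and a routing
component (ordering the visits: 4.8 s/location), survey-derived regression
coefficients taken as constants. For a five-site route this gives 182 s +
24 s = 206 s. Savings are summed over *all* requests, repeats included
(users presumably had reason to re-plan), minus a 30 s upload penalty per
request for using the service itself.

**Human-performance penalty.** Human TSP solutions are near-optimal for
small problems and degrade with size. The fractional excess distance is
modelled as `p(n) = A (1 - e^{-n/B})`: zero at `n = 0`, monotone, saturating
at `A`. (The saturating sign of the exponent is the only form consistent
with a bounded penalty.) The shipped defaults `A = 0.15, B = 70` are a
calibration to two qualitative anchors — the penalty stays below 5% for
routes of up to 25 locations (`p(25) = 4.5%`) and below 10% up to about 60
(`p(60) = 8.6%`) — not fitted constants; `fit_penalty_model()` refits both
parameters from observations by positivity-constrained Levenberg–Marquardt
least squares. Because published fitted values are unavailable, aggregate
distance-savings figures depend on this calibration and are reported as
model outputs, not reproductions.

**Aggregation.** Driving savings per non-repeat record are
`L · p(n)` metres (repeats were likely never driven), converted to time at
50 km/h. Planning and driving hours add into total hours and 40 h work
weeks. The cost estimate multiplies total hours by a blended hourly rate:
the mean of the configured annual salaries (defaults £38,000 practice
manager, £32,000 community nurse) over `work_hours_per_year` (default
52 × 40 = 2,080 h). The blend is configurable because any single headline
figure depends on staffing assumptions the log cannot reveal.

# The synthetic-data generator

`generate_usage_log()` exists so every stage is testable without external
data. It emulates:

* **Request sizes**: log-normal with `meanlog = log 17` and
  `sdlog = sqrt(2 log(30/17))`, rounded and capped to [1, 300] — chosen
  analytically so the median is 17 and the mean near 30, the two moments
  real usage exhibits. Capping trims the mean by under 2%.
* **Cluster sizes**: a discrete bell over 3–25 with mode 10.
* **Geography**: a weighted Gaussian mixture around eight UK town centres
  (5 km spread), with a 5% chance a patient duplicates an earlier address
  exactly (households), clamped to a UK bounding box.
* **Timing**: five Gaussian campaign waves between early 2021 and late 2022,
  echoing dose-and-booster usage peaks; cosmetic for tests.
* **Repeats**: a configured fraction of requests re-emit an earlier record's
  patient set 1–20 days later; the generator records the ground-truth flags
  so repeat detection can be tested for exact recovery.

Labels and visit orders in generated logs come from running the actual
planner (with lighter effort settings: one restart, exact routing up to 8
members), so they satisfy every structural invariant of real logs. What the
generator does **not** emulate: real postcode geography and its district
distribution, correlation between request size and place, user-level
behaviour (the same surgery returning weekly), or road networks. Passing
tests therefore demonstrate algorithmic correctness and internal
consistency, not calibration against any real deposit.

# Numerical choices and degenerate inputs

* All randomness is seeded and scoped (`withr::with_seed`), so plans,
  logs and reports are bit-reproducible; restart seeds derive from the user
  seed by fixed offsets.
* Swap refinement accepts a move only if it improves the objective by more
  than a relative epsilon (1e-9 of the mean point cost), preventing
  tie-cycling among co-located points.
* 2-opt/or-opt use first-improvement sweeps with a 1e-9 metre threshold.
* Degenerate cases: a single patient yields one zero-length route; `G = 1`
  skips priority logic; co-located duplicates are legal everywhere;
  a cluster of one contributes zero reconstructed length; an empty usage log
  parses to an empty list (with a warning) and reports all-zero savings.
* Postcode districts are taken as the outward code (text before the final
  3-character inward code, or before the first space). Geocoding is a
  pluggable contract — a CSV lookup table or a deterministic synthetic
  backend hashing postcodes into a UK bounding box — because no live
  geocoding service is a build or test dependency; which granularity a live
  service would resolve to is left to the backend.
* Test problem sizes are scaled for a fast default run (the full suite
  executes in well under a minute): exactness checks enumerate up to 8-point
  instances, the size-invariant property samples 1,000 assignment instances
  and 150 full-pipeline instances.

# Interface decisions

The package surface is function-first (`plan_routes`, `aggregate_report`,
`generate_usage_log` and the parameter constructors); `cmd_plan`,
`cmd_analyze` and `cmd_simulate` wrap complete subcommand behaviours, and
`inst/cli/vialroute.R` is a thin option-parsing shell around them with exit
codes 0 (success), 2 (validation/limit), 3 (format/IO). Configuration lives
in the three parameter objects rather than a config-file format: R users
compose and reuse them directly, and the CLI exposes the commonly varied
fields as flags.

# Known limitations

* Clustering and open-route endpoints are heuristics; neither is optimal in
  general, and the farthest-pair endpoint rule is kept deliberately even
  where better open-route heuristics exist.
* Travel times ignore road networks, traffic and dwell time; the detour
  index is a single national constant.
* The Mercator inflation in the reconstruction (kept for fidelity) means
  absolute reconstructed kilometres overstate ground distance at UK
  latitudes by ~1.66×; comparisons *between* requests are unaffected.
* Cold-chain limits are not enforced — per-route travel-time estimates are
  reported so users can compare them against their vaccine's storage window.
* The cost estimate is a configurable conversion, not an audited figure.
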