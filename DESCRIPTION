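Package: vialroute
Title: Vial-Constrained Route Planning for Home Vaccination Visits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Plans home-visit routes for vaccination campaigns under a
    vial-size constraint: patient locations are partitioned into clusters of a
    fixed size via priority-ordered, capacity-constrained iterative k-means, and
    an optimal visit order is computed within each cluster (exact Held-Karp
    dynamic programming for small clusters, nearest-neighbour with 2-opt
    refinement otherwise), either as a closed tour from a fixed depot or as an
    open route between the farthest-apart pair of patients. Also implements a
    usage-log analysis that converts planned routes into estimated
    planning-time, driving-distance and cost savings: repeat-request detection,
    route-length reconstruction from anonymised relative coordinates
    (Web-Mercator projection with a detour index), a saturating-exponential
    model of human route-planning performance, and aggregate reporting.
    Includes a synthetic-data generator for patient sets and usage logs, a
    pluggable postcode geocoder, GeoJSON export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    geosphere,
    jsonlite,
    minpack.lm,
    readxl,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
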