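# Coordinate handling: postcode normalisation, pluggable geocoding,
# Web-Mercator projection, UK recentring of anonymised relative coordinates,
# distance matrices and patient-file / GeoJSON I/O.

# WGS84-sphere radius used by the spherical (Web) Mercator projection, metres.
EARTH_RADIUS_M <- 6378137

# Half the projected circumference: |x| and |y| of any valid EPSG:3857 point.
WEB_MERCATOR_MAX <- pi * EARTH_RADIUS_M

# Latitude bound of the square Web-Mercator domain.
WEB_MERCATOR_MAX_LAT <- 85.06

# Bounding box containing Great Britain and Northern Ireland, used by the
# synthetic geocoder and the synthetic patient generator.
UK_BBOX <- list(lat_min = 49.9, lat_max = 60.9, lon_min = -8.2, lon_max = 1.8)

# Approximate mid-point of the UK; anonymised relative coordinates are shifted
# here before projection so that metric distances are evaluated at a
# representative UK latitude.
UK_MIDPOINT <- c(lat = 53, lon = -1.2)

#' Construct a validated table of geographic points
#'
#' @param lat,lon Numeric vectors of equal length; WGS84 degrees.
#' @return A `data.frame` with columns `lat` and `lon`.
#' @examples
#' geo_points(c(51.5, 53), c(-0.1, -1.2))
#' @export
geo_points <- function(lat, lon) {
  if (length(lat) != length(lon))
    stop_validation("'lat' and 'lon' must have equal length")
  if (!all(is.finite(lat)) || !all(is.finite(lon)))
    stop_validation("coordinates must be finite")
  if (any(lat < -90 | lat > 90))
    stop_validation("latitude out of [-90, 90]")
  if (any(lon < -180 | lon > 180))
    stop_validation("longitude out of [-180, 180]")
  data.frame(lat = as.numeric(lat), lon = as.numeric(lon))
}

#' Normalise UK postcodes and extract the postal district
#'
#' Uppercases, trims and collapses internal whitespace. The postal district
#' (outward code, e.g. `"OX1"`) is the text before the final 3-character
#' inward code, or before the first space when one is present.
#'
#' @param raw Character vector of postcode text.
#' @return A `data.frame` with columns `raw`, `normalized`, `district`.
#' @examples
#' normalize_postcode(" ox1  2jd ")
#' @export
normalize_postcode <- function(raw) {
  if (!is.character(raw)) stop_validation("'raw' must be character")
  norm <- toupper(gsub("\\s+", " ", trimws(raw)))
  if (any(!nzchar(norm)))
    stop_validation("empty postcode at position %d", which(!nzchar(norm))[1])
  district <- ifelse(
    grepl(" ", norm),
    sub(" .*$", "", norm),
    # no space: strip the trailing 3-character inward code if there is room
    ifelse(nchar(norm) > 3L, substr(norm, 1L, nchar(norm) - 3L), norm)
  )
  data.frame(raw = raw, normalized = norm, district = district)
}

#' Geocoder backed by a postcode lookup table
#'
#' @param table A `data.frame` with columns `postcode`, `lat`, `lon`, or a
#'   path to a CSV file with that header. Postcodes are normalised on load;
#'   duplicates collapse to the first entry.
#' @return A geocoder function: `character -> data.frame(lat, lon)` with `NA`
#'   rows for postcodes absent from the table.
#' @seealso [geocoder_synthetic()], [geocode_batch()]
#' @export
geocoder_table <- function(table) {
  if (is.character(table)) {
    if (!file.exists(table)) stop_io("geocoder table not found: %s", table)
    table <- utils::read.csv(table, stringsAsFactors = FALSE)
  }
  need <- c("postcode", "lat", "lon")
  if (!all(need %in% names(table)))
    stop_format("geocoder table needs columns: %s", paste(need, collapse = ", "))
  key <- normalize_postcode(table$postcode)$normalized
  keep <- !duplicated(key)
  tab <- data.frame(lat = table$lat[keep], lon = table$lon[keep],
                    row.names = key[keep])
  function(postcodes) {
    idx <- match(normalize_postcode(postcodes)$normalized, rownames(tab))
    data.frame(lat = tab$lat[idx], lon = tab$lon[idx])
  }
}

# Deterministic 31-bit polynomial rolling hash of a string; basis for the
# synthetic geocoder so identical postcodes always land on identical points.
string_hash <- function(s, salt = 0L) {
  vapply(s, function(one) {
    h <- (17 + salt) %% 2147483647
    for (code in utf8ToInt(one)) h <- (h * 131 + code) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

#' Deterministic synthetic geocoder
#'
#' Maps any postcode to a stable pseudo-random point inside the UK bounding
#' box (49.9--60.9 N, -8.2--1.8 E) via a hash of the normalised text. Useful
#' for testing the pipeline without a real geocoding service; the points bear
#' no relation to true postcode locations.
#'
#' @param seed Integer mixed into the hash so different tables can be drawn.
#' @return A geocoder function: `character -> data.frame(lat, lon)`.
#' @export
geocoder_synthetic <- function(seed = 0L) {
  force(seed)
  function(postcodes) {
    norm <- normalize_postcode(postcodes)$normalized
    u_lat <- string_hash(norm, salt = seed) / 2147483647
    u_lon <- string_hash(norm, salt = seed + 7919L) / 2147483647
    data.frame(
      lat = UK_BBOX$lat_min + u_lat * (UK_BBOX$lat_max - UK_BBOX$lat_min),
      lon = UK_BBOX$lon_min + u_lon * (UK_BBOX$lon_max - UK_BBOX$lon_min)
    )
  }
}

#' Geocode a batch of postcode records
#'
#' Resolves every record through the supplied backend, preserving order.
#' Unresolved postcodes are never dropped silently: they are returned in a
#' `failures` table alongside the resolved records.
#'
#' @param records Output of [normalize_postcode()], or a character vector of
#'   raw postcodes.
#' @param backend A geocoder function, e.g. from [geocoder_table()] or
#'   [geocoder_synthetic()].
#' @return A list with `records` (the input plus `lat`/`lon` columns, `NA`
#'   where unresolved) and `failures` (rows of `records` that did not resolve,
#'   with their original positions in `index`).
#' @export
geocode_batch <- function(records, backend) {
  if (is.character(records)) records <- normalize_postcode(records)
  if (!is.function(backend)) stop_validation("'backend' must be a function")
  pts <- backend(records$normalized)
  records$lat <- pts$lat
  records$lon <- pts$lon
  bad <- which(is.na(pts$lat) | is.na(pts$lon))
  failures <- records[bad, c("raw", "normalized", "district")]
  failures$index <- bad
  rownames(failures) <- NULL
  list(records = records, failures = failures)
}

#' Forward spherical Web-Mercator projection (EPSG:3857)
#'
#' @param points A `data.frame` with `lat`/`lon` columns (WGS84 degrees);
#'   latitudes must lie strictly inside the Mercator domain (|lat| < 85.06).
#' @return A `data.frame` with columns `x` and `y` in metres.
#' @examples
#' project_web_mercator(geo_points(53, -1.2))
#' @export
project_web_mercator <- function(points) {
  lat <- points$lat; lon <- points$lon
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    stop_validation("coordinates must be finite")
  if (any(abs(lat) >= WEB_MERCATOR_MAX_LAT))
    stop_validation("latitude outside Web-Mercator domain (|lat| < %s)",
                    WEB_MERCATOR_MAX_LAT)
  data.frame(
    x = EARTH_RADIUS_M * lon * pi / 180,
    y = EARTH_RADIUS_M * log(tan(pi / 4 + lat * pi / 360))
  )
}

#' Shift centroid-anonymised relative coordinates back onto the UK
#'
#' Usage logs store patient coordinates relative to their centroid, an
#' irreversible anonymisation. For metric reconstruction the offsets are
#' translated to the approximate mid-point of the UK, (53, -1.2), so that
#' projected distances are evaluated at a representative latitude.
#'
#' @param offsets A two-column matrix or `data.frame` of (lat, lon) offsets in
#'   degrees, centroid approximately at the origin.
#' @param shift Length-2 numeric, degrees added componentwise (lat, lon).
#' @return A `data.frame` of absolute `lat`/`lon` coordinates.
#' @export
recenter_relative <- function(offsets, shift = UK_MIDPOINT) {
  offsets <- as.matrix(offsets)
  if (ncol(offsets) != 2L) stop_validation("'offsets' must have two columns")
  geo_points(offsets[, 1] + shift[[1]], offsets[, 2] + shift[[2]])
}

#' Euclidean distance matrix of projected points
#'
#' @param proj A `data.frame` with `x`/`y` columns in metres (see
#'   [project_web_mercator()]).
#' @return An n x n symmetric matrix of plane distances in metres.
#' @export
pairwise_distances <- function(proj) {
  n <- nrow(proj)
  if (is.null(n) || n < 1L) stop_validation("need at least one point")
  as.matrix(stats::dist(cbind(proj$x, proj$y)))
}

#' Great-circle distance matrix of geographic points
#'
#' Haversine distances on the sphere, an alternative to projected-plane
#' distances that does not carry the Mercator scale inflation
#' (about 1/cos(latitude), roughly 1.66x at 53 N).
#'
#' @param points A `data.frame` with `lat`/`lon` columns (WGS84 degrees).
#' @return An n x n symmetric matrix of distances in metres.
#' @export
haversine_distances <- function(points) {
  m <- cbind(points$lon, points$lat)
  geosphere::distm(m, fun = geosphere::distHaversine)
}

#' Read a patient location file
#'
#' Two upload formats are supported, mirroring how practices export patient
#' lists: an XLSX spreadsheet whose first column holds postcodes, or a CSV
#' with either a `postcode` column or `lat`/`lon` columns (header-detected).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"xlsx"` or `"csv"`.
#' @param max_patients Upload cap; more rows than this is an error.
#' @return For postcode inputs, a postcode record `data.frame` (see
#'   [normalize_postcode()]); for lat/lon CSVs, a [geo_points()] table.
#' @export
read_patient_file <- function(path, format = c("auto", "xlsx", "csv"),
                              max_patients = 300L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_io("file not found: %s", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("xlsx", "xls")) "xlsx" else "csv"
  }
  if (format == "xlsx") {
    sheet <- tryCatch(
      readxl::read_excel(path, sheet = 1, col_names = FALSE, col_types = "text"),
      error = function(e) stop_format("cannot parse XLSX file: %s", conditionMessage(e))
    )
    vals <- as.character(sheet[[1]])
    vals <- vals[!is.na(vals) & nzchar(trimws(vals))]
    # tolerate a header row labelling the column
    if (length(vals) && grepl("^post", tolower(vals[1]))) vals <- vals[-1]
    if (!length(vals)) stop_format("no postcodes found in first column of %s", path)
    check_patient_cap(length(vals), max_patients)
    return(normalize_postcode(vals))
  }
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) stop_format("cannot parse CSV file: %s", conditionMessage(e)))
  names(df) <- tolower(names(df))
  if (all(c("lat", "lon") %in% names(df))) {
    df <- df[!is.na(df$lat) & !is.na(df$lon), , drop = FALSE]
    check_patient_cap(nrow(df), max_patients)
    return(geo_points(df$lat, df$lon))
  }
  if ("postcode" %in% names(df)) {
    vals <- df$postcode[!is.na(df$postcode) & nzchar(trimws(df$postcode))]
    check_patient_cap(length(vals), max_patients)
    return(normalize_postcode(vals))
  }
  stop_format("CSV must have a 'postcode' column or 'lat'/'lon' columns")
}

check_patient_cap <- function(n, max_patients) {
  if (n > max_patients)
    stop_limit("%d locations exceed the configured maximum of %d patients",
               n, max_patients)
  invisible(n)
}

#' Write a route plan as GeoJSON
#'
#' Emits one FeatureCollection: a LineString per cluster tracing the visit
#' order, plus a Point per patient carrying its cluster id and visit rank.
#' GeoJSON coordinate order is (lon, lat) as the format requires.
#'
#' @param result A plan from [plan_routes()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_routes_geojson <- function(result, path) {
  if (!inherits(result, "vialroute_plan") || !length(result$routes))
    stop_validation("'result' must be a non-empty plan")
  pts <- result$patients
  if (is.null(pts))
    stop_validation("GeoJSON output needs lat/lon patient coordinates")
  lonlat <- function(i) {
    if (i == 0L) c(result$depot$lon[1L], result$depot$lat[1L])
    else c(pts$lon[i], pts$lat[i])
  }
  features <- list()
  for (r in result$routes) {
    features[[length(features) + 1L]] <- list(
      type = "Feature",
      geometry = list(type = "LineString",
                      coordinates = lapply(r$order, lonlat)),
      properties = list(cluster = r$cluster, length_m = r$length_m,
                        travel_time_s = r$travel_time_s, closed = r$closed)
    )
  }
  for (r in result$routes) {
    members <- unique(r$order[r$order > 0L])  # 0 marks the depot
    for (rank in seq_along(members)) {
      i <- members[rank]
      features[[length(features) + 1L]] <- list(
        type = "Feature",
        geometry = list(type = "Point", coordinates = lonlat(i)),
        properties = list(cluster = r$cluster, visit_rank = rank, patient = i)
      )
    }
  }
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
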