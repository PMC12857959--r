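# Reading per-animal length records, stratum assignment, binning.

#' Column schema for length-record CSV files
#'
#' Maps the package's canonical field names to the column names of an input
#' file. `length` (total length in mm, anterior eye edge to telson end) and
#' `date` are required; the others are optional.
#'
#' @param length,date,lat,lon,stratum,vessel,nationality Column names.
#' @param window Plausibility window for krill total length, mm; records
#'   outside it are dropped and counted.
#' @return A schema list for [read_length_records].
#' @export
record_schema <- function(length = "length", date = "date", lat = "lat",
                          lon = "lon", stratum = "stratum",
                          vessel = "vessel", nationality = "nationality",
                          window = c(10, 70)) {
  list(length = length, date = date, lat = lat, lon = lon,
       stratum = stratum, vessel = vessel, nationality = nationality,
       window = window)
}

#' Read per-animal length records from CSV
#'
#' Rows with lengths outside the plausibility window or unparseable dates are
#' dropped and counted; the load report is attached as attribute
#' `"load_report"` (kept / dropped per reason).
#'
#' @param path CSV file path.
#' @param schema A [record_schema].
#' @return A tibble of records with columns `length`, `date`, `lat`, `lon`,
#'   `stratum`, `vessel`, `nationality` (missing optionals are `NA`).
#' @export
read_length_records <- function(path, schema = record_schema()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("length", "date")) {
    if (!schema[[col]] %in% names(raw))
      stop("required column missing: ", schema[[col]], call. = FALSE)
  }
  get_opt <- function(col, as = as.character) {
    if (schema[[col]] %in% names(raw)) as(raw[[schema[[col]]]])
    else as(rep(NA, nrow(raw)))
  }
  rec <- tibble::tibble(
    length = as.numeric(raw[[schema$length]]),
    date = as.Date(as.character(raw[[schema$date]])),
    lat = get_opt("lat", as.numeric),
    lon = get_opt("lon", as.numeric),
    stratum = get_opt("stratum"),
    vessel = get_opt("vessel"),
    nationality = get_opt("nationality")
  )
  bad_date <- is.na(rec$date)
  out_window <- !bad_date &
    (is.na(rec$length) | rec$length < schema$window[1] |
       rec$length > schema$window[2])
  keep <- !bad_date & !out_window
  out <- rec[keep, ]
  attr(out, "load_report") <- list(
    read = nrow(rec), kept = sum(keep),
    dropped_out_of_window = sum(out_window),
    dropped_bad_date = sum(bad_date)
  )
  out
}

#' Read stratum polygons from GeoJSON
#'
#' Accepts a FeatureCollection of Polygon (or single-ring MultiPolygon)
#' features; the stratum id is taken from the `name` (or `id`) property.
#' Coordinates are plain lon/lat; no projection is applied.
#'
#' @param path GeoJSON file path.
#' @return A `stratum_map`: named list of two-column (lon, lat) ring
#'   matrices, in declared order.
#' @export
read_strata_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- gj$features
  polys <- list()
  for (f in feats) {
    nm <- f$properties$name
    if (is.null(nm)) nm <- f$properties$id
    if (is.null(nm)) stop("feature without a name/id property", call. = FALSE)
    geom <- f$geometry
    ring <- switch(geom$type,
      Polygon = geom$coordinates[[1]],
      MultiPolygon = geom$coordinates[[1]][[1]],
      stop("unsupported geometry type: ", geom$type, call. = FALSE))
    polys[[nm]] <- do.call(rbind, lapply(ring, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
  }
  if (anyDuplicated(names(polys)))
    stop("duplicate stratum names in map", call. = FALSE)
  structure(polys, class = "stratum_map")
}

#' Build a stratum map from ring coordinates
#'
#' @param ... Named two-column matrices (lon, lat) of polygon rings.
#' @return A `stratum_map`.
#' @export
stratum_map <- function(...) {
  polys <- list(...)
  if (is.null(names(polys)) || any(names(polys) == ""))
    stop("all polygons must be named", call. = FALSE)
  if (anyDuplicated(names(polys)))
    stop("duplicate stratum names", call. = FALSE)
  structure(polys, class = "stratum_map")
}

# Even-odd ray casting with an explicit on-boundary test. Returns TRUE for
# interior and boundary points. (No spatial package in the dependency stack
# provides point-in-polygon for plain lon/lat rings.)
point_in_ring <- function(x, y, ring, tol = 1e-12) {
  n <- nrow(ring)
  xs <- ring[, 1]
  ys <- ring[, 2]
  j <- c(n, seq_len(n - 1))
  # boundary: point collinear with and between segment endpoints
  dx <- xs - xs[j]
  dy <- ys - ys[j]
  cross <- dx * (y - ys[j]) - dy * (x - xs[j])
  on_seg <- abs(cross) <= tol * pmax(1, abs(dx) + abs(dy)) &
    x >= pmin(xs, xs[j]) - tol & x <= pmax(xs, xs[j]) + tol &
    y >= pmin(ys, ys[j]) - tol & y <= pmax(ys, ys[j]) + tol
  if (any(on_seg)) return(TRUE)
  crossings <- (ys > y) != (ys[j] > y) &
    x < (xs[j] - xs) * (y - ys) / (ys[j] - ys) + xs
  sum(crossings) %% 2 == 1
}

#' Assign management strata to records
#'
#' An explicit `stratum` field wins; otherwise the record's lon/lat is tested
#' against the polygons in declared order and the first containing polygon
#' (boundary inclusive) gives the id. Records matching no polygon get
#' `"UNASSIGNED"`.
#'
#' @param records Tibble from [read_length_records] (or compatible).
#' @param map A `stratum_map`.
#' @return `records` with the `stratum` column filled.
#' @export
assign_stratum <- function(records, map) {
  stopifnot(inherits(map, "stratum_map"))
  nms <- names(map)
  need <- is.na(records$stratum) | records$stratum == ""
  idx <- which(need)
  for (i in idx) {
    x <- records$lon[i]
    y <- records$lat[i]
    hit <- "UNASSIGNED"
    if (!is.na(x) && !is.na(y)) {
      for (nm in nms) {
        if (point_in_ring(x, y, map[[nm]])) { hit <- nm; break }
      }
    }
    records$stratum[i] <- hit
  }
  records
}

#' Bin records into length compositions
#'
#' Half-open bins `[edge, edge + width)` anchored at 0 mm: a length exactly
#' on an edge goes to the bin that edge opens. Records with stratum
#' `"UNASSIGNED"` or `NA` are excluded and counted. Cells are
#' `year x stratum`, or `year x month x stratum` with `by_month = TRUE`.
#'
#' @param records Tibble with `length`, `date`, `stratum`.
#' @param bin_width Bin width, mm (default 2).
#' @param by_month Keep months as separate cells?
#' @param grid Optional common [length_grid]; default spans the data.
#' @return Named list of [length_composition] objects with attribute
#'   `"excluded"` (count of unassigned records).
#' @export
bin_composition <- function(records, bin_width = 2, by_month = FALSE,
                            grid = NULL) {
  stopifnot(nrow(records) > 0)
  unas <- is.na(records$stratum) | records$stratum == "UNASSIGNED"
  rec <- records[!unas, ]
  if (is.null(grid)) {
    grid <- length_grid(linf = 1, bin_width = bin_width,
                        l_max = max(rec$length) + bin_width)
  }
  year <- as.integer(format(rec$date, "%Y"))
  month <- as.integer(format(rec$date, "%m"))
  key <- if (by_month) paste(rec$stratum, year, month, sep = ":")
         else paste(rec$stratum, year, sep = ":")
  bin_idx <- floor(rec$length / grid$bin_width) + 1L
  if (max(bin_idx) > length(grid$edges))
    stop("grid does not cover the largest record length", call. = FALSE)
  out <- lapply(split(seq_len(nrow(rec)), key), function(ii) {
    counts <- tabulate(bin_idx[ii], nbins = length(grid$edges))
    length_composition(counts, grid,
                       stratum = rec$stratum[ii[1]],
                       year = year[ii[1]],
                       month = if (by_month) month[ii[1]] else NA_integer_)
  })
  attr(out, "excluded") <- sum(unas)
  out
}
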