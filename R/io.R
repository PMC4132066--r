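#' Column-name schema for GPS fix tables
#'
#' @param id,timestamp,lat,lon Column names in the source CSV.
#' @return A named list used by [read_gps_csv()].
#' @export
gps_schema <- function(id = "id", timestamp = "timestamp",
                       lat = "lat", lon = "lon") {
  list(id = id, timestamp = timestamp, lat = lat, lon = lon)
}

#' Column-name schema for TDR depth tables
#'
#' @param id,timestamp,depth Column names in the source CSV.
#' @return A named list used by [read_tdr_csv()].
#' @export
tdr_schema <- function(id = "id", timestamp = "timestamp",
                       depth = "depth_m") {
  list(id = id, timestamp = timestamp, depth = depth)
}

# Parse ISO-8601 (or "YYYY-mm-dd HH:MM:SS") timestamps to POSIXct UTC.
# Naive timestamps are taken as UTC.  Unparseable rows raise an error
# carrying 1-based data line numbers (header = line 1).
parse_timestamps <- function(x, context = "timestamp") {
  xx <- sub("Z$", "", sub("T", " ", as.character(x)))
  out <- as.POSIXct(xx, tz = "UTC", format = "%Y-%m-%d %H:%M:%OS")
  # date-only fallback
  miss <- is.na(out) & !is.na(xx)
  if (any(miss)) {
    out[miss] <- as.POSIXct(xx[miss], tz = "UTC", format = "%Y-%m-%d")
  }
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop(sprintf("unparseable %s at line(s) %s", context,
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)
  }
  out
}

read_table_checked <- function(path, cols) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(unlist(cols), names(df))
  if (length(missing)) {
    stop(sprintf("configuration error: missing column(s) %s in %s",
                 paste(missing, collapse = ", "), path), call. = FALSE)
  }
  df
}

#' Read a GPS fix table
#'
#' Reads a CSV of timestamped positions, parses timestamps to UTC, drops
#' rows with out-of-range coordinates (with a warning), sorts each
#' individual's fixes by time and collapses exact-duplicate timestamps to
#' their first occurrence.
#'
#' @param path Path to a CSV with columns named per `schema`.
#' @param schema A [gps_schema()].
#' @return A data frame with columns `individual_id`, `time` (POSIXct UTC),
#'   `lat`, `lon`, sorted by individual then time.  Attributes
#'   `n_duplicates_dropped` and `n_range_rejected` record cleaning counts.
#' @export
read_gps_csv <- function(path, schema = gps_schema()) {
  df <- read_table_checked(path, schema)
  if (nrow(df) == 0L) {
    warning("empty GPS file: ", path)
    out <- data.frame(individual_id = character(),
                      time = as_utc(numeric()),
                      lat = numeric(), lon = numeric())
    attr(out, "n_duplicates_dropped") <- 0L
    attr(out, "n_range_rejected") <- 0L
    return(out)
  }
  out <- data.frame(
    individual_id = as.character(df[[schema$id]]),
    time = parse_timestamps(df[[schema$timestamp]]),
    lat = as.numeric(df[[schema$lat]]),
    lon = as.numeric(df[[schema$lon]]),
    stringsAsFactors = FALSE
  )
  bad <- !is.finite(out$lat) | !is.finite(out$lon) |
    out$lat < -90 | out$lat > 90 | out$lon <= -180 | out$lon > 180
  if (any(bad)) {
    warning(sprintf("rejected %d row(s) with coordinate range errors",
                    sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  out <- out[order(out$individual_id, out$time), , drop = FALSE]
  dup <- unlist(tapply(as.numeric(out$time), out$individual_id,
                       function(t) duplicated(t), simplify = FALSE),
                use.names = FALSE)
  if (any(dup)) {
    warning(sprintf("dropped %d duplicate-timestamp fix(es)", sum(dup)))
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "n_duplicates_dropped") <- sum(dup)
  attr(out, "n_range_rejected") <- sum(bad)
  out
}

#' Read a TDR depth table
#'
#' As [read_gps_csv()] but for depth samples.  Negative depths are retained
#' (pre-correction sensor drift is expected); non-finite depths are dropped
#' with a warning.  The modal sampling interval per individual is reported
#' in attribute `interval_s` and a warning is emitted when more than 5% of
#' intervals deviate from the mode.
#'
#' @param path Path to a CSV with columns named per `schema`.
#' @param schema A [tdr_schema()].
#' @return Data frame with columns `individual_id`, `time`, `depth_m`.
#' @export
read_tdr_csv <- function(path, schema = tdr_schema()) {
  df <- read_table_checked(path, schema)
  if (nrow(df) == 0L) {
    warning("empty TDR file: ", path)
    out <- data.frame(individual_id = character(),
                      time = as_utc(numeric()), depth_m = numeric())
    attr(out, "interval_s") <- setNames(numeric(), character())
    return(out)
  }
  out <- data.frame(
    individual_id = as.character(df[[schema$id]]),
    time = parse_timestamps(df[[schema$timestamp]]),
    depth_m = as.numeric(df[[schema$depth]]),
    stringsAsFactors = FALSE
  )
  bad <- !is.finite(out$depth_m)
  if (any(bad)) {
    warning(sprintf("dropped %d non-finite depth sample(s)", sum(bad)))
    out <- out[!bad, , drop = FALSE]
  }
  out <- out[order(out$individual_id, out$time), , drop = FALSE]
  dup <- unlist(tapply(as.numeric(out$time), out$individual_id, duplicated,
                       simplify = FALSE), use.names = FALSE)
  if (any(dup)) {
    warning(sprintf("dropped %d duplicate-timestamp sample(s)", sum(dup)))
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  iv <- vapply(split(as.numeric(out$time), out$individual_id),
               function(t) mode_interval(diff(t)), numeric(1))
  irregular <- vapply(split(as.numeric(out$time), out$individual_id),
                      function(t) {
                        d <- diff(t)
                        if (!length(d)) return(0)
                        mean(abs(d - mode_interval(d)) > 1e-6)
                      }, numeric(1))
  if (any(irregular > 0.05, na.rm = TRUE)) {
    warning("TDR sampling interval irregular for: ",
            paste(names(irregular)[irregular > 0.05], collapse = ", "))
  }
  attr(out, "interval_s") <- iv
  out
}

#' Read a deployment metadata table
#'
#' @param path CSV with columns `id`, `sex` (`female`/`male`/`unknown`),
#'   `nest_id`, `nest_lat`, `nest_lon`, `date` (ISO date).
#' @return Data frame with `individual_id`, `sex`, `nest_id`, `nest_lat`,
#'   `nest_lon`, `deployment_date` (Date).
#' @export
read_deployments_csv <- function(path) {
  cols <- list("id", "sex", "nest_id", "nest_lat", "nest_lon", "date")
  df <- read_table_checked(path, cols)
  sex <- tolower(as.character(df$sex))
  bad_sex <- !sex %in% c("female", "male", "unknown")
  if (any(bad_sex)) {
    warning(sprintf("%d unrecognised sex value(s) set to 'unknown'",
                    sum(bad_sex)))
    sex[bad_sex] <- "unknown"
  }
  out <- data.frame(
    individual_id = as.character(df$id),
    sex = sex,
    nest_id = as.character(df$nest_id),
    nest_lat = as.numeric(df$nest_lat),
    nest_lon = as.numeric(df$nest_lon),
    deployment_date = as.Date(df$date),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out[c("individual_id", "deployment_date")])) {
    stop("duplicate individual_id within a deployment day")
  }
  out
}

#' Read a colony-site configuration (JSON)
#'
#' @param path JSON file with keys `lat`, `lon` and `rafting_radius_m`.
#' @return Named list with `lat`, `lon`, `rafting_radius_m`.
#' @export
read_colony_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$lat) || is.null(x$lon)) {
    stop("colony config must provide lat and lon")
  }
  if (is.null(x$rafting_radius_m)) x$rafting_radius_m <- 1000
  if (x$rafting_radius_m <= 0) stop("rafting_radius_m must be positive")
  x[c("lat", "lon", "rafting_radius_m")]
}

# Format POSIXct columns as ISO-8601 so CSV round-trips are exact at
# 1-second resolution.
format_times_for_csv <- function(df) {
  for (nm in names(df)) {
    if (inherits(df[[nm]], "POSIXct")) df[[nm]] <- fmt_time(df[[nm]])
  }
  df
}

#' Write result tables to a directory
#'
#' Writes each element of a named list of data frames to
#' `<out_dir>/<name>.csv` (header row always written, POSIXct columns as
#' ISO-8601 UTC).
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_results <- function(tables, out_dir) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(format_times_for_csv(tables[[nm]]), p,
                     row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read back a result table written by [write_results()]
#'
#' Columns with time-like names (`time`, `start`, `end`, `departure`,
#' `return`, `t_a`, `t_b`) are re-parsed to POSIXct UTC.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_result_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  timeish <- c("time", "start", "end", "departure", "return", "t_a", "t_b")
  for (nm in intersect(names(df), timeish)) {
    df[[nm]] <- parse_timestamps(df[[nm]], context = nm)
  }
  df
}

#' Export a track as a GeoJSON LineString feature
#'
#' @param track Data frame with `lat`, `lon` (a trip's fixes or an
#'   interpolated track).
#' @param path Output file.
#' @param properties Named list attached to the feature.
#' @return Invisibly, `path`.
#' @export
write_track_geojson <- function(track, path, properties = list()) {
  coords <- lapply(seq_len(nrow(track)),
                   function(i) c(track$lon[i], track$lat[i]))
  gj <- list(
    type = "FeatureCollection",
    features = list(list(
      type = "Feature",
      properties = properties,
      geometry = list(type = "LineString", coordinates = coords)
    ))
  )
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = 10)
  invisible(path)
}
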