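#' Forward-pass speed filter
#'
#' Walks a single individual's time-sorted track keeping a "last retained"
#' fix and drops any fix whose straight-line speed from the last retained
#' fix strictly exceeds `vmax`.  The first fix is always retained.  This is
#' the single-ended variant of the root-mean-square speed filter commonly
#' applied to GPS seabird tracks; only the 2 m s^-1 ceiling is essential.
#'
#' @param fixes Data frame with `time`, `lat`, `lon` (one individual,
#'   time-sorted).
#' @param vmax Speed ceiling in m s^-1 (strict inequality; default 2).
#' @return List with `retained` and `removed` data frames and
#'   `fraction_removed`.
#' @export
speed_filter <- function(fixes, vmax = 2) {
  n <- nrow(fixes)
  if (n < 2L) {
    warning("fewer than 2 fixes: nothing to filter")
    return(list(retained = fixes, removed = fixes[0, , drop = FALSE],
                fraction_removed = 0))
  }
  t <- as.numeric(fixes$time)
  if (is.unsorted(t)) stop("fixes must be time-sorted")
  keep <- logical(n)
  keep[1] <- TRUE
  last <- 1L
  for (i in 2:n) {
    dt <- t[i] - t[last]
    d <- haversine_m(fixes$lat[last], fixes$lon[last],
                     fixes$lat[i], fixes$lon[i])
    if (dt > 0 && d / dt <= vmax) {
      keep[i] <- TRUE
      last <- i
    }
  }
  list(retained = fixes[keep, , drop = FALSE],
       removed = fixes[!keep, , drop = FALSE],
       fraction_removed = mean(!keep))
}

#' Segment a filtered track into complete foraging trips
#'
#' A trip spans from the last fix within `colony_radius_m` of the colony
#' before an excursion to the first fix within that radius after it.
#' Excursions still at sea when the record ends are flagged incomplete and
#' excluded.
#'
#' @param fixes One individual's filtered fixes (`time`, `lat`, `lon`,
#'   optional `individual_id`).
#' @param colony List with `lat`, `lon`.
#' @param colony_radius_m Distance threshold defining "at the colony"
#'   (default 150 m: larger than GPS error, smaller than the rafting
#'   buffer).
#' @return List of `trip` objects (fields `individual_id`,
#'   `departure_time`, `return_time`, `duration_h`, `fixes`); attribute
#'   `n_incomplete` counts excursions without a return.
#' @export
segment_trips <- function(fixes, colony, colony_radius_m = 150) {
  id <- if ("individual_id" %in% names(fixes) && nrow(fixes)) {
    as.character(fixes$individual_id[1])
  } else NA_character_
  if ("individual_id" %in% names(fixes) &&
      length(unique(fixes$individual_id)) > 1L) {
    stop("segment_trips() expects a single individual's fixes")
  }
  n <- nrow(fixes)
  d <- haversine_m(fixes$lat, fixes$lon, colony$lat, colony$lon)
  inside <- d <= colony_radius_m
  trips <- list()
  n_incomplete <- 0L
  i <- 1L
  while (i < n) {
    if (inside[i] && !inside[i + 1L]) {
      j <- i + 1L
      while (j <= n && !inside[j]) j <- j + 1L
      if (j > n) {
        n_incomplete <- n_incomplete + 1L
        break
      }
      tr <- structure(list(
        individual_id = id,
        departure_time = fixes$time[i],
        return_time = fixes$time[j],
        duration_h = as.numeric(fixes$time[j] - fixes$time[i],
                                units = "hours"),
        fixes = fixes[i:j, , drop = FALSE]
      ), class = "trip")
      trips <- c(trips, list(tr))
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (!length(trips) && n_incomplete == 0L) {
    warning("no fix ever leaves the colony radius: zero trips")
  }
  attr(trips, "n_incomplete") <- n_incomplete
  trips
}

#' @export
print.trip <- function(x, ...) {
  cat(sprintf("<trip> %s  %s -> %s  (%.2f h, %d fixes)\n",
              x$individual_id, fmt_time(x$departure_time),
              fmt_time(x$return_time), x$duration_h, nrow(x$fixes)))
  invisible(x)
}

#' Interpolate a trip onto a regular time grid
#'
#' Linear interpolation in latitude and longitude independently between
#' the bracketing retained fixes.  With `align = "departure"` the grid is
#' anchored at the departure time; with `align = "epoch"` grid times are
#' whole multiples of `grid_step_s` since the Unix epoch, so tracks of
#' different individuals share grid instants (required for dyadic
#' distances).
#'
#' @param trip A `trip` from [segment_trips()].
#' @param grid_step_s Grid step in seconds (default 60).
#' @param align `"departure"` or `"epoch"`.
#' @return Data frame `time`, `lat`, `lon` of class `interp_track` with
#'   attributes `individual_id` and `grid_step_s`.
#' @export
interpolate_track <- function(trip, grid_step_s = 60,
                              align = c("departure", "epoch")) {
  align <- match.arg(align)
  t0 <- as.numeric(trip$departure_time)
  t1 <- as.numeric(trip$return_time)
  start <- if (align == "epoch") ceiling(t0 / grid_step_s) * grid_step_s
           else t0
  grid <- seq(start, t1, by = grid_step_s)
  tf <- as.numeric(trip$fixes$time)
  out <- data.frame(
    time = as_utc(grid),
    lat = stats::approx(tf, trip$fixes$lat, xout = grid, ties = "ordered")$y,
    lon = stats::approx(tf, trip$fixes$lon, xout = grid, ties = "ordered")$y
  )
  structure(out, class = c("interp_track", "data.frame"),
            individual_id = trip$individual_id,
            grid_step_s = grid_step_s)
}

#' Summarise a foraging trip
#'
#' @param trip A `trip`.
#' @param colony List with `lat`, `lon` (for maximum range).
#' @return List with `duration_h`, `path_distance_km` (sum of haversine
#'   segment lengths over retained fixes) and `max_range_km` (maximum
#'   distance from the colony).
#' @export
trip_summary <- function(trip, colony) {
  f <- trip$fixes
  n <- nrow(f)
  seg <- if (n > 1L) {
    haversine_m(f$lat[-n], f$lon[-n], f$lat[-1], f$lon[-1])
  } else 0
  list(
    duration_h = trip$duration_h,
    path_distance_km = sum(seg) / 1000,
    max_range_km = max(haversine_m(f$lat, f$lon, colony$lat, colony$lon)) / 1000
  )
}

# Path length (km) along an interpolated track between two instants,
# using the grid points bracketing [start, end].  A zero-duration span
# returns the length of the single bracketing segment.
track_path_km <- function(track, start, end) {
  t <- as.numeric(track$time)
  s <- as.numeric(start); e <- as.numeric(end)
  if (e < t[1] || s > t[length(t)]) return(NA_real_)
  i0 <- max(c(1L, which(t <= s)))
  i1 <- min(c(length(t), which(t >= e)))
  if (i1 <= i0) i1 <- min(i0 + 1L, length(t))
  if (i1 == i0) return(0)
  idx <- i0:i1
  sum(haversine_m(track$lat[idx[-length(idx)]], track$lon[idx[-length(idx)]],
                  track$lat[idx[-1]], track$lon[idx[-1]])) / 1000
}

# Interpolated position(s) on a track at arbitrary instants.
track_locate <- function(track, at) {
  t <- as.numeric(track$time)
  a <- as.numeric(at)
  lat <- stats::approx(t, track$lat, xout = a, ties = "ordered")$y
  lon <- stats::approx(t, track$lon, xout = a, ties = "ordered")$y
  data.frame(time = as_utc(a), lat = lat, lon = lon,
             in_track = a >= t[1] & a <= t[length(t)])
}
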