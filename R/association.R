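#' Association-detection parameters
#'
#' Defaults follow the field-derived rules: a 500 m radius (half the mean
#' bout horizontal distance of about 1 km), a minimum episode duration of
#' one mean dive-bout duration (12.4 min = 744 s), a 4 s dive-synchrony
#' window, a 1,000 m colony buffer inside which surface rafting is
#' excluded, and a 120 s gap-merge tolerance (one nominal GPS sampling
#' interval).
#'
#' @param radius_m Association radius in metres.
#' @param min_duration_s Minimum episode duration in seconds.
#' @param sync_window_s Dive-start synchrony window in seconds.
#' @param rafting_radius_m Colony buffer for rafting exclusion, metres.
#' @param merge_gap_s Maximum gap between runs merged into one episode.
#' @return Named list of class `assoc_params`.
#' @export
assoc_params <- function(radius_m = 500, min_duration_s = 744,
                         sync_window_s = 4, rafting_radius_m = 1000,
                         merge_gap_s = 120) {
  stopifnot(radius_m > 0, min_duration_s > 0, sync_window_s > 0,
            rafting_radius_m > 0, merge_gap_s >= 0)
  structure(list(radius_m = radius_m, min_duration_s = min_duration_s,
                 sync_window_s = sync_window_s,
                 rafting_radius_m = rafting_radius_m,
                 merge_gap_s = merge_gap_s),
            class = c("assoc_params", "list"))
}

#' Dyadic distance series between two interpolated tracks
#'
#' Haversine distance at every grid instant shared by the two tracks
#' (tracks must be interpolated on the same grid step with epoch
#' alignment, see [interpolate_track()]).
#'
#' @param track_a,track_b `interp_track` objects on a common grid.
#' @return Data frame `time`, `dist_m`; zero rows when the trips do not
#'   overlap in time.
#' @export
dyadic_distance_series <- function(track_a, track_b) {
  ta <- as.numeric(track_a$time)
  tb <- as.numeric(track_b$time)
  common <- intersect(ta, tb)
  if (!length(common)) {
    return(data.frame(time = as_utc(numeric()), dist_m = numeric()))
  }
  common <- sort(common)
  ia <- match(common, ta)
  ib <- match(common, tb)
  data.frame(
    time = as_utc(common),
    dist_m = haversine_m(track_a$lat[ia], track_a$lon[ia],
                         track_b$lat[ib], track_b$lon[ib])
  )
}

# Merge interval runs closer than gap_s, then drop those shorter than
# min_s.  Intervals are rows (start, end) in seconds.
merge_and_filter_runs <- function(runs, gap_s, min_s) {
  if (!nrow(runs)) return(runs)
  runs <- runs[order(runs$start), , drop = FALSE]
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      k <- nrow(merged)
      if (runs$start[i] - merged$end[k] <= gap_s) {
        merged$end[k] <- max(merged$end[k], runs$end[i])
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
  }
  merged[merged$end - merged$start >= min_s, , drop = FALSE]
}

#' Detect association episodes from a dyadic distance series
#'
#' Maximal runs of grid instants with distance at or below the radius
#' (boundary inclusive) become candidate episodes; runs separated by gaps
#' of at most `merge_gap_s` are merged; merged runs shorter than
#' `min_duration_s` are discarded.
#'
#' @param distance_series From [dyadic_distance_series()].
#' @param params An [assoc_params()].
#' @param id_a,id_b Identifiers of the dyad (unordered; stored sorted).
#' @return Data frame: `id_a`, `id_b`, `start`, `end`, `duration_s`,
#'   `mean_dist_m`, `min_dist_m`.
#' @export
detect_episodes <- function(distance_series, params = assoc_params(),
                            id_a = "a", id_b = "b") {
  ids <- sort(c(as.character(id_a), as.character(id_b)))
  empty <- data.frame(id_a = character(), id_b = character(),
                      start = as_utc(numeric()), end = as_utc(numeric()),
                      duration_s = numeric(), mean_dist_m = numeric(),
                      min_dist_m = numeric())
  if (!nrow(distance_series)) return(empty)
  t <- as.numeric(distance_series$time)
  inside <- distance_series$dist_m <= params$radius_m
  if (!any(inside)) return(empty)
  r <- rle(inside)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = t[starts[r$values]], end = t[ends[r$values]])
  runs <- merge_and_filter_runs(runs, params$merge_gap_s,
                                params$min_duration_s)
  if (!nrow(runs)) return(empty)
  out <- do.call(rbind, lapply(seq_len(nrow(runs)), function(i) {
    sel <- t >= runs$start[i] & t <= runs$end[i]
    data.frame(id_a = ids[1], id_b = ids[2],
               start = as_utc(runs$start[i]), end = as_utc(runs$end[i]),
               duration_s = runs$end[i] - runs$start[i],
               mean_dist_m = mean(distance_series$dist_m[sel]),
               min_dist_m = min(distance_series$dist_m[sel]))
  }))
  rownames(out) <- NULL
  out
}

#' Remove rafting segments from association episodes
#'
#' Penguins congregate at the surface near the colony ("rafting") before
#' coming ashore; that proximity is not at-sea association.  Episode
#' portions during which both individuals are within `rafting_radius_m`
#' of the colony are trimmed out, and the surviving portions are
#' re-checked against the minimum episode duration.
#'
#' @param episodes From [detect_episodes()] for one dyad.
#' @param track_a,track_b The dyad's interpolated tracks.
#' @param colony List with `lat`, `lon`.
#' @param params An [assoc_params()].
#' @return Filtered/trimmed episode data frame; attribute
#'   `rafting_trimmed_s` records the total time removed.
#' @export
exclude_rafting <- function(episodes, track_a, track_b, colony,
                            params = assoc_params()) {
  if (!nrow(episodes)) {
    attr(episodes, "rafting_trimmed_s") <- 0
    return(episodes)
  }
  ds <- dyadic_distance_series(track_a, track_b)
  t <- as.numeric(ds$time)
  la <- track_locate(track_a, t)
  lb <- track_locate(track_b, t)
  raft <- haversine_m(la$lat, la$lon, colony$lat, colony$lon) <=
            params$rafting_radius_m &
          haversine_m(lb$lat, lb$lon, colony$lat, colony$lon) <=
            params$rafting_radius_m
  kept <- list()
  for (i in seq_len(nrow(episodes))) {
    sel <- t >= as.numeric(episodes$start[i]) &
           t <= as.numeric(episodes$end[i])
    ok <- sel & !raft
    if (!any(ok)) next
    r <- rle(ok[sel])
    tt <- t[sel]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = tt[starts[r$values]],
                       end = tt[ends[r$values]])
    runs <- runs[runs$end - runs$start >= params$min_duration_s, ,
                 drop = FALSE]
    for (j in seq_len(nrow(runs))) {
      sel2 <- t >= runs$start[j] & t <= runs$end[j]
      kept[[length(kept) + 1L]] <- data.frame(
        id_a = episodes$id_a[i], id_b = episodes$id_b[i],
        start = as_utc(runs$start[j]), end = as_utc(runs$end[j]),
        duration_s = runs$end[j] - runs$start[j],
        mean_dist_m = mean(ds$dist_m[sel2]),
        min_dist_m = min(ds$dist_m[sel2]))
    }
  }
  out <- if (length(kept)) do.call(rbind, kept) else episodes[0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rafting_trimmed_s") <-
    sum(episodes$duration_s) - sum(out$duration_s)
  out
}

#' Detect synchronous dive pairs within shared association episodes
#'
#' Greedy earliest-first one-to-one matching: walking individual a's dives
#' in time order, each is matched to the closest not-yet-matched dive of b
#' with |start difference| at most `sync_window_s` (boundary inclusive),
#' both starts falling inside the same association episode.  Ties in
#' |difference| resolve toward the earlier b dive.  Surface distance is
#' the haversine distance between the two interpolated dive-start
#' locations.
#'
#' @param episodes Episodes for the dyad (after rafting exclusion).
#' @param dives_a,dives_b The two individuals' located dive tables
#'   (from [locate_dives()]; plain [detect_dives()] output works but
#'   yields NA surface distances).
#' @param params An [assoc_params()].
#' @return Data frame: `id_a`, `id_b`, `t_a`, `t_b`, `delta_s`,
#'   `surface_dist_m`, plus per-dive `duration_s_a/b`, `max_depth_m_a/b`,
#'   `postdive_s_a/b`.
#' @export
detect_sync_dives <- function(episodes, dives_a, dives_b,
                              params = assoc_params()) {
  empty <- data.frame(id_a = character(), id_b = character(),
                      t_a = as_utc(numeric()), t_b = as_utc(numeric()),
                      delta_s = numeric(), surface_dist_m = numeric(),
                      duration_s_a = numeric(), duration_s_b = numeric(),
                      max_depth_m_a = numeric(), max_depth_m_b = numeric(),
                      postdive_s_a = numeric(), postdive_s_b = numeric())
  if (!nrow(episodes) || !nrow(dives_a) || !nrow(dives_b)) return(empty)
  ep_of <- function(times) {
    vapply(as.numeric(times), function(tt) {
      hit <- which(tt >= as.numeric(episodes$start) &
                   tt <= as.numeric(episodes$end))
      if (length(hit)) hit[1] else NA_integer_
    }, integer(1))
  }
  ea <- ep_of(dives_a$start)
  eb <- ep_of(dives_b$start)
  ta <- as.numeric(dives_a$start)
  tb <- as.numeric(dives_b$start)
  used_b <- rep(FALSE, length(tb))
  rows <- list()
  for (i in order(ta)) {
    if (is.na(ea[i])) next
    cand <- which(!used_b & !is.na(eb) & eb == ea[i] &
                  abs(tb - ta[i]) <= params$sync_window_s)
    if (!length(cand)) next
    d <- abs(tb[cand] - ta[i])
    j <- cand[order(d, tb[cand])][1]
    used_b[j] <- TRUE
    sd <- if (all(c("lat", "lon") %in% names(dives_a)) &&
              all(c("lat", "lon") %in% names(dives_b))) {
      haversine_m(dives_a$lat[i], dives_a$lon[i],
                  dives_b$lat[j], dives_b$lon[j])
    } else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      id_a = episodes$id_a[1], id_b = episodes$id_b[1],
      t_a = dives_a$start[i], t_b = dives_b$start[j],
      delta_s = abs(tb[j] - ta[i]), surface_dist_m = sd,
      duration_s_a = dives_a$duration_s[i],
      duration_s_b = dives_b$duration_s[j],
      max_depth_m_a = dives_a$max_depth_m[i],
      max_depth_m_b = dives_b$max_depth_m[j],
      postdive_s_a = dives_a$postdive_s[i],
      postdive_s_b = dives_b$postdive_s[j])
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Union length (seconds) of a set of intervals given as start/end vectors.
interval_union_s <- function(start, end) {
  if (!length(start)) return(0)
  o <- order(start)
  start <- start[o]; end <- end[o]
  total <- 0
  cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= cur_e) {
      cur_e <- max(cur_e, end[i])
    } else {
      total <- total + (cur_e - cur_s)
      cur_s <- start[i]; cur_e <- end[i]
    }
  }
  total + (cur_e - cur_s)
}

#' Classify a trip's association type
#'
#' Assigns the focal trip one of five categories: 1 (no association),
#' 2 (association only while commuting out of / into the colony),
#' 3a (at-sea association while surface travelling only), 3b (diving
#' asynchronously during association), 3c (synchronous diving).  Commuting
#' windows are the trip segments before the first and after the last dive
#' bout; trips without bouts are treated as all-commute.  The label is the
#' highest degree attained; per-category membership flags are also
#' reported.  Time budgets are percentages of trip duration; total
#' association time is the union of episode intervals so overlapping
#' partners are not double-counted.
#'
#' @param trip The focal `trip`.
#' @param episodes All (rafting-excluded) episodes involving the focal
#'   individual, any partner.
#' @param dives The focal individual's dive table (NULL when no TDR was
#'   deployed: classification is then limited to groups 1/2/3a and
#'   flagged).
#' @param sync_pairs Synchronous dive pairs involving the focal individual
#'   (columns as [detect_sync_dives()]; the focal may be side a or b).
#' @param bouts The focal individual's bout table (for commute windows).
#' @return One-row data frame: `individual_id`, `group`,
#'   `pct_travelling_assoc`, `pct_async_diving_assoc`, `pct_sync_diving`,
#'   `pct_total_assoc`, membership flags and `tdr_limited`.
#' @export
classify_track <- function(trip, episodes, dives = NULL,
                           sync_pairs = NULL, bouts = NULL) {
  id <- trip$individual_id
  dur <- as.numeric(trip$return_time) - as.numeric(trip$departure_time)
  res <- data.frame(
    individual_id = id, group = "1",
    pct_travelling_assoc = 0, pct_async_diving_assoc = 0,
    pct_sync_diving = 0, pct_total_assoc = 0,
    flag_commute_assoc = FALSE, flag_travel_assoc = FALSE,
    flag_async_dive_assoc = FALSE, flag_sync_dive = FALSE,
    tdr_limited = is.null(dives),
    stringsAsFactors = FALSE)
  if (is.null(episodes) || !nrow(episodes)) return(res)

  es <- as.numeric(episodes$start)
  ee <- as.numeric(episodes$end)
  dep <- as.numeric(trip$departure_time)
  ret <- as.numeric(trip$return_time)
  if (!is.null(bouts) && nrow(bouts)) {
    first_bout <- as.numeric(min(bouts$start))
    last_bout <- as.numeric(max(bouts$end))
  } else {
    first_bout <- ret   # whole trip is commute when no bouts exist
    last_bout <- dep
  }
  in_commute <- (ee <= first_bout) | (es >= last_bout)

  total_s <- interval_union_s(pmax(es, dep), pmin(ee, ret))
  res$pct_total_assoc <- 100 * total_s / dur

  # focal dives inside any episode
  sync_s <- 0; async_s <- 0
  any_dive_in_ep <- FALSE; any_sync <- FALSE
  if (!is.null(dives) && nrow(dives)) {
    ds <- as.numeric(dives$start)
    in_ep <- vapply(ds, function(tt) any(tt >= es & tt <= ee), logical(1))
    any_dive_in_ep <- any(in_ep)
    sync_t <- numeric(0)
    if (!is.null(sync_pairs) && nrow(sync_pairs)) {
      sync_t <- c(as.numeric(sync_pairs$t_a[sync_pairs$id_a == id]),
                  as.numeric(sync_pairs$t_b[sync_pairs$id_b == id]))
    }
    is_sync <- ds %in% sync_t
    any_sync <- any(is_sync)
    sync_s <- sum(dives$duration_s[is_sync])
    async_s <- sum(dives$duration_s[in_ep & !is_sync])
  } else if (!is.null(sync_pairs) && nrow(sync_pairs)) {
    any_sync <- any(sync_pairs$id_a == id | sync_pairs$id_b == id)
  }

  res$pct_sync_diving <- 100 * sync_s / dur
  res$pct_async_diving_assoc <- 100 * async_s / dur
  res$pct_travelling_assoc <- max(0, res$pct_total_assoc -
                                    res$pct_sync_diving -
                                    res$pct_async_diving_assoc)
  res$flag_commute_assoc <- any(in_commute)
  res$flag_travel_assoc <- any(!in_commute)
  res$flag_async_dive_assoc <- any_dive_in_ep
  res$flag_sync_dive <- any_sync

  res$group <- if (any_sync) "3c"
    else if (any_dive_in_ep) "3b"
    else if (any(!in_commute)) "3a"
    else "2"
  if (is.null(dives) && res$group == "3b") res$group <- "3a"
  res
}

#' Per-pair association and synchronous-diving summary
#'
#' One row per dyad that shared at least one episode: total association
#' duration (min), number of synchronous dive pairs, and median [range]
#' of the synchronous dives' durations, depths, post-dive intervals
#' (pooled over both members) and surface distances.
#'
#' @param episodes Episode table over all dyads.
#' @param sync_pairs Synchronous dive pairs over all dyads.
#' @return Data frame keyed by `id_a`, `id_b`.
#' @export
pair_summary <- function(episodes, sync_pairs) {
  if (!nrow(episodes)) {
    return(data.frame(id_a = character(), id_b = character(),
                      assoc_min = numeric(), n_sync_dives = integer(),
                      dive_dur_med_s = numeric(), dive_dur_min_s = numeric(),
                      dive_dur_max_s = numeric(), depth_med_m = numeric(),
                      depth_min_m = numeric(), depth_max_m = numeric(),
                      postdive_med_s = numeric(),
                      surface_dist_med_m = numeric()))
  }
  key <- paste(episodes$id_a, episodes$id_b, sep = "/")
  out <- do.call(rbind, lapply(split(episodes, key), function(ep) {
    sp <- if (!is.null(sync_pairs) && nrow(sync_pairs)) {
      sync_pairs[sync_pairs$id_a == ep$id_a[1] &
                 sync_pairs$id_b == ep$id_b[1], , drop = FALSE]
    } else NULL
    durs <- if (!is.null(sp) && nrow(sp)) {
      c(sp$duration_s_a, sp$duration_s_b)
    } else numeric(0)
    deps <- if (!is.null(sp) && nrow(sp)) {
      c(sp$max_depth_m_a, sp$max_depth_m_b)
    } else numeric(0)
    pds <- if (!is.null(sp) && nrow(sp)) {
      c(sp$postdive_s_a, sp$postdive_s_b)
    } else numeric(0)
    pds <- pds[!is.na(pds)]
    sdist <- if (!is.null(sp) && nrow(sp)) sp$surface_dist_m else numeric(0)
    med_or_na <- function(v) if (length(v)) stats::median(v) else NA_real_
    rng_or_na <- function(v, f) if (length(v)) f(v) else NA_real_
    data.frame(
      id_a = ep$id_a[1], id_b = ep$id_b[1],
      assoc_min = sum(ep$duration_s) / 60,
      n_sync_dives = if (is.null(sp)) 0L else nrow(sp),
      dive_dur_med_s = med_or_na(durs),
      dive_dur_min_s = rng_or_na(durs, min),
      dive_dur_max_s = rng_or_na(durs, max),
      depth_med_m = med_or_na(deps),
      depth_min_m = rng_or_na(deps, min),
      depth_max_m = rng_or_na(deps, max),
      postdive_med_s = med_or_na(pds),
      surface_dist_med_m = med_or_na(sdist[!is.na(sdist)]))
  }))
  rownames(out) <- NULL
  out
}

#' Per-deployment-day association summary
#'
#' @param classifications Rows from [classify_track()] (one per trip).
#' @param deployments Deployment metadata ([read_deployments_csv()]).
#' @return One row per deployment date: `date`, `n_instrumented`,
#'   `n_associating` (group other than 1), `pct_associating`.
#' @export
deployment_day_summary <- function(classifications, deployments) {
  m <- merge(classifications, deployments, by = "individual_id")
  out <- do.call(rbind, lapply(split(m, m$deployment_date), function(d) {
    data.frame(date = d$deployment_date[1],
               n_instrumented = nrow(d),
               n_associating = sum(d$group != "1"),
               pct_associating = round(100 * sum(d$group != "1") / nrow(d),
                                       1))
  }))
  rownames(out) <- NULL
  out
}
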