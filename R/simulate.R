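#' Configuration for the synthetic deployment generator
#'
#' The defaults state the world the analysis assumes: out-and-back
#' central-place foraging trips of 14.8 +/- 4.1 h, 2-min GPS and 4-s TDR
#' sampling, dive bouts with a mean duration of 12.4 min (744 s) and a
#' fast within-bout / slow between-bout surface-interval structure, a
#' during-bout ground speed calibrated so a mean bout covers about
#' 0.99 km, 7% GPS outlier fixes, planned dyadic association episodes
#' with a controllable dyadic distance, all-synchronous or all-
#' asynchronous partner dives during episodes, and a pre-landfall
#' surface-rafting segment near the colony.
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param ids Individual identifiers.  Individuals named in
#'   `associations` are generated as coupled pairs; the rest are solitary.
#' @param colony List with `lat`, `lon`.
#' @param deployment_date Date of the simulated deployment day.
#' @param trip_duration_mean_h,trip_duration_sd_h Trip-duration normal
#'   (truncated to 6-24 h).
#' @param gps_step_s,tdr_step_s Sampling intervals, seconds.
#' @param speed_commute_ms,speed_bout_ms Ground speed outside/inside dive
#'   bouts, m s^-1.
#' @param crw_turn_sd Heading innovation SD (radians per GPS step) of the
#'   correlated random walk.
#' @param bout List of bout-structure parameters: `duration_target_s`,
#'   `dive_dur_meanlog`, `dive_dur_sdlog`, `postdive_rate_fast` (s^-1),
#'   `gap_min_s`, `gap_rate_slow` (s^-1; between-bout gap =
#'   `gap_min_s` + Exp(`gap_rate_slow`)), `depth_meanlog`,
#'   `depth_sdlog`, `depth_min_m`, `depth_max_m`.
#' @param associations List of episode plans:
#'   `list(pair = c(id, id), start_frac, duration_s, target_distance_m,
#'   sync = TRUE/FALSE)`.  `start_frac` positions the episode as a
#'   fraction of trip duration.
#' @param far_distance_m Dyadic distance outside planned episodes.
#' @param ramp_s Seconds over which the dyadic offset ramps between
#'   `far_distance_m` and the episode target (kept slow enough that the
#'   partner's ground speed stays below the 2 m s^-1 filter).
#' @param outlier_fix_rate Fraction of GPS fixes displaced so their speed
#'   from the previous fix exceeds 2 m s^-1.
#' @param gps_noise_m Isotropic per-fix GPS error SD, metres.
#' @param rafting_duration_s Stationary near-colony segment appended
#'   before the final return ashore.
#' @param nest_spread_m SD of nest scatter around the colony centre.
#' @param params [assoc_params()] used when deriving ground-truth episode
#'   intervals.
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(
    seed = 1,
    ids = sprintf("P%02d", 1:6),
    colony = list(lat = -38.6219, lon = 142.9325),
    deployment_date = as.Date("2012-10-30"),
    trip_duration_mean_h = 14.8,
    trip_duration_sd_h = 4.1,
    gps_step_s = 120,
    tdr_step_s = 4,
    speed_commute_ms = 1.0,
    speed_bout_ms = 1.37,
    crw_turn_sd = 0.08,
    bout = list(duration_target_s = 744,
                dive_dur_meanlog = log(28), dive_dur_sdlog = 0.45,
                postdive_rate_fast = 0.05, postdive_min_s = 16,
                postdive_max_s = 80,
                gap_min_s = 600, gap_rate_slow = 1 / 300,
                depth_meanlog = log(5), depth_sdlog = 0.7,
                depth_min_m = 1.1, depth_max_m = 26.5),
    associations = list(
      list(pair = c("P01", "P02"), start_frac = 0.35, duration_s = 3600,
           target_distance_m = 300, sync = TRUE),
      list(pair = c("P03", "P04"), start_frac = 0.45, duration_s = 2700,
           target_distance_m = 300, sync = FALSE)),
    far_distance_m = 2200,
    ramp_s = 4200,
    outlier_fix_rate = 0.07,
    gps_noise_m = 7,
    rafting_duration_s = 1500,
    nest_spread_m = 60,
    params = assoc_params()) {
  cfg <- list(seed = seed, ids = ids, colony = colony,
              deployment_date = as.Date(deployment_date),
              trip_duration_mean_h = trip_duration_mean_h,
              trip_duration_sd_h = trip_duration_sd_h,
              gps_step_s = gps_step_s, tdr_step_s = tdr_step_s,
              speed_commute_ms = speed_commute_ms,
              speed_bout_ms = speed_bout_ms,
              crw_turn_sd = crw_turn_sd, bout = bout,
              associations = associations,
              far_distance_m = far_distance_m, ramp_s = ramp_s,
              outlier_fix_rate = outlier_fix_rate,
              gps_noise_m = gps_noise_m,
              rafting_duration_s = rafting_duration_s,
              nest_spread_m = nest_spread_m, params = params)
  plan_ids <- unlist(lapply(associations, `[[`, "pair"))
  if (anyDuplicated(plan_ids)) {
    stop("an individual may appear in at most one association plan")
  }
  if (!all(plan_ids %in% ids)) {
    stop("association plan names unknown individual(s)")
  }
  structure(cfg, class = c("sim_config", "list"))
}

# metres-per-degree helpers consistent with haversine_m at small extents
m_per_deg_lat <- function() pi / 180 * 6371000
enu_to_lonlat <- function(x, y, colony) {
  list(lat = colony$lat + y / m_per_deg_lat(),
       lon = colony$lon + x / (m_per_deg_lat() * cos(colony$lat * pi / 180)))
}

# Draw one individual's bout/dive schedule over [t0, t1] (seconds from
# departure, on the TDR grid).  `anchors` are instants where a bout must
# begin; `forbid` is a 2-column matrix of windows bouts must avoid.
draw_dive_schedule <- function(t0, t1, bout, step, anchors = numeric(0),
                               forbid = NULL) {
  mean_dive <- exp(bout$dive_dur_meanlog + bout$dive_dur_sdlog^2 / 2)
  # post-dive interval is max(postdive_min_s, Exp(rate)); use its true
  # mean so realised bout durations are unbiased for the target
  pd_min <- if (is.null(bout$postdive_min_s)) 0 else bout$postdive_min_s
  pd_max <- if (is.null(bout$postdive_max_s)) Inf else bout$postdive_max_s
  rate <- bout$postdive_rate_fast
  # mean of the doubly truncated interval max(pd_min, min(pd_max, Exp))
  mean_pd <- pd_min + (exp(-rate * pd_min) - exp(-rate * pd_max)) / rate
  nbar <- (bout$duration_target_s + mean_pd) / (mean_dive + mean_pd)
  anchors <- sort(anchors)
  rows <- list()
  bout_id <- 0L
  t <- t0 + bout$gap_min_s + rexp(1, bout$gap_rate_slow)
  snap <- function(t) {
    if (length(anchors)) {
      a <- anchors[1]
      if (t >= a) {            # already past: dives fall inside anyway
        anchors <<- anchors[-1]
      } else if (a - t <= bout$duration_target_s + bout$gap_min_s + 600) {
        anchors <<- anchors[-1]
        return(a)              # start the next bout exactly at the anchor
      }
    }
    t
  }
  repeat {
    t <- snap(t)
    t <- ceiling(t / step) * step
    if (t >= t1) break
    n <- max(2L, rpois(1, nbar))
    durs <- pmax(step, round(rlnorm(n, bout$dive_dur_meanlog,
                                    bout$dive_dur_sdlog) / step) * step)
    pds <- pmax(max(step, pd_min),
                pmin(pd_max,
                     round(rexp(n, bout$postdive_rate_fast) / step) * step))
    starts <- t + cumsum(c(0, durs[-n] + pds[-n]))
    ends <- starts + durs
    if (ends[n] > t1) break   # an over-running final bout would bias
                              # realised bout durations below target
    skip <- FALSE
    if (!is.null(forbid) && nrow(forbid)) {
      for (k in seq_len(nrow(forbid))) {
        if (starts[1] < forbid[k, 2] && ends[n] > forbid[k, 1]) {
          t <- forbid[k, 2] + bout$gap_min_s
          skip <- TRUE
          break
        }
      }
    }
    if (!skip) {
      bout_id <- bout_id + 1L
      rows[[bout_id]] <- data.frame(
        bout_id = bout_id, start = starts, end = ends,
        duration_s = durs, postdive_s = c(pds[-n], NA_real_))
      t <- ends[n] + pds[n] + bout$gap_min_s + rexp(1, bout$gap_rate_slow)
    }
  }
  if (!length(rows)) {
    return(data.frame(bout_id = integer(), start = numeric(),
                      end = numeric(), duration_s = numeric(),
                      postdive_s = numeric()))
  }
  do.call(rbind, rows)
}

# Piecewise-linear dyadic offset magnitude (metres) over trip time.
offset_profile <- function(duration_s, episodes, far, ramp, raft_start,
                           raft_offset = 80) {
  knots_t <- c(0)
  knots_o <- c(60)
  if (nrow(episodes)) {
    for (i in seq_len(nrow(episodes))) {
      knots_t <- c(knots_t, episodes$start[i] - ramp, episodes$start[i],
                   episodes$end[i], episodes$end[i] + ramp)
      knots_o <- c(knots_o, far, episodes$target[i], episodes$target[i],
                   far)
    }
  }
  knots_t <- c(knots_t, raft_start - ramp, raft_start, duration_s)
  knots_o <- c(knots_o, far, raft_offset, raft_offset)
  if (is.unsorted(knots_t, strictly = FALSE)) {
    stop("infeasible association plan: episode/ramp windows overlap")
  }
  function(t) stats::approx(knots_t, knots_o, xout = t, rule = 2)$y
}

#' Simulate one deployment day of GPS/TDR-tracked individuals
#'
#' Generates per-individual GPS fix and TDR depth tables with the
#' statistical structure the analysis pipeline assumes, plus ground-truth
#' labels computed from the clean (noise-free) series by construction.
#' Paired individuals share a correlated-random-walk base path; the
#' partner's position is the focal position plus an offset whose
#' magnitude ramps between a far distance and the planned episode target,
#' so episodes exist by construction with a controllable dyadic distance.
#' Partner dives during planned episodes copy the focal dives with a
#' constant start offset (0 or 4 s for synchronous plans, 12 s for
#' asynchronous), and both pair members raft near the colony before the
#' final return.
#'
#' @param config A [sim_config()].
#' @return List with `gps`, `tdr`, `deployments` (data frames in the
#'   schemas the readers ingest), `colony`, `truth` (list: `trips`,
#'   `dives`, `episodes`, `sync`, `classification`) and `config`.
#' @export
simulate_deployment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_deployment_impl(config))
}

simulate_deployment_impl <- function(cfg) {
  colony <- cfg$colony
  step <- cfg$gps_step_s
  tstep <- cfg$tdr_step_s
  # units: one per pair plus one per solitary individual
  paired <- lapply(cfg$associations, `[[`, "pair")
  solo <- setdiff(cfg$ids, unlist(paired))
  units <- c(lapply(paired, function(p) p), as.list(solo))
  n_units <- length(units)
  bearings <- 2 * pi * (seq_len(n_units) - 1) / n_units +
    runif(n_units, -0.1, 0.1)
  day0 <- as.POSIXct(paste(cfg$deployment_date, "00:00:00"), tz = "UTC")

  gps <- list(); tdr <- list(); dep_rows <- list()
  truth_trips <- list(); truth_dives <- list()
  clean_tracks <- list(); dive_tabs <- list()

  for (u in seq_len(n_units)) {
    members <- units[[u]]
    # trip envelope (shared within a pair)
    D <- 3600 * min(24, max(6, rnorm(1, cfg$trip_duration_mean_h,
                                     cfg$trip_duration_sd_h)))
    D <- round(D / step) * step
    dep_t <- day0 + 5 * 3600 + (u - 1) * step  # pre-dawn departures
    raft_start <- D - cfg$rafting_duration_s
    forage0 <- 0.08 * raft_start
    forage1 <- 0.90 * raft_start

    # planned episodes for this unit
    plans <- Filter(function(a) identical(sort(a$pair), sort(members)),
                    cfg$associations)
    ep <- if (length(plans)) {
      do.call(rbind, lapply(plans, function(a) {
        s <- round(a$start_frac * D / tstep) * tstep
        e <- s + a$duration_s
        if (s - cfg$ramp_s < 600 || e + cfg$ramp_s > raft_start - cfg$ramp_s ||
            e > forage1) {
          stop("infeasible association plan: episode outside the trip ",
               "envelope for pair ", paste(members, collapse = "/"))
        }
        data.frame(start = s, end = e, target = a$target_distance_m,
                   sync = a$sync)
      }))
    } else data.frame(start = numeric(), end = numeric(),
                      target = numeric(), sync = logical())

    # dyadic offset profile (needed both for partner positions and to
    # keep the partner from diving independently while inside the
    # association radius, where accidental 4-s co-timing would corrupt
    # the planned synchrony labels)
    theta <- runif(1, 0, 2 * pi)
    off <- if (length(members) == 2L) {
      offset_profile(D, ep, cfg$far_distance_m, cfg$ramp_s, raft_start)
    } else NULL

    # focal dive schedule, bouts anchored at episode starts
    sched_f <- draw_dive_schedule(forage0, forage1, cfg$bout, tstep,
                                  anchors = ep$start)
    # partner: independent bouts only while far from the focal bird,
    # plus copies of the focal dives inside planned episodes
    sched_list <- list(sched_f)
    if (length(members) == 2L) {
      tg0 <- seq(0, D, by = step)
      near <- off(tg0) <= cfg$params$radius_m + 100
      forbid <- NULL
      if (any(near)) {
        r <- rle(near)
        re <- cumsum(r$lengths); rs <- re - r$lengths + 1L
        forbid <- cbind(tg0[rs[r$values]] - 120, tg0[re[r$values]] + 120)
      }
      if (nrow(ep)) {
        forbid <- rbind(forbid, cbind(ep$start - 300, ep$end + 300))
      }
      sched_p <- draw_dive_schedule(forage0, forage1, cfg$bout, tstep,
                                    forbid = forbid)
      if (nrow(sched_p)) sched_p$bout_id <- sched_p$bout_id + 1000L
      for (i in seq_len(nrow(ep))) {
        sel <- sched_f$start >= ep$start[i] & sched_f$end <= ep$end[i]
        if (!any(sel)) next
        copy <- sched_f[sel, , drop = FALSE]
        delta <- if (ep$sync[i]) sample(c(0, tstep), 1) else 3 * tstep
        copy$start <- copy$start + delta
        copy$end <- copy$end + delta
        copy$bout_id <- copy$bout_id + 2000L
        sched_p <- rbind(sched_p, copy)
      }
      sched_p <- sched_p[order(sched_p$start), , drop = FALSE]
      # recompute partner post-dive intervals from realised starts
      if (nrow(sched_p) > 1L) {
        sched_p$postdive_s <- c(sched_p$start[-1] -
                                  sched_p$end[-nrow(sched_p)], NA_real_)
      }
      sched_list <- c(sched_list, list(sched_p))
    }

    # base path in local ENU metres, speeds raised during focal bouts
    tg <- seq(0, D, by = step)
    ng <- length(tg)
    in_bout <- rep(FALSE, ng)
    for (i in seq_len(nrow(sched_f))) {
      b <- sched_f[i, ]
      in_bout <- in_bout | (tg >= b$start & tg <= b$end)
    }
    # aggregate per-bout coverage: mark grid cells inside any focal bout
    bout_rng <- if (nrow(sched_f)) {
      do.call(rbind, lapply(split(sched_f, sched_f$bout_id), function(b) {
        c(min(b$start), max(b$end))
      }))
    } else NULL
    in_bout <- rep(FALSE, ng)
    if (!is.null(bout_rng)) {
      for (i in seq_len(nrow(bout_rng))) {
        in_bout <- in_bout | (tg >= bout_rng[i, 1] & tg <= bout_rng[i, 2])
      }
    }
    v <- ifelse(in_bout, cfg$speed_bout_ms, cfg$speed_commute_ms)
    t_turn <- raft_start / 2
    out_idx <- tg <= t_turn
    h <- numeric(ng)
    h[1] <- bearings[u]
    for (i in 2:ng) {
      h[i] <- bearings[u] + 0.9 * (h[i - 1] - bearings[u]) +
        rnorm(1, 0, cfg$crw_turn_sd)
    }
    x <- numeric(ng); y <- numeric(ng)
    for (i in 2:ng) {
      ti <- tg[i]
      if (ti <= t_turn) {
        x[i] <- x[i - 1] + v[i - 1] * step * cos(h[i])
        y[i] <- y[i - 1] + v[i - 1] * step * sin(h[i])
      } else break
    }
    iturn <- max(which(out_idx))
    # return leg: retrace the outbound path down to ~400 m from the
    # colony (the rafting spot), rescaled to the return time
    dcol <- sqrt(x[seq_len(iturn)]^2 + y[seq_len(iturn)]^2)
    i400 <- which(dcol >= 400)[1]
    if (is.na(i400)) i400 <- 2L
    ret_idx <- which(tg > t_turn & tg < raft_start)
    if (length(ret_idx)) {
      frac <- (tg[ret_idx] - t_turn) / (raft_start - t_turn)
      xi <- iturn - frac * (iturn - i400)
      x[ret_idx] <- stats::approx(seq_len(iturn), x[seq_len(iturn)],
                                  xout = xi, rule = 2)$y
      y[ret_idx] <- stats::approx(seq_len(iturn), y[seq_len(iturn)],
                                  xout = xi, rule = 2)$y
    }
    raft_x <- x[i400]; raft_y <- y[i400]
    raft_idx <- which(tg >= raft_start & tg <= D - 4 * step)
    x[raft_idx] <- raft_x + rnorm(length(raft_idx), 0, 15)
    y[raft_idx] <- raft_y + rnorm(length(raft_idx), 0, 15)
    x[(ng - 3L):ng] <- raft_x; y[(ng - 3L):ng] <- raft_y

    # per-member positions
    for (m in seq_along(members)) {
      id <- members[m]
      nest <- rnorm(2, 0, cfg$nest_spread_m / sqrt(2))
      nr <- sqrt(sum(nest^2))
      if (nr > 120) nest <- nest * 120 / nr  # keep nests inside colony radius
      if (m == 1L) {
        mx <- x; my <- y
      } else {
        o <- off(tg)
        mx <- x + o * cos(theta); my <- y + o * sin(theta)
      }
      mx[1] <- nest[1]; my[1] <- nest[2]
      # ease the first offshore step so the departure fix chain survives
      # the speed filter even when nest and track lie on opposite sides
      mx[2] <- nest[1] + (mx[3] - nest[1]) * 0.5
      my[2] <- nest[2] + (my[3] - nest[2]) * 0.5
      # gentle landing ramp from this member's rafting spot to its nest,
      # so the final ashore fix survives the 2 m/s speed filter
      fr <- c(0.75, 0.5, 0.25, 0)
      li <- (ng - 3L):ng
      mx[li] <- nest[1] + (mx[ng - 4L] - nest[1]) * fr
      my[li] <- nest[2] + (my[ng - 4L] - nest[2]) * fr
      ll_clean <- enu_to_lonlat(mx, my, colony)
      clean_tracks[[id]] <- data.frame(
        time = as_utc(as.numeric(dep_t) + tg),
        lat = ll_clean$lat, lon = ll_clean$lon)

      # observed fixes: GPS noise + injected outlier displacements
      ox <- mx + rnorm(ng, 0, cfg$gps_noise_m)
      oy <- my + rnorm(ng, 0, cfg$gps_noise_m)
      n_out <- round(cfg$outlier_fix_rate * ng)
      if (n_out > 0) {
        cand <- sample(3:(ng - 2))   # shuffled, keep non-adjacent picks
        pick <- integer(0)
        for (ci in cand) {
          if (!length(pick) || !any(abs(pick - ci) <= 1L)) {
            pick <- c(pick, ci)
          }
          if (length(pick) >= n_out) break
        }
        ang <- runif(length(pick), 0, 2 * pi)
        dd <- runif(length(pick), 500, 800)
        ox[pick] <- ox[pick] + dd * cos(ang)
        oy[pick] <- oy[pick] + dd * sin(ang)
      } else pick <- integer(0)
      ll <- enu_to_lonlat(ox, oy, colony)
      gps[[id]] <- data.frame(
        id = id, timestamp = fmt_time(as.numeric(dep_t) + tg),
        lat = ll$lat, lon = ll$lon, stringsAsFactors = FALSE)

      # TDR record
      sched <- sched_list[[min(m, length(sched_list))]]
      tt <- seq(0, D, by = tstep)
      depth <- numeric(length(tt))
      maxd <- numeric(nrow(sched))
      for (i in seq_len(nrow(sched))) {
        d0 <- min(cfg$bout$depth_max_m,
                  max(cfg$bout$depth_min_m,
                      rlnorm(1, cfg$bout$depth_meanlog,
                             cfg$bout$depth_sdlog)))
        maxd[i] <- d0
        i0 <- sched$start[i] / tstep + 1
        nsamp <- sched$duration_s[i] / tstep
        shape <- 1 - abs(2 * ((seq_len(nsamp) - 0.5) / nsamp) - 1)
        depth[i0:(i0 + nsamp - 1)] <- 1.05 + (d0 - 1.05) * shape
      }
      drift <- runif(1, 0.1, 0.3) +
        seq(0, runif(1, 0.3, 0.7), length.out = length(tt))
      obs_depth <- depth + drift + rnorm(length(tt), 0, 0.02)
      tdr[[id]] <- data.frame(
        id = id, timestamp = fmt_time(as.numeric(dep_t) + tt),
        depth_m = round(obs_depth, 3), stringsAsFactors = FALSE)

      nest_ll <- enu_to_lonlat(nest[1], nest[2], colony)
      dep_rows[[id]] <- data.frame(
        id = id, sex = if (runif(1) < 0.5) "female" else "male",
        nest_id = paste0("N", id), nest_lat = nest_ll$lat,
        nest_lon = nest_ll$lon, date = as.character(cfg$deployment_date),
        stringsAsFactors = FALSE)

      truth_trips[[id]] <- data.frame(
        individual_id = id, departure = as_utc(as.numeric(dep_t)),
        return = as_utc(as.numeric(dep_t) + D), duration_h = D / 3600)
      truth_dives[[id]] <- if (nrow(sched)) data.frame(
        individual_id = id,
        start = as_utc(as.numeric(dep_t) + sched$start),
        end = as_utc(as.numeric(dep_t) + sched$end),
        duration_s = sched$duration_s, max_depth_m = maxd,
        postdive_s = sched$postdive_s, bout_id = sched$bout_id)
      else data.frame(individual_id = character(),
                      start = as_utc(numeric()), end = as_utc(numeric()),
                      duration_s = numeric(), max_depth_m = numeric(),
                      postdive_s = numeric(), bout_id = integer())
    }
  }

  out <- list(
    gps = do.call(rbind, unname(gps[cfg$ids])),
    tdr = do.call(rbind, unname(tdr[cfg$ids])),
    deployments = do.call(rbind, unname(dep_rows[cfg$ids])),
    colony = c(colony, list(rafting_radius_m = cfg$params$rafting_radius_m)),
    config = cfg
  )
  rownames(out$gps) <- rownames(out$tdr) <- NULL
  out$truth <- derive_truth(cfg, clean_tracks, truth_trips, truth_dives)
  out
}

# Ground truth derived from the clean series: episodes from the
# noise-free tracks under the configured association rules; synchronous
# dives from the planned start offsets; classification from the truth
# components.
derive_truth <- function(cfg, clean_tracks, truth_trips, truth_dives) {
  params <- cfg$params
  colony <- cfg$colony
  itracks <- lapply(clean_tracks, function(tr) {
    trip <- structure(list(
      individual_id = NA_character_,
      departure_time = tr$time[1],
      return_time = tr$time[nrow(tr)],
      duration_h = as.numeric(tr$time[nrow(tr)] - tr$time[1],
                              units = "hours"),
      fixes = tr), class = "trip")
    interpolate_track(trip, grid_step_s = 60, align = "epoch")
  })
  pairs <- lapply(cfg$associations, `[[`, "pair")
  eps <- list(); syncs <- list()
  for (p in pairs) {
    a <- sort(p)[1]; b <- sort(p)[2]
    ds <- dyadic_distance_series(itracks[[a]], itracks[[b]])
    e <- detect_episodes(ds, params, a, b)
    e <- exclude_rafting(e, itracks[[a]], itracks[[b]], colony, params)
    eps[[paste(a, b, sep = "/")]] <- e
    plan <- Filter(function(x) identical(sort(x$pair), c(a, b)),
                   cfg$associations)
    if (any(vapply(plan, `[[`, logical(1), "sync"))) {
      da <- truth_dives[[a]]; db <- truth_dives[[b]]
      # partner copies carry bout_id offset by 2000 and a start delta <= 4 s
      copy <- db[db$bout_id > 2000L, , drop = FALSE]
      if (nrow(copy)) {
        ta <- as.numeric(da$start)
        match_i <- vapply(as.numeric(copy$start), function(s) {
          hit <- which(abs(ta - s) <= params$sync_window_s)
          if (length(hit)) hit[1] else NA_integer_
        }, integer(1))
        ok <- !is.na(match_i)
        # only pairs whose focal dive also lies inside a truth episode
        in_ep <- function(tt) {
          nrow(e) > 0 && any(tt >= as.numeric(e$start) &
                             tt <= as.numeric(e$end))
        }
        ok <- ok & vapply(as.numeric(copy$start), in_ep, logical(1))
        if (any(ok)) {
          syncs[[paste(a, b, sep = "/")]] <- data.frame(
            id_a = a, id_b = b,
            t_a = da$start[match_i[ok]], t_b = copy$start[ok],
            delta_s = abs(as.numeric(copy$start[ok]) -
                          as.numeric(da$start[match_i[ok]])))
        }
      }
    }
  }
  episodes <- if (length(eps)) do.call(rbind, unname(eps)) else
    data.frame(id_a = character(), id_b = character(),
               start = as_utc(numeric()), end = as_utc(numeric()),
               duration_s = numeric(), mean_dist_m = numeric(),
               min_dist_m = numeric())
  sync <- if (length(syncs)) do.call(rbind, unname(syncs)) else
    data.frame(id_a = character(), id_b = character(),
               t_a = as_utc(numeric()), t_b = as_utc(numeric()),
               delta_s = numeric())
  rownames(episodes) <- rownames(sync) <- NULL

  cls <- do.call(rbind, lapply(cfg$ids, function(id) {
    tt <- truth_trips[[id]]
    trip <- structure(list(
      individual_id = id, departure_time = tt$departure,
      return_time = tt$return, duration_h = tt$duration_h,
      fixes = NULL), class = "trip")
    de <- truth_dives[[id]]
    ep_i <- episodes[episodes$id_a == id | episodes$id_b == id, ,
                     drop = FALSE]
    sp_i <- sync[sync$id_a == id | sync$id_b == id, , drop = FALSE]
    bouts <- if (nrow(de)) {
      do.call(rbind, lapply(split(de, de$bout_id), function(d) {
        data.frame(bout_id = d$bout_id[1], start = min(d$start),
                   end = max(d$end),
                   duration_min = as.numeric(max(d$end) - min(d$start),
                                             units = "mins"),
                   n_dives = nrow(d))
      }))
    } else NULL
    classify_track(trip, ep_i, dives = if (nrow(de)) de else NULL,
                   sync_pairs = sp_i, bouts = bouts)
  }))
  rownames(cls) <- NULL
  list(trips = do.call(rbind, unname(truth_trips[cfg$ids])),
       dives = do.call(rbind, unname(truth_dives[cfg$ids])),
       episodes = episodes, sync = sync, classification = cls)
}

#' Write a simulated deployment to CSV/JSON files
#'
#' Emits the same schemas the readers ingest: `gps.csv`, `tdr.csv`,
#' `deployments.csv`, `colony.json`, plus ground-truth tables under
#' `truth/`.
#'
#' @param sim Result of [simulate_deployment()].
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_sim_csvs <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(sim$gps, file.path(dir, "gps.csv"), row.names = FALSE)
  utils::write.csv(sim$tdr, file.path(dir, "tdr.csv"), row.names = FALSE)
  utils::write.csv(sim$deployments, file.path(dir, "deployments.csv"),
                   row.names = FALSE)
  jsonlite::write_json(sim$colony, file.path(dir, "colony.json"),
                       auto_unbox = TRUE, digits = 10)
  write_results(sim$truth[c("trips", "dives", "episodes", "sync",
                            "classification")],
                file.path(dir, "truth"))
  invisible(dir)
}
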