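# Shared helpers: small constructed tracks/series and a cached default
# simulated deployment (the simulation + pipeline run is reused by
# several test files to stay inside the time budget).

COLONY <- list(lat = -38.6219, lon = 142.9325, rafting_radius_m = 1000)

M_PER_DEG_LAT <- pi / 180 * 6371000

# place a point x,y metres east/north of the colony
enu_ll <- function(x, y, colony = COLONY) {
  list(lat = colony$lat + y / M_PER_DEG_LAT,
       lon = colony$lon + x / (M_PER_DEG_LAT * cos(colony$lat * pi / 180)))
}

T0 <- as.POSIXct("2012-10-30 05:00:00", tz = "UTC")

# fixes data frame from ENU metre offsets at fixed time step
make_fixes <- function(x, y, step_s = 120, id = "A", t0 = T0) {
  ll <- enu_ll(x, y)
  data.frame(individual_id = id, time = t0 + (seq_along(x) - 1) * step_s,
             lat = ll$lat, lon = ll$lon, stringsAsFactors = FALSE)
}

make_trip <- function(fixes) {
  structure(list(individual_id = fixes$individual_id[1],
                 departure_time = fixes$time[1],
                 return_time = fixes$time[nrow(fixes)],
                 duration_h = as.numeric(fixes$time[nrow(fixes)] -
                                           fixes$time[1], units = "hours"),
                 fixes = fixes), class = "trip")
}

# depth series at 4-s sampling from a vector of depths
make_depths <- function(depth, step_s = 4, id = "A", t0 = T0) {
  data.frame(individual_id = id,
             time = t0 + (seq_along(depth) - 1) * step_s,
             depth_m = depth, stringsAsFactors = FALSE)
}

# convert simulate_deployment() output to the reader-schema data frames
sim_inputs <- function(sim) {
  parse_t <- function(x) as.POSIXct(sub("Z", "", sub("T", " ", x)),
                                    tz = "UTC")
  list(
    gps = data.frame(individual_id = sim$gps$id,
                     time = parse_t(sim$gps$timestamp),
                     lat = sim$gps$lat, lon = sim$gps$lon,
                     stringsAsFactors = FALSE),
    tdr = data.frame(individual_id = sim$tdr$id,
                     time = parse_t(sim$tdr$timestamp),
                     depth_m = sim$tdr$depth_m, stringsAsFactors = FALSE),
    deployments = data.frame(individual_id = sim$deployments$id,
                             sex = sim$deployments$sex,
                             nest_id = sim$deployments$nest_id,
                             nest_lat = sim$deployments$nest_lat,
                             nest_lon = sim$deployments$nest_lon,
                             deployment_date = as.Date(sim$deployments$date),
                             stringsAsFactors = FALSE))
}

# cached default-world simulation + pipeline run (seed 1)
shared_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_deployment(sim_config(seed = 1))
      inp <- sim_inputs(sim)
      res <- suppressMessages(run_pipeline(pipeline_config(
        gps = inp$gps, tdr = inp$tdr, deployments = inp$deployments,
        colony = sim$colony, seed = 1)))
      cache <<- list(sim = sim, inputs = inp, res = res)
    }
    cache
  }
})

# total-time Jaccard overlap between two episode interval sets
episode_jaccard <- function(truth, detected, step = 30) {
  if (!nrow(truth)) return(NA_real_)
  key <- function(e) paste(e$id_a, e$id_b)
  ov <- 0; un <- 0
  for (k in unique(c(key(truth), key(detected)))) {
    ts <- truth[key(truth) == k, , drop = FALSE]
    ds <- detected[key(detected) == k, , drop = FALSE]
    lo <- min(as.numeric(c(ts$start, ds$start)))
    hi <- max(as.numeric(c(ts$end, ds$end)))
    grid <- seq(lo, hi, by = step)
    cover <- function(e) {
      z <- rep(FALSE, length(grid))
      for (i in seq_len(nrow(e))) {
        z <- z | (grid >= as.numeric(e$start[i]) &
                    grid <= as.numeric(e$end[i]))
      }
      z
    }
    a <- cover(ts); b <- cover(ds)
    ov <- ov + sum(a & b); un <- un + sum(a | b)
  }
  ov / un
}
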