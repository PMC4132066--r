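#' Pipeline configuration
#'
#' Bundles input paths (or in-memory tables), stage parameters and the
#' random seed for one end-to-end run.  Paths and data are alternatives:
#' supply `gps`/`tdr`/`deployments` data frames and a `colony` list
#' directly, or the corresponding file paths.
#'
#' @param gps,tdr,deployments Data frames (reader output schemas) or file
#'   paths.  `tdr` may be NULL: the pipeline then runs in GPS-only mode
#'   and classification is limited to groups 1/2/3a.
#' @param colony List with `lat`, `lon` (and optionally
#'   `rafting_radius_m`) or a JSON path.
#' @param out_dir Output directory for the result tables and manifest;
#'   NULL keeps results in memory only.
#' @param vmax_ms Speed-filter ceiling, m s^-1.
#' @param colony_radius_m Trip-segmentation radius, metres.
#' @param grid_step_s Interpolation grid step, seconds.
#' @param dive_threshold_m Minimum dive depth, metres.
#' @param zoc_window_s,zoc_quantile Zero-offset-correction window and
#'   surface quantile.
#' @param bout_variable Criterion variable for the bout model.
#' @param pooled_bec Fit one bout-ending criterion across all trips
#'   (TRUE) or one per trip (FALSE, default).
#' @param params An [assoc_params()].
#' @param n_perm,seed Mantel permutation count and RNG seed.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(gps, tdr = NULL, deployments = NULL,
                            colony = list(lat = -38.6219, lon = 142.9325,
                                          rafting_radius_m = 1000),
                            out_dir = NULL,
                            vmax_ms = 2, colony_radius_m = 150,
                            grid_step_s = 60, dive_threshold_m = 1,
                            zoc_window_s = 300, zoc_quantile = 0.02,
                            bout_variable = "postdive_s",
                            pooled_bec = FALSE,
                            params = assoc_params(),
                            n_perm = 999, seed = 1) {
  structure(list(gps = gps, tdr = tdr, deployments = deployments,
                 colony = colony, out_dir = out_dir, vmax_ms = vmax_ms,
                 colony_radius_m = colony_radius_m,
                 grid_step_s = grid_step_s,
                 dive_threshold_m = dive_threshold_m,
                 zoc_window_s = zoc_window_s, zoc_quantile = zoc_quantile,
                 bout_variable = bout_variable, pooled_bec = pooled_bec,
                 params = params, n_perm = n_perm, seed = seed),
            class = c("pipeline_config", "list"))
}

resolve_input <- function(x, reader) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1L) return(reader(x))
  x
}

#' Run the full association-analysis pipeline
#'
#' Stages, in order: ingest, speed filter, trip segmentation,
#' interpolation (epoch-aligned grid), zero-offset correction, dive
#' detection, bout-ending-criterion fit and bout assignment, dive
#' location, dyadic episode detection, rafting exclusion, synchronous-
#' dive detection, per-trip classification, per-pair and per-day
#' summaries, and group statistics (Mantel nest-distance vs association-
#' time test; Mann-Whitney sex comparison of total association time).
#' Row counts per stage are logged via `message()`.
#'
#' @param config A [pipeline_config()].
#' @return List of result tables (`trips`, `dives`, `bouts`, `episodes`,
#'   `sync_dives`, `classification`, `pairs`, `day_summary`, `bec`),
#'   `stats` (list) and `manifest`.  When `out_dir` is set everything is
#'   also written to disk (CSV + JSON) with a run manifest of MD5 hashes.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  gps <- resolve_input(config$gps, read_gps_csv)
  tdr <- resolve_input(config$tdr, read_tdr_csv)
  deployments <- resolve_input(config$deployments, read_deployments_csv)
  colony <- if (is.character(config$colony)) {
    read_colony_json(config$colony)
  } else config$colony
  if (!is.null(colony$rafting_radius_m)) {
    config$params$rafting_radius_m <- colony$rafting_radius_m
  }
  message(sprintf("[ingest] %d GPS fixes, %d TDR samples, %d individuals",
                  nrow(gps), if (is.null(tdr)) 0L else nrow(tdr),
                  length(unique(gps$individual_id))))

  trips <- list(); tracks <- list(); removed_frac <- c()
  for (id in unique(gps$individual_id)) {
    fx <- gps[gps$individual_id == id, , drop = FALSE]
    sf <- speed_filter(fx, vmax = config$vmax_ms)
    removed_frac[id] <- sf$fraction_removed
    tr <- segment_trips(sf$retained, colony, config$colony_radius_m)
    if (!length(tr)) {
      message(sprintf("[trips] %s: no complete trip", id))
      next
    }
    if (length(tr) > 1L) {
      message(sprintf("[trips] %s: %d trips, analysing the first", id,
                      length(tr)))
    }
    trips[[id]] <- tr[[1]]
    tracks[[id]] <- interpolate_track(tr[[1]], config$grid_step_s,
                                      align = "epoch")
  }
  ids <- names(trips)
  message(sprintf("[filter] mean removal %.1f%%; [trips] %d complete",
                  100 * mean(removed_frac), length(ids)))

  trip_tab <- do.call(rbind, lapply(ids, function(id) {
    s <- trip_summary(trips[[id]], colony)
    data.frame(individual_id = id,
               departure = trips[[id]]$departure_time,
               return = trips[[id]]$return_time,
               duration_h = s$duration_h,
               distance_km = s$path_distance_km,
               max_range_km = s$max_range_km)
  }))

  dives <- list(); bouts <- list(); bec_tab <- list()
  if (!is.null(tdr)) {
    pooled_diffs <- list()
    for (id in ids) {
      sm <- tdr[tdr$individual_id == id, , drop = FALSE]
      if (!nrow(sm)) next
      sm <- sm[as.numeric(sm$time) >= as.numeric(trips[[id]]$departure_time) &
               as.numeric(sm$time) <= as.numeric(trips[[id]]$return_time), ,
               drop = FALSE]
      sm <- zero_offset_correct(sm, config$zoc_window_s,
                                config$zoc_quantile)
      dv <- detect_dives(sm, config$dive_threshold_m)
      if (!nrow(dv)) next
      dives[[id]] <- dv
      pooled_diffs[[id]] <- sequential_differences(dv,
                                                   config$bout_variable)
    }
    all_diffs <- unlist(pooled_diffs, use.names = FALSE)
    tdr_res <- mode_interval(diff(as.numeric(
      tdr$time[tdr$individual_id == tdr$individual_id[1]])))
    if (is.na(tdr_res)) tdr_res <- 0
    pooled_fit <- if (config$pooled_bec && length(all_diffs) >= 2) {
      fit_bout_model(all_diffs, resolution = tdr_res)
    } else NULL
    for (id in names(dives)) {
      fit <- if (config$pooled_bec) pooled_fit else {
        tryCatch(suppressWarnings(
          fit_bout_model(pooled_diffs[[id]], resolution = tdr_res)),
          error = function(e) pooled_fit)
      }
      if (is.null(fit)) {
        fit <- suppressWarnings(fit_bout_model(all_diffs,
                                               resolution = tdr_res))
      }
      ab <- assign_bouts(dives[[id]], fit$bec, config$bout_variable)
      dives[[id]] <- locate_dives(ab$dives, tracks[[id]])
      b <- ab$bouts
      b$individual_id <- id
      b$horiz_km <- vapply(seq_len(nrow(b)), function(i) {
        bout_horizontal_distance(b[i, ], tracks[[id]])
      }, numeric(1))
      bouts[[id]] <- b
      bec_tab[[id]] <- data.frame(individual_id = id, bec_s = fit$bec,
                                  p_fast = fit$p_fast,
                                  lambda_fast = fit$lambda_fast,
                                  lambda_slow = fit$lambda_slow,
                                  n = fit$n)
    }
    message(sprintf("[dives] %d dives in %d bouts",
                    sum(vapply(dives, nrow, integer(1))),
                    sum(vapply(bouts, nrow, integer(1)))))
  }

  episodes <- list(); syncs <- list(); overlap_pairs <- list()
  if (length(ids) > 1L) {
    cmb <- utils::combn(sort(ids), 2)
    for (k in seq_len(ncol(cmb))) {
      a <- cmb[1, k]; b <- cmb[2, k]
      ds <- dyadic_distance_series(tracks[[a]], tracks[[b]])
      if (!nrow(ds)) next
      overlap_pairs[[k]] <- data.frame(a = a, b = b)
      e <- detect_episodes(ds, config$params, a, b)
      e <- exclude_rafting(e, tracks[[a]], tracks[[b]], colony,
                           config$params)
      if (!nrow(e)) next
      episodes[[paste(a, b)]] <- e
      if (!is.null(dives[[a]]) && !is.null(dives[[b]])) {
        sp <- detect_sync_dives(e, dives[[a]], dives[[b]], config$params)
        if (nrow(sp)) syncs[[paste(a, b)]] <- sp
      }
    }
  }
  ep_tab <- if (length(episodes)) {
    do.call(rbind, unname(episodes))
  } else {
    data.frame(id_a = character(), id_b = character(),
               start = as_utc(numeric()), end = as_utc(numeric()),
               duration_s = numeric(), mean_dist_m = numeric(),
               min_dist_m = numeric())
  }
  sync_tab <- if (length(syncs)) do.call(rbind, unname(syncs)) else
    detect_sync_dives(ep_tab[0, ], data.frame(), data.frame(),
                      config$params)
  rownames(ep_tab) <- rownames(sync_tab) <- NULL
  message(sprintf("[associate] %d episodes, %d synchronous dive pairs",
                  nrow(ep_tab), nrow(sync_tab)))

  classification <- do.call(rbind, lapply(ids, function(id) {
    ep_i <- ep_tab[ep_tab$id_a == id | ep_tab$id_b == id, , drop = FALSE]
    sp_i <- sync_tab[sync_tab$id_a == id | sync_tab$id_b == id, ,
                     drop = FALSE]
    classify_track(trips[[id]], ep_i, dives = dives[[id]],
                   sync_pairs = sp_i, bouts = bouts[[id]])
  }))

  pairs_tab <- pair_summary(ep_tab, sync_tab)
  day_tab <- if (!is.null(deployments)) {
    deployment_day_summary(classification, deployments)
  } else NULL

  stats_out <- list()
  if (!is.null(deployments) && length(ids) >= 4L) {
    dpl <- deployments[deployments$individual_id %in% ids, , drop = FALSE]
    nd <- nest_distance_matrix(dpl)
    ov <- if (length(overlap_pairs)) {
      do.call(rbind, overlap_pairs)
    } else NULL
    at <- association_time_matrix(ep_tab, dpl$individual_id, ov)
    mt <- tryCatch(mantel_test(nd, at, n_perm = config$n_perm,
                               seed = config$seed),
                   error = function(e) NULL)
    if (!is.null(mt)) {
      stats_out$mantel <- list(r = mt$r, p = mt$p, n_perm = mt$n_perm,
                               seed = config$seed)
    }
    assoc_time <- classification$pct_total_assoc
    sex <- dpl$sex[match(classification$individual_id,
                         dpl$individual_id)]
    if (sum(sex == "female") > 0 && sum(sex == "male") > 0) {
      u <- mann_whitney(assoc_time[sex == "female"],
                        assoc_time[sex == "male"])
      stats_out$sex_test <- list(U = u$U, p = u$p, n1 = u$n1, n2 = u$n2)
    }
  }

  tables <- list(trips = trip_tab,
                 dives = if (length(dives)) {
                   d <- do.call(rbind, unname(dives)); rownames(d) <- NULL; d
                 } else NULL,
                 bouts = if (length(bouts)) {
                   b <- do.call(rbind, unname(bouts)); rownames(b) <- NULL; b
                 } else NULL,
                 bec = if (length(bec_tab)) {
                   do.call(rbind, unname(bec_tab))
                 } else NULL,
                 episodes = ep_tab, sync_dives = sync_tab,
                 classification = classification,
                 pairs = pairs_tab, day_summary = day_tab)
  tables <- Filter(Negate(is.null), tables)

  manifest <- list(package_version = as.character(utils::packageVersion("divesync")),
                   seed = config$seed,
                   params = unclass(config$params),
                   grid_step_s = config$grid_step_s,
                   vmax_ms = config$vmax_ms)
  if (!is.null(config$out_dir)) {
    paths <- write_results(tables, config$out_dir)
    jsonlite::write_json(stats_out,
                         file.path(config$out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = 10)
    manifest$files <- as.list(tools::md5sum(sort(c(paths,
      file.path(config$out_dir, "stats.json")))))
    names(manifest$files) <- basename(names(manifest$files))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = 10)
  }
  invisible(list(tables = tables, stats = stats_out, manifest = manifest))
}
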