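make_track <- function(x, y, step_s = 60, t0 = T0, id = "A") {
  ll <- enu_ll(x, y)
  structure(data.frame(time = t0 + (seq_along(x) - 1) * step_s,
                       lat = ll$lat, lon = ll$lon),
            class = c("interp_track", "data.frame"),
            individual_id = id, grid_step_s = step_s)
}

test_that("dyadic distance series covers the temporal overlap", {
  n <- 31
  a <- make_track(seq(0, 3000, length.out = n), rep(0, n))
  b <- make_track(seq(0, 3000, length.out = n), rep(300, n), id = "B")
  ds <- dyadic_distance_series(a, b)
  expect_equal(nrow(ds), n)   # length = overlap/step + 1
  expect_equal(ds$dist_m, rep(300, n), tolerance = 1e-3)

  b2 <- make_track(rep(0, 5), rep(0, 5), t0 = T0 + n * 60 + 3600)
  expect_equal(nrow(dyadic_distance_series(a, b2)), 0L)
})

test_that("episode detection applies radius, merge and duration rules", {
  p <- assoc_params()
  # 20 min at 300 m apart -> one episode of 20 min
  n <- 21
  ds <- data.frame(time = T0 + (0:(n - 1)) * 60,
                   dist_m = rep(300, n))
  ep <- detect_episodes(ds, p, "A", "B")
  expect_equal(nrow(ep), 1L)
  expect_equal(ep$duration_s, 1200)
  expect_equal(ep$id_a, "A"); expect_equal(ep$id_b, "B")

  # 10 min is below the 12.4-min minimum unit
  ds10 <- data.frame(time = T0 + (0:10) * 60, dist_m = rep(300, 11))
  expect_equal(nrow(detect_episodes(ds10, p, "A", "B")), 0L)

  # two 8-min runs separated by a 60-s gap merge into 17 min
  # (30-s grid so the outside spell is exactly one minute)
  dist <- c(rep(300, 17), 800, rep(300, 17))
  ds2 <- data.frame(time = T0 + (0:34) * 30, dist_m = dist)
  ep2 <- detect_episodes(ds2, p, "A", "B")
  expect_equal(nrow(ep2), 1L)
  expect_equal(ep2$duration_s, 1020)   # 17 min

  # the boundary is inclusive: exactly radius_m counts as inside
  dsb <- data.frame(time = T0 + (0:20) * 60, dist_m = rep(500, 21))
  expect_equal(nrow(detect_episodes(dsb, p, "A", "B")), 1L)
})

test_that("episodes are symmetric in the dyad", {
  n <- 31
  a <- make_track(seq(0, 3000, length.out = n), rep(0, n))
  b <- make_track(seq(0, 3000, length.out = n), rep(300, n), id = "B")
  e1 <- detect_episodes(dyadic_distance_series(a, b), assoc_params(),
                        "A", "B")
  e2 <- detect_episodes(dyadic_distance_series(b, a), assoc_params(),
                        "B", "A")
  expect_equal(e1, e2)
})

test_that("rafting near the colony is excluded and episodes re-checked", {
  p <- assoc_params()
  n <- 41   # 40 min side by side
  # first 20 min inside the 1 km colony buffer, then straight out to sea
  xa <- c(rep(500, 20), seq(2000, 8000, length.out = n - 20))
  a <- make_track(xa, rep(0, n))
  b <- make_track(xa, rep(300, n), id = "B")
  ds <- dyadic_distance_series(a, b)
  ep <- detect_episodes(ds, p, "A", "B")
  expect_equal(nrow(ep), 1L)
  trimmed <- exclude_rafting(ep, a, b, COLONY, p)
  expect_equal(nrow(trimmed), 1L)
  # rafting half removed; surviving at-sea half starts at fix 21
  expect_gte(as.numeric(trimmed$start), as.numeric(a$time[21]))
  expect_gt(attr(trimmed, "rafting_trimmed_s"), 0)

  # an episode entirely within the buffer disappears
  araft <- make_track(rep(400, 30), rep(0, 30))
  braft <- make_track(rep(400, 30), rep(200, 30), id = "B")
  dsr <- dyadic_distance_series(araft, braft)
  epr <- detect_episodes(dsr, p, "A", "B")
  expect_equal(nrow(exclude_rafting(epr, araft, braft, COLONY, p)), 0L)

  # an episode 5 km out is untouched
  afar <- make_track(rep(5000, 30), rep(0, 30))
  bfar <- make_track(rep(5000, 30), rep(300, 30), id = "B")
  epf <- detect_episodes(dyadic_distance_series(afar, bfar), p, "A", "B")
  epf2 <- exclude_rafting(epf, afar, bfar, COLONY, p)
  expect_equal(epf2$duration_s, epf$duration_s)
})

mk_dives <- function(starts, id = "A", dur = 20, depth = 5) {
  data.frame(individual_id = id, start = starts, end = starts + dur,
             duration_s = dur, max_depth_m = depth,
             postdive_s = c(diff(as.numeric(starts)) - dur, NA),
             lat = COLONY$lat, lon = COLONY$lon + 0.01)
}

ep1 <- data.frame(id_a = "A", id_b = "B", start = T0, end = T0 + 1200,
                  duration_s = 1200, mean_dist_m = 300, min_dist_m = 250)

test_that("synchronous dives obey the 4-s window, inclusively", {
  sp <- detect_sync_dives(ep1, mk_dives(T0 + 100),
                          mk_dives(T0 + 103, id = "B"), assoc_params())
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$delta_s, 3)
  # 5 s misses; exactly 4 s matches
  expect_equal(nrow(detect_sync_dives(ep1, mk_dives(T0 + 100),
                                      mk_dives(T0 + 105, id = "B"),
                                      assoc_params())), 0L)
  expect_equal(nrow(detect_sync_dives(ep1, mk_dives(T0 + 100),
                                      mk_dives(T0 + 104, id = "B"),
                                      assoc_params())), 1L)
  # both dives must fall inside a shared episode
  expect_equal(nrow(detect_sync_dives(ep1, mk_dives(T0 + 2000),
                                      mk_dives(T0 + 2001, id = "B"),
                                      assoc_params())), 0L)
})

test_that("greedy matching is one-to-one and maximal on the spec example", {
  # a-dives at 100 and 104 s, one b-dive at 102 s: exactly one pair
  da <- mk_dives(T0 + c(100, 104))
  db <- mk_dives(T0 + 102, id = "B")
  sp <- detect_sync_dives(ep1, da, db, assoc_params())
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$delta_s, 2)   # earliest a wins the shared b dive

  # brute-force oracle: maximal one-to-one matching size over all
  # assignments of a-dives to b-dives within the window
  brute_max_matching <- function(ta, tb, win = 4) {
    best <- 0
    assign_next <- function(i, used, count) {
      if (i > length(ta)) { best <<- max(best, count); return() }
      assign_next(i + 1, used, count)           # leave a_i unmatched
      for (j in seq_along(tb)) {
        if (!used[j] && abs(tb[j] - ta[i]) <= win) {
          used2 <- used; used2[j] <- TRUE
          assign_next(i + 1, used2, count + 1)
        }
      }
    }
    assign_next(1, rep(FALSE, length(tb)), 0)
    best
  }
  expect_equal(brute_max_matching(c(100, 104), 102), 1L)

  # property: the matching is one-to-one, within-window, and never
  # exceeds the brute-force maximum (the nearest-first tie rule can be
  # submaximal in contrived lattices, so only an upper bound is exact)
  withr::with_seed(31, {
    for (k in 1:25) {
      ta <- sort(sample(seq(0, 60, by = 2), sample(2:5, 1)))
      tb <- sort(sample(seq(0, 60, by = 2), sample(2:5, 1)))
      sp <- detect_sync_dives(ep1, mk_dives(T0 + ta),
                              mk_dives(T0 + tb, id = "B"),
                              assoc_params())
      expect_false(any(duplicated(sp$t_a)))
      expect_false(any(duplicated(sp$t_b)))
      expect_true(all(sp$delta_s <= 4))
      expect_lte(nrow(sp), brute_max_matching(ta, tb))
    }
  })
})

test_that("track classification covers all five groups", {
  trip <- make_trip(make_fixes(c(0, 5000, 0), c(0, 0, 0), step_s = 18000))
  bouts <- data.frame(bout_id = 1L, start = T0 + 9000, end = T0 + 27000,
                      duration_min = 300, n_dives = 10L)
  dives <- mk_dives(T0 + seq(9000, 26000, by = 2000))

  # no episodes -> group 1, all budgets zero
  c1 <- classify_track(trip, ep1[0, ], dives, NULL, bouts)
  expect_equal(c1$group, "1")
  expect_equal(c1$pct_total_assoc, 0)

  # episode wholly inside the outward commute, no dives during it -> 2
  ep_com <- data.frame(id_a = "A", id_b = "B", start = T0 + 600,
                       end = T0 + 2400, duration_s = 1800,
                       mean_dist_m = 300, min_dist_m = 250)
  c2 <- classify_track(trip, ep_com, dives, NULL, bouts)
  expect_equal(c2$group, "2")

  # at-sea episode (inside the bout span, hence not commuting) that
  # contains none of the focal dives -> 3a
  ep_sea <- data.frame(id_a = "A", id_b = "B", start = T0 + 26100,
                       end = T0 + 26900, duration_s = 800,
                       mean_dist_m = 300, min_dist_m = 250)
  c3a <- classify_track(trip, ep_sea, dives, NULL, bouts)
  expect_equal(c3a$group, "3a")

  # dives inside an at-sea episode, no synchrony -> 3b
  ep_dive <- data.frame(id_a = "A", id_b = "B", start = T0 + 9000,
                        end = T0 + 12600, duration_s = 3600,
                        mean_dist_m = 300, min_dist_m = 250)
  c3b <- classify_track(trip, ep_dive, dives, NULL, bouts)
  expect_equal(c3b$group, "3b")
  expect_gt(c3b$pct_async_diving_assoc, 0)

  # with synchronous pairs -> 3c; totals dominate the components
  sp <- data.frame(id_a = "A", id_b = "B", t_a = dives$start[1:3],
                   t_b = dives$start[1:3] + 2, delta_s = 2,
                   surface_dist_m = 50)
  c3c <- classify_track(trip, ep_dive, dives, sp, bouts)
  expect_equal(c3c$group, "3c")
  expect_gte(c3c$pct_total_assoc, c3c$pct_sync_diving)
  expect_gte(c3c$pct_total_assoc,
             c3c$pct_sync_diving + c3c$pct_async_diving_assoc +
               c3c$pct_travelling_assoc - 1e-9)

  # no dive record: limited to 1/2/3a and flagged
  cl <- classify_track(trip, ep_dive, dives = NULL, NULL, NULL)
  expect_true(cl$tdr_limited)
  expect_true(cl$group %in% c("1", "2", "3a"))
})

test_that("classification is deterministic and total", {
  run <- shared_run()
  cls <- run$res$tables$classification
  expect_equal(nrow(cls), 6L)
  expect_true(all(cls$group %in% c("1", "2", "3a", "3b", "3c")))
  expect_true(all(cls$pct_total_assoc >= 0 & cls$pct_total_assoc <= 100))
  again <- suppressMessages(run_pipeline(pipeline_config(
    gps = run$inputs$gps, tdr = run$inputs$tdr,
    deployments = run$inputs$deployments,
    colony = run$sim$colony, seed = 1)))
  expect_identical(again$tables$classification, cls)
})

test_that("pair summary aggregates per dyad", {
  da <- mk_dives(T0 + seq(100, 1000, by = 100))
  db <- mk_dives(T0 + seq(100, 1000, by = 100) + 2, id = "B")
  sp <- detect_sync_dives(ep1, da, db, assoc_params())
  expect_equal(nrow(sp), 10L)
  ps <- pair_summary(ep1, sp)
  expect_equal(ps$n_sync_dives, 10L)
  expect_equal(ps$assoc_min, 20)
  # single sync dive: the range collapses to one value
  sp1 <- detect_sync_dives(ep1, mk_dives(T0 + 100),
                           mk_dives(T0 + 101, id = "B"), assoc_params())
  ps1 <- pair_summary(ep1, sp1)
  expect_equal(ps1$dive_dur_min_s, ps1$dive_dur_max_s)
  expect_equal(ps1$dive_dur_med_s, ps1$dive_dur_min_s)
})

test_that("deployment-day summary counts associating individuals", {
  cls <- data.frame(individual_id = c("A", "B", "C", "D", "E"),
                    group = c("3c", "2", "3b", "1", "1"))
  dpl <- data.frame(individual_id = c("A", "B", "C", "D", "E"),
                    sex = "female", nest_id = "N",
                    nest_lat = COLONY$lat, nest_lon = COLONY$lon,
                    deployment_date = as.Date(c(rep("2012-10-30", 3),
                                                rep("2012-10-31", 2))))
  day <- deployment_day_summary(cls, dpl)
  expect_equal(day$n_instrumented, c(3L, 2L))
  expect_equal(day$n_associating, c(3L, 0L))
  expect_equal(day$pct_associating, c(100, 0))
})
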