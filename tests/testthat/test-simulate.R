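test_that("simulation is deterministic given the seed", {
  s1 <- simulate_deployment(sim_config(seed = 99, ids = c("A", "B"),
                                       associations = list()))
  s2 <- simulate_deployment(sim_config(seed = 99, ids = c("A", "B"),
                                       associations = list()))
  expect_identical(s1$gps, s2$gps)
  expect_identical(s1$tdr, s2$tdr)
  expect_identical(s1$truth$classification, s2$truth$classification)
  s3 <- simulate_deployment(sim_config(seed = 100, ids = c("A", "B"),
                                       associations = list()))
  expect_false(identical(s1$gps, s3$gps))
})

test_that("a plan with no associations yields all group 1", {
  sim <- simulate_deployment(sim_config(seed = 5, ids = c("A", "B", "C"),
                                        associations = list()))
  expect_true(all(sim$truth$classification$group == "1"))
  expect_equal(nrow(sim$truth$episodes), 0L)
})

test_that("zero outlier rate leaves nothing for the speed filter", {
  sim <- simulate_deployment(sim_config(seed = 6, ids = c("A", "B"),
                                        associations = list(),
                                        outlier_fix_rate = 0))
  inp <- sim_inputs(sim)
  for (id in c("A", "B")) {
    sf <- speed_filter(inp$gps[inp$gps$individual_id == id, ])
    expect_equal(nrow(sf$removed), 0L)
  }
})

test_that("infeasible association plans fail before generation", {
  cfg <- sim_config(seed = 1, ids = c("A", "B"),
                    associations = list(list(pair = c("A", "B"),
                                             start_frac = 0.95,
                                             duration_s = 3600,
                                             target_distance_m = 300,
                                             sync = TRUE)))
  expect_error(simulate_deployment(cfg), "infeasible")
  expect_error(sim_config(ids = c("A", "B"),
                          associations = list(list(pair = c("A", "Z"),
                                                   start_frac = 0.4,
                                                   duration_s = 600,
                                                   target_distance_m = 300,
                                                   sync = TRUE))),
               "unknown individual")
})

test_that("ground truth is internally consistent", {
  run <- shared_run()
  truth <- run$sim$truth
  # every planned pair has at least one truth episode; distances stay
  # inside the association radius at every episode instant
  expect_true(all(c("P01/P02", "P03/P04") %in%
                    paste(truth$episodes$id_a, truth$episodes$id_b,
                          sep = "/")))
  expect_true(all(truth$episodes$min_dist_m <= 500))
  expect_true(all(truth$episodes$duration_s >= 744))
  # sync truth only for the synchronous pair, all offsets within 4 s
  expect_true(all(paste(truth$sync$id_a, truth$sync$id_b) == "P01 P02"))
  expect_true(all(truth$sync$delta_s <= 4))
  # dive truth partitions into bouts
  expect_true(all(truth$dives$duration_s > 0))
  expect_true(all(truth$dives$max_depth_m >= 1.1 - 1e-9))
  # classification truth covers the designed mix of groups
  expect_setequal(truth$classification$group, c("3c", "3b", "1"))
})

test_that("realism targets hold for the generated world", {
  # pool several seeded deployments of solitary birds (> 50 trips total
  # would exceed the time budget; 3 x 6 trips already pins the means)
  td <- c(); tb <- c()
  for (sd in 1:3) {
    sim <- simulate_deployment(sim_config(seed = 300 + sd,
                                          ids = sprintf("S%d", 1:6),
                                          associations = list()))
    td <- c(td, sim$truth$trips$duration_h)
    dv <- sim$truth$dives
    key <- paste(dv$individual_id, dv$bout_id)
    tb <- c(tb, (tapply(as.numeric(dv$end), key, max) -
                   tapply(as.numeric(dv$start), key, min)) / 60)
  }
  expect_lt(abs(mean(td) - 14.8), 2 * 4.1 / sqrt(length(td)) + 0.5)
  expect_lt(abs(mean(tb) - 12.4), 2 * sd(tb) / sqrt(length(tb)))
})

test_that("published fixtures are internally consistent", {
  t1 <- deployment_day_fixture()
  expect_equal(nrow(t1), 22L)
  expect_equal(t1$pct_associating,
               round(100 * t1$n_associating / t1$n_instrumented, 1))
  t3 <- sync_pair_fixture()
  expect_equal(nrow(t3), 20L)
  expect_true(all(t3$n_sync_dives >= 1))
  cnt <- track_count_fixture()
  expect_equal(cnt$n_no_assoc + (cnt$n_tracks - cnt$n_no_assoc),
               cnt$n_tracks)
})

test_that("simulated deployments round-trip through the CSV writers", {
  dir <- withr::local_tempdir()
  sim <- simulate_deployment(sim_config(seed = 7, ids = c("A", "B"),
                                        associations = list()))
  write_sim_csvs(sim, dir)
  gps <- read_gps_csv(file.path(dir, "gps.csv"))
  expect_equal(nrow(gps), nrow(sim$gps))
  expect_equal(sort(unique(gps$individual_id)), c("A", "B"))
  tdr <- read_tdr_csv(file.path(dir, "tdr.csv"))
  expect_equal(unname(attr(tdr, "interval_s")), c(4, 4))
  col <- read_colony_json(file.path(dir, "colony.json"))
  expect_equal(col$lat, sim$colony$lat)
  expect_true(file.exists(file.path(dir, "truth", "classification.csv")))
})
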