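#' Published deployment-day summary fixture
#'
#' Machine-readable copy of the published per-deployment-day counts for
#' the London Bridge little penguin colony study: individuals
#' instrumented, individuals associating for at least one dive-bout-
#' duration unit, the resulting percentage, and the estimated number of
#' adults foraging from the colony that day.  Used by the acceptance
#' tests as a worked example for [deployment_day_summary()]-style
#' arithmetic.
#'
#' @return Data frame with 22 deployment-day rows.
#' @export
deployment_day_fixture <- function() {
  df <- data.frame(
    date = as.Date(c(
      "2011-10-01", "2011-10-03", "2011-10-04", "2011-10-18",
      "2012-08-20", "2012-08-22", "2012-08-23", "2012-09-25",
      "2012-09-26", "2012-09-27", "2012-10-30", "2012-10-31",
      "2012-11-20", "2012-11-21", "2012-11-22", "2012-12-02",
      "2012-12-03", "2012-12-12", "2012-12-13", "2013-01-18",
      "2013-01-19", "2013-01-21")),
    n_instrumented = c(3L, 5L, 7L, 3L, 5L, 5L, 3L, 3L, 2L, 2L, 4L, 4L,
                       3L, 2L, 2L, 3L, 2L, 4L, 4L, 3L, 3L, 2L),
    n_associating = c(3L, 5L, 7L, 3L, 3L, 5L, 2L, 2L, 0L, 2L, 3L, 3L,
                      3L, 2L, 0L, 3L, 0L, 2L, 3L, 2L, 3L, 2L),
    pct_associating = c(100, 100, 100, 100, 60, 100, 66.7, 66.7, 0, 100,
                        75, 75, 100, 100, 0, 100, 0, 50, 75, 66.7, 100,
                        100),
    n_foraging_at_sea = c(46L, 46L, 43L, 59L, 24L, 24L, 24L, 39L, 39L,
                          39L, 39L, 39L, 35L, 35L, 35L, 22L, 22L, 22L,
                          22L, 32L, 32L, 32L)
  )
  df
}

#' Published synchronous-diving pair fixture
#'
#' Machine-readable copy of the published per-pair synchronous-diving
#' summary: association duration (min), number of synchronous dives, and
#' median dive duration, depth, post-dive duration and surface distance
#' per pair.  Range columns from the printed table are omitted where the
#' source text was not machine-recoverable.
#'
#' @return Data frame with 20 pair rows.
#' @export
sync_pair_fixture <- function() {
  data.frame(
    pair = c("ID35/ID56", "ID48/ID49", "ID29/ID41", "ID28/ID49",
             "ID5/ID6", "ID1/ID2", "ID11/ID15", "ID24/ID82",
             "ID14/ID16", "ID13/ID19", "ID63/ID65", "ID66/ID69",
             "ID15/ID17", "ID19/ID20", "ID29/ID40", "ID37/ID57",
             "ID50/ID52", "ID6/ID8", "ID12/ID14", "ID40/ID41"),
    assoc_min = c(4, 4.7, 4.9, 12.2, 12.5, 18.5, 21.3, 27.9, 32.7, 34.5,
                  83.7, 91.2, 121.1, 135.7, 178.8, 199.5, 248.9, 276.2,
                  357.3, 479.5),
    n_sync_dives = c(1L, 4L, 5L, 3L, 6L, 2L, 4L, 5L, 4L, 4L, 20L, 9L,
                     3L, 8L, 11L, 3L, 57L, 70L, 30L, 68L),
    dive_dur_med_s = c(4, 18, 14, 8, 36, 28, 28, 24, 28, 40, 28, 8, 42,
                       38, 10, 10, 32, 40, 44, 12),
    depth_med_m = c(1.1, 2.8, 2.9, 4.3, 10.6, 4.5, 6.2, 5.4, 9.2, 12.9,
                    8.0, 3.6, 16.9, 11.6, 2.3, 2.8, 8.2, 11.1, 12.1,
                    2.4),
    postdive_med_s = c(NA, 50, 72, 4, 16, 20, 38, 20, 26, 28, 24, 44,
                       34, 32, 62, 46, 20, 20, 20, 30),
    surface_dist_med_m = c(290.1, 329.1, 48.3, 495.3, 63.0, 375.2, 317.2,
                           112.6, 344.7, 79.4, 218.9, 141.1, 203.2, 49.3,
                           97.1, 94.9, 201.8, 39.4, 34.1, 119.1)
  )
}

#' Published track-classification counts
#'
#' Headline counts over the 84 recorded foraging tracks: 26 tracks with no
#' association, 39 with asynchronous diving while associated, 32 with
#' synchronous diving.
#'
#' @return Named list `n_tracks`, `n_no_assoc`, `n_commute`,
#'   `n_travel_only`, `n_async_dive`, `n_sync_dive`.
#' @export
track_count_fixture <- function() {
  list(n_tracks = 84L, n_no_assoc = 26L, n_commute = 10L,
       n_travel_only = 6L, n_async_dive = 39L, n_sync_dive = 32L)
}
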