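#' Zero-offset correction of a depth record
#'
#' Pressure sensors drift, so surface readings sit away from 0 m.  The
#' record is cut into consecutive windows of `window_s`; the surface
#' baseline in each window is a low quantile of its depths; baselines are
#' linearly interpolated between window centres, subtracted, and corrected
#' depths below 0 are clamped to 0.
#'
#' @param samples Data frame with `time`, `depth_m` for one deployment at a
#'   constant sampling interval.
#' @param window_s Baseline window length in seconds (default 300; must
#'   cover at least 3 samples).
#' @param quantile Surface quantile within each window (default 0.02).
#' @return `samples` with corrected `depth_m`; attribute `baseline` holds
#'   the subtracted per-sample baseline.
#' @export
zero_offset_correct <- function(samples, window_s = 300, quantile = 0.02) {
  n <- nrow(samples)
  if (n == 0L) return(samples)
  t <- as.numeric(samples$time)
  interval <- mode_interval(diff(t))
  if (is.na(interval)) interval <- window_s
  k <- max(1L, round(window_s / interval))
  if (k < 3L) stop("ZOC window shorter than 3 samples")
  win <- floor((seq_len(n) - 1L) / k)
  centres <- tapply(seq_len(n), win, function(i) mean(i))
  base_w <- tapply(samples$depth_m, win, stats::quantile,
                   probs = quantile, names = FALSE)
  baseline <- if (length(base_w) > 1L) {
    stats::approx(as.numeric(centres), as.numeric(base_w),
                  xout = seq_len(n), rule = 2)$y
  } else rep(as.numeric(base_w), n)
  samples$depth_m <- pmax(0, samples$depth_m - baseline)
  attr(samples, "baseline") <- baseline
  samples
}

#' Detect dives in a corrected depth record
#'
#' A dive is a maximal run of samples at or below `dive_threshold_m`
#' (depth positive downward, so "at least 1 m deep").  The dive starts at
#' the first submerged sample and ends one sampling interval after the
#' last, so an n-sample dive lasts n x interval seconds.  The post-dive
#' interval is the surface time until the next dive's start (NA for the
#' last dive).
#'
#' @param samples Corrected depth samples (`time`, `depth_m`, optional
#'   `individual_id`), one deployment.
#' @param dive_threshold_m Minimum dive depth in metres (default 1).
#' @return Data frame: `individual_id`, `start`, `end` (POSIXct),
#'   `duration_s`, `max_depth_m`, `postdive_s`.
#' @export
detect_dives <- function(samples, dive_threshold_m = 1) {
  id <- if ("individual_id" %in% names(samples) && nrow(samples)) {
    as.character(samples$individual_id[1])
  } else NA_character_
  empty <- data.frame(individual_id = character(), start = as_utc(numeric()),
                      end = as_utc(numeric()), duration_s = numeric(),
                      max_depth_m = numeric(), postdive_s = numeric())
  if (nrow(samples) == 0L) return(empty)
  t <- as.numeric(samples$time)
  interval <- mode_interval(diff(t))
  wet <- samples$depth_m >= dive_threshold_m
  if (!any(wet)) return(empty)
  r <- rle(wet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ws <- starts[r$values]
  we <- ends[r$values]
  out <- data.frame(
    individual_id = id,
    start = as_utc(t[ws]),
    end = as_utc(t[we] + interval),
    duration_s = (t[we] + interval) - t[ws],
    max_depth_m = vapply(seq_along(ws), function(i) {
      max(samples$depth_m[ws[i]:we[i]])
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  nd <- nrow(out)
  out$postdive_s <- c(as.numeric(out$start[-1]) - as.numeric(out$end[-nd]),
                      NA_real_)
  out
}

#' Absolute sequential differences of a dive variable
#'
#' The input to the bout-ending-criterion fit: |x(i+1) - x(i)| over
#' successive dives of one trip, after dropping the undefined terminal
#' post-dive interval.
#'
#' @param dives Data frame from [detect_dives()].
#' @param variable Column to difference (default `"postdive_s"`;
#'   `"duration_s"` is the common alternative).
#' @return Numeric vector of non-negative differences.
#' @export
sequential_differences <- function(dives, variable = "postdive_s") {
  x <- dives[[variable]]
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(numeric(0))
  abs(diff(x))
}

#' Closed-form bout-ending criterion of the two-process model
#'
#' For a mixture density p lf exp(-lf t) + (1-p) ls exp(-ls t) with a fast
#' within-bout process (rate `lambda_fast`) and a slow between-bout process
#' (rate `lambda_slow`), the criterion at which an interval is equally
#' likely under either process is
#' `log((p * lf) / ((1 - p) * ls)) / (lf - ls)`.
#'
#' @param p_fast Mixture proportion of the fast process (0-1).
#' @param lambda_fast,lambda_slow Process rates in s^-1
#'   (`lambda_fast > lambda_slow > 0`).
#' @return The bout-ending criterion in the units of 1/rate (seconds).
#' @export
bec_closed_form <- function(p_fast, lambda_fast, lambda_slow) {
  stopifnot(lambda_fast > lambda_slow, lambda_slow > 0,
            p_fast > 0, p_fast < 1)
  log((p_fast * lambda_fast) / ((1 - p_fast) * lambda_slow)) /
    (lambda_fast - lambda_slow)
}

#' Draw from the two-process exponential mixture
#'
#' @param n Number of draws.
#' @param p_fast,lambda_fast,lambda_slow Mixture parameters as in
#'   [bec_closed_form()].
#' @return Numeric vector of n non-negative draws.
#' @export
rbout_mixture <- function(n, p_fast, lambda_fast, lambda_slow) {
  fast <- runif(n) < p_fast
  ifelse(fast, rexp(n, lambda_fast), rexp(n, lambda_slow))
}

mixture_nll <- function(par, x, resolution = 0) {
  p <- plogis(par[1])
  ls <- exp(par[2])
  lf <- ls + exp(par[3])
  if (resolution > 0) {
    # interval-censored: observations are rounded to the sampling grid,
    # so score P(T in [x - w/2, x + w/2]) instead of the density (the
    # density form degenerates when many values tie at 0)
    lo <- pmax(0, x - resolution / 2)
    hi <- x + resolution / 2
    pr <- p * (exp(-lf * lo) - exp(-lf * hi)) +
      (1 - p) * (exp(-ls * lo) - exp(-ls * hi))
    v <- -sum(log(pmax(pr, 1e-300)))
  } else {
    a <- log(p) + log(lf) - lf * x
    b <- log1p(-p) + log(ls) - ls * x
    m <- pmax(a, b)
    v <- -sum(m + log(exp(a - m) + exp(b - m)))
  }
  if (!is.finite(v)) return(1e12)
  v
}

#' Fit the two-process bout model by maximum likelihood
#'
#' Maximises the mixture log-likelihood
#' sum(log(p lf exp(-lf t) + (1-p) ls exp(-ls t))) over (p, lf, ls) with
#' 0 < p < 1 and lf > ls > 0 (enforced by reparameterisation), using a
#' method-of-moments start from a median split plus jittered restarts
#' (deterministic: the jitter stream is seeded internally).  The
#' bout-ending criterion (BEC) follows from [bec_closed_form()].
#'
#' @param differences Non-negative criterion values (typically from
#'   [sequential_differences()]); a warning is emitted below n = 30.
#' @param n_starts Number of jittered restarts beyond the moment start.
#' @param resolution Sampling resolution of the criterion values in
#'   seconds.  0 (default) scores the continuous mixture density; a
#'   positive value (e.g. the TDR sampling interval) switches to an
#'   interval-censored likelihood, which is required for gridded data:
#'   with many exactly-tied values the continuous density is unbounded in
#'   `lambda_fast` and the fit degenerates.
#' @return Object of class `bout_fit`: `p_fast`, `lambda_fast`,
#'   `lambda_slow`, `bec`, `loglik`, `n`, `converged`.
#' @export
fit_bout_model <- function(differences, n_starts = 5, resolution = 0) {
  x <- differences[!is.na(differences)]
  n <- length(x)
  if (n < 2L) stop("need at least 2 criterion values")
  if (diff(range(x)) < sqrt(.Machine$double.eps)) {
    stop("degenerate data: all criterion values equal")
  }
  if (n < 30L) warning("fewer than 30 criterion values: fit may be unstable")
  med <- stats::median(x)
  fast <- x[x <= med]
  slow <- x[x > med]
  lf0 <- 1 / max(mean(fast), 1e-6)
  ls0 <- 1 / max(mean(slow), 1e-6)
  if (ls0 >= lf0) { ls0 <- lf0 / 10 }
  base <- c(qlogis(0.5), log(ls0), log(lf0 - ls0))
  starts <- list(base)
  jit <- with_seed(20140813, matrix(rnorm(3 * n_starts, 0, 0.6),
                                    ncol = 3))
  for (i in seq_len(n_starts)) starts[[i + 1L]] <- base + jit[i, ]
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(s, mixture_nll, x = x, resolution = resolution,
                   method = "L-BFGS-B",
                   lower = c(-15, -25, -25), upper = c(15, 5, 5),
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("bout model fit failed from every start")
  p <- plogis(best$par[1])
  ls <- exp(best$par[2])
  lf <- ls + exp(best$par[3])
  if (p * lf <= (1 - p) * ls) {
    stop("degenerate fit: fast process not dominant at t = 0 (BEC <= 0)")
  }
  structure(list(
    p_fast = p, lambda_fast = lf, lambda_slow = ls,
    bec = bec_closed_form(p, lf, ls),
    loglik = -best$value, n = n,
    converged = best$convergence == 0
  ), class = "bout_fit")
}

#' @export
print.bout_fit <- function(x, ...) {
  cat(sprintf(
    "<bout_fit> p_fast=%.3f  lambda_fast=%.4g  lambda_slow=%.4g  BEC=%.1f s  (n=%d, loglik=%.1f)\n",
    x$p_fast, x$lambda_fast, x$lambda_slow, x$bec, x$n, x$loglik))
  invisible(x)
}

#' Group dives into bouts using a bout-ending criterion
#'
#' Each dive carries a criterion value: its pre-dive surface interval,
#' i.e. the previous dive's `variable` (undefined for the first dive).
#' A dive starts a new bout when the sequential difference from the
#' previous dive's criterion value rises by at least `bec` — an
#' ascent-only rule: only a jump *up* into a long surface interval marks
#' a boundary.  (The naive rule on absolute differences fires twice per
#' boundary, once on the jump and once on the drop back, isolating every
#' bout's last dive; the descent is therefore ignored.)  A dive whose
#' predecessor has no defined criterion value is judged on its own raw
#' pre-dive interval against `bec`.
#'
#' @param dives Data frame from [detect_dives()] (one trip, time-sorted).
#' @param bec Bout-ending criterion in the units of `variable`.
#' @param variable Criterion variable (default `"postdive_s"`).
#' @return List with `dives` (input plus `bout_id`) and `bouts` (one row
#'   per bout: `bout_id`, `start`, `end`, `duration_min`, `n_dives`).
#' @export
assign_bouts <- function(dives, bec, variable = "postdive_s") {
  n <- nrow(dives)
  if (n == 0L) {
    return(list(dives = dives,
                bouts = data.frame(bout_id = integer(),
                                   start = as_utc(numeric()),
                                   end = as_utc(numeric()),
                                   duration_min = numeric(),
                                   n_dives = integer())))
  }
  x <- dives[[variable]]
  pre <- c(NA_real_, x[-n])   # pre-dive interval attached to each dive
  new_bout <- logical(n)
  new_bout[1] <- TRUE
  if (n > 1L) {
    for (i in 2:n) {
      new_bout[i] <- if (is.na(pre[i])) {
        TRUE
      } else if (i == 2L || is.na(pre[i - 1L])) {
        pre[i] >= bec
      } else {
        (pre[i] - pre[i - 1L]) >= bec
      }
    }
  }
  dives$bout_id <- cumsum(new_bout)
  bouts <- do.call(rbind, lapply(split(dives, dives$bout_id), function(d) {
    data.frame(bout_id = d$bout_id[1],
               start = min(d$start), end = max(d$end),
               duration_min = as.numeric(max(d$end) - min(d$start),
                                         units = "mins"),
               n_dives = nrow(d))
  }))
  rownames(bouts) <- NULL
  list(dives = dives, bouts = bouts)
}

#' Horizontal distance travelled during a dive bout
#'
#' Path length along the interpolated track between the bout's first dive
#' start and last dive end.  A single-dive (near-zero duration) bout
#' returns the length of the bracketing interpolation segment.
#'
#' @param bout One row of the `bouts` table from [assign_bouts()].
#' @param track An `interp_track`.
#' @return Distance in km (NA when the bout lies outside the track span).
#' @export
bout_horizontal_distance <- function(bout, track) {
  track_path_km(track, bout$start, bout$end)
}

#' Attach interpolated locations to dives
#'
#' Each dive start time is mapped to the interpolated position on the
#' trip's track; dives outside the track's time span get NA coordinates
#' and `in_track = FALSE`.
#'
#' @param dives Data frame from [detect_dives()].
#' @param track An `interp_track` for the same individual and trip.
#' @return `dives` with added `lat`, `lon`, `in_track`.
#' @export
locate_dives <- function(dives, track) {
  if (nrow(dives) == 0L) {
    dives$lat <- numeric(0); dives$lon <- numeric(0)
    dives$in_track <- logical(0)
    return(dives)
  }
  loc <- track_locate(track, dives$start)
  dives$lat <- ifelse(loc$in_track, loc$lat, NA_real_)
  dives$lon <- ifelse(loc$in_track, loc$lon, NA_real_)
  dives$in_track <- loc$in_track
  dives
}
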