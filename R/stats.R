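#' Mantel permutation test between two distance matrices
#'
#' The normalized Mantel statistic is the Pearson correlation of the
#' vectorised lower triangles, so it behaves like a correlation
#' coefficient in [-1, 1].  Significance comes from simultaneously
#' permuting the rows and columns of one matrix; the two-sided p-value is
#' `(count(|r_perm| >= |r_obs|) + 1) / (n_perm + 1)`.
#'
#' @param matrix_x,matrix_y Square symmetric matrices of equal dimension
#'   (at least 4 rows).  NA entries (masked pairs, e.g. dyads never at sea
#'   on the same day) are excluded pairwise from both triangles.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Optional integer seed for the permutation stream.
#' @return List of class `mantel_result`: `r`, `p`, `n_perm`, `n`.
#' @export
mantel_test <- function(matrix_x, matrix_y, n_perm = 9999, seed = NULL) {
  stopifnot(is.matrix(matrix_x), is.matrix(matrix_y),
            nrow(matrix_x) == ncol(matrix_x),
            all(dim(matrix_x) == dim(matrix_y)))
  n <- nrow(matrix_x)
  if (n < 4L) stop("need matrices of dimension >= 4")
  lower <- lower.tri(matrix_x)
  mask <- lower & !is.na(matrix_x) & !is.na(matrix_y)
  xv <- matrix_x[mask]
  yv <- matrix_y[mask]
  if (stats::sd(xv) == 0 || stats::sd(yv) == 0) {
    stop("zero variance in a lower triangle: r undefined")
  }
  r_obs <- stats::cor(xv, yv)
  stat_perm <- function() {
    perm <- sample.int(n)
    yp <- matrix_y[perm, perm]
    m2 <- lower & !is.na(matrix_x) & !is.na(yp)
    a <- matrix_x[m2]; b <- yp[m2]
    if (length(a) < 3L || stats::sd(a) == 0 || stats::sd(b) == 0) {
      return(NA_real_)
    }
    stats::cor(a, b)
  }
  run <- function() {
    rp <- vapply(seq_len(n_perm), function(i) stat_perm(), numeric(1))
    rp <- rp[!is.na(rp)]
    (sum(abs(rp) >= abs(r_obs) - 1e-12) + 1) / (length(rp) + 1)
  }
  p <- if (is.null(seed)) run() else with_seed(seed, run())
  structure(list(r = r_obs, p = p, n_perm = n_perm, n = n),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("<mantel> r = %.4f, p = %.4g (%d permutations, n = %d)\n",
              x$r, x$p, x$n_perm, x$n))
  invisible(x)
}

# Exact two-sided Mann-Whitney p via dynamic programming over the pooled
# midranks (ranks doubled to integers), counting subsets of size n1 by
# rank sum.  Works with ties; distribution of U is symmetric about
# n1*n2/2.
mw_exact_p <- function(ranks2, n1, u_obs, n1n2) {
  total <- sum(ranks2)
  # f[k+1, s+1] = number of size-k subsets with doubled-rank sum s
  f <- matrix(0, nrow = n1 + 1L, ncol = total + 1L)
  f[1, 1] <- 1
  for (r in ranks2) {
    kmax <- n1
    for (k in seq(min(kmax, n1), 1L)) {
      src <- f[k, ]
      if (!any(src > 0)) next
      shifted <- c(rep(0, r), src[seq_len(total + 1L - r)])
      f[k + 1L, ] <- f[k + 1L, ] + shifted
    }
  }
  counts <- f[n1 + 1L, ]
  sums2 <- which(counts > 0) - 1L            # doubled rank sums
  u_vals <- sums2 / 2 - n1 * (n1 + 1) / 2    # U for each achievable sum
  probs <- counts[counts > 0] / sum(counts[counts > 0])
  m <- n1n2 / 2
  sum(probs[abs(u_vals - m) >= abs(u_obs - m) - 1e-9])
}

#' Mann-Whitney U test with midrank ties
#'
#' U is computed from rank sums with midranks for ties.  The two-sided
#' p-value is exact (full enumeration of the permutation distribution via
#' dynamic programming, valid under ties) when `n1 * n2 <= 400`, and a
#' normal approximation with tie correction and continuity correction
#' otherwise.
#'
#' @param values_1,values_2 Numeric samples.
#' @return List of class `rank_test`: `U` (for group 1), `p`, `n1`, `n2`,
#'   `method`.
#' @export
mann_whitney <- function(values_1, values_2) {
  x <- values_1[!is.na(values_1)]
  y <- values_2[!is.na(values_2)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  pooled <- c(x, y)
  rk <- rank(pooled)
  u1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  n1n2 <- n1 * n2
  if (n1n2 <= 400) {
    p <- mw_exact_p(round(2 * rk), n1, u1, n1n2)
    method <- "exact"
  } else {
    ties <- table(pooled)
    sigma2 <- n1n2 / 12 *
      ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
    z <- u1 - n1n2 / 2
    cc <- sign(z) * 0.5
    z <- (z - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  structure(list(U = u1, p = min(1, p), n1 = n1, n2 = n2, method = method),
            class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("<mann_whitney> U = %g, p = %.4g (n1 = %d, n2 = %d, %s)\n",
              x$U, x$p, x$n1, x$n2, x$method))
  invisible(x)
}

#' Median with range
#'
#' The summary format used throughout the reporting tables: median with
#' [min, max].  Even-length medians are the mean of the central order
#' statistics.
#'
#' @param values Numeric vector (NAs dropped).
#' @return Named vector `median`, `min`, `max`.
#' @export
median_range_summary <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) return(c(median = NA_real_, min = NA_real_,
                           max = NA_real_))
  c(median = stats::median(v), min = min(v), max = max(v))
}

#' Between-nest distance matrix
#'
#' Pairwise haversine distances between deployment nest coordinates.
#'
#' @param deployments Data frame from [read_deployments_csv()].
#' @return Square symmetric matrix (metres, zero diagonal) with
#'   individual ids as dimnames.
#' @export
nest_distance_matrix <- function(deployments) {
  n <- nrow(deployments)
  m <- matrix(0, n, n,
              dimnames = list(deployments$individual_id,
                              deployments$individual_id))
  for (i in seq_len(n)) {
    m[i, ] <- haversine_m(deployments$nest_lat[i], deployments$nest_lon[i],
                          deployments$nest_lat, deployments$nest_lon)
  }
  (m + t(m)) / 2
}

#' Per-pair total association-time matrix
#'
#' Builds the second input of the Mantel test: a symmetric matrix of total
#' association seconds per dyad.  Pairs with no episode get 0; pairs whose
#' trips never overlapped at sea can be masked to NA via `overlap_pairs`.
#'
#' @param episodes Episode table over all dyads.
#' @param ids Character vector fixing matrix order.
#' @param overlap_pairs Optional two-column matrix/data frame of id pairs
#'   that were simultaneously at sea; all other off-diagonal cells are set
#'   to NA (masked from the Mantel correlation).
#' @return Square symmetric matrix of seconds.
#' @export
association_time_matrix <- function(episodes, ids, overlap_pairs = NULL) {
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  if (!is.null(overlap_pairs) && nrow(overlap_pairs)) {
    mask <- matrix(TRUE, n, n, dimnames = list(ids, ids))
    for (k in seq_len(nrow(overlap_pairs))) {
      a <- as.character(overlap_pairs[k, 1])
      b <- as.character(overlap_pairs[k, 2])
      mask[a, b] <- mask[b, a] <- FALSE
    }
    m[mask] <- NA_real_
  } else if (!is.null(overlap_pairs)) {
    m[upper.tri(m) | lower.tri(m)] <- NA_real_
  }
  for (k in seq_len(nrow(episodes))) {
    a <- as.character(episodes$id_a[k])
    b <- as.character(episodes$id_b[k])
    if (!a %in% ids || !b %in% ids) next
    cur <- m[a, b]
    if (is.na(cur)) cur <- 0
    m[a, b] <- m[b, a] <- cur + episodes$duration_s[k]
  }
  diag(m) <- 0
  m
}
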