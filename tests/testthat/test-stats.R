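sym <- function(v, n) {
  m <- matrix(0, n, n)
  m[lower.tri(m)] <- v
  m + t(m)
}

test_that("Mantel r is a correlation: identity 1, anti-order -1", {
  withr::with_seed(1, x <- sym(runif(10, 1, 9), 5))
  r1 <- mantel_test(x, x, n_perm = 99, seed = 1)
  expect_equal(r1$r, 1)
  y <- 10 - x; diag(y) <- 0
  expect_equal(mantel_test(x, y, n_perm = 99, seed = 1)$r, -1)
  expect_error(mantel_test(sym(rep(1, 10), 5), x, n_perm = 9),
               "zero variance")
})

test_that("Mantel r is invariant to positive affine maps of a matrix", {
  withr::with_seed(2, {
    x <- sym(runif(15, 0, 100), 6)
    y <- sym(runif(15, 0, 100), 6)
  })
  r0 <- mantel_test(x, y, n_perm = 9, seed = 5)$r
  y2 <- 3 * y + 7; diag(y2) <- 0
  expect_equal(mantel_test(x, y2, n_perm = 9, seed = 5)$r, r0,
               tolerance = 1e-12)
  x2 <- 0.25 * x + 2; diag(x2) <- 0
  expect_equal(mantel_test(x2, y, n_perm = 9, seed = 5)$r, r0,
               tolerance = 1e-12)
})

test_that("Monte-Carlo Mantel p matches exhaustive enumeration on 4x4", {
  withr::with_seed(3, {
    x <- sym(runif(6, 0, 10), 4)
    y <- sym(runif(6, 0, 10), 4)
  })
  # oracle: all 24 simultaneous row/column permutations
  perms <- list()
  for (a in 1:4) for (b in setdiff(1:4, a)) for (cc in setdiff(1:4, c(a, b)))
    perms[[length(perms) + 1]] <- c(a, b, cc, setdiff(1:4, c(a, b, cc)))
  lower <- lower.tri(x)
  r_obs <- cor(x[lower], y[lower])
  r_all <- vapply(perms, function(p) {
    yp <- y[p, p]; cor(x[lower], yp[lower])
  }, numeric(1))
  p_exact <- mean(abs(r_all) >= abs(r_obs) - 1e-12)
  mt <- mantel_test(x, y, n_perm = 9999, seed = 11)
  expect_lt(abs(mt$p - p_exact), 0.02)
})

test_that("NA-masked pairs are excluded from the Mantel correlation", {
  withr::with_seed(4, {
    x <- sym(runif(15, 0, 10), 6)
    y <- x + sym(rnorm(15, 0, 0.1), 6)
  })
  y[1, 2] <- y[2, 1] <- NA
  mt <- mantel_test(x, y, n_perm = 99, seed = 1)
  expect_gt(mt$r, 0.9)
})

test_that("Mann-Whitney matches the hand-enumerated and base oracles", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 1 / 3)   # 2 of the 6 orderings are as extreme
  expect_equal(mw$method, "exact")

  # identical groups: p = 1 by symmetry
  expect_equal(mann_whitney(1:5, 1:5)$p, 1, tolerance = 1e-9)

  # oracle: base wilcox.test exact p, tie-free samples
  withr::with_seed(6, {
    for (k in 1:10) {
      x <- rnorm(sample(3:8, 1))
      y <- rnorm(sample(3:8, 1))
      ours <- mann_whitney(x, y)
      ref <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
      expect_equal(ours$U, unname(ref$statistic))
      expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
    }
  })
})

test_that("U statistics of the two groups always sum to n1*n2", {
  withr::with_seed(7, {
    for (k in 1:10) {
      x <- sample(1:6, sample(3:9, 1), replace = TRUE)  # heavy ties
      y <- sample(1:6, sample(3:9, 1), replace = TRUE)
      u1 <- mann_whitney(x, y)$U
      u2 <- mann_whitney(y, x)$U
      expect_equal(u1 + u2, length(x) * length(y))
    }
  })
})

test_that("exact and normal branches agree at the size boundary", {
  withr::with_seed(8, {
    x <- rnorm(20); y <- rnorm(20, 0.3)          # n1*n2 = 400: exact
    exact <- mann_whitney(x, y)
    expect_equal(exact$method, "exact")
    approx_p <- mann_whitney(c(x, rnorm(1, 10)), y)  # 420: normal branch
    expect_equal(approx_p$method, "normal")
    # same data through both formulas
    big <- mann_whitney(x, y)
    ties <- table(c(x, y)); n1 <- 20; n2 <- 20
    sigma2 <- n1 * n2 / 12 *
      ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
    z <- big$U - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p_norm <- min(1, 2 * pnorm(-abs(z)))
    expect_lt(abs(big$p - p_norm), 0.02)
  })
})

test_that("median-range summaries use central order statistics", {
  expect_equal(median_range_summary(c(5, 1, 9)),
               c(median = 5, min = 1, max = 9))
  expect_equal(median_range_summary(c(4, 8))["median"], c(median = 6))
  expect_equal(unname(median_range_summary(7)), c(7, 7, 7))
})

test_that("nest distance matrix is metric-like", {
  dpl <- data.frame(individual_id = c("A", "B", "C"),
                    nest_lat = c(COLONY$lat, COLONY$lat,
                                 COLONY$lat + 50 / M_PER_DEG_LAT),
                    nest_lon = c(COLONY$lon,
                                 COLONY$lon + 50 /
                                   (M_PER_DEG_LAT *
                                      cos(COLONY$lat * pi / 180)),
                                 COLONY$lon))
  m <- nest_distance_matrix(dpl)
  expect_equal(diag(m), setNames(rep(0, 3), dpl$individual_id))
  expect_equal(m, t(m))
  expect_equal(m["A", "B"], 50, tolerance = 0.1)
  expect_equal(m["A", "C"], 50, tolerance = 0.1)
})

test_that("association-time matrix masks never-overlapping dyads", {
  ep <- data.frame(id_a = c("A", "A"), id_b = c("B", "C"),
                   duration_s = c(600, 900))
  ids <- c("A", "B", "C", "D")
  ov <- data.frame(a = c("A", "A", "A"), b = c("B", "C", "D"))
  m <- association_time_matrix(ep, ids, ov)
  expect_equal(m["A", "B"], 600)
  expect_equal(m["C", "A"], 900)
  expect_equal(m["A", "D"], 0)          # overlapped but never associated
  expect_true(is.na(m["B", "C"]))       # never simultaneously at sea
  expect_equal(m, t(m))
})
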