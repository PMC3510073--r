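test_that("sigma points have the prescribed spread, mean, and covariance", {
  # scalar case: x = 0, P = sigma^2 -> points {+sigma, -sigma}
  s2 <- 0.49
  pts <- sigma_points(0, matrix(s2, 1, 1))
  expect_equal(sort(as.numeric(pts)), c(-0.7, 0.7), tolerance = 1e-9)
  expect_equal(mean(pts), 0)
  expect_equal(sum(pts^2) / 2, s2, tolerance = 1e-9)

  # n = 2, P = I -> +/- sqrt(2) e_i
  pts2 <- sigma_points(c(0, 0), diag(2))
  expect_equal(sort(abs(pts2[pts2 != 0])), rep(sqrt(2), 4), tolerance = 1e-9)

  # property: weighted mean and covariance reproduce (x, P) for random SPD P
  set.seed(11)
  for (i in 1:10) {
    n <- sample(2:8, 1)
    A <- matrix(rnorm(n * n), n)
    P <- crossprod(A) + diag(1e-3, n)
    x <- rnorm(n)
    pts <- sigma_points(x, P)
    expect_equal(rowMeans(pts), x, tolerance = 1e-9)
    D <- pts - x
    expect_equal(D %*% t(D) / (2 * n), P, tolerance = 1e-8)
  }
})

test_that("sigma points survive a semi-definite covariance via jitter", {
  P <- diag(c(1, 0))  # rank deficient
  pts <- sigma_points(c(0, 0), P)
  expect_true(all(is.finite(pts)))
})

test_that("prediction under identity dynamics only inflates by Q", {
  idm <- function(x, t) x
  x <- c(1, -2); P <- diag(c(0.3, 0.5))
  cfg0 <- ukf_config(idm, Q = c(0, 0), dt = 1)
  pr <- ukf_predict(x, P, cfg0)
  expect_equal(pr$x, x, tolerance = 1e-9)
  expect_equal(pr$P, P, tolerance = 1e-8)
  cfgq <- ukf_config(idm, Q = c(0.1, 0.2), dt = 1)
  prq <- ukf_predict(x, P, cfgq)
  expect_equal(prq$P, P + diag(c(0.1, 0.2)), tolerance = 1e-8)
})

test_that("prediction under linear dynamics equals F P F' + Q", {
  A <- matrix(c(0.9, 0.2, -0.1, 0.8), 2, 2)
  cfg <- ukf_config(function(x, t) drop(A %*% x), Q = c(0.01, 0.02), dt = 1)
  x <- c(0.5, -1); P <- matrix(c(0.4, 0.1, 0.1, 0.3), 2, 2)
  pr <- ukf_predict(x, P, cfg)
  expect_equal(pr$x, drop(A %*% x), tolerance = 1e-10)
  expect_equal(pr$P, A %*% P %*% t(A) + diag(c(0.01, 0.02)), tolerance = 1e-8)
})

test_that("correction obeys the trust limits and scalar Kalman algebra", {
  pred <- list(x = c(1, 2), P = diag(c(1, 1)),
               points = sigma_points(c(1, 2), diag(2)))
  # R -> infinity: measurement ignored
  co <- ukf_correct(pred, y = 5, obs_idx = 1L, R = 1e12)
  expect_equal(co$x, pred$x, tolerance = 1e-6)
  # R -> 0: observed component snaps to y
  co0 <- ukf_correct(pred, y = 5, obs_idx = 1L, R = 1e-12)
  expect_equal(co0$x[1], 5, tolerance = 1e-6)
  # scalar algebra: P_yy = 1, R = 1 -> K = 1/2, midpoint correction
  co5 <- ukf_correct(pred, y = 3, obs_idx = 1L, R = 1)
  expect_equal(as.numeric(co5$K)[1], 0.5, tolerance = 1e-9)
  expect_equal(co5$x[1], (1 + 3) / 2, tolerance = 1e-9)
  expect_error(ukf_correct(pred, y = NaN, obs_idx = 1L, R = 1), "non-finite")
})

test_that("corrected covariance never exceeds the forecast in the observed subspace", {
  set.seed(21)
  for (i in 1:5) {
    n <- 4
    A <- matrix(rnorm(n * n), n)
    P <- crossprod(A) / n + diag(0.1, n)
    pred <- list(x = rnorm(n), P = P, points = sigma_points(rnorm(n), P))
    co <- ukf_correct(pred, y = rnorm(2), obs_idx = c(1L, 3L),
                      R = c(0.5, 0.5))
    expect_lte(co$P[1, 1], P[1, 1] + 1e-12)
    expect_lte(co$P[3, 3], P[3, 3] + 1e-12)
    expect_equal(co$P, t(co$P), tolerance = 1e-12)
  }
})

test_that("full pipeline matches the exact Kalman filter on a linear system", {
  set.seed(7)
  A <- matrix(c(0.9, 0.1, 0, -0.2, 0.95, 0.1, 0.05, 0, 0.9), 3, 3)
  Qd <- rep(1e-4, 3); Rv <- 0.05
  x <- c(1, 0, -1); Tn <- 1000
  Y <- matrix(NA_real_, Tn, 1)
  for (k in seq_len(Tn)) {
    x <- drop(A %*% x)
    Y[k, 1] <- x[1] + rnorm(1, 0, sqrt(Rv))
  }
  obs <- as_obs_series(seq(0.5, by = 0.5, length.out = Tn), Y, Rv, "x1",
                       obs_idx = 1L)
  cfg <- ukf_config(function(x, t) drop(A %*% x), Qd, dt = 0.5)
  rec <- assimilate(obs, cfg, x0 = c(0, 0, 0), P0 = diag(1, 3))
  kf <- exact_kf(A, matrix(c(1, 0, 0), 1, 3), diag(Qd), Rv, Y,
                 c(0, 0, 0), diag(1, 3))
  expect_lt(max(abs(as.matrix(rec$est[, -1]) - kf$x)), 1e-8)
  expect_lt(max(abs(as.matrix(rec$P_diag[, -1]) - kf$P_diag)), 1e-8)
})

test_that("inflation never lowers the matching Kalman-gain row at the next correction", {
  A <- matrix(c(0.9, 0.15, 0.05, -0.1, 0.85, 0.2, 0.05, -0.1, 0.9), 3, 3)
  step <- function(x, t) drop(A %*% x)
  x0 <- c(0.3, -0.2, 0.4)
  P0 <- diag(c(0.2, 0.3, 0.25))
  base_Q <- c(1e-3, 1e-3, 1e-3)
  gain_rows <- function(Q) {
    cfg <- ukf_config(step, Q, dt = 1)
    pr <- ukf_predict(x0, P0, cfg)
    co <- ukf_correct(pr, y = 0.1, obs_idx = 1L, R = 0.05)
    pr2 <- ukf_predict(co$x, co$P, cfg)
    co2 <- ukf_correct(pr2, y = 0.05, obs_idx = 1L, R = 0.05)
    sqrt(rowSums(co2$K^2))
  }
  g0 <- gain_rows(base_Q)
  for (i in 1:3) {
    Qb <- base_Q
    Qb[i] <- Qb[i] * 50
    expect_gte(gain_rows(Qb)[i], g0[i] - 1e-12)
  }
})

test_that("missing observations trigger predict-only steps", {
  Tn <- 40
  Y <- matrix(1, Tn, 1)
  Y[10:20, 1] <- NA  # gap
  obs <- as_obs_series(seq_len(Tn), Y, 0.1, "x1", obs_idx = 1L)
  cfg <- ukf_config(function(x, t) x, Q = 1e-4, dt = 1)  # random-walk model
  rec <- assimilate(obs, cfg, x0 = 0, P0 = diag(1, 1))
  # covariance grows through the gap, shrinks on correction
  pv <- rec$P_diag[[2]]
  expect_true(all(diff(pv[10:20]) > 0))
  expect_lt(pv[21], pv[20])
})

test_that("noise-free self-consistent twin is reproduced essentially exactly", {
  p <- quiet_db()
  truth <- simulate_sleep(p, 900)
  y <- as.matrix(truth[-1, c("F_LC", "F_R")])
  obs <- as_obs_series(truth$t[-1], y, 1e-12, c("F_LC", "F_R"))
  cfg <- ukf_config(p, Q = rep(0, 12))
  rec <- assimilate(obs, cfg, x0 = as.numeric(truth[1, -1]),
                    P0 = diag(1e-12, 12))
  err <- max(abs(as.matrix(rec$est[, -1]) - as.matrix(truth[-1, -1])))
  expect_lt(err, 1e-6)
})

test_that("identical-twin reconstruction recovers hidden variables", {
  p <- twin_1h()
  cfg <- ukf_config(p$params, p$Q)
  rec <- assimilate(p$obs, cfg)
  al <- recon_vs_truth(rec, p$truth, transient = 1200)
  expect_lt(nmse(rec$est$F_VLPO[al$keep], p$truth$F_VLPO[al$rows][al$keep]),
            0.5)
  expect_lt(nmse(rec$est$F_LC[al$keep], p$truth$F_LC[al$rows][al$keep]),
            0.04)
  # determinism of the whole assimilation
  rec2 <- assimilate(p$obs, cfg)
  expect_identical(rec$est, rec2$est)
})

test_that("non-uniform observation timestamps are rejected", {
  obs <- as_obs_series(c(0.5, 1.0, 2.5), matrix(0, 3, 1), 0.1, "F_LC")
  expect_error(assimilate(obs, ukf_config(db_params(), rep(1e-4, 12))),
               "uniform")
})
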