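# independent brute-force re-implementation of the shooting cost: explicit
# loop over segments, integrating with the R-side RK4 of simulate_sleep()
naive_shooting_cost <- function(p_test, param, est, params, measured, cfg,
                                dt = 0.5) {
  pt <- param_set(params, param, p_test)
  pt$noise$rate <- 0
  nm <- state_names(params)
  sds <- vapply(measured, function(v) sd(est[[v]]), numeric(1))
  w <- 1 / sds
  seg <- round(cfg$segment_s / dt)
  Tn <- nrow(est)
  J <- 0; npts <- 0
  s <- 1
  while (s < Tn) {
    x0 <- as.numeric(est[s, nm])
    names(x0) <- nm
    end <- min(s + seg, Tn)
    sim <- simulate_sleep(pt, (end - s) * dt, dt = dt, init = x0,
                          t0 = est$t[s])
    for (k in seq_len(end - s)) {
      for (j in seq_along(measured)) {
        e <- sim[[measured[j]]][k + 1] - est[[measured[j]]][s + k]
        J <- J + w[j]^2 * e^2
      }
      npts <- npts + 1
    }
    s <- s + seg
  }
  unname(J / npts)
}

test_that("shooting cost agrees with a brute-force reference", {
  p <- quiet_db()
  truth <- cached("quiet_truth_30min", simulate_sleep(p, 1800))
  cfg <- shooting_config(window_s = 1800, segment_s = 120)
  for (ptest in c(0.8, 1.0, 1.3)) {
    a <- shooting_cost(ptest, "coupling.A_LC", truth, p,
                       c("F_LC", "F_R"), cfg)
    b <- naive_shooting_cost(ptest, "coupling.A_LC", truth, p,
                             c("F_LC", "F_R"), cfg)
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("shooting cost vanishes at the generating parameter and is non-negative", {
  p <- quiet_db()
  truth <- cached("quiet_truth_30min", simulate_sleep(p, 1800))
  cfg <- shooting_config()
  true_val <- p$coupling$A_LC
  j0 <- shooting_cost(true_val, "coupling.A_LC", truth, p,
                      c("F_LC", "F_R"), cfg)
  expect_equal(j0, 0, tolerance = 1e-16)
  grid <- true_val * seq(0.5, 1.5, by = 0.125)
  js <- vapply(grid, shooting_cost, numeric(1), param = "coupling.A_LC",
               recon = truth, params = p, measured = c("F_LC", "F_R"),
               cfg = cfg)
  expect_true(all(js >= 0))
  # exhaustive grid evaluation puts the minimum at the truth
  expect_equal(grid[which.min(js)], true_val)
})

test_that("infeasible candidates get infinite cost", {
  p <- quiet_db()
  truth <- cached("quiet_truth_30min", simulate_sleep(p, 1800))
  cfg <- shooting_config()
  j <- shooting_cost(1e-13, "groups.lc.tau_F", truth, p, "F_LC", cfg)
  expect_identical(j, Inf)
})

test_that("estimation started at the truth stays near the truth", {
  s <- twin_fit()
  true_val <- s$params$coupling$A_LC
  fit <- estimate_parameter(s$obs, ukf_config(s$params, s$Q),
                            "coupling.A_LC", init = true_val)
  grid_step <- 0.3 / 5 * max(abs(true_val), 0.05)
  expect_lt(abs(fit$estimate - true_val), grid_step + 1e-9)
  # window-to-window scatter never walks the estimate away from the truth
  expect_lt(max(abs(fit$track$estimate - true_val)) / true_val, 0.15)
})

test_that("estimation converges from a 30% offset and respects the step cap", {
  s <- twin_fit()
  true_val <- s$params$coupling$A_LC
  fit <- estimate_parameter(s$obs, ukf_config(s$params, s$Q),
                            "coupling.A_LC", init = 0.7 * true_val)
  expect_lt(abs(fit$estimate - true_val) / true_val, 0.06)
  # per-window relative updates never exceed the cap (plus the scale floor)
  est <- c(0.7 * true_val, fit$track$estimate)
  steps <- abs(diff(est)) / pmax(abs(est[-length(est)]), 0.05)
  expect_true(all(steps <= 0.1 + 1e-9))
})

test_that("a constant parameter tracks flat", {
  s <- twin_fit()
  true_val <- s$params$coupling$A_LC
  fit <- track_parameter(s$obs, ukf_config(s$params, s$Q),
                         param = "coupling.A_LC", init = true_val)
  expect_gt(nrow(fit$track), 10)
  # flat within statistical tolerance: unbiased and low scatter
  expect_lt(abs(mean(fit$track$estimate) - true_val) / true_val, 0.05)
  expect_lt(stats::sd(fit$track$estimate) / true_val, 0.1)
})

test_that("the observation record must cover at least one window", {
  s <- twin_fit()
  tiny <- structure(list(t = s$obs$t[1:100], y = s$obs$y[1:100, , drop = FALSE],
                         R = s$obs$R[1:100, , drop = FALSE],
                         vars = s$obs$vars), class = "obs_series")
  expect_error(estimate_parameter(tiny, ukf_config(s$params, s$Q),
                                  "coupling.A_LC", init = 1),
               "shorter than one estimation window")
})

test_that("dominant_period recovers the period of a clean oscillation", {
  t <- seq(0, 36 * 3600, by = 360)
  tr <- data.frame(t_center = t,
                   estimate = -0.4 + 0.3 * sin(2 * pi * t / (24 * 3600)))
  expect_equal(dominant_period(tr), 24, tolerance = 0.08)
})
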