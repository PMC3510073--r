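# Shared fixtures, generated in code and cached per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# deterministic core-model parameter set (no thalamic impulses)
quiet_db <- function() {
  p <- db_params()
  p$noise$rate <- 0
  p
}

# one-hour identical-twin setup shared by several UKF tests
twin_1h <- function() {
  cached("twin_1h", {
    p <- db_params()
    truth <- simulate_sleep(p, 3600, seed = 2)
    obs <- observe(truth, "F_LC", noise_frac = 0.04, seed = 3)
    Q <- default_q(p, duration = 3600, seed = 1)
    list(params = p, truth = truth, obs = obs, Q = Q)
  })
}

# two-variable identical-twin setup shared by the estimation tests
twin_fit <- function() {
  cached("twin_fit_4h", {
    p <- db_params()
    truth <- simulate_sleep(p, 4 * 3600, seed = 21)
    obs <- observe(truth, c("F_LC", "F_R"), noise_frac = 0.04, seed = 22)
    Q <- default_q(p, seed = 1)
    list(params = p, truth = truth, obs = obs, Q = Q)
  })
}

# closed-form Kalman filter for y = H x + noise, x' = A x (discrete)
exact_kf <- function(A, H, Q, Rm, Y, x0, P0) {
  d <- length(x0)
  Tn <- nrow(Y)
  X <- matrix(NA_real_, Tn, d)
  Pd <- matrix(NA_real_, Tn, d)
  x <- x0; P <- P0
  for (k in seq_len(Tn)) {
    xp <- drop(A %*% x)
    Pp <- A %*% P %*% t(A) + Q
    S <- H %*% Pp %*% t(H) + Rm
    K <- Pp %*% t(H) %*% solve(S)
    x <- xp + drop(K %*% (Y[k, ] - H %*% xp))
    P <- Pp - K %*% H %*% Pp
    X[k, ] <- x
    Pd[k, ] <- diag(P)
  }
  list(x = X, P_diag = Pd)
}

# wrap a matrix of observations into the obs_series contract
as_obs_series <- function(t, y, Rv, vars, obs_idx = NULL) {
  y <- as.matrix(y)
  o <- structure(list(t = t, y = y,
                      R = matrix(Rv, nrow(y), ncol(y), byrow = TRUE),
                      vars = vars),
                 class = "obs_series")
  if (!is.null(obs_idx)) attr(o, "obs_idx") <- obs_idx
  o
}

# truth rows aligned with a reconstruction, post-transient mask
recon_vs_truth <- function(rec, truth, transient) {
  rows <- match(rec$est$t, truth$t)
  keep <- rec$est$t - truth$t[1] >= transient
  list(rows = rows, keep = keep)
}
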