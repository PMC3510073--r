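#' Symmetric sigma-point set
#'
#' The 2n deterministically chosen ensemble members `x +/- columns of
#' sqrt(nP)` with equal weights `1/(2n)`. Their weighted mean is `x` and
#' their weighted covariance is exactly `P`. The matrix square root is a
#' Cholesky factor; if `P` has drifted off the positive-definite cone
#' numerically, escalating diagonal jitter (1e-12 up to 1e-6) is applied
#' before failing.
#'
#' @param x mean state (length n).
#' @param P covariance (n x n, symmetric positive semi-definite).
#' @return an n x 2n matrix of sigma points.
#' @export
sigma_points <- function(x, P) {
  n <- length(x)
  stopifnot(all(dim(P) == c(n, n)))
  L <- chol_jitter(n * P)
  cbind(x + L, x - L)
}

chol_jitter <- function(M) {
  jit <- 1e-12
  for (i in 1:8) {
    L <- tryCatch(t(chol(M + diag(jit, nrow(M)))), error = function(e) NULL)
    if (!is.null(L)) return(L)
    jit <- jit * 100
  }
  stop("covariance square root failed even after jitter repair", call. = FALSE)
}

#' Filter configuration for the unscented Kalman filter
#'
#' Bundles the filter model with the covariance-inflation diagonal `Q` and
#' the filter step. The filter model is the deterministic skeleton of the
#' simulator: inside the filter the thalamic input `delta` evolves by pure
#' decay and its uncertainty is supplied entirely by its `Q` entry.
#'
#' @param model either a `sleep_params` object (fast compiled path) or a
#'   deterministic step function `function(x, t)` returning the state one
#'   `dt` later (used for generic/linear models).
#' @param Q covariance-inflation diagonal: a non-negative vector with one
#'   entry per state component ("nonzero only on the diagonal").
#' @param dt filter step (s); must equal the observation spacing. Default
#'   0.5 s, the integration step used throughout.
#' @param t0 filter start time (s).
#' @return an object of class `ukf_config`.
#' @export
ukf_config <- function(model, Q, dt = 0.5, t0 = 0) {
  stopifnot(dt > 0)
  if (any(Q < 0)) stop("Q entries must be non-negative", call. = FALSE)
  if (inherits(model, "sleep_params")) {
    if (length(Q) != state_dim(model))
      stop("Q must have one entry per state component", call. = FALSE)
  } else if (!is.function(model)) {
    stop("model must be a sleep_params object or a step function",
         call. = FALSE)
  }
  structure(list(model = model, Q = as.numeric(Q), dt = dt, t0 = t0),
            class = "ukf_config")
}

#' Default covariance inflation for a sleep model
#'
#' `Q_ii = multiplier * var_i`, where `var_i` is the variance of variable `i`
#' over a reference simulation of the model itself. The multiplier (default
#' 1e-4) sets how much forecast-error underestimation the filter assumes.
#'
#' @param params a `sleep_params` object.
#' @param duration,seed,dt reference simulation settings.
#' @param multiplier scale applied to the per-variable variances.
#' @param transient seconds discarded before computing variances.
#' @return named non-negative vector, one entry per state component.
#' @export
default_q <- function(params, duration = 6 * 3600, seed = 1, dt = 0.5,
                      multiplier = 1e-4, transient = 1800) {
  traj <- simulate_sleep(params, duration, dt = dt, seed = seed)
  keep <- traj$t - traj$t[1] >= transient
  v <- apply(traj[keep, state_names(params), drop = FALSE], 2, stats::var)
  # delta is flat when the generator is switched off; give it the scale a
  # unit impulse would have so its Q entry stays usable
  v[v == 0] <- multiplier_floor(params)[v == 0]
  multiplier * v
}

multiplier_floor <- function(params) {
  f <- rep(1e-6, state_dim(params))
  names(f) <- state_names(params)
  f["delta"] <- params$noise$impulse_amplitude^2
  f
}

#' Observation specification
#'
#' Which state components are observed and with what noise variance. The
#' number of observed components need not equal the state dimension.
#'
#' @param vars character names of observed variables (subset of
#'   [state_names()]).
#' @param noise_var per-observation noise variances (recycled to
#'   `length(vars)`).
#' @return an object of class `obs_spec`.
#' @export
obs_spec <- function(vars, noise_var) {
  stopifnot(length(vars) >= 1, !anyDuplicated(vars))
  structure(list(vars = vars,
                 noise_var = rep_len(as.numeric(noise_var), length(vars))),
            class = "obs_spec")
}

#' Apply a noisy observation function to a trajectory
#'
#' Selects a subset of variables and adds independent zero-mean Gaussian
#' noise with variance equal to `noise_frac` times each variable's variance
#' over the trajectory (4% by default). Returns the observation series
#' together with the implied measurement-noise variances.
#'
#' @param traj a `sleep_traj` data.frame.
#' @param vars observed variable names.
#' @param noise_frac noise variance as a fraction of each signal's variance.
#' @param seed optional seed for the noise draw.
#' @return an object of class `obs_series`: list with `t` (times of the
#'   observed samples, excluding the initial condition), `y` (T x m matrix),
#'   `R` (T x m matrix of noise variances), `vars`.
#' @export
observe <- function(traj, vars, noise_frac = 0.04, seed = NULL) {
  stopifnot(all(vars %in% names(traj)))
  if (!is.null(seed)) set.seed(seed)
  idx <- seq(2, nrow(traj))  # observations start one step after the IC
  y <- as.matrix(traj[idx, vars, drop = FALSE])
  vr <- noise_frac * apply(as.matrix(traj[, vars, drop = FALSE]), 2, stats::var)
  for (j in seq_along(vars))
    y[, j] <- y[, j] + stats::rnorm(nrow(y), 0, sqrt(vr[j]))
  structure(list(t = traj$t[idx], y = y,
                 R = matrix(vr, nrow(y), length(vars), byrow = TRUE,
                            dimnames = list(NULL, vars)),
                 vars = vars),
            class = "obs_series")
}

#' UKF prediction step
#'
#' Propagates each sigma point one filter step through the deterministic
#' model; the forecast is the unweighted mean of the iterated points and the
#' forecast covariance is their covariance plus the diagonal inflation `Q`.
#'
#' @param x,P current estimate and covariance.
#' @param cfg a [ukf_config()] whose model is a step function.
#' @param t current time (s).
#' @return list with `x` (forecast mean), `P` (inflated forecast
#'   covariance), and `points` (the iterated sigma points, needed by
#'   [ukf_correct()]).
#' @export
ukf_predict <- function(x, P, cfg, t = cfg$t0) {
  stopifnot(is.function(cfg$model))
  pts <- sigma_points(x, P)
  for (j in seq_len(ncol(pts))) pts[, j] <- cfg$model(pts[, j], t)
  xp <- rowMeans(pts)
  D <- pts - xp
  Pp <- D %*% t(D) / ncol(pts) + diag(cfg$Q, length(x))
  list(x = xp, P = Pp, points = pts)
}

#' UKF correction step
#'
#' Forms the Kalman gain from the ratio of the forecast cross-covariance to
#' the innovation covariance (both taken in the observed subspace of the
#' inflated forecast covariance), corrects the forecast toward the
#' measurement, and collapses the forecast covariance accordingly. Because
#' the inflation enters the gain, on linear dynamics the recursion is
#' exactly the classical Kalman filter.
#'
#' @param pred output of [ukf_predict()].
#' @param y observation vector (length m).
#' @param obs_idx indices of the observed state components.
#' @param R measurement-noise covariance (m x m matrix or length-m diagonal).
#' @return list with corrected `x`, `P`, and the gain `K`.
#' @export
ukf_correct <- function(pred, y, obs_idx, R) {
  if (any(!is.finite(y))) stop("non-finite observation", call. = FALSE)
  m <- length(y)
  if (length(R) == m) R <- diag(as.numeric(R), m)
  # covariances in/with the observed subspace, taken from the inflated
  # forecast covariance so the inflation acts on the current gain and the
  # filter is exactly the Kalman filter on linear dynamics
  Pyy <- pred$P[obs_idx, obs_idx, drop = FALSE]
  Pxy <- pred$P[, obs_idx, drop = FALSE]
  S <- Pyy + R
  K <- tryCatch(t(solve(S, t(Pxy))), error = function(e)
    stop("singular innovation covariance in UKF correction", call. = FALSE))
  ypred <- pred$x[obs_idx]
  x <- pred$x + drop(K %*% (y - ypred))
  P <- pred$P - K %*% t(Pxy)
  list(x = x, P = 0.5 * (P + t(P)), K = K)
}

#' Assimilate an observation series with the unscented Kalman filter
#'
#' Runs the alternating predict/correct recursion over the whole series and
#' returns the reconstructed state at every step. The filter model excludes
#' the stochastic impulse generator: `delta` is a filtered state driven only
#' by its `Q` entry. A step whose observation contains `NA` performs
#' predict-only (missing-data contract). Deterministic given its inputs.
#'
#' @param obs an `obs_series` (from [observe()] or [infer_observations()]).
#' @param cfg a [ukf_config()].
#' @param x0 initial state estimate (defaults to [default_init()] for sleep
#'   models).
#' @param P0 initial covariance (defaults to `diag(Q) * 1e4` scaled to the
#'   state, see Details); supply explicitly for reproducible comparisons.
#' @return an object of class `ukf_recon`: list with `est` (data.frame of
#'   reconstructed states, rows aligned with `obs$t`), `P_diag` (data.frame
#'   of covariance diagonals), `vars`, and the final filter state.
#' @export
assimilate <- function(obs, cfg, x0 = NULL, P0 = NULL) {
  stopifnot(inherits(obs, "obs_series"), inherits(cfg, "ukf_config"))
  dts <- diff(obs$t)
  if (length(dts) > 0 && max(abs(dts - cfg$dt)) > 1e-8)
    stop("observation timestamps must be uniform at the filter step",
         call. = FALSE)
  if (inherits(cfg$model, "sleep_params")) {
    params <- cfg$model
    nm <- state_names(params)
    obs_idx <- match(obs$vars, nm)
    if (anyNA(obs_idx))
      stop("observed variables not in the model state: ",
           paste(obs$vars[is.na(obs_idx)], collapse = ", "), call. = FALSE)
    if (is.null(x0)) x0 <- default_init(params)
    if (is.null(P0)) P0 <- diag(pmax(cfg$Q, 1e-8) * 1e4, length(x0))
    fp <- params
    fp$noise$rate <- 0  # deterministic skeleton inside the filter
    pv <- flatten_params(fp)
    t0 <- obs$t[1] - cfg$dt
    fit <- cpp_ukf_sleep(t(obs$y), obs_idx, t(obs$R), cfg$Q,
                         as.numeric(x0), P0, t0, cfg$dt, pv)
    est <- as.data.frame(t(fit$xhat))
    names(est) <- nm
    pd <- as.data.frame(t(fit$Pdiag))
    names(pd) <- nm
    out <- list(est = cbind(t = obs$t, est), P_diag = cbind(t = obs$t, pd),
                vars = obs$vars, x_final = as.numeric(fit$x_final),
                P_final = fit$P_final, config = cfg)
  } else {
    if (is.null(x0)) stop("x0 is required for a generic model", call. = FALSE)
    d <- length(x0)
    if (is.null(P0)) P0 <- diag(1, d)
    x <- as.numeric(x0); P <- P0
    Tn <- nrow(obs$y)
    obs_idx <- attr(obs, "obs_idx")
    if (is.null(obs_idx)) obs_idx <- seq_along(obs$vars)
    est <- matrix(NA_real_, Tn, d)
    pd <- matrix(NA_real_, Tn, d)
    tprev <- obs$t[1] - cfg$dt
    for (k in seq_len(Tn)) {
      pr <- ukf_predict(x, P, cfg, t = tprev)
      y <- obs$y[k, ]
      if (any(!is.finite(y))) {
        x <- pr$x; P <- pr$P
      } else {
        co <- ukf_correct(pr, y, obs_idx, obs$R[k, ])
        x <- co$x; P <- co$P
      }
      est[k, ] <- x
      pd[k, ] <- diag(P)
      tprev <- obs$t[k]
    }
    est <- as.data.frame(est)
    pd <- as.data.frame(pd)
    out <- list(est = cbind(t = obs$t, est), P_diag = cbind(t = obs$t, pd),
                vars = obs$vars, x_final = x, P_final = P, config = cfg)
  }
  class(out) <- "ukf_recon"
  out
}

#' @export
print.ukf_recon <- function(x, ...) {
  cat("<ukf_recon>", nrow(x$est), "steps,",
      ncol(x$est) - 1, "state components; observed:",
      paste(x$vars, collapse = ", "), "\n")
  invisible(x)
}
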