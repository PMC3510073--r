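#' Normalized mean square reconstruction error
#'
#' Mean squared difference between a reconstructed and a true series, divided
#' by the variance of the truth. Zero for perfect reconstruction; about 1
#' when the reconstruction carries no information beyond the truth's mean.
#'
#' @param reconstructed,truth numeric vectors of equal length (>= 2).
#' @return non-negative scalar.
#' @export
nmse <- function(reconstructed, truth) {
  stopifnot(length(reconstructed) == length(truth), length(truth) >= 2)
  v <- stats::var(truth)
  if (v == 0)
    stop("truth series has zero variance; NMSE undefined", call. = FALSE)
  mean((reconstructed - truth)^2) / v
}

#' Empirical Observability Coefficient from an NMSE value
#'
#' Regularized inverse `1/(1 + NMSE)`: equals 1 for perfect reconstruction,
#' is bounded in `(0, 1]`, and decreases strictly as the error grows.
#'
#' @param nmse_value non-negative scalar (vectorized).
#' @return value(s) in `(0, 1]`.
#' @export
eoc <- function(nmse_value) {
  if (any(nmse_value < 0)) stop("NMSE must be non-negative", call. = FALSE)
  1 / (1 + nmse_value)
}

# shared machinery: simulate filter-model truth, observe column(s), assimilate,
# score every variable
eoc_run <- function(params, measured, truth, Q, noise_frac, dt, seed,
                    transient, x0, P0) {
  obs <- observe(truth, measured, noise_frac = noise_frac, seed = seed)
  cfg <- ukf_config(params, Q, dt = dt, t0 = truth$t[1])
  rec <- assimilate(obs, cfg, x0 = x0, P0 = P0)
  keep <- rec$est$t - truth$t[1] >= transient
  nm <- state_names(params)
  truth_rows <- match(rec$est$t, truth$t)
  vapply(nm, function(v) {
    tv <- truth[[v]][truth_rows][keep]
    if (stats::var(tv) == 0) return(NA_real_)
    eoc(nmse(rec$est[[v]][keep], tv))
  }, numeric(1))
}

#' Empirical Observability Coefficient matrix
#'
#' For each candidate measured variable `j`, generates truth from the filter
#' model itself (identical-twin design), observes `j` with Gaussian noise,
#' assimilates with the UKF, and scores the reconstruction of every variable
#' `i` with [eoc()]. Row `i`, column `j` therefore answers: how well is `i`
#' reconstructed when `j` is measured?
#'
#' @param params a `sleep_params` object.
#' @param duration length of the scored record (s); default 12 h, which
#'   spans many sleep-wake cycles.
#' @param dt filter/integration step (s).
#' @param noise_frac observation-noise variance as a fraction of each
#'   signal's variance.
#' @param Q covariance-inflation diagonal; default [default_q()].
#' @param seed seed for truth generation and observation noise.
#' @param include_delta if `FALSE` (default), the thalamic noise process is
#'   switched off: truth is deterministic, `delta` stays 0, and the
#'   delta row/column is dropped from the matrix.
#' @param transient seconds discarded before scoring (reconstruction is poor
#'   while the filter converges from its arbitrary initial state).
#' @return an object of class `eoc_matrix`: the EOC values with metadata
#'   (`duration`, `Q`, `noise_frac`, `seed`) attached. A column whose
#'   assimilation failed is `NA` and flagged in the `failed` attribute.
#' @export
eoc_matrix <- function(params, duration = 12 * 3600, dt = 0.5,
                       noise_frac = 0.04, Q = NULL, seed = 1,
                       include_delta = FALSE, transient = 3600) {
  if (!include_delta) params$noise$rate <- 0
  if (is.null(Q)) Q <- default_q(params, seed = seed)
  nm <- state_names(params)
  vars <- if (include_delta) nm else setdiff(nm, "delta")
  truth <- simulate_sleep(params, duration + transient, dt = dt, seed = seed)
  x0 <- default_init(params)
  P0 <- diag(pmax(Q, 1e-8) * 1e4, length(x0))
  M <- matrix(NA_real_, length(vars), length(vars),
              dimnames = list(reconstructed = vars, measured = vars))
  failed <- character(0)
  for (j in vars) {
    col <- tryCatch(
      eoc_run(params, j, truth, Q, noise_frac, dt, seed, transient, x0, P0),
      error = function(e) {
        warning("assimilation failed for measured variable ", j, ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(col)) failed <- c(failed, j) else M[, j] <- col[vars]
  }
  structure(M, class = c("eoc_matrix", class(M)), failed = failed,
            duration = duration, Q = Q, noise_frac = noise_frac, seed = seed)
}

#' EOC under joint measurement of several variables
#'
#' Same identical-twin design as [eoc_matrix()], but observing two or more
#' variables simultaneously; returns the single resulting EOC column.
#'
#' @inheritParams eoc_matrix
#' @param measured character vector (length >= 2 typically) of jointly
#'   observed variables.
#' @return named vector of EOC values, one per state variable.
#' @export
eoc_multi <- function(params, measured, duration = 12 * 3600, dt = 0.5,
                      noise_frac = 0.04, Q = NULL, seed = 1,
                      include_delta = FALSE, transient = 3600) {
  if (!include_delta) params$noise$rate <- 0
  if (is.null(Q)) Q <- default_q(params, seed = seed)
  measured <- unique(measured)
  truth <- simulate_sleep(params, duration + transient, dt = dt, seed = seed)
  x0 <- default_init(params)
  P0 <- diag(pmax(Q, 1e-8) * 1e4, length(x0))
  eoc_run(params, measured, truth, Q, noise_frac, dt, seed, transient, x0, P0)
}

# off-diagonal row/column means used for the inflation-tuning ranking
eoc_rowcol_means <- function(M) {
  n <- nrow(M)
  offdiag <- function(v, i) mean(v[-i], na.rm = TRUE)
  list(row = vapply(seq_len(n), function(i) offdiag(M[i, ], i), numeric(1)),
       col = vapply(seq_len(n), function(j) offdiag(M[, j], j), numeric(1)))
}

#' Log-spaced sweep grid for one inflation entry
#'
#' Zero plus a logarithmic grid (7 points per decade) up to `q_max`,
#' covering `n_decades` decades below it.
#'
#' @param q_max largest value (the square of the variable's full range).
#' @param n_decades decades spanned below `q_max`.
#' @param pts_per_decade grid density.
#' @return increasing numeric vector starting at 0.
#' @export
q_sweep_grid <- function(q_max, n_decades = 5, pts_per_decade = 7) {
  stopifnot(q_max > 0)
  c(0, 10^seq(log10(q_max) - n_decades, log10(q_max),
              length.out = n_decades * pts_per_decade + 1))
}

#' EOC-guided optimization of the covariance-inflation diagonal
#'
#' Iteratively tunes `Q` using the ranked partial observability: compute the
#' EOC matrix; find the variable with the lowest off-diagonal mean row or
#' column; if its *column* is low (measuring it reconstructs others poorly)
#' sweep its `Q` entry upward, if its *row* is low (it is poorly
#' reconstructed from others) sweep downward; at each sweep value, assimilate
#' the designated measurement and keep the `Q` entry maximizing the mean EOC
#' over all reconstructed variables. A sweep is accepted only if that mean
#' improves; iteration stops at `max_iter`, on improvement below `tol`, or
#' when the matrix carries no ranking information.
#'
#' @inheritParams eoc_matrix
#' @param observe_var the measured variable the filter is being tuned for.
#' @param Q0 starting inflation diagonal; default [default_q()].
#' @param max_iter maximum accepted iterations.
#' @param tol minimum improvement in mean EOC to continue.
#' @param include_delta include the stochastic thalamic process (default
#'   `TRUE` here: tuning its inflation entry is the typical use).
#' @return list with `Q` (tuned diagonal), `history` (one row per iteration:
#'   variable, direction, chosen value, mean EOC before/after), and
#'   `matrices` (the EOC matrix at each iteration).
#' @export
optimize_q <- function(params, observe_var = "F_LC", duration = 6 * 3600,
                       dt = 0.5, noise_frac = 0.04, Q0 = NULL, seed = 1,
                       max_iter = 3, tol = 1e-3, include_delta = TRUE,
                       transient = 3600) {
  if (!include_delta) params$noise$rate <- 0
  if (is.null(Q0)) Q0 <- default_q(params, seed = seed)
  Q <- Q0
  nm <- state_names(params)
  truth <- simulate_sleep(params, duration + transient, dt = dt, seed = seed)
  rng <- apply(truth[nm], 2, function(v) diff(range(v)))
  x0 <- default_init(params)
  col_mean_eoc <- function(Qx) {
    P0 <- diag(pmax(Qx, 1e-8) * 1e4, length(x0))
    v <- eoc_run(params, observe_var, truth, Qx, noise_frac, dt, seed,
                 transient, x0, P0)
    mean(v, na.rm = TRUE)
  }
  history <- list()
  matrices <- list()
  current <- col_mean_eoc(Q)
  for (it in seq_len(max_iter)) {
    M <- eoc_matrix(params, duration = duration, dt = dt,
                    noise_frac = noise_frac, Q = Q, seed = seed,
                    include_delta = include_delta, transient = transient)
    matrices[[it]] <- M
    if (max(M, na.rm = TRUE) - min(M, na.rm = TRUE) < 1e-12) break
    rc <- eoc_rowcol_means(M)
    vars <- rownames(M)
    if (min(rc$col, na.rm = TRUE) <= min(rc$row, na.rm = TRUE)) {
      v <- vars[which.min(rc$col)]
      direction <- "increase"
    } else {
      v <- vars[which.min(rc$row)]
      direction <- "decrease"
    }
    vi <- match(v, nm)
    grid <- q_sweep_grid(rng[v]^2)
    grid <- if (direction == "increase") grid[grid >= Q[vi]]
            else grid[grid <= Q[vi]]
    if (length(grid) < 2) break
    scores <- vapply(grid, function(q) {
      Qt <- Q; Qt[vi] <- q
      col_mean_eoc(Qt)
    }, numeric(1))
    best <- which.max(scores)
    improved <- scores[best] - current
    history[[length(history) + 1]] <-
      data.frame(iteration = it, variable = v, direction = direction,
                 q_before = Q[vi], q_after = grid[best],
                 mean_eoc_before = current, mean_eoc_after = scores[best],
                 accepted = improved > 0)
    if (improved <= 0) break
    Q[vi] <- grid[best]
    if (improved < tol) { current <- scores[best]; break }
    current <- scores[best]
  }
  list(Q = Q, history = do.call(rbind, history), matrices = matrices)
}
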