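#' Multiple-shooting configuration
#'
#' Settings for windowed parameter estimation: reconstruction windows of
#' length `window_s` (default half an hour, longer than a typical sleep-wake
#' cycle) advanced with `overlap` fractional overlap (default 0.8, i.e. an
#' update period of 6 minutes), short model-generated segments of
#' `segment_s` (2 minutes) re-anchored on the reconstruction, a candidate
#' grid of `n_candidates` test values spanning `+/- span_frac` of the
#' current estimate, and a per-iteration cap `max_step_frac` on the relative
#' parameter update.
#'
#' @param window_s window length T_w (s).
#' @param overlap fractional window overlap in `[0, 1)`; the update period
#'   is `window_s * (1 - overlap)`.
#' @param segment_s length of the short shooting segments (s).
#' @param n_candidates test parameter values per iteration (odd keeps the
#'   current estimate on the grid).
#' @param span_frac half-width of the candidate grid, relative.
#' @param max_step_frac cap on the relative parameter change per iteration.
#' @param refine factor applied to `span_frac` when the cost minimum is
#'   interior on consecutive iterations; set to 1 to disable refinement.
#' @param min_span_frac floor for the refined span.
#' @param min_scale absolute floor on the parameter scale used for the grid
#'   and the step cap, so estimates passing through zero keep a usable
#'   search range.
#' @param burn_in_s seconds of assimilation discarded before the first
#'   parameter update, so the filter's convergence transient (during which
#'   the reconstruction is poor) cannot bias the cost.
#' @param tol relative change defining convergence.
#' @param converge_windows consecutive windows below `tol` required to stop.
#' @return an object of class `shooting_config`.
#' @export
shooting_config <- function(window_s = 1800, overlap = 0.8, segment_s = 120,
                            n_candidates = 11, span_frac = 0.3,
                            max_step_frac = 0.1, refine = 0.5,
                            min_span_frac = 0.02, min_scale = 0.05,
                            burn_in_s = 1800, tol = 1e-3,
                            converge_windows = 5) {
  stopifnot(overlap >= 0, overlap < 1, segment_s < window_s,
            n_candidates >= 3, span_frac > 0, max_step_frac > 0)
  structure(list(window_s = window_s, overlap = overlap,
                 segment_s = segment_s, n_candidates = n_candidates,
                 span_frac = span_frac, max_step_frac = max_step_frac,
                 refine = refine, min_span_frac = min_span_frac,
                 min_scale = min_scale, burn_in_s = burn_in_s, tol = tol,
                 converge_windows = converge_windows),
            class = "shooting_config")
}

#' Multiple-shooting cost of a candidate parameter value
#'
#' Partitions a reconstruction window into segments of `segment_s`,
#' initializes the deterministic model on the reconstructed trajectory at
#' each segment start, integrates forward with the candidate parameter, and
#' returns the window-averaged squared divergence between the model segments
#' and the reconstruction, restricted to the measured variables and weighted
#' by the inverse standard deviation of each measured variable over the
#' window. Returns `Inf` when a segment integration leaves the finite
#' domain (infeasible candidate).
#'
#' @param p_test candidate value of the parameter.
#' @param param dotted name of the parameter (see [param_set()]).
#' @param recon a `ukf_recon` (or its `est` data.frame) covering one window.
#' @param params the filter-model parameter set the candidate is patched
#'   into.
#' @param measured names of the measured variables the cost is computed on.
#' @param cfg a [shooting_config()].
#' @param dt integration step (s).
#' @param weights optional named per-variable weights; default
#'   `1/sd(variable)` computed from the window's reconstruction.
#' @return non-negative scalar cost.
#' @export
shooting_cost <- function(p_test, param, recon, params, measured, cfg,
                          dt = 0.5, weights = NULL) {
  est <- if (inherits(recon, "ukf_recon")) recon$est else recon
  nm <- state_names(params)
  stopifnot(all(nm %in% names(est)), all(measured %in% nm))
  obs_idx <- match(measured, nm)
  if (is.null(weights)) {
    sds <- vapply(measured, function(v) stats::sd(est[[v]]), numeric(1))
    if (any(sds == 0)) stop("measured variable with zero spread in window",
                            call. = FALSE)
    weights <- 1 / sds
  }
  pt <- param_set(params, param, p_test)
  pt$noise$rate <- 0
  seg_steps <- max(1L, as.integer(round(cfg$segment_s / dt)))
  cpp_shooting_cost(t(as.matrix(est[nm])), est$t[1], dt, seg_steps,
                    obs_idx, as.numeric(weights), flatten_params(pt))
}

# shared windowed estimation loop; `stop_on_converge` distinguishes the
# static-parameter estimator from the tracker
shoot_loop <- function(obs, cfg_ukf, params, param, init, shoot_cfg,
                       x0, P0, stop_on_converge, verbose = FALSE) {
  dt <- cfg_ukf$dt
  win_steps <- as.integer(round(shoot_cfg$window_s / dt))
  upd_steps <- max(1L, as.integer(round(shoot_cfg$window_s *
                                          (1 - shoot_cfg$overlap) / dt)))
  Tn <- nrow(obs$y)
  if (Tn < win_steps)
    stop("observation record shorter than one estimation window",
         call. = FALSE)
  nm <- state_names(params)
  est_val <- init
  span <- shoot_cfg$span_frac
  cur_params <- param_set(params, param, est_val)
  if (is.null(x0)) x0 <- default_init(params)
  if (is.null(P0)) P0 <- diag(pmax(cfg_ukf$Q, 1e-8) * 1e4, length(x0))
  x <- as.numeric(x0); P <- P0
  recon_buf <- NULL
  t_buf <- NULL
  pos <- 0L
  track <- list()
  interior_prev <- FALSE
  small_changes <- 0L
  while (pos + upd_steps <= Tn) {
    idx <- (pos + 1L):(pos + upd_steps)
    sub <- structure(list(t = obs$t[idx],
                          y = obs$y[idx, , drop = FALSE],
                          R = obs$R[idx, , drop = FALSE],
                          vars = obs$vars), class = "obs_series")
    cfg_i <- ukf_config(cur_params, cfg_ukf$Q, dt = dt,
                        t0 = sub$t[1] - dt)
    rec <- assimilate(sub, cfg_i, x0 = x, P0 = P)
    x <- rec$x_final; P <- rec$P_final
    recon_buf <- rbind(recon_buf, as.matrix(rec$est[nm]))
    t_buf <- c(t_buf, rec$est$t)
    if (nrow(recon_buf) > win_steps) {
      drop <- seq_len(nrow(recon_buf) - win_steps)
      recon_buf <- recon_buf[-drop, , drop = FALSE]
      t_buf <- t_buf[-drop]
    }
    pos <- pos + upd_steps
    if (nrow(recon_buf) < win_steps) next
    if (max(t_buf) - obs$t[1] < shoot_cfg$burn_in_s + shoot_cfg$window_s)
      next  # filter still in its convergence transient
    win <- data.frame(t = t_buf, recon_buf, check.names = FALSE)
    scale <- max(abs(est_val), shoot_cfg$min_scale)
    grid <- est_val + scale * seq(-span, span,
                                  length.out = shoot_cfg$n_candidates)
    costs <- vapply(grid, function(p_test)
      tryCatch(shooting_cost(p_test, param, win, params, obs$vars,
                             shoot_cfg, dt = dt),
               error = function(e) Inf), numeric(1))
    if (all(!is.finite(costs)))
      stop("all candidate parameter values were infeasible in window ending ",
           max(t_buf), " s", call. = FALSE)
    best <- which.min(costs)
    proposal <- grid[best]
    cap <- shoot_cfg$max_step_frac * scale
    new_val <- est_val + max(-cap, min(cap, proposal - est_val))
    interior <- best > 1 && best < length(grid)
    if (interior && interior_prev)
      span <- max(shoot_cfg$min_span_frac, span * shoot_cfg$refine)
    interior_prev <- interior
    rel_change <- abs(new_val - est_val) / max(abs(est_val), 1e-12)
    est_val <- new_val
    cur_params <- param_set(cur_params, param, est_val)
    track[[length(track) + 1L]] <-
      data.frame(t_center = mean(range(t_buf)), estimate = est_val,
                 min_cost = min(costs, na.rm = TRUE))
    if (verbose)
      message(sprintf("window ending %.0f s: %s = %.6g (cost %.4g)",
                      max(t_buf), param, est_val, min(costs)))
    if (stop_on_converge) {
      small_changes <- if (rel_change < shoot_cfg$tol) small_changes + 1L
                       else 0L
      if (small_changes >= shoot_cfg$converge_windows) break
    }
  }
  out <- do.call(rbind, track)
  structure(list(track = out, estimate = est_val, param = param,
                 converged = stop_on_converge &&
                   small_changes >= shoot_cfg$converge_windows,
                 params = cur_params),
            class = "param_track")
}

#' Estimate a stationary model parameter by multiple shooting
#'
#' Alternates between state reconstruction and parameter update: the UKF
#' assimilates the observations with the current parameter value; over each
#' (overlapping) window the shooting cost is evaluated on a candidate grid
#' around the current estimate; the estimate moves to the minimizer, capped
#' at `max_step_frac` relative change per window; the updated parameter is
#' used for the next stretch of assimilation. Stops once the relative change
#' stays below `tol` for `converge_windows` consecutive windows, or at the
#' end of the record.
#'
#' @param obs an `obs_series` of the measured variables.
#' @param cfg_ukf a [ukf_config()] whose model carries the filter parameter
#'   set (with the parameter of interest at its initial guess or any value;
#'   `init` takes precedence).
#' @param param dotted name of the parameter (e.g. `"coupling.A_LC"`).
#' @param init initial guess for the parameter value.
#' @param shoot_cfg a [shooting_config()].
#' @param x0,P0 initial filter state and covariance.
#' @param verbose print one line per window.
#' @return an object of class `param_track`: list with `track` (data.frame
#'   `t_center`, `estimate`, `min_cost`), the final `estimate`, a
#'   `converged` flag, and the parameter set patched with the estimate.
#' @export
estimate_parameter <- function(obs, cfg_ukf, param, init,
                               shoot_cfg = shooting_config(),
                               x0 = NULL, P0 = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg_ukf$model, "sleep_params"))
  shoot_loop(obs, cfg_ukf, cfg_ukf$model, param, init, shoot_cfg,
             x0, P0, stop_on_converge = TRUE, verbose = verbose)
}

#' Track a slowly varying parameter in overlapping windows
#'
#' Same windowed multiple-shooting machinery as [estimate_parameter()], but
#' never declaring convergence: one estimate is produced per overlapping
#' window, anchored at the window's center time. The track is inherently
#' smoothed at the window scale, so it follows the mean of dynamics slower
#' than the update period (e.g. a quasi-static circadian drive) while
#' ignoring faster oscillations.
#'
#' @inheritParams estimate_parameter
#' @param param dotted parameter name; default `"a_scn"`, the additive
#'   drive standing in for unmodeled SCN input.
#' @return a `param_track` object; `track$t_center` gives the window centers.
#' @export
track_parameter <- function(obs, cfg_ukf, param = "a_scn", init = 0,
                            shoot_cfg = shooting_config(refine = 1),
                            x0 = NULL, P0 = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg_ukf$model, "sleep_params"))
  shoot_loop(obs, cfg_ukf, cfg_ukf$model, param, init, shoot_cfg,
             x0, P0, stop_on_converge = FALSE, verbose = verbose)
}

#' @export
print.param_track <- function(x, ...) {
  cat("<param_track>", x$param, ":", nrow(x$track), "windows; final estimate",
      signif(x$estimate, 6),
      if (isTRUE(x$converged)) "(converged)" else "", "\n")
  invisible(x)
}

#' Dominant spectral period of a tracked parameter series
#'
#' Least-squares periodogram peak of a `param_track` series, returned as a
#' period in hours: after linear detrending, a sinusoid is regressed onto
#' the series at each candidate period and the period with the largest
#' explained sum of squares wins. Unlike a raw FFT periodogram, the
#' least-squares power is evaluated on an arbitrarily fine period grid and
#' stays unbiased for records spanning only a few cycles of the rhythm of
#' interest — the typical situation when recovering a circadian cycle from
#' a day or two of tracked quasi-static drive.
#'
#' @param track a `param_track` object or a data.frame with `t_center` and
#'   `estimate`.
#' @param min_period,max_period candidate period range (s); defaults to 8
#'   sample spacings up to 1.2 times the record span.
#' @param n_grid number of candidate periods.
#' @return dominant period in hours.
#' @export
dominant_period <- function(track, min_period = NULL, max_period = NULL,
                            n_grid = 2000) {
  tr <- if (inherits(track, "param_track")) track$track else track
  stopifnot(nrow(tr) >= 8)
  t <- tr$t_center
  span <- diff(range(t))
  if (is.null(min_period)) min_period <- 8 * stats::median(diff(t))
  if (is.null(max_period)) max_period <- 1.2 * span
  x <- stats::residuals(stats::lm(tr$estimate ~ t))
  periods <- seq(min_period, max_period, length.out = n_grid)
  power <- vapply(periods, function(P) {
    X <- cbind(cos(2 * pi * t / P), sin(2 * pi * t / P))
    sum(stats::lm.fit(X, x)$fitted.values^2)
  }, numeric(1))
  periods[which.max(power)] / 3600
}
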