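#' Build the state-conditioned observation map
#'
#' Simulates the filter model, scores the state of vigilance, and computes
#' the median and standard deviation of each mapped variable conditioned on
#' each sleep state. The resulting map converts a hypnogram into
#' pseudo-observations: within a scored state, the state-conditioned median
#' is used as the "observed" value of each mapped variable and the
#' state-conditioned variance as its measurement uncertainty.
#'
#' @param params a `sleep_params` object (the filter model).
#' @param duration simulation length (s); must cover several sleep-wake
#'   cycles so all three states occur.
#' @param seed simulation seed.
#' @param variables variables to map; default `F_LC`, `F_VLPO`, `F_R` (the
#'   wake-, NREM- and REM-active firing rates that define the scoring).
#' @param dt integration step (s).
#' @param transient seconds discarded before conditioning.
#' @param var_floor_frac variance floor as a fraction of each variable's
#'   squared range, guarding against near-degenerate conditional
#'   distributions.
#' @return an object of class `sov_obs_map`: list with `median` and `sd`
#'   (state x variable matrices), the variable names, and provenance
#'   metadata (`duration`, `seed`).
#' @export
build_observation_map <- function(params, duration = 6 * 3600, seed = 1,
                                  variables = c("F_LC", "F_VLPO", "F_R"),
                                  dt = 0.5, transient = 1800,
                                  var_floor_frac = 1e-6) {
  traj <- simulate_sleep(params, duration, dt = dt, seed = seed)
  keep <- traj$t - traj$t[1] >= transient
  traj <- traj[keep, , drop = FALSE]
  lab <- score_sov(traj, params)
  present <- sort(unique(lab))
  if (!all(sov_levels %in% present))
    stop("not all vigilance states occurred in the mapping simulation; ",
         "increase its duration", call. = FALSE)
  states <- names(sov_levels)
  med <- sdm <- matrix(NA_real_, length(states), length(variables),
                       dimnames = list(states, variables))
  for (s in states) {
    rows <- lab == sov_levels[[s]]
    for (v in variables) {
      med[s, v] <- stats::median(traj[[v]][rows])
      sdm[s, v] <- stats::sd(traj[[v]][rows])
    }
  }
  floor_sd <- vapply(variables, function(v)
    sqrt(var_floor_frac) * diff(range(traj[[v]])), numeric(1))
  sdm <- pmax(sdm, rep(floor_sd, each = length(states)))
  structure(list(median = med, sd = sdm, variables = variables,
                 duration = duration, seed = seed),
            class = "sov_obs_map")
}

#' @export
print.sov_obs_map <- function(x, ...) {
  cat("<sov_obs_map> variables:", paste(x$variables, collapse = ", "),
      "| built from", x$duration, "s, seed", x$seed, "\n")
  print(round(x$median, 3))
  invisible(x)
}

#' Convert a hypnogram into pseudo-observations
#'
#' At each step the "observed" vector is the state-conditioned medians for
#' the hypnogram's label, and the measurement-noise variances are the
#' state-conditioned variances — so the uncertainty handed to the filter is
#' time dependent, changing exactly at the hypnogram's transitions.
#'
#' @param hyp a hypnogram: data.frame with columns `t` (s, uniform) and
#'   `sov` (integer 0 = Wake, 1 = NREM, 2 = REM).
#' @param map a [build_observation_map()] result covering all labels
#'   present.
#' @return an `obs_series` usable by [assimilate()].
#' @export
infer_observations <- function(hyp, map) {
  stopifnot(all(c("t", "sov") %in% names(hyp)), inherits(map, "sov_obs_map"))
  if (!all(hyp$sov %in% sov_levels))
    stop("hypnogram contains labels outside {0,1,2}", call. = FALSE)
  srow <- match(hyp$sov, sov_levels)  # row index into the map
  y <- map$median[srow, , drop = FALSE]
  R <- map$sd[srow, , drop = FALSE]^2
  rownames(y) <- rownames(R) <- NULL
  structure(list(t = hyp$t, y = y, R = R, vars = map$variables),
            class = "obs_series")
}

#' Reconstruct model state from a hypnogram
#'
#' Composition of [infer_observations()] and [assimilate()]: the discretized
#' state of vigilance is translated into state-conditioned
#' pseudo-observations with time-varying uncertainty, and the UKF
#' reconstructs the full state — including variables never observed, such as
#' the homeostatic drive. Details the scoring does not resolve (brief
#' awakenings, individual NREM transitions) are not expected to be
#' recovered.
#'
#' @param hyp hypnogram data.frame (`t`, `sov`), sampled at the filter step.
#' @param map a [build_observation_map()] result.
#' @param cfg a [ukf_config()].
#' @param x0,P0 initial filter state and covariance.
#' @return a `ukf_recon`.
#' @export
assimilate_hypnogram <- function(hyp, map, cfg, x0 = NULL, P0 = NULL) {
  obs <- infer_observations(hyp, map)
  assimilate(obs, cfg, x0 = x0, P0 = P0)
}

#' Median-map baseline reconstruction
#'
#' The trivial reconstruction that uses the state-conditioned medians
#' themselves as the estimate of every mapped variable (and carries no
#' estimate at all for unmapped ones). Serves as the reference the filter
#' must beat.
#'
#' @inheritParams infer_observations
#' @return data.frame with `t` and one column per mapped variable.
#' @export
median_map_reconstruction <- function(hyp, map) {
  obs <- infer_observations(hyp, map)
  data.frame(t = obs$t, obs$y)
}

#' Estimate a parameter from a hypnogram
#'
#' [estimate_parameter()] driven by the pseudo-observations of
#' [infer_observations()]: the shooting cost is restricted to the mapped
#' variables and the time-varying state-conditioned uncertainties are used
#' as the measurement noise.
#'
#' @inheritParams assimilate_hypnogram
#' @inheritParams estimate_parameter
#' @return a `param_track`.
#' @export
estimate_parameter_from_hypnogram <- function(hyp, map, cfg_ukf, param, init,
                                              shoot_cfg = shooting_config(),
                                              x0 = NULL, P0 = NULL,
                                              verbose = FALSE) {
  obs <- infer_observations(hyp, map)
  estimate_parameter(obs, cfg_ukf, param, init, shoot_cfg,
                     x0 = x0, P0 = P0, verbose = verbose)
}

#' Read and write hypnogram CSV files
#'
#' Plain CSV with columns `t_seconds` and `sov` (0 = Wake, 1 = NREM,
#' 2 = REM).
#'
#' @param hyp data.frame with `t` and `sov`.
#' @param path file path.
#' @return `read_hypnogram()`: data.frame with `t`, `sov`;
#'   `write_hypnogram()`: `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(all(c("t", "sov") %in% names(hyp)))
  utils::write.csv(data.frame(t_seconds = hyp$t, sov = as.integer(hyp$sov)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  if (!file.exists(path)) stop("no such hypnogram file: ", path, call. = FALSE)
  d <- utils::read.csv(path)
  stopifnot(all(c("t_seconds", "sov") %in% names(d)))
  data.frame(t = d$t_seconds, sov = as.integer(d$sov))
}

#' Hold a coarse hypnogram onto the filter grid
#'
#' Zero-order hold: each coarse label applies until the next one, sampled at
#' the filter step `dt`.
#'
#' @param hyp data.frame with `t`, `sov` at a coarser uniform spacing.
#' @param dt target step (s); must divide the hypnogram spacing.
#' @return data.frame with `t`, `sov` on the fine grid.
#' @export
regrid_hypnogram <- function(hyp, dt) {
  t_fine <- seq(min(hyp$t), max(hyp$t), by = dt)
  idx <- findInterval(t_fine + 1e-9, hyp$t)
  data.frame(t = t_fine, sov = hyp$sov[idx])
}
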