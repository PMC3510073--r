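#' Steady-state firing rate of a cell group
#'
#' The saturating response `F_max/2 * (1 + tanh((c - beta)/alpha))` of a
#' population to its summed weighted transmitter input. For the VLPO the
#' midpoint is not constant but shifts with the homeostatic sleep drive,
#' `beta(h) = beta - k*h`, so accumulated sleep pressure lowers the firing
#' threshold of the sleep-active population.
#'
#' @param c_in summed weighted input concentration (can be a vector).
#' @param group one element of `params$groups`, e.g. `db_params()$groups$lc`.
#' @param h homeostatic drive; only used when `group` carries a threshold
#'   coefficient `k` (the VLPO).
#' @return firing rate(s) in Hz, in `(0, F_max)`.
#' @export
steady_state_firing <- function(c_in, group, h = 0) {
  if (group$alpha == 0) stop("sigmoid slope alpha must be nonzero", call. = FALSE)
  beta <- group$beta
  if (!is.null(group$k)) beta <- beta - group$k * h
  0.5 * group$F_max * (1 + tanh((c_in - beta) / group$alpha))
}

#' Steady-state transmitter concentration released by a cell group
#'
#' Monotone saturating release `tanh(F / gamma)` in normalized concentration
#' units: zero at zero firing, saturating at 1 for firing rates well above
#' the scale parameter `gamma`.
#'
#' @param F firing rate (Hz), non-negative.
#' @param group one element of `params$groups` (supplies `gamma`).
#' @return concentration(s) in `[0, 1)`.
#' @export
steady_state_concentration <- function(F, group) {
  if (any(F < 0)) stop("firing rate must be non-negative", call. = FALSE)
  tanh(F / group$gamma)
}

#' Time derivative of the homeostatic sleep drive
#'
#' `h` accumulates toward `h_max` with time constant `tau_acc` while the
#' wake-active firing rate exceeds the threshold `theta`, and decays toward 0
#' with time constant `tau_diss` otherwise (Heaviside switching).
#'
#' @param h current drive, in `[0, h_max]`.
#' @param F_wake wake-active firing rate (Hz); the model uses `F_LC`.
#' @param hp the `homeostatic` block of a `sleep_params` object.
#' @return dh/dt in 1/s.
#' @export
homeostatic_derivative <- function(h, F_wake, hp) {
  ifelse(F_wake > hp$theta, (hp$h_max - h) / hp$tau_acc, -h / hp$tau_diss)
}

#' One step of the stochastic thalamic input process
#'
#' Random excitatory thalamocortical projections onto the wake-active
#' populations are modeled as Poisson impulses (rate `rate`, default
#' 0.003 Hz) feeding a leaky integrator with decay constant `tau_delta`.
#' Between impulses `delta` decays exponentially; each impulse adds
#' `impulse_amplitude`. Uses R's RNG, so the stream is reproducible under
#' `set.seed()`.
#'
#' @param delta current value.
#' @param dt time step (s), positive.
#' @param np the `noise` block of a `sleep_params` object.
#' @return updated value after `dt`.
#' @export
thalamic_noise_step <- function(delta, dt, np) {
  stopifnot(dt > 0)
  delta * exp(-dt / np$tau_delta) +
    stats::rpois(1L, np$rate * dt) * np$impulse_amplitude
}

#' Simulate the Poisson impulse process alone
#'
#' Convenience generator for the thalamic input: returns the impulse counts
#' per step and the resulting `delta` series. Used to characterize the noise
#' process (e.g. its empirical impulse rate) independently of the network.
#'
#' @inheritParams thalamic_noise_step
#' @param duration total simulated time (s).
#' @param delta0 initial value.
#' @return data.frame with columns `t`, `impulses`, `delta`.
#' @export
simulate_noise <- function(duration, dt, np, delta0 = 0) {
  n <- round(duration / dt)
  counts <- stats::rpois(n, np$rate * dt)
  decay <- exp(-dt / np$tau_delta)
  delta <- numeric(n + 1)
  delta[1] <- delta0
  for (i in seq_len(n))
    delta[i + 1] <- delta[i] * decay + counts[i] * np$impulse_amplitude
  data.frame(t = seq(0, by = dt, length.out = n + 1),
             impulses = c(NA_integer_, counts), delta = delta)
}

#' Circadian drive of the SCN
#'
#' Sinusoid with period `period_h` hours, amplitude `circ_amplitude` and mean
#' `circ_offset`, phased so the drive is high during the light phase, which
#' starts at `light_onset_h` (06:00 by default) and spans half the period.
#' `t = 0` is midnight.
#'
#' @param t time (s), vectorized.
#' @param scn the `scn` block of an FBFD `sleep_params` object.
#' @return drive value(s).
#' @export
circ_drive <- function(t, scn) {
  scn$circ_offset + scn$circ_amplitude *
    sin(2 * pi * (t - scn$light_onset_h * 3600) / (scn$period_h * 3600))
}

#' Full model vector field
#'
#' Time derivative of the 12-variable core model (or 14-variable circadian
#' extension) at state `state` and time `t`. Each firing rate and transmitter
#' concentration relaxes toward its steady-state target; inputs are the
#' signed weighted transmitter sums with total ACh taken as
#' `C_AR + C_AWR`; the thalamic input decays (impulses are injected by the
#' integrator, not the vector field); the FBFD variant adds the circadian SCN
#' group and its GABAergic feed-forward projections.
#'
#' This is a reference implementation in R, composed from the steady-state
#' primitives; [simulate_sleep()] and the filter use an identical compiled
#' version.
#'
#' @param state numeric state vector in the canonical order
#'   ([state_names()]).
#' @param t time (s); only the FBFD variant is time-dependent.
#' @param params a `sleep_params` object.
#' @return the derivative vector, same length and order as `state`.
#' @export
model_derivative <- function(state, t, params) {
  d <- state_dim(params)
  if (length(state) != d)
    stop("state has length ", length(state), " but variant '", params$variant,
         "' has dimension ", d, call. = FALSE)
  g <- params$coupling
  gr <- params$groups
  C_A <- state[9] + state[10]
  s_lc <- s_dr <- s_v <- s_r <- 0
  if (params$variant == "fbfd") {
    cgs <- state[14]
    s <- params$scn
    s_lc <- s$g_scn_LC * cgs; s_dr <- s$g_scn_DR * cgs
    s_v <- s$g_scn_VLPO * cgs; s_r <- s$g_scn_R * cgs
  }
  a <- params$a_scn
  c_lc <- g$A_LC * C_A + g$G_LC * state[8] + g$D_LC * state[12] + a + s_lc
  c_dr <- g$A_DR * C_A + g$G_DR * state[8] + g$D_DR * state[12] + a + s_dr
  c_v <- g$N_VLPO * state[6] + g$S_VLPO * state[7] + a + s_v
  c_r <- g$A_R * C_A + g$N_R * state[6] + g$S_R * state[7] +
    g$G_R * state[8] + a + s_r
  c_wr <- g$A_WR * C_A + g$G_WR * state[8]
  dF <- c((steady_state_firing(c_lc, gr$lc) - state[1]) / gr$lc$tau_F,
          (steady_state_firing(c_dr, gr$dr) - state[2]) / gr$dr$tau_F,
          (steady_state_firing(c_v, gr$vlpo, h = state[11]) - state[3]) / gr$vlpo$tau_F,
          (steady_state_firing(c_r, gr$r) - state[4]) / gr$r$tau_F,
          (steady_state_firing(c_wr, gr$wr) - state[5]) / gr$wr$tau_F)
  # raw tanh release (not the guarded steady_state_concentration) so the
  # vector field stays defined for transiently negative sigma-point states
  dC <- c((tanh(state[1] / gr$lc$gamma) - state[6]) / gr$lc$tau_C,
          (tanh(state[2] / gr$dr$gamma) - state[7]) / gr$dr$tau_C,
          (tanh(state[3] / gr$vlpo$gamma) - state[8]) / gr$vlpo$tau_C,
          (tanh(state[4] / gr$r$gamma) - state[9]) / gr$r$tau_C,
          (tanh(state[5] / gr$wr$gamma) - state[10]) / gr$wr$tau_C)
  dh <- homeostatic_derivative(state[11], state[1], params$homeostatic)
  ddel <- -state[12] / params$noise$tau_delta
  out <- c(dF, dC, dh, ddel)
  if (params$variant == "fbfd") {
    s <- params$scn
    c_scn <- circ_drive(t, s) + s$g_feedback * (state[7] + C_A)
    dscn <- (steady_state_firing(c_scn, s) - state[13]) / s$tau_F
    dcgs <- (tanh(state[13] / s$gamma) - state[14]) / s$tau_C
    out <- c(out, dscn, dcgs)
  }
  out
}

#' A generic resting initial state
#'
#' Wake-like initial condition used when no initial state is supplied:
#' wake-active groups firing, sleep- and REM-active groups quiescent,
#' homeostatic drive at half saturation.
#'
#' @param params a `sleep_params` object.
#' @return named numeric state vector.
#' @export
default_init <- function(params) {
  x <- c(F_LC = 6, F_DR = 5.5, F_VLPO = 0.1, F_R = 0.1, F_WR = 4,
         C_N = 0.8, C_S = 0.75, C_G = 0.1, C_AR = 0.05, C_AWR = 0.9,
         h = 0.5, delta = 0)
  if (params$variant == "fbfd") x <- c(x, F_SCN = 0, C_SCN = 0)
  x
}

#' Simulate a sleep-wake trajectory
#'
#' Integrates the model with classical 4th-order Runge-Kutta at fixed step
#' `dt` (0.5 s by default). The deterministic vector field is integrated
#' exactly as written; Poisson thalamic impulses are applied as discrete
#' jumps to `delta` between RK4 steps, so the integrator keeps its order on
#' the deterministic part. Identical `seed` and configuration give an
#' identical trajectory.
#'
#' @param params a `sleep_params` object.
#' @param duration simulated time (s).
#' @param dt integration step (s), default 0.5.
#' @param seed optional integer seed applied with `set.seed()` before
#'   drawing the impulse counts.
#' @param init initial state (canonical order); default [default_init()].
#' @param t0 start time (s since midnight), relevant for the FBFD variant.
#' @return a data.frame of class `sleep_traj` with column `t` and one column
#'   per state variable, one row per step.
#' @export
simulate_sleep <- function(params, duration, dt = 0.5, seed = NULL,
                           init = NULL, t0 = 0) {
  stopifnot(dt > 0, duration >= dt)
  if (is.null(init)) init <- default_init(params)
  d <- state_dim(params)
  if (length(init) != d) stop("init has wrong dimension", call. = FALSE)
  n <- round(duration / dt)
  if (!is.null(seed)) set.seed(seed)
  impulses <- if (params$noise$rate > 0)
    stats::rpois(n, params$noise$rate * dt) else integer(n)
  pv <- flatten_params(params)
  m <- cpp_rk4_path(as.numeric(init), t0, dt, n, pv, as.integer(impulses),
                    params$noise$impulse_amplitude)
  colnames(m) <- state_names(params)
  out <- data.frame(t = t0 + seq(0, by = dt, length.out = n + 1), m)
  class(out) <- c("sleep_traj", "data.frame")
  attr(out, "variant") <- params$variant
  attr(out, "dt") <- dt
  out
}

#' Score the state of vigilance
#'
#' Rank-ordered scoring of Wake / NREM / REM from the firing rates, with the
#' REM-active population dominating the definition: a sample is REM whenever
#' `F_R` exceeds `rem_frac * F_max(R)`; otherwise it is Wake when `F_LC`
#' exceeds `wake_frac * F_max(LC)` and NREM when it does not. Thresholds are
#' taken from `params$sov` and expressed as fractions of each population's
#' maximum rate.
#'
#' @param traj a `sleep_traj` data.frame (or any data.frame with columns
#'   `F_LC`, `F_VLPO`, `F_R`).
#' @param params a `sleep_params` object.
#' @return integer vector, one label per row: 0 = Wake, 1 = NREM, 2 = REM.
#' @export
score_sov <- function(traj, params) {
  need <- c("F_LC", "F_VLPO", "F_R")
  if (!all(need %in% names(traj)))
    stop("trajectory must contain ", paste(need, collapse = ", "),
         call. = FALSE)
  rem_thr <- params$sov$rem_frac * params$groups$r$F_max
  wake_thr <- params$sov$wake_frac * params$groups$lc$F_max
  ifelse(traj$F_R >= rem_thr, 2L, ifelse(traj$F_LC >= wake_thr, 0L, 1L))
}

#' @rdname score_sov
#' @format NULL
#' @export
sov_levels <- c(Wake = 0L, NREM = 1L, REM = 2L)
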