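#' Read and write trajectory CSV files
#'
#' Delimited text with a header of canonical variable names (`t`, `F_LC`,
#' ..., `delta`[, `F_SCN`, `C_SCN`]), time in seconds, one row per step.
#' Values are written with full double precision (17 significant digits) so
#' a write/read round trip is lossless.
#'
#' @param traj a `sleep_traj` (or any data.frame with a `t` column).
#' @param path file path.
#' @return `read_trajectory()`: data.frame; `write_trajectory()`: `path`,
#'   invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot("t" %in% names(traj))
  df <- as.data.frame(lapply(traj, function(col)
    if (is.double(col)) sprintf("%.17g", col) else col))
  names(df) <- names(traj)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such trajectory file: ", path,
                               call. = FALSE)
  d <- utils::read.csv(path, colClasses = "numeric")
  if (!"t" %in% names(d)) stop("trajectory file has no 't' column",
                               call. = FALSE)
  d
}

#' Experiment configuration
#'
#' Serializable description of a full identical-twin experiment: a run is
#' reproducible from the configuration plus its seed alone.
#'
#' @param variant `"db"` or `"fbfd"`.
#' @param duration simulated time (s).
#' @param dt step (s).
#' @param seed integer seed for truth generation and observation noise.
#' @param observe_vars observed variables.
#' @param noise_frac observation-noise variance fraction.
#' @param q_multiplier multiplier for [default_q()].
#' @param transient seconds discarded before metrics.
#' @param params_overrides named list of parameter overrides.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(variant = "db", duration = 4 * 3600, dt = 0.5,
                              seed = 1, observe_vars = "F_LC",
                              noise_frac = 0.04, q_multiplier = 1e-4,
                              transient = 3600, params_overrides = list()) {
  stopifnot(variant %in% c("db", "fbfd"), duration > transient)
  structure(list(variant = variant, duration = duration, dt = dt,
                 seed = seed, observe_vars = observe_vars,
                 noise_frac = noise_frac, q_multiplier = q_multiplier,
                 transient = transient, params_overrides = params_overrides),
            class = "experiment_config")
}

#' Run a full identical-twin experiment
#'
#' simulate -> observe -> assimilate -> score: generates truth, applies the
#' noisy observation function, reconstructs with the UKF, and computes the
#' per-variable NMSE and EOC after the transient. When `out_dir` is given,
#' writes the truth and reconstruction CSVs, the metrics, and a JSON
#' manifest recording the configuration, seed, package version, and which
#' stages completed.
#'
#' @param cfg an [experiment_config()].
#' @param out_dir optional output directory.
#' @return list with `truth`, `obs`, `recon`, `metrics` (data.frame of NMSE
#'   and EOC per variable), and the manifest.
#' @export
run_experiment <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "experiment_config"))
  manifest <- list(config = unclass(cfg),
                   package_version = as.character(utils::packageVersion("sleepda")),
                   r_version = R.version.string,
                   stages = character(0))
  params <- if (cfg$variant == "fbfd") fbfd_params(cfg$params_overrides)
            else db_params(cfg$params_overrides)
  truth <- simulate_sleep(params, cfg$duration, dt = cfg$dt, seed = cfg$seed)
  manifest$stages <- c(manifest$stages, "simulate")
  obs <- observe(truth, cfg$observe_vars, noise_frac = cfg$noise_frac,
                 seed = cfg$seed + 1)
  manifest$stages <- c(manifest$stages, "observe")
  Q <- default_q(params, seed = cfg$seed, multiplier = cfg$q_multiplier)
  ucfg <- ukf_config(params, Q, dt = cfg$dt)
  recon <- assimilate(obs, ucfg)
  manifest$stages <- c(manifest$stages, "assimilate")
  keep <- recon$est$t - truth$t[1] >= cfg$transient
  rows <- match(recon$est$t, truth$t)
  nm <- state_names(params)
  metrics <- do.call(rbind, lapply(nm, function(v) {
    tv <- truth[[v]][rows][keep]
    if (stats::var(tv) == 0)
      return(data.frame(variable = v, nmse = NA_real_, eoc = NA_real_))
    e <- nmse(recon$est[[v]][keep], tv)
    data.frame(variable = v, nmse = e, eoc = eoc(e))
  }))
  manifest$stages <- c(manifest$stages, "metrics")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trajectory(truth, file.path(out_dir, "truth.csv"))
    write_trajectory(recon$est, file.path(out_dir, "recon.csv"))
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(truth = truth, obs = obs, recon = recon, metrics = metrics,
       manifest = manifest)
}

#' Generate small bundled fixtures for tests and examples
#'
#' `kind = "small"`: a 10-minute core-model trajectory plus its hypnogram
#' (contains all three vigilance states). `kind = "standard"`: a 12-hour
#' set for observability work. Regeneration under a fixed seed is
#' idempotent.
#'
#' @param kind `"small"` or `"standard"`.
#' @param seed integer seed.
#' @param dir output directory (created if needed); when `NULL`, nothing is
#'   written and the objects are returned.
#' @return list with `traj` and `hypnogram` (data.frames), invisibly when
#'   written to `dir`.
#' @export
make_fixture <- function(kind = c("small", "standard"), seed = 1,
                         dir = NULL) {
  kind <- match.arg(kind)
  params <- db_params()
  duration <- if (kind == "small") 600 else 12 * 3600
  init <- default_init(params)
  if (kind == "small") {
    # start on the cusp of a sleep episode so 10 minutes covers all states
    init["h"] <- 0.85
  }
  traj <- simulate_sleep(params, duration, seed = seed, init = init)
  hyp <- data.frame(t = traj$t, sov = score_sov(traj, params))
  out <- list(traj = traj, hypnogram = hyp)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_trajectory(traj, file.path(dir, paste0("traj_", kind, ".csv")))
    write_hypnogram(hyp, file.path(dir, paste0("hyp_", kind, ".csv")))
    return(invisible(out))
  }
  out
}
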