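#' Default parameters for the core sleep-wake network model
#'
#' Loads the packaged parameter set for the 12-variable sleep-wake regulatory
#' network: five neuronal populations (wake-active LC and DR, NREM-active
#' VLPO, REM-active R, wake/REM-active WR), the five transmitter
#' concentrations they release (NE, 5-HT, GABA and the two ACh pools whose sum
#' is the effective cholinergic input), the homeostatic sleep drive `h`, and
#' the stochastic thalamic input `delta`. Any entry can be overridden.
#'
#' @param overrides named list merged recursively into the defaults, e.g.
#'   `list(coupling = list(A_LC = 1.1))`.
#' @param file optional path to a YAML parameter file replacing the packaged
#'   defaults.
#' @return an object of class `sleep_params`.
#' @seealso [fbfd_params()] for the circadian extension,
#'   [simulate_sleep()], [write_params()].
#' @export
db_params <- function(overrides = list(), file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "db_params.yaml", package = "sleepda",
                        mustWork = TRUE)
  p <- yaml::read_yaml(file)
  p <- modify_list_deep(p, overrides)
  p$variant <- "db"
  validate_params(structure(p, class = "sleep_params"))
}

#' Default parameters for the circadian-extended sleep-wake model
#'
#' The core network of [db_params()] plus a suprachiasmatic nucleus (SCN)
#' cell group: an inherent 24-hour circadian drive (high during the 12-hour
#' light phase starting at 06:00), feedback from the sleep-wake network
#' through 5-HT and total ACh, and GABAergic feed-forward projections onto
#' the LC, DR, VLPO and R populations. The state gains `F_SCN` and `C_SCN`.
#'
#' @inheritParams db_params
#' @return an object of class `sleep_params` with `variant = "fbfd"`.
#' @export
fbfd_params <- function(overrides = list(), file = NULL) {
  base <- unclass(db_params())
  if (is.null(file))
    file <- system.file("extdata", "fbfd_params.yaml", package = "sleepda",
                        mustWork = TRUE)
  ext <- yaml::read_yaml(file)
  p <- modify_list_deep(base, ext)
  p <- modify_list_deep(p, overrides)
  p$variant <- "fbfd"
  validate_params(structure(p, class = "sleep_params"))
}

modify_list_deep <- function(base, new) {
  if (length(new) == 0) return(base)
  stopifnot(is.list(new))
  unknown <- setdiff(names(new), c(names(base), "scn"))
  if (length(unknown) > 0)
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    else
      base[[nm]] <- new[[nm]]
  }
  base
}

validate_params <- function(p) {
  stopifnot(inherits(p, "sleep_params"))
  if (!p$variant %in% c("db", "fbfd"))
    stop("variant must be 'db' or 'fbfd'", call. = FALSE)
  gn <- c("lc", "dr", "vlpo", "r", "wr")
  for (g in gn) {
    gr <- p$groups[[g]]
    if (is.null(gr)) stop("missing cell group '", g, "'", call. = FALSE)
    with(gr, {
      if (F_max <= 0 || tau_F <= 0 || tau_C <= 0 || gamma <= 0 || alpha == 0)
        stop("invalid parameters for group '", g,
             "': need F_max, tau_F, tau_C, gamma > 0 and alpha != 0",
             call. = FALSE)
    })
  }
  if (is.null(p$groups$vlpo$k) || p$groups$vlpo$k <= 0)
    stop("vlpo needs a positive homeostatic threshold coefficient k",
         call. = FALSE)
  with(p$homeostatic, stopifnot(h_max > 0, tau_acc > 0, tau_diss > 0))
  with(p$noise, stopifnot(rate >= 0, tau_delta > 0))
  # circuit sign structure: GABA and monoamine projections inhibitory,
  # ACh and thalamic input excitatory
  g <- p$coupling
  neg <- c("G_LC", "G_DR", "N_VLPO", "S_VLPO", "N_R", "S_R", "G_R", "G_WR")
  pos <- c("A_LC", "D_LC", "A_DR", "D_DR", "A_R", "A_WR")
  if (any(unlist(g[neg]) > 0) || any(unlist(g[pos]) < 0))
    stop("coupling signs violate the circuit diagram ",
         "(GABA/NE/5-HT inhibitory, ACh/thalamic input excitatory)",
         call. = FALSE)
  if (p$variant == "fbfd") {
    s <- p$scn
    if (is.null(s)) stop("fbfd variant requires an 'scn' block", call. = FALSE)
    stopifnot(s$period_h > 0, s$F_max > 0, s$tau_F > 0, s$tau_C > 0)
    if (any(unlist(s[c("g_scn_LC", "g_scn_DR", "g_scn_VLPO", "g_scn_R")]) > 0))
      stop("SCN feed-forward projections are GABAergic (non-positive weights)",
           call. = FALSE)
  }
  p
}

#' @export
print.sleep_params <- function(x, ...) {
  cat("<sleep_params> variant:", x$variant,
      "| state dimension:", state_dim(x), "\n")
  cat("  groups:", paste(names(x$groups), collapse = ", "), "\n")
  cat("  noise: rate", x$noise$rate, "Hz, tau_delta", x$noise$tau_delta, "s\n")
  if (x$variant == "fbfd")
    cat("  scn: period", x$scn$period_h, "h, light onset",
        x$scn$light_onset_h, "h\n")
  invisible(x)
}

#' State dimension and canonical variable names
#'
#' The core model has 12 dynamical variables; the circadian extension adds
#' `F_SCN` and `C_SCN` for 14.
#'
#' @param params a `sleep_params` object.
#' @return `state_dim()`: integer; `state_names()`: character vector in the
#'   canonical order used by all trajectory tables.
#' @export
state_dim <- function(params) if (params$variant == "fbfd") 14L else 12L

#' @rdname state_dim
#' @export
state_names <- function(params) {
  nm <- c("F_LC", "F_DR", "F_VLPO", "F_R", "F_WR",
          "C_N", "C_S", "C_G", "C_AR", "C_AWR", "h", "delta")
  if (params$variant == "fbfd") nm <- c(nm, "F_SCN", "C_SCN")
  nm
}

# Flat named vector handed to the compiled code.
flatten_params <- function(p) {
  stopifnot(inherits(p, "sleep_params"))
  out <- c()
  for (g in c("lc", "dr", "vlpo", "r", "wr")) {
    gr <- p$groups[[g]]
    flds <- c("F_max", "alpha", "beta", "tau_F", "gamma", "tau_C")
    if (g == "vlpo") flds <- c(flds, "k")
    v <- unlist(gr[flds])
    names(v) <- paste0(g, ".", flds)
    out <- c(out, v)
  }
  gv <- unlist(p$coupling)
  names(gv) <- paste0("g.", names(p$coupling))
  hv <- unlist(p$homeostatic)
  names(hv) <- paste0("h.", names(p$homeostatic))
  nv <- unlist(p$noise)
  names(nv) <- paste0("noise.", names(p$noise))
  out <- c(out, gv, hv, nv, a_scn = p$a_scn,
           fbfd = as.numeric(p$variant == "fbfd"))
  if (p$variant == "fbfd") {
    sv <- unlist(p$scn)
    names(sv) <- paste0("scn.", names(p$scn))
    out <- c(out, sv)
  }
  out
}

#' Read or write a parameter set as YAML
#'
#' Round-trips the full parameter object, so a simulation is reproducible
#' from the file plus a seed alone.
#'
#' @param params a `sleep_params` object.
#' @param path file path.
#' @return `read_params()` returns a `sleep_params` object;
#'   `write_params()` returns `path` invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "sleep_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("no such parameter file: ", path, call. = FALSE)
  p <- yaml::read_yaml(path)
  validate_params(structure(p, class = "sleep_params"))
}

#' Get or set a single parameter by dotted path
#'
#' Parameters are addressed as `"coupling.A_LC"`, `"groups.vlpo.k"`,
#' `"a_scn"`, etc. Used by the estimation routines to vary one parameter
#' while leaving the rest of the set untouched.
#'
#' @param params a `sleep_params` object.
#' @param name dotted path of the parameter.
#' @param value replacement value (scalar).
#' @return `param_get()` the value; `param_set()` the modified object.
#' @export
param_get <- function(params, name) {
  path <- strsplit(name, ".", fixed = TRUE)[[1]]
  node <- unclass(params)
  for (k in path) {
    node <- node[[k]]
    if (is.null(node)) stop("no parameter '", name, "'", call. = FALSE)
  }
  node
}

#' @rdname param_get
#' @export
param_set <- function(params, name, value) {
  path <- strsplit(name, ".", fixed = TRUE)[[1]]
  expr <- Reduce(function(acc, k) call("[[", acc, k), path,
                 accumulate = FALSE, init = quote(p))
  p <- unclass(params)
  param_get(params, name)  # errors if absent
  eval(call("<-", expr, value))
  validate_params(structure(p, class = "sleep_params"))
}
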