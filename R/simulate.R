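#' Simulation configuration
#'
#' @param dt Time step (s), default `1e-3` (the reference step; `1e-2` is
#'   validated against it and is the usual choice for long sweeps).
#' @param T Horizon (s); `hours` is a convenience alternative.
#' @param hours Horizon in hours (ignored when `T` is given).
#' @param stochastic Integrate the stochastic (Euler-Maruyama) system.
#' @param seed RNG seed used for the run (`NULL` leaves the RNG state alone).
#' @param record_every Output decimation in steps; default records roughly
#'   once per second of model time.
#' @param noise_scale Amplitude of the optional stochastic stretch offset in
#'   the release function (`xi = 1 + noise_scale * Z`, `Z ~ N(0,1)` drawn
#'   after the length increment each step). Default 0: `xi = 1` in both
#'   modes.
#' @param tol_drive Relay trip tolerance on the ATP drive `dc/dt` (mM/s); see
#'   [ec_simulate()].
#' @return A list of class `ec_sim_config`.
#' @export
ec_sim_config <- function(dt = 1e-3, T = NULL, hours = 12,
                          stochastic = FALSE, seed = NULL,
                          record_every = NULL, noise_scale = 0,
                          tol_drive = 1e-12) {
  if (is.null(T)) T <- hours * 3600
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  if (!is.finite(T) || T < dt) stop("T must be >= dt")
  if (is.null(record_every)) record_every <- max(1L, as.integer(round(1 / dt)))
  record_every <- as.integer(record_every)
  if (record_every < 1L) stop("record_every must be >= 1")
  structure(list(dt = dt, T = T, stochastic = isTRUE(stochastic), seed = seed,
                 record_every = record_every, noise_scale = noise_scale,
                 tol_drive = tol_drive),
            class = "ec_sim_config")
}

#' Default initial state for a phenotype
#'
#' RECs and UECs start at the F-actin equilibrium of their slow switch rate
#' (`a = a_max`) and at their statistical length; TECs start rounded, at the
#' minimum F-actin concentration and minimum length. All phenotypes start at
#' the intermediate ATP level `(c_h + c_L) / 2` on the rising branch.
#'
#' @param p An [ec_params] object.
#' @return A list with `a`, `L`, `c`, `branch`.
#' @export
ec_default_init <- function(p) {
  c_in <- (p$c_h + p$c_L) / 2
  if (identical(p$phenotype, "TEC")) {
    list(a = a_min(p), L = p$L_min, c = c_in, branch = "rising")
  } else {
    a0 <- a_max(p)
    list(a = a0, L = equilibrium_length(a0, p), c = c_in, branch = "rising")
  }
}

branch_code <- function(branch) {
  if (is.numeric(branch)) return(as.integer(branch))
  match(match.arg(branch, c("rising", "falling")), c("rising", "falling"))
}

#' Single IMEX step of the coupled system
#'
#' Reference R implementation of one time step (the production loop lives in
#' compiled code; the two are tested to agree step for step). Linear terms
#' are implicit, the switch `K(c)` and the gate `H(c)` explicit:
#' \enumerate{
#'   \item `a' = (a + dt k a_h) / (1 + dt (k + K(c)))`
#'   \item `L' = (L + dt v_p / phi + beta dW) / (1 + dt sigma(a') / phi)`
#'   \item `c' = (c + dt (lam c_h - S_max R(L') H(c, branch))) / (1 + dt lam)`
#' }
#' The hysteresis branch trips when the ATP drive
#' `dc/dt = lam (c_h - c) - S_max R H` under the current branch comes within
#' `tol_drive` of zero (rising -> falling at the crest, falling -> rising at
#' the trough). See the package vignette for why the relay uses a drive
#' tolerance rather than the sign of the discrete ATP difference.
#'
#' @param state List with `a`, `L`, `c` and `branch`
#'   (`"rising"`/`"falling"`).
#' @param p An [ec_params] object.
#' @param dt Time step (s).
#' @param dW Brownian increment for the length equation (0 for the
#'   deterministic system; `N(0, dt)` draws in stochastic mode).
#' @param xi Stretch offset passed to [release_fraction()] (default 1).
#' @param tol_drive Relay trip tolerance (mM/s).
#' @return The updated state list.
#' @export
imex_step <- function(state, p, dt, dW = 0, xi = 1, tol_drive = 1e-12) {
  br <- branch_code(state$branch)
  K <- actin_switch_rate(state$c, p)
  a_new <- (state$a + dt * p$k * p$a_h) / (1 + dt * (p$k + K))
  sig <- contractility(a_new, p)
  L_new <- (state$L + dt * p$v_p / p$phi + p$beta * dW) / (1 + dt * sig / p$phi)
  R <- release_fraction(L_new, p, xi = xi)
  H <- hysteresis_value(state$c, c("rising", "falling")[br], p)
  drive <- p$lam * (p$c_h - state$c) - p$S_max * R * H
  c_new <- (state$c + dt * (p$lam * p$c_h - p$S_max * R * H)) / (1 + dt * p$lam)
  if (br == 1L && drive <= tol_drive) br <- 2L
  else if (br == 2L && drive >= -tol_drive) br <- 1L
  if (!all(is.finite(c(a_new, L_new, c_new)))) {
    bad <- c("a", "L", "c")[!is.finite(c(a_new, L_new, c_new))][1]
    stop("numerical blow-up in state variable '", bad, "'")
  }
  list(a = a_new, L = L_new, c = c_new,
       branch = c("rising", "falling")[br])
}

#' Integrate the coupled F-actin / length / ATP system
#'
#' Repeated [imex_step()] over the horizon, with `N(0, dt)` Brownian
#' increments from the seeded generator in stochastic mode (Euler-Maruyama)
#' and `dW = 0`, `xi = 1` in deterministic mode.
#'
#' @param p An [ec_params] object.
#' @param init Initial state list (`a`, `L`, `c`, `branch`); defaults to
#'   [ec_default_init()] for the phenotype.
#' @param config An [ec_sim_config()]; the `...` arguments are passed to
#'   [ec_sim_config()] when `config` is `NULL`.
#' @param ... Passed to [ec_sim_config()].
#' @return An object of class `ec_traj`: a data frame with columns `t_s`,
#'   `a_mM`, `L_um`, `c_mM`, `branch`, with the parameters, configuration and
#'   initial state attached as attributes.
#' @export
#' @examples
#' tr <- ec_simulate(ec_phenotype_params("REC"), hours = 1, dt = 1e-2)
#' tail(tr$L_um, 1)  # ~50.1 um
ec_simulate <- function(p, init = NULL, config = NULL, ...) {
  validate_ec_params(p)
  if (is.null(config)) config <- ec_sim_config(...)
  if (is.null(init)) init <- ec_default_init(p)
  if (!all(c("a", "L", "c") %in% names(init)))
    stop("init must provide a, L and c")
  if (is.null(init$branch)) init$branch <- "rising"
  if (!(init$a > 0 && init$L > 0 && init$c >= 0))
    stop("initial state must satisfy a > 0, L > 0, c >= 0")
  n_steps <- round(config$T / config$dt)
  if (!is.null(config$seed)) set.seed(config$seed)
  par <- coef(p)
  raw <- .sim_imex(par, init$a, init$L, init$c, branch_code(init$branch),
                   config$dt, n_steps, config$record_every,
                   config$stochastic, config$noise_scale, config$tol_drive)
  out <- data.frame(t_s = raw$t, a_mM = raw$a, L_um = raw$L, c_mM = raw$c,
                    branch = c("rising", "falling")[raw$branch])
  structure(out, class = c("ec_traj", "data.frame"),
            params = p, config = config, init = init)
}

#' @rdname ec_simulate
#' @param object An [ec_params] object.
#' @param nsim Number of trajectories.
#' @param seed RNG seed for the first trajectory (subsequent ones continue
#'   the stream).
#' @details The [simulate()][stats::simulate] method integrates the
#'   stochastic system; with `nsim > 1` it returns a list of trajectories
#'   drawn from one seeded stream.
#' @export
simulate.ec_params <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- ec_sim_config(..., stochastic = TRUE, seed = NULL)
  out <- lapply(seq_len(nsim), function(i) ec_simulate(object, config = cfg))
  if (nsim == 1) out[[1]] else out
}

#' @export
print.ec_traj <- function(x, ...) {
  p <- attr(x, "params"); cfg <- attr(x, "config")
  cat(sprintf("Cell trajectory%s: %d states over %.2f h (dt = %g s, %s)\n",
              if (!is.na(p$phenotype)) paste0(" [", p$phenotype, "]") else "",
              nrow(x), max(x$t_s) / 3600, cfg$dt,
              if (cfg$stochastic) "stochastic" else "deterministic"))
  cat(sprintf("  L in [%.2f, %.2f] um, c in [%.3f, %.3f] mM\n",
              min(x$L_um), max(x$L_um), min(x$c_mM), max(x$c_mM)))
  invisible(x)
}

#' @export
plot.ec_traj <- function(x, which = c("L", "a", "c"), ...) {
  which <- match.arg(which, several.ok = TRUE)
  old <- graphics::par(mfrow = c(length(which), 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(old))
  lab <- c(L = "length (um)", a = "F-actin (mM)", c = "ATP (mM)")
  col <- c(L = "L_um", a = "a_mM", c = "c_mM")
  for (w in which)
    graphics::plot(x$t_s / 3600, x[[col[w]]], type = "l",
                   xlab = "time (h)", ylab = lab[w], ...)
  invisible(x)
}

#' Mean and variance of the mean-reverting length process
#'
#' Closed-form moments of the Ornstein-Uhlenbeck length dynamics obtained
#' when F-actin (hence the contractility) is frozen: reversion rate
#' `alpha = sigma(a)/phi`, asymptotic mean `mu = v_p/sigma(a)`. Used as the
#' analytic oracle for the stochastic integrator.
#'
#' @param t Time (s), vectorized.
#' @param L0 Initial length (um).
#' @param alpha Reversion rate (1/s), `> 0`.
#' @param mu Asymptotic mean (um).
#' @param beta Noise amplitude (um s^-1/2).
#' @return A list with vectors `mean` (um) and `variance` (um^2).
#' @export
ou_moments <- function(t, L0, alpha, mu, beta) {
  if (!is.finite(alpha) || alpha <= 0) stop("alpha must be > 0")
  list(mean = mu + (L0 - mu) * exp(-alpha * t),
       variance = beta^2 / (2 * alpha) * (1 - exp(-2 * alpha * t)))
}

#' Write / read a trajectory as CSV with a JSON sidecar
#'
#' The CSV holds the columns `t_s,a_mM,L_um,c_mM,branch`; the sidecar
#' (`<path>.meta.json`) records the parameters, configuration, seed, initial
#' state and package version, enough to reproduce the run.
#'
#' @param traj An `ec_traj` object.
#' @param path CSV file path.
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   returns an `ec_traj` (attributes restored from the sidecar when
#'   present).
#' @export
write_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE, quote = FALSE)
  p <- attr(traj, "params"); cfg <- attr(traj, "config")
  meta <- list(
    params = p[setdiff(names(p), "phenotype")],
    phenotype = p$phenotype, config = cfg[!vapply(cfg, is.null, logical(1))],
    init = attr(traj, "init"),
    package_version = as.character(utils::packageVersion("eclen")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  attrs <- NULL
  side <- paste0(path, ".meta.json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    ph <- if (is.null(meta$phenotype)) NA_character_ else meta$phenotype
    attrs <- list(
      params = do.call(ec_params, c(list(phenotype = ph), meta$params)),
      config = do.call(ec_sim_config, meta$config),
      init = meta$init)
  }
  structure(out, class = c("ec_traj", "data.frame"),
            params = attrs$params, config = attrs$config, init = attrs$init)
}
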