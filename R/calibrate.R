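#' Calibration problem definition
#'
#' Bundles everything the objective needs: the free parameter names (a subset
#' of the shape/rate parameters `M1`, `M2`, `M3`, `lam`, `c_eq`), their search
#' bounds, the template parameter set supplying all fixed values, the
#' prototype target profile, and the (deterministic) simulation
#' configuration. Parameters listed in `log_scale` are searched in log10
#' space, which is the natural parameterization for rates and shape
#' coefficients spanning several decades.
#'
#' @param free Character vector of free parameter names.
#' @param bounds Named list of `c(low, high)` per free parameter.
#' @param template An [ec_params] object.
#' @param target An [make_prototype()] profile (or any list with `times`,
#'   `lengths`).
#' @param sim_config Deterministic [ec_sim_config()]; defaults to the target
#'   horizon at `dt = 1e-2` s.
#' @param init Initial state for the simulations; defaults to
#'   [ec_default_init()] of the template.
#' @param log_scale Names searched in log10 space (default: the members of
#'   `free` among `M1`, `M3`, `lam`).
#' @param objective Either `"l2"` (the discrete L2 norm of the
#'   length mismatch, the reference objective) or `"features"` (relative
#'   mismatch of oscillation minimum, maximum, tumbling phase and interval —
#'   insensitive to phase drift of periodic solutions).
#' @return A list of class `ec_calib_problem`.
#' @export
ec_calib_problem <- function(free, bounds, template, target,
                             sim_config = NULL, init = NULL,
                             log_scale = intersect(free, c("M1", "M3", "lam")),
                             objective = c("l2", "features")) {
  objective <- match.arg(objective)
  allowed <- c("M1", "M2", "M3", "lam", "c_eq")
  if (!length(free) || !all(free %in% allowed))
    stop("free parameters must be a nonempty subset of: ",
         paste(allowed, collapse = ", "))
  if (!all(free %in% names(bounds)))
    stop("bounds missing for: ",
         paste(setdiff(free, names(bounds)), collapse = ", "))
  for (nm in free) {
    b <- bounds[[nm]]
    if (length(b) != 2 || !all(is.finite(b)) || b[1] > b[2])
      stop("invalid bounds for ", nm)
  }
  if (is.null(sim_config))
    sim_config <- ec_sim_config(dt = 1e-2, T = max(target$times))
  if (sim_config$stochastic)
    stop("calibration runs on the non-stochastic system")
  if (max(target$times) > sim_config$T + 1e-9)
    stop("target grid extends past the simulation horizon")
  if (is.null(init)) init <- ec_default_init(template)
  structure(list(free = free, bounds = bounds[free], template = template,
                 target = target, sim_config = sim_config, init = init,
                 log_scale = intersect(log_scale, free),
                 objective = objective),
            class = "ec_calib_problem")
}

# substitute a named theta (natural scale) into the template; S_max follows
# the release balance whenever lam (or M1) moves
theta_into_params <- function(theta, prob) {
  stopifnot(all(names(theta) %in% prob$free))
  do.call(update_params,
          c(list(p = prob$template), as.list(theta),
            list(rederive_S_max = any(c("lam", "M1") %in% names(theta)))))
}

#' Calibration objective
#'
#' Simulates the deterministic system with `theta` substituted into the
#' template (`S_max` re-derived from the release balance whenever `lam` or
#' `M1` change), samples the length on the target grid and returns the
#' discrete L2 mismatch `sqrt(sum((L - L_s)^2) * delta)` where `delta` is the
#' grid spacing. A simulation failure returns a large finite penalty
#' (`1e6`) rather than an exception so the swarm can continue.
#'
#' @param theta Named numeric vector of free parameter values (natural
#'   scale).
#' @param prob An [ec_calib_problem()].
#' @return Nonnegative scalar objective value.
#' @export
objective <- function(theta, prob) {
  for (nm in names(theta)) {
    b <- prob$bounds[[nm]]
    if (theta[[nm]] < b[1] || theta[[nm]] > b[2])
      stop("theta out of bounds for ", nm)
  }
  L_fit <- tryCatch(simulate_on_grid(theta, prob),
                    error = function(e) NULL)
  if (is.null(L_fit)) return(1e6)
  if (prob$objective == "features") return(feature_mismatch(L_fit, prob))
  delta <- diff(prob$target$times[1:2])
  sqrt(sum((L_fit - prob$target$lengths)^2) * delta)
}

simulate_on_grid <- function(theta, prob) {
  p <- theta_into_params(unlist(theta), prob)
  traj <- ec_simulate(p, init = prob$init, config = prob$sim_config)
  stats::approx(traj$t_s, traj$L_um, xout = prob$target$times,
                rule = 2)$y
}

feature_mismatch <- function(L_fit, prob) {
  grid <- diff(prob$target$times[1:2])
  mk <- function(L) measure_trace(list(times = prob$target$times, lengths = L))
  ft <- mk(L_fit); tg <- mk(prob$target$lengths)
  rel <- function(a, b) if (!is.finite(b)) NULL else {
    if (!is.finite(a)) 10 else abs(a - b) / max(abs(b), 1e-12)
  }
  parts <- c(rel(ft$L_min, tg$L_min), rel(ft$L_max, tg$L_max),
             rel(ft$T_P_mean, tg$T_P_mean), rel(ft$T_I_mean, tg$T_I_mean))
  sum(parts)
}

#' Particle swarm optimization settings
#'
#' Global-best PSO with the standard constriction-type coefficients:
#' inertia 0.72, cognitive = social = 1.49.
#'
#' @param swarm_size Number of particles (default 40).
#' @param iterations Number of iterations (default 200).
#' @param inertia,cognitive,social Velocity-update weights.
#' @param seed RNG seed for the swarm.
#' @return A list of class `ec_pso_config`.
#' @export
ec_pso_config <- function(swarm_size = 40, iterations = 200,
                          inertia = 0.72, cognitive = 1.49, social = 1.49,
                          seed = NULL) {
  stopifnot(swarm_size >= 1, iterations >= 1,
            inertia > 0, cognitive > 0, social > 0)
  structure(list(swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations),
                 inertia = inertia, cognitive = cognitive, social = social,
                 seed = seed),
            class = "ec_pso_config")
}

#' Global-best particle swarm minimization
#'
#' Standard gbest PSO over the free parameters of a calibration problem:
#' uniform random initialization within bounds, velocity update with
#' inertia/cognitive/social terms, positions clipped to the bounds,
#' best-so-far tracking. Reproducible from the seed. Parameters in
#' `prob$log_scale` are searched in log10 space.
#'
#' @param prob An [ec_calib_problem()] (or any list with `free`, `bounds` and
#'   an objective; see `fn`).
#' @param config An [ec_pso_config()].
#' @param fn Objective `function(theta_named, prob)`; defaults to
#'   [objective()].
#' @return A list of class `ec_pso_result`: `theta_best` (named, natural
#'   scale), `J_best`, `history` (best-so-far per iteration, nonincreasing),
#'   `evaluations`.
#' @export
pso_minimize <- function(prob, config = ec_pso_config(), fn = objective) {
  if (!is.null(config$seed)) set.seed(config$seed)
  free <- prob$free
  d <- length(free)
  tf <- function(x) { y <- x; y[prob$log_scale] <- log10(y[prob$log_scale]); y }
  itf <- function(y) { x <- y; x[prob$log_scale] <- 10^(x[prob$log_scale]); x }
  lo <- tf(vapply(prob$bounds, `[`, numeric(1), 1)[free])
  hi <- tf(vapply(prob$bounds, `[`, numeric(1), 2)[free])
  span <- hi - lo
  n <- config$swarm_size
  pos <- matrix(runif(n * d, rep(lo, each = n), rep(hi, each = n)), n, d,
                dimnames = list(NULL, free))
  vel <- matrix(runif(n * d, rep(-span, each = n), rep(span, each = n)),
                n, d) / 2
  evalJ <- function(y) fn(itf(setNames(y, free)), prob)
  J <- apply(pos, 1, evalJ)
  pbest <- pos; Jp <- J
  g <- which.min(Jp)
  gbest <- pbest[g, ]; Jg <- Jp[g]
  history <- numeric(config$iterations)
  evals <- n
  for (it in seq_len(config$iterations)) {
    r1 <- matrix(runif(n * d), n, d)
    r2 <- matrix(runif(n * d), n, d)
    vel <- config$inertia * vel +
      config$cognitive * r1 * (pbest - pos) +
      config$social * r2 * matrix(gbest, n, d, byrow = TRUE) -
      config$social * r2 * pos
    pos <- pos + vel
    pos <- pmin(pmax(pos, matrix(lo, n, d, byrow = TRUE)),
                matrix(hi, n, d, byrow = TRUE))
    J <- apply(pos, 1, evalJ)
    evals <- evals + n
    imp <- J < Jp
    pbest[imp, ] <- pos[imp, , drop = FALSE]; Jp[imp] <- J[imp]
    g <- which.min(Jp)
    if (Jp[g] < Jg) { gbest <- pbest[g, ]; Jg <- Jp[g] }
    history[it] <- Jg
  }
  structure(list(theta_best = itf(setNames(gbest, free)), J_best = Jg,
                 history = history, evaluations = evals),
            class = "ec_pso_result")
}

#' Default calibration search bounds
#'
#' Spans the sensitivity ranges of the shape parameters and keeps `c_eq`
#' strictly inside `(c_L, c_h)`.
#'
#' @param c_L,c_h ATP bounds (mM).
#' @return Named list of `c(low, high)` bounds.
#' @export
ec_calib_bounds <- function(c_L = 1, c_h = 10) {
  list(M1 = c(10, 1e5), M2 = c(1e-3, 1e2), M3 = c(1e-6, 1e-2),
       lam = c(1e-5, 1e-2), c_eq = c(c_L + 0.01, c_h - 0.01))
}

#' Calibrate the model for one phenotype
#'
#' The fitting front end: builds the prototype target from the phenotype's
#' length statistics, pre-fills the constrained parameters with
#' [derive_parameters()], frees the shape parameters the statistics cannot
#' fix, and minimizes the length mismatch with PSO on the non-stochastic
#' system. For TECs the free set is `M1`, `M2`, `lam`, `c_eq` with the
#' hysteresis slope `M3` fixed a priori at `1e-5` (the sharp-relay regime in
#' which tumbling oscillations arise); for RECs and UECs the free set is
#' `M1`, `M2`, `M3`, `c_eq` with the production rate `lam` fixed at the TEC
#' value.
#'
#' @param stats An [ec_phenotype_stats()] object (defaults to the bundled
#'   statistics for `label`).
#' @param label Phenotype label, used when `stats` is not given.
#' @param base Baseline constants.
#' @param pso An [ec_pso_config()].
#' @param bounds Search bounds, default [ec_calib_bounds()].
#' @param duration,grid Target profile duration and spacing (s).
#' @param ... Passed to [ec_calib_problem()] (e.g. `objective =
#'   "features"`).
#' @return An object of class `ec_fit` with elements `params` (the calibrated
#'   [ec_params]), `theta` (named optimum), `J`, `history`, `evaluations`,
#'   `problem`, `pso_config`.
#' @export
ec_calibrate <- function(label = c("REC", "UEC", "TEC"),
                         stats = ec_phenotype_stats(label),
                         base = ec_constants(),
                         pso = ec_pso_config(),
                         bounds = ec_calib_bounds(base$c_L, base$c_h),
                         duration = 12 * 3600, grid = 120, ...) {
  label <- match.arg(label)
  validate_ec_stats(stats)
  template <- derive_parameters(stats, base = base)
  if (label == "TEC") {
    free <- c("M1", "M2", "lam", "c_eq")
    template <- update_params(template, M3 = 1e-5)
  } else {
    free <- c("M1", "M2", "M3", "c_eq")
    template <- update_params(template, lam = ec_optimized_values("TEC")$lam,
                              rederive_S_max = TRUE)
  }
  target <- make_prototype(stats, duration = duration, grid = grid)
  prob <- ec_calib_problem(free = free, bounds = bounds, template = template,
                           target = target, ...)
  res <- pso_minimize(prob, pso)
  params <- theta_into_params(res$theta_best, prob)
  structure(list(params = params, theta = res$theta_best, J = res$J_best,
                 history = res$history, evaluations = res$evaluations,
                 problem = prob, pso_config = pso),
            class = "ec_fit")
}

#' @export
print.ec_fit <- function(x, ...) {
  cat("Calibrated cell length model",
      if (!is.na(x$params$phenotype)) paste0("[", x$params$phenotype, "]"),
      "\n")
  cat("  free parameters:\n")
  for (nm in names(x$theta))
    cat(sprintf("    %-4s = %.6g\n", nm, x$theta[[nm]]))
  cat(sprintf("  objective J = %.6g after %d evaluations\n",
              x$J, x$evaluations))
  invisible(x)
}

#' @export
coef.ec_fit <- function(object, ...) object$theta

#' @export
summary.ec_fit <- function(object, ...) {
  r <- residuals(object)
  cat("Calibration summary\n")
  print(object)
  cat(sprintf("  residual length mismatch: rms = %.3g um, max = %.3g um\n",
              sqrt(mean(r^2)), max(abs(r))))
  invisible(object)
}

#' @export
fitted.ec_fit <- function(object, ...) {
  simulate_on_grid(object$theta, object$problem)
}

#' @export
residuals.ec_fit <- function(object, ...) {
  fitted(object) - object$problem$target$lengths
}

#' @export
simulate.ec_fit <- function(object, nsim = 1, seed = NULL, ...) {
  simulate(object$params, nsim = nsim, seed = seed, ...)
}

#' @export
plot.ec_fit <- function(x, ...) {
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  tg <- x$problem$target
  graphics::plot(tg$times / 3600, tg$lengths, type = "l", lty = 2,
                 xlab = "time (h)", ylab = "length (um)",
                 main = "target (dashed) vs fit", ...)
  graphics::lines(tg$times / 3600, fitted(x))
  graphics::plot(seq_along(x$history), x$history, type = "l", log = "y",
                 xlab = "iteration", ylab = "best J")
  invisible(x)
}
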