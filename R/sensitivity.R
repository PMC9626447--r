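#' Tumbling metrics of a simulated trajectory
#'
#' Applies the tumbling-episode logic of [measure_trace()] to the
#' post-transient portion of a trajectory and reports the mean tumbling-phase
#' duration `T_P`, the mean inter-tumble interval `T_I`, and the oscillation
#' extrema computed over complete cycles only (a cycle runs from the start of
#' one tumbling episode to the start of the next).
#'
#' @param traj An `ec_traj` from [ec_simulate()].
#' @param threshold Tumbling length threshold (um), default 20.
#' @param discard Transient discard (s), default 2 h.
#' @return List with `T_P`, `T_I` (s), `L_osc_min`, `L_osc_max` (um),
#'   `n_episodes`, and `n_cycle_samples` (number of recorded states inside
#'   the complete-cycle window the extrema are taken over).
#' @export
tumbling_metrics <- function(traj, threshold = 20, discard = 7200) {
  post <- traj[traj$t_s >= discard, , drop = FALSE]
  if (nrow(post) < 2) stop("trajectory too short after transient discard")
  frame <- post$t_s[2] - post$t_s[1]
  low <- post$L_um < threshold
  r <- rle(low)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  epi <- which(r$values)
  if (length(epi) < 2)
    stop("fewer than 2 complete tumbling episodes after discard; ",
         "not a sustained oscillation")
  interior <- epi[starts[epi] > 1 & ends[epi] < nrow(post)]
  T_P <- if (length(interior)) mean(r$lengths[interior]) * frame else NA_real_
  gaps <- (starts[epi][-1] - ends[epi][-length(epi)] - 1) * frame
  # complete cycles: start of first episode to start of last episode
  cyc <- seq(starts[epi][1], starts[epi][length(epi)] - 1)
  list(T_P = T_P, T_I = mean(gaps),
       L_osc_min = min(post$L_um[cyc]), L_osc_max = max(post$L_um[cyc]),
       n_episodes = length(epi), n_cycle_samples = length(cyc))
}

#' Classify the dynamical regime of a trajectory
#'
#' Three regimes are distinguished on the post-transient length signal:
#' `"tumbling"` if the length enters the sub-threshold range (`< 20` um) at
#' least twice after the discard window; `"constant"` if the relative length
#' variation `(max - min)/mean` stays below 1% both after the discard and
#' already within the first hour; `"constant_with_transient"` if the length
#' has settled (final-hour variation below 1%) but moved by more than 10%
#' along the way. Trajectories still drifting at the end fall back to
#' `"constant_with_transient"` (settling slower than the horizon) unless
#' they tumble.
#'
#' @param traj An `ec_traj`.
#' @param discard Transient discard (s), default 2 h.
#' @param threshold Tumbling threshold (um), default 20.
#' @return One of `"tumbling"`, `"constant"`, `"constant_with_transient"`.
#' @export
classify_regime <- function(traj, discard = 7200, threshold = 20) {
  if (max(traj$t_s) < discard + 3600)
    stop("trajectory must extend at least 1 h past the discard window")
  relvar <- function(x) (max(x) - min(x)) / mean(x)
  post <- traj$L_um[traj$t_s >= discard]
  # entries into the sub-threshold range (downward crossings)
  below <- post < threshold
  n_entries <- sum(diff(below) == 1) + 0L
  if (n_entries >= 2) return("tumbling")
  first_hour <- traj$L_um[traj$t_s <= 3600]
  last_hour <- traj$L_um[traj$t_s >= max(traj$t_s) - 3600]
  if (relvar(last_hour) < 0.01) {
    if (relvar(post) < 0.01 && relvar(first_hour) < 0.01) return("constant")
    return("constant_with_transient")
  }
  "constant_with_transient"
}

#' One-at-a-time parameter sweep
#'
#' Runs one deterministic simulation per value of a single parameter, holding
#' every other parameter at its template value, and records the regime and
#' its metrics. The maximal release rate `S_max` is re-derived from the
#' full-stretch balance whenever the swept parameter enters it (`lam`, `M1`,
#' `L_min`, `L_max`).
#'
#' @param name Parameter name (a field of [ec_params]).
#' @param values Numeric vector of values to sweep, in the order reported.
#' @param template An [ec_params] object giving every other parameter.
#' @param config An [ec_sim_config()] (deterministic); defaults to 12 h at
#'   `dt = 1e-2` s.
#' @param discard Transient discard (s) for the metrics.
#' @return A data frame (one row per value, input order) with columns
#'   `param`, `value`, `regime`, `L_steady`, `L_osc_min`, `L_osc_max`,
#'   `T_P_s`, `T_I_s`, `c_steady`, `error`. `L_steady` is the final-hour mean
#'   length for non-tumbling runs; `c_steady` is the post-discard maximum
#'   ATP, i.e. the production/release balance level at the crest of the
#'   charge cycle.
#' @export
sweep_parameter <- function(name, values, template,
                            config = ec_sim_config(dt = 1e-2, hours = 12),
                            discard = 7200) {
  if (!name %in% setdiff(names(template), "phenotype"))
    stop("not a model parameter: ", name)
  rows <- lapply(values, function(v) {
    row <- data.frame(param = name, value = v, regime = NA_character_,
                      L_steady = NA_real_, L_osc_min = NA_real_,
                      L_osc_max = NA_real_, T_P_s = NA_real_,
                      T_I_s = NA_real_, c_steady = NA_real_,
                      error = NA_character_, stringsAsFactors = FALSE)
    res <- tryCatch({
      p <- do.call(update_params,
                   c(setNames(list(v), name), list(p = template),
                     list(rederive_S_max = name %in%
                            c("lam", "M1", "L_min", "L_max"))))
      traj <- ec_simulate(p, config = config)
      post <- traj[traj$t_s >= discard, ]
      row$regime <- classify_regime(traj, discard = discard)
      row$c_steady <- max(post$c_mM)
      if (row$regime == "tumbling") {
        tm <- tumbling_metrics(traj, discard = discard)
        row$L_osc_min <- tm$L_osc_min; row$L_osc_max <- tm$L_osc_max
        row$T_P_s <- tm$T_P; row$T_I_s <- tm$T_I
      } else {
        last_hour <- traj$L_um[traj$t_s >= max(traj$t_s) - 3600]
        row$L_steady <- mean(last_hour)
      }
      row
    }, error = function(e) {
      row$error <- conditionMessage(e)
      row
    })
    res
  })
  do.call(rbind, rows)
}

#' Tumbling phase diagram over (c_eq, M2, M3)
#'
#' Classifies the regime at every point of a grid over the three parameters
#' that discriminate the phenotypes: tumbling requires intermediate ATP
#' equilibrium thresholds `c_eq` combined with a sufficiently switch-like
#' F-actin response (large `M2`) and a sufficiently sharp hysteresis (small
#' `M3`).
#'
#' @param c_eq,M2,M3 Numeric vectors spanning the grid.
#' @param template An [ec_params] object for all remaining parameters.
#' @param config Deterministic [ec_sim_config()]; default 12 h at
#'   `dt = 1e-2` s.
#' @param discard Transient discard (s).
#' @return A list with `grid` (data frame `c_eq`, `M2`, `M3`, `regime`,
#'   `error`) and `tumbling_box` (per-parameter range of the tumbling
#'   points, or `NULL` when none tumble).
#' @export
phase_diagram <- function(c_eq, M2, M3, template,
                          config = ec_sim_config(dt = 1e-2, hours = 12),
                          discard = 7200) {
  grid <- expand.grid(c_eq = c_eq, M2 = M2, M3 = M3,
                      KEEP.OUT.ATTRS = FALSE)
  grid$regime <- NA_character_
  grid$error <- NA_character_
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch({
      p <- update_params(template, c_eq = grid$c_eq[i], M2 = grid$M2[i],
                         M3 = grid$M3[i])
      classify_regime(ec_simulate(p, config = config), discard = discard)
    }, error = function(e) structure(conditionMessage(e), failed = TRUE))
    if (is.null(attr(res, "failed"))) grid$regime[i] <- res
    else grid$error[i] <- res
  }
  tb <- grid[!is.na(grid$regime) & grid$regime == "tumbling", ]
  box <- if (nrow(tb)) list(c_eq = range(tb$c_eq), M2 = range(tb$M2),
                            M3 = range(tb$M3)) else NULL
  list(grid = grid, tumbling_box = box)
}

#' Write sweep or phase-diagram results to CSV
#'
#' Long-format CSV as produced by [sweep_parameter()] /
#' [phase_diagram()]`$grid`.
#'
#' @param x A data frame of sweep records.
#' @param path CSV file path.
#' @export
write_sweep <- function(x, path) {
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
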