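#' Prototype ("statistical cell") target length profile
#'
#' The idealized length series the calibrator fits against, built from the
#' measured statistics: a constant series at `L_mean` for RECs and UECs, and
#' for TECs a two-level square wave that starts in the tumbling (low) state at
#' `L_min` for spans of `T_P` seconds and sits at `L_max` for spans of `T_I`
#' seconds, period `T_P + T_I`.
#'
#' @param stats An [ec_phenotype_stats()] object (or compatible list).
#' @param duration Profile duration (s), default 12 h.
#' @param grid Sampling interval (s), default 120 s (one frame every 2 min).
#' @return An object of class `ec_prototype`: list with `label`, `times`,
#'   `lengths`.
#' @export
#' @examples
#' pr <- make_prototype(ec_phenotype_stats("REC"))
#' unique(pr$lengths)  # 50.1
make_prototype <- function(stats, duration = 12 * 3600, grid = 120) {
  validate_ec_stats(stats)
  times <- seq(0, duration, by = grid)
  if (stats$label %in% c("REC", "UEC")) {
    lengths <- rep(stats$L_mean, length(times))
  } else {
    period <- stats$T_P + stats$T_I
    phase <- times %% period
    lengths <- ifelse(phase < stats$T_P, stats$L_min, stats$L_max)
  }
  structure(list(label = stats$label, times = times, lengths = lengths),
            class = "ec_prototype")
}

#' @export
print.ec_prototype <- function(x, ...) {
  cat(sprintf("Prototype length profile [%s]: %d samples over %.2f h, L in [%.1f, %.1f] um\n",
              x$label, length(x$times), max(x$times) / 3600,
              min(x$lengths), max(x$lengths)))
  invisible(x)
}

# Exact OU transition sampling on a uniform grid: L_{i+1} given L_i is
# Gaussian with mean mu + (L_i - mu) e^{-alpha dt} and the stationary-bridge
# variance.  Exact in distribution for any frame interval.
ou_path <- function(n, L0, alpha, mu, beta, dt) {
  e <- exp(-alpha * dt)
  sdv <- sqrt(beta^2 / (2 * alpha) * (1 - e^2))
  L <- numeric(n)
  L[1] <- L0
  z <- rnorm(n - 1)
  for (i in seq_len(n - 1))
    L[i + 1] <- mu + (L[i] - mu) * e + sdv * z[i]
  L
}

#' Synthetic experiment-like length trace
#'
#' Generates a sampled length trace emulating the time-lapse measurements
#' (uniform frames, default one every 2 min). RECs/UECs: a mean-reverting
#' (OU) path around `L_mean` with diffusion `beta`; the reversion rate is
#' chosen so the stationary standard deviation is one third of the distance
#' from the mean to the nearer length bound, and the path is clipped to
#' `[L_min, L_max]`. TECs: a square wave whose low/high dwell times are drawn
#' uniformly around the mean durations `T_P` / `T_I` (half-width
#' `jitter * w_max`, where `w_max` keeps the draw inside the observed 10 min
#' to 4 h range), with OU fluctuations superimposed on the running (high)
#' level.
#'
#' @param stats An [ec_phenotype_stats()] object.
#' @param duration Trace duration (s), default 24 h.
#' @param frame Frame interval (s), default 120, must be `>= 1`.
#' @param seed RNG seed (traces are reproducible from it).
#' @param jitter TEC dwell-time jitter as a fraction of the maximal
#'   admissible half-width (0 = strictly periodic, default 1).
#' @return An object of class `ec_trace`: list with `times`, `lengths`,
#'   `label`, `seed`.
#' @export
synth_trace <- function(stats, duration = 24 * 3600, frame = 120,
                        seed = NULL, jitter = 1) {
  validate_ec_stats(stats)
  if (frame < 1) stop("frame must be >= 1 s")
  if (!is.null(seed)) set.seed(seed)
  times <- seq(0, duration, by = frame)
  n <- length(times)
  if (stats$label %in% c("REC", "UEC")) {
    sd_target <- min(stats$L_mean - stats$L_min,
                     stats$L_max - stats$L_mean) / 3
    alpha <- stats$beta^2 / (2 * sd_target^2)
    L <- ou_path(n, stats$L_mean, alpha, stats$L_mean, stats$beta, frame)
    L <- pmin(pmax(L, stats$L_min), stats$L_max)
  } else {
    # jitter range centered on the mean dwell, kept within [10 min, 4 h]
    draw_dwell <- function(m) {
      w <- jitter * min(m - 600, 14400 - m)
      runif(1, m - w, m + w)
    }
    lev <- numeric(n)
    t_end <- 0; low <- TRUE; i <- 1
    while (i <= n) {
      dwell <- draw_dwell(if (low) stats$T_P else stats$T_I)
      t_end <- t_end + dwell
      j <- i
      while (j <= n && times[j] < t_end) j <- j + 1
      if (j > i) lev[i:min(j - 1, n)] <- if (low) stats$L_min else stats$L_max
      if (j - 1 >= n) break
      i <- j; low <- !low
    }
    noise <- ou_path(n, 0, stats$beta^2 / (2 * 3^2), 0, stats$beta, frame)
    L <- lev + ifelse(lev > stats$L_min, noise, 0)
  }
  structure(list(times = times, lengths = L, label = stats$label,
                 seed = seed),
            class = "ec_trace")
}

#' @export
print.ec_trace <- function(x, ...) {
  cat(sprintf("Length trace%s: %d frames (%.0f s apart) over %.1f h, L in [%.1f, %.1f] um\n",
              if (!is.null(x$label)) paste0(" [", x$label, "]") else "",
              length(x$times), x$times[2] - x$times[1],
              max(x$times) / 3600, min(x$lengths), max(x$lengths)))
  invisible(x)
}

#' Extract summary statistics from a length trace
#'
#' Computes the quantities used to characterize a phenotype from any sampled
#' length series: extrema, mean and standard deviation of the lengths, the
#' noise amplitude estimate `beta_hat = sd(diff(L)) / sqrt(frame)` (the lag-1
#' quadratic-variation estimator, accurate when the frame interval is short
#' compared to the reversion time), and the tumbling-episode statistics.
#' Tumbling episodes are maximal runs of frames with length strictly below
#' `tumble_threshold`; runs shorter than `min_frames` frames are ignored as
#' noise. `T_P_mean` is the mean episode duration and `T_I_mean` the mean gap
#' from the end of one episode to the start of the next; episodes touching
#' the trace boundary are excluded from the duration means (but still
#' counted in `n_tumbles`).
#'
#' @param trace An `ec_trace`, `ec_traj`, or list with `times` and `lengths`.
#' @param tumble_threshold Length below which the cell counts as tumbling
#'   (um), default 20.
#' @param min_frames Minimum episode extent in frames, default 2.
#' @return A list of class `ec_trace_stats` with fields `L_max`, `L_min`,
#'   `L_mean`, `sd`, `beta_hat`, `n_tumbles`, `T_P_mean`, `T_I_mean`.
#' @export
measure_trace <- function(trace, tumble_threshold = 20, min_frames = 2) {
  tl <- as_trace(trace)
  L <- tl$lengths; times <- tl$times
  if (length(L) < 2) stop("trace must have at least 2 frames")
  frame <- times[2] - times[1]
  r <- rle(L < tumble_threshold)
  keep <- r$values & r$lengths >= min_frames
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  epi <- which(keep)
  n_tumbles <- length(epi)
  T_P_mean <- T_I_mean <- NA_real_
  if (n_tumbles) {
    interior <- epi[starts[epi] > 1 & ends[epi] < length(L)]
    if (length(interior))
      T_P_mean <- mean(r$lengths[interior]) * frame
    if (n_tumbles >= 2) {
      gaps <- (starts[epi][-1] - ends[epi][-n_tumbles] - 1) * frame
      T_I_mean <- mean(gaps)
    }
  }
  structure(list(L_max = max(L), L_min = min(L), L_mean = mean(L),
                 sd = sd(L),
                 beta_hat = sd(diff(L)) / sqrt(frame),
                 n_tumbles = n_tumbles,
                 T_P_mean = T_P_mean, T_I_mean = T_I_mean),
            class = "ec_trace_stats")
}

as_trace <- function(trace) {
  if (inherits(trace, "ec_traj"))
    return(list(times = trace$t_s, lengths = trace$L_um))
  if (is.list(trace) && all(c("times", "lengths") %in% names(trace))) {
    if (!length(trace$times)) stop("empty trace")
    return(trace[c("times", "lengths")])
  }
  stop("cannot interpret object as a length trace")
}

#' @export
print.ec_trace_stats <- function(x, ...) {
  cat(sprintf("Trace statistics: L_min = %.2f, L_max = %.2f, L_mean = %.2f um (sd %.2f)\n",
              x$L_min, x$L_max, x$L_mean, x$sd))
  cat(sprintf("  beta_hat = %.3f um s^-1/2; %d tumbling episode(s)",
              x$beta_hat, x$n_tumbles))
  if (is.finite(x$T_P_mean)) cat(sprintf("; T_P = %.0f s", x$T_P_mean))
  if (is.finite(x$T_I_mean)) cat(sprintf(", T_I = %.0f s", x$T_I_mean))
  cat("\n")
  invisible(x)
}

#' Threshold classifier for length traces
#'
#' Assigns a phenotype label from trace statistics: any tumbling episode
#' makes the trace a TEC; otherwise the mean length separates UECs
#' (`L_mean > 100` um) from RECs.
#'
#' @param trace A length trace (see [measure_trace()]).
#' @param tumble_threshold,uec_length Classification thresholds (um).
#' @return `"REC"`, `"UEC"` or `"TEC"`.
#' @export
classify_trace <- function(trace, tumble_threshold = 20, uec_length = 100) {
  st <- measure_trace(trace, tumble_threshold = tumble_threshold)
  if (st$n_tumbles >= 1) "TEC" else if (st$L_mean > uec_length) "UEC" else "REC"
}

#' Write / read a length trace as CSV
#'
#' Two columns `t_s,L_um`.
#'
#' @param trace An `ec_trace` (or compatible list).
#' @param path CSV file path.
#' @export
write_trace <- function(trace, path) {
  tl <- as_trace(trace)
  write.csv(data.frame(t_s = tl$times, L_um = tl$lengths), path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  d <- read.csv(path)
  structure(list(times = d$t_s, lengths = d$L_um, label = NULL, seed = NULL),
            class = "ec_trace")
}

#' Trace statistics as JSON
#'
#' Writes an `ec_trace_stats` object to JSON with keys named as the summary
#' columns (`L_max`, `L_min`, `L_mean`, `sd`, `beta_hat`, `n_tumbles`,
#' `T_P_mean`, `T_I_mean`).
#'
#' @param stats An `ec_trace_stats` object.
#' @param path JSON file path.
#' @export
write_trace_stats <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
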