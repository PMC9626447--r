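#' Baseline literature constants
#'
#' Rate constants and concentration bounds shared by all three phenotypes:
#' F-actin regulation rate `k` (1/s), homeostatic F-actin `a_h` (mM), the
#' literature lower bound of the F-actin range `a_min` (mM), minimum and
#' homeostatic ATP concentrations `c_L` and `c_h` (mM), protrusion velocity
#' `v_p` (um/s) and the dimensionless cell-substrate friction coefficient
#' `phi`. Units are fixed globally: time in seconds, length in micrometres,
#' concentration in millimolar.
#'
#' @return Named list of baseline constants.
#' @export
#' @examples
#' ec_constants()$k
ec_constants <- function() {
  list(
    k     = 347,    # F-actin regulation (polymerization) rate, 1/s
    a_h   = 0.2,    # homeostatic F-actin concentration, mM
    a_min = 0.05,   # lower bound of the physiological F-actin range, mM
    c_L   = 1,      # minimum acceptable intracellular ATP, mM
    c_h   = 10,     # homeostatic intracellular ATP, mM
    v_p   = 25,     # protrusion velocity, um/s
    phi   = 3e-2    # friction coefficient, dimensionless
  )
}

#' Measured per-phenotype length statistics
#'
#' Length statistics of the pooled time-lapse measurements (2-min frames over
#' 24 h) used to build the prototype ("statistical") cell of each phenotype:
#' extreme lengths `L_min`/`L_max` (um), the mean length `L_mean` (um, RECs and
#' UECs only), the mean tumbling-phase duration `T_P` and inter-tumble interval
#' `T_I` (s, TECs only), the length-noise amplitude `beta` (um s^-1/2) and the
#' number of cells measured.
#'
#' @param label Phenotype label, one of `"REC"`, `"UEC"`, `"TEC"`.
#' @return An object of class `ec_stats`: a named list with fields `label`,
#'   `n_cells`, `L_max`, `L_min`, `L_mean` (or `NA`), `T_P`, `T_I` (or `NA`)
#'   and `beta`.
#' @export
#' @examples
#' ec_phenotype_stats("TEC")$T_P  # 1 h 14 min in seconds
ec_phenotype_stats <- function(label = c("REC", "UEC", "TEC")) {
  label <- match.arg(label)
  s <- switch(label,
    REC = list(label = "REC", n_cells = 12, L_max = 70.5, L_min = 31.4,
               L_mean = 50.1, T_P = NA_real_, T_I = NA_real_, beta = 1.6),
    UEC = list(label = "UEC", n_cells = 13, L_max = 314.6, L_min = 101.9,
               L_mean = 185.5, T_P = NA_real_, T_I = NA_real_, beta = 2.2),
    TEC = list(label = "TEC", n_cells = 17, L_max = 64.1, L_min = 13.1,
               L_mean = NA_real_, T_P = 4440, T_I = 9180, beta = 2.1)
  )
  structure(s, class = "ec_stats")
}

#' Validate a set of phenotype length statistics
#'
#' @param stats An `ec_stats` object or a named list with the same fields.
#' @return The validated `ec_stats` object (invisibly errors otherwise).
#' @export
validate_ec_stats <- function(stats) {
  need <- c("label", "L_max", "L_min", "beta")
  miss <- setdiff(need, names(stats))
  if (length(miss))
    stop("phenotype statistics missing field(s): ", paste(miss, collapse = ", "))
  if (!stats$label %in% c("REC", "UEC", "TEC"))
    stop("unknown phenotype label: ", stats$label)
  if (!is.finite(stats$L_min) || !is.finite(stats$L_max) || stats$L_min >= stats$L_max)
    stop("need finite L_min < L_max")
  if (stats$label %in% c("REC", "UEC")) {
    if (is.null(stats$L_mean) || !is.finite(stats$L_mean))
      stop(stats$label, " statistics require L_mean")
    if (stats$L_mean < stats$L_min || stats$L_mean > stats$L_max)
      stop("L_mean must lie in [L_min, L_max]")
  } else {
    if (is.null(stats$T_P) || is.null(stats$T_I) ||
        !is.finite(stats$T_P) || !is.finite(stats$T_I) ||
        stats$T_P <= 0 || stats$T_I <= 0)
      stop("TEC statistics require positive T_P and T_I")
  }
  if (!is.finite(stats$beta) || stats$beta < 0) stop("beta must be >= 0")
  if (!inherits(stats, "ec_stats")) class(stats) <- "ec_stats"
  invisible(stats)
}

#' @export
print.ec_stats <- function(x, ...) {
  cat("Phenotype length statistics:", x$label,
      sprintf("(n = %s cells)\n", x$n_cells))
  cat(sprintf("  L_min = %.1f um, L_max = %.1f um", x$L_min, x$L_max))
  if (is.finite(x$L_mean)) cat(sprintf(", L_mean = %.1f um", x$L_mean))
  cat("\n")
  if (is.finite(x$T_P))
    cat(sprintf("  T_P = %.0f s, T_I = %.0f s\n", x$T_P, x$T_I))
  cat(sprintf("  beta = %.2f um s^-1/2\n", x$beta))
  invisible(x)
}

#' Published computed and optimized parameter values
#'
#' The computed/optimized per-phenotype parameter values as printed, for
#' side-by-side comparison with [derive_parameters()] output (see
#' [cmd_derive()]). Note the published UEC contractility constant `psi = 752`
#' mM^-2 s^-1 is inconsistent with the published `k2 = 351.8` 1/s: recomputing
#' `psi` from the minimum-length constraint with `L_min = 101.9` um gives
#' ~725, which is the value consistent with the rest of the UEC column. The
#' derivation in this package therefore uses the recomputed value; this table
#' keeps the printed one.
#'
#' @return A data frame with one row per parameter and columns `TEC`, `REC`,
#'   `UEC` and `units`.
#' @export
ec_published_values <- function() {
  data.frame(
    symbol = c("a_min", "a_sat", "k1", "k2", "psi", "M1", "M2", "M3",
               "lam", "c_eq"),
    TEC = c(5e-2, 2.5e-2, 1.04e3, 142.2, 5.6e3, 7.4e4, 6.4, 1e-5,
            8.75e-4, 2.26),
    REC = c(5e-2, 2.5e-2, 1.04e3, 404, 2.4e3, 2.15e2, 1.6e-2, 8.5e-4,
            8.75e-4, 8.07),
    UEC = c(5e-2, 2.5e-2, 1.04e3, 351.8, 752, 2.15e2, 1.6e-2, 8.5e-4,
            8.75e-4, 8.07),
    units = c("mM", "mM", "1/s", "1/s", "mM^-2 s^-1", "-", "-", "mM^-1",
              "1/s", "mM"),
    stringsAsFactors = FALSE
  )
}

#' Optimized shape parameters per phenotype
#'
#' The swarm-optimized values of the release-shape coefficient `M1`, the
#' F-actin switch slope `M2`, the hysteresis slope `M3`, the ATP production
#' rate `lam` and the ATP equilibrium threshold `c_eq` for one phenotype.
#'
#' @param label Phenotype label.
#' @return Named list with `M1`, `M2`, `M3`, `lam`, `c_eq`.
#' @export
ec_optimized_values <- function(label = c("REC", "UEC", "TEC")) {
  label <- match.arg(label)
  tab <- ec_published_values()
  v <- tab[[label]]
  names(v) <- tab$symbol
  as.list(v[c("M1", "M2", "M3", "lam", "c_eq")])
}
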