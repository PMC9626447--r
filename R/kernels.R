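#' ATP-dependent F-actin switch rate K(c)
#'
#' The elimination-side rate of the F-actin balance. For ATP below the
#' homeostatic level `c_h` it interpolates between the fast rate `k1`
#' (attained as `c -> 0`, driving F-actin to its minimum) and the slow rate
#' `k2` (attained at `c >= c_h`, letting F-actin reach its maximum):
#' `K(c) = (k1 - k2) exp(-c / (M2 (c_h - c))) + k2` for `c < c_h`, and
#' `K(c) = k2` otherwise. Larger `M2` makes the transition more switch-like.
#' `K` is continuous and nonincreasing, with values in `[k2, k1]`.
#'
#' @param c ATP concentration (mM), vectorized, `c >= 0`.
#' @param p An [ec_params] object.
#' @return Rate (1/s), same length as `c`.
#' @export
actin_switch_rate <- function(c, p) {
  if (any(!is.finite(c))) stop("non-finite ATP concentration")
  if (any(c < 0)) stop("ATP concentration must be >= 0")
  out <- rep(p$k2, length(c))
  lo <- c < p$c_h
  out[lo] <- (p$k1 - p$k2) * exp(-c[lo] / (p$M2 * (p$c_h - c[lo]))) + p$k2
  out
}

#' Contractility as a function of F-actin
#'
#' `sigma(a) = psi a^2 exp(-a / a_sat)`: quasi-quadratic growth up to the
#' network-compaction maximum at `a = 2 a_sat`, exponential decay beyond it.
#' Contractile shortening of the cell enters the length equation as
#' `sigma(a) L`.
#'
#' @param a F-actin concentration (mM), vectorized, `a >= 0`.
#' @param p An [ec_params] object.
#' @return Rate (1/s).
#' @export
contractility <- function(a, p) {
  if (any(!is.finite(a))) stop("non-finite F-actin concentration")
  p$psi * a^2 * exp(-a / p$a_sat)
}

#' Stretch-induced ATP release fraction R(L)
#'
#' Sigmoidal fraction of the maximal release rate activated by membrane
#' stretch: `R(L) = clamp(1 - exp(-M1 (L/L_min - xi)), 0, 1)^3`. It is zero at
#' `L = xi L_min`, nondecreasing in `L`, and saturates at 1. The base is
#' clamped before cubing so the release fraction stays in `[0, 1]` even if a
#' stochastic length excursion dips below `L_min`.
#'
#' @param L Cell length (um), vectorized, `L > 0`.
#' @param p An [ec_params] object.
#' @param xi Stretch offset (default 1, the deterministic convention: no
#'   release at minimum length).
#' @return Release fraction in `[0, 1]`.
#' @export
release_fraction <- function(L, p, xi = 1) {
  base <- 1 - exp(-p$M1 * (L / p$L_min - xi))
  pmin(pmax(base, 0), 1)^3
}

#' Two-branch hysteresis gate H(c)
#'
#' Relay gating of ATP release. On the rising branch (`f1`, traversed while
#' ATP is recharging) the gate stays closed up to the equilibrium threshold
#' `c_eq`, then opens as `exp(-(c_h - c) / (M3 (c - c_eq)^2))`, reaching 1 at
#' the homeostatic level `c_h`. On the falling branch (`f2`, traversed while
#' ATP is draining) the gate stays fully open down to `c_eq`, then closes as
#' `exp(-(c_eq - c) / (M3 (c - c_L)^2))`, shut at the minimum level `c_L`.
#' Both branches are nondecreasing in `c` and `f2(c) >= f1(c)` everywhere,
#' which is what makes the loop traverse different paths up and down.
#'
#' @param c ATP concentration (mM), vectorized, `c >= 0`.
#' @param branch `"rising"` (f1) or `"falling"` (f2).
#' @param p An [ec_params] object.
#' @return Gate fraction in `[0, 1]`.
#' @export
hysteresis_value <- function(c, branch = c("rising", "falling"), p) {
  branch <- match.arg(branch)
  if (any(!is.finite(c))) stop("non-finite ATP concentration")
  if (branch == "rising") {
    out <- ifelse(c <= p$c_eq, 0,
           ifelse(c >= p$c_h, 1,
                  exp(-(p$c_h - c) / (p$M3 * (c - p$c_eq)^2))))
  } else {
    out <- ifelse(c <= p$c_L, 0,
           ifelse(c >= p$c_eq, 1,
                  exp(-(p$c_eq - c) / (p$M3 * (c - p$c_L)^2))))
  }
  as.numeric(out)
}

#' F-actin equilibrium for a frozen switch rate
#'
#' Setting the F-actin balance `k (a_h - a) = a K` to zero for a fixed switch
#' rate `K` gives `a = k a_h / (k + K)`, decreasing in `K`. With `K = k1` this
#' is the minimum F-actin concentration, with `K = k2` the maximum.
#'
#' @param K_value Switch rate (1/s), `>= 0`, vectorized.
#' @param p An [ec_params] object.
#' @return F-actin concentration (mM).
#' @export
equilibrium_actin <- function(K_value, p) {
  if (any(!is.finite(K_value)) || any(K_value < 0))
    stop("K_value must be finite and >= 0")
  p$k * p$a_h / (p$k + K_value)
}

#' Cell length equilibrium for a frozen F-actin level
#'
#' In the mean (noise-free) length dynamics the protrusion/contraction balance
#' gives the equilibrium `L = v_p / sigma(a)`. Because `sigma` is maximal at
#' `a = 2 a_sat`, this equilibrium is bounded below by `L_min`, with equality
#' exactly when `a` sits at the minimum F-actin concentration.
#'
#' @param a F-actin concentration (mM), `> 0`, vectorized.
#' @param p An [ec_params] object.
#' @return Length (um).
#' @export
equilibrium_length <- function(a, p) {
  if (any(!is.finite(a))) stop("non-finite F-actin concentration")
  if (any(a <= 0)) stop("F-actin concentration must be > 0 (sigma(0) = 0)")
  p$v_p / contractility(a, p)
}
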