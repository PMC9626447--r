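#' Derive constrained model parameters from length statistics
#'
#' Builds a complete, self-consistent parameter set for one phenotype by
#' inverting the model's equilibrium constraints against the measured length
#' statistics:
#' \enumerate{
#'   \item `k1 = k (a_h - a_min) / a_min` — the fast switch rate that pins the
#'     minimum F-actin equilibrium at the literature lower bound `a_min`;
#'   \item `a_sat = a_min / 2` — contractility is maximal exactly at `a_min`,
#'     so the shortest cell corresponds to the most contractile state;
#'   \item `psi = v_p / (L_min a_min^2 e^-2)` — fixes the contractility scale
#'     so the equilibrium length at `a_min` is exactly the measured `L_min`;
#'   \item `a_max` — the root of `sigma(a) = v_p / L_ref` on the decreasing
#'     branch `a > 2 a_sat` (bisection, absolute tolerance 1e-12 mM), where
#'     the reference length `L_ref` is `L_max` for TECs and `L_mean` for RECs
#'     and UECs;
#'   \item `k2 = k (a_h - a_max) / a_max` — the slow switch rate that places
#'     the maximum F-actin equilibrium at that root;
#'   \item `S_max = lam (c_h - c_L) / R(L_max)` — inverts the full-stretch
#'     release balance (gate fully open, deterministic stretch offset
#'     `xi = 1`) for the maximal release rate, given the production rate
#'     `lam`.
#' }
#' The shape parameters `M1`, `M2`, `M3`, `c_eq` and the production rate `lam`
#' are not constrained by the length statistics; they default to the
#' swarm-optimized per-phenotype values ([ec_optimized_values()]) and can be
#' overridden through `optimized`.
#'
#' @param stats An [ec_phenotype_stats()] object (or compatible list).
#' @param base Baseline constants, default [ec_constants()].
#' @param optimized Named list with `M1`, `M2`, `M3`, `lam`, `c_eq`; defaults
#'   to the published optimized values for `stats$label`.
#' @return A validated [ec_params] object for the phenotype.
#' @export
#' @examples
#' p <- derive_parameters(ec_phenotype_stats("TEC"))
#' c(k1 = p$k1, k2 = p$k2, psi = p$psi)  # ~1041, ~142.2, ~5.6e3
derive_parameters <- function(stats, base = ec_constants(),
                              optimized = ec_optimized_values(stats$label)) {
  validate_ec_stats(stats)
  need <- c("M1", "M2", "M3", "lam", "c_eq")
  miss <- setdiff(need, names(optimized))
  if (length(miss))
    stop("optimized values missing: ", paste(miss, collapse = ", "))

  am <- base$a_min
  k1 <- base$k * (base$a_h - am) / am
  a_sat <- am / 2
  psi <- base$v_p / (stats$L_min * am^2 * exp(-2))

  L_ref <- if (stats$label == "TEC") stats$L_max else stats$L_mean
  aM <- solve_a_max(psi, a_sat, base$v_p, L_ref, base$a_h)
  k2 <- base$k * (base$a_h - aM) / aM

  p <- ec_params(
    phenotype = stats$label,
    k = base$k, a_h = base$a_h, k1 = k1, k2 = k2, M2 = optimized$M2,
    v_p = base$v_p, phi = base$phi, psi = psi, a_sat = a_sat,
    beta = stats$beta, L_min = stats$L_min, L_max = stats$L_max,
    c_h = base$c_h, c_L = base$c_L, c_eq = optimized$c_eq,
    lam = optimized$lam, S_max = 1, M1 = optimized$M1, M3 = optimized$M3
  )
  p$S_max <- derive_S_max(p)
  validate_ec_params(p)
  p
}

# Root of sigma(a) = v_p / L_ref on the decreasing branch a in (2 a_sat, a_h].
# sigma is strictly decreasing there, so plain bisection is exact enough.
solve_a_max <- function(psi, a_sat, v_p, L_ref, a_h, tol = 1e-12) {
  if (!is.finite(L_ref) || L_ref <= 0) stop("invalid reference length")
  target <- v_p / L_ref
  sig <- function(a) psi * a^2 * exp(-a / a_sat)
  lo <- 2 * a_sat
  if (target > sig(lo))
    stop("no root: requested equilibrium length ", L_ref,
         " um is below the minimum length implied by the contractility maximum")
  hi <- a_h
  while (sig(hi) > target) hi <- hi * 2  # sigma -> 0, always terminates
  f_lo <- sig(lo) - target
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    f_mid <- sig(mid) - target
    if (xor(f_lo > 0, f_mid > 0)) hi <- mid else { lo <- mid; f_lo <- f_mid }
    if (hi - lo < tol) break
  }
  if (hi - lo >= tol) stop("bisection for a_max did not converge")
  (lo + hi) / 2
}

#' Maximal ATP release rate from the full-stretch balance
#'
#' At full stretch (`L = L_max`, hysteresis gate fully open) the homeostatic
#' production `lam (c_h - c_L)` must be matched by the release
#' `S_max R(L_max)`; inverting gives `S_max = lam (c_h - c_L) / R(L_max)` with
#' the deterministic release fraction (`xi = 1`).
#'
#' @param p An [ec_params] object (uses `lam`, `c_h`, `c_L`, `M1`, `L_min`,
#'   `L_max`).
#' @return Maximal release rate (mM/s).
#' @export
derive_S_max <- function(p) {
  R <- release_fraction(p$L_max, p, xi = 1)
  if (R <= 0) stop("release fraction vanishes at L_max; cannot derive S_max")
  p$lam * (p$c_h - p$c_L) / R
}

#' Canonical parameter set for a phenotype
#'
#' Convenience wrapper: [derive_parameters()] applied to the bundled length
#' statistics and optimized values of the phenotype.
#'
#' @param label Phenotype label (`"REC"`, `"UEC"`, `"TEC"`).
#' @return A validated [ec_params] object.
#' @export
ec_phenotype_params <- function(label = c("REC", "UEC", "TEC")) {
  label <- match.arg(label)
  derive_parameters(ec_phenotype_stats(label))
}
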