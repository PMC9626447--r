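#' Construct a validated model parameter set
#'
#' Bundles all rate constants, thresholds and shape coefficients of the three
#' governing equations into a single validated object. Most users will not
#' call this directly but go through [ec_phenotype_params()] or
#' [derive_parameters()], which fill in the constrained values from length
#' statistics.
#'
#' @param phenotype Phenotype label (`"REC"`, `"UEC"`, `"TEC"`), or `NA` for a
#'   free-standing parameter set.
#' @param k,a_h F-actin regulation rate (1/s) and homeostatic concentration (mM).
#' @param k1,k2 Convergence rates towards the minimum and maximum F-actin
#'   equilibria (1/s); `k1 > k2 > 0`.
#' @param M2 Dimensionless slope modulator of the ATP-dependent F-actin switch.
#' @param v_p Protrusion velocity (um/s).
#' @param phi Friction coefficient (dimensionless).
#' @param psi Contractility constant (mM^-2 s^-1).
#' @param a_sat F-actin saturation concentration of the contractility
#'   function (mM).
#' @param beta Length-noise amplitude (um s^-1/2).
#' @param L_min,L_max Minimum and maximum cell length (um).
#' @param c_h,c_L,c_eq Homeostatic, minimum and equilibrium ATP
#'   concentrations (mM); `c_L < c_eq < c_h`.
#' @param lam ATP production/elimination rate (1/s).
#' @param S_max Maximal ATP release rate (mM/s).
#' @param M1 Dimensionless shape coefficient of the stretch-release function.
#' @param M3 Hysteresis slope modulator (mM^-1).
#' @return An object of class `ec_params` (a named list of the above).
#' @seealso [a_min()], [a_max()] for the implied F-actin equilibria,
#'   [derive_parameters()] for the constraint-based construction.
#' @export
#' @examples
#' p <- ec_phenotype_params("TEC")
#' coef(p)[c("k2", "psi", "c_eq")]
ec_params <- function(phenotype = NA_character_,
                      k, a_h, k1, k2, M2,
                      v_p, phi, psi, a_sat, beta, L_min, L_max,
                      c_h, c_L, c_eq, lam, S_max, M1, M3) {
  p <- list(phenotype = phenotype,
            k = k, a_h = a_h, k1 = k1, k2 = k2, M2 = M2,
            v_p = v_p, phi = phi, psi = psi, a_sat = a_sat, beta = beta,
            L_min = L_min, L_max = L_max,
            c_h = c_h, c_L = c_L, c_eq = c_eq, lam = lam, S_max = S_max,
            M1 = M1, M3 = M3)
  class(p) <- "ec_params"
  validate_ec_params(p)
  p
}

#' @rdname ec_params
#' @param p An `ec_params` object.
#' @export
validate_ec_params <- function(p) {
  num <- setdiff(names(p), "phenotype")
  bad <- num[!vapply(p[num], function(v) is.numeric(v) && length(v) == 1 &&
                       is.finite(v), logical(1))]
  if (length(bad))
    stop("non-finite or non-scalar parameter(s): ", paste(bad, collapse = ", "))
  with(p, {
    if (!(k1 > k2 && k2 > 0)) stop("need k1 > k2 > 0")
    if (k <= 0 || a_h <= 0) stop("need k > 0 and a_h > 0")
    pos <- c(v_p = v_p, phi = phi, psi = psi, a_sat = a_sat,
             L_min = L_min, L_max = L_max, lam = lam, M1 = M1, M3 = M3)
    if (any(pos <= 0))
      stop("parameter(s) must be positive: ",
           paste(names(pos)[pos <= 0], collapse = ", "))
    if (beta < 0) stop("beta must be >= 0")
    if (S_max < 0) stop("S_max must be >= 0")
    if (M2 <= 0) stop("M2 must be > 0")
    if (L_min >= L_max) stop("need L_min < L_max")
    if (!(c_L < c_eq && c_eq < c_h)) stop("need c_L < c_eq < c_h")
  })
  am <- a_min(p); aM <- a_max(p)
  if (!(am > 0 && am < aM && aM <= p$a_h))
    stop("implied F-actin equilibria violate 0 < a_min < a_max <= a_h")
  invisible(p)
}

#' Implied F-actin equilibria
#'
#' The minimum and maximum F-actin concentrations implied by the regulation
#' rate `k`, homeostatic value `a_h` and the switch rates `k1`, `k2`:
#' `a_min = k a_h / (k + k1)` and `a_max = k a_h / (k + k2)`.
#'
#' @param p An `ec_params` object.
#' @return F-actin concentration (mM).
#' @export
a_min <- function(p) p$k * p$a_h / (p$k + p$k1)

#' @rdname a_min
#' @export
a_max <- function(p) p$k * p$a_h / (p$k + p$k2)

#' @export
print.ec_params <- function(x, ...) {
  cat("Cell length model parameters",
      if (!is.na(x$phenotype)) paste0("(", x$phenotype, ")"), "\n")
  cat(sprintf("  F-actin: k = %g /s, a_h = %g mM, k1 = %.4g /s, k2 = %.4g /s, M2 = %g\n",
              x$k, x$a_h, x$k1, x$k2, x$M2))
  cat(sprintf("           a_min = %.4g mM, a_max = %.4g mM\n", a_min(x), a_max(x)))
  cat(sprintf("  Length:  v_p = %g um/s, phi = %g, psi = %.4g /mM^2/s, a_sat = %g mM\n",
              x$v_p, x$phi, x$psi, x$a_sat))
  cat(sprintf("           L_min = %g um, L_max = %g um, beta = %g um s^-1/2\n",
              x$L_min, x$L_max, x$beta))
  cat(sprintf("  ATP:     c_L = %g mM, c_eq = %g mM, c_h = %g mM, lam = %.4g /s\n",
              x$c_L, x$c_eq, x$c_h, x$lam))
  cat(sprintf("           S_max = %.4g mM/s, M1 = %.4g, M3 = %.4g /mM\n",
              x$S_max, x$M1, x$M3))
  invisible(x)
}

#' @export
coef.ec_params <- function(object, ...) {
  unlist(object[setdiff(names(object), "phenotype")])
}

#' Update a parameter set with new values
#'
#' Replaces named fields and re-validates. When `lam`, `M1`, `L_max` or
#' `L_min` change, the maximal release rate `S_max` can be re-derived from the
#' full-stretch release balance (see [derive_S_max()]) by setting
#' `rederive_S_max = TRUE`.
#'
#' @param p An `ec_params` object.
#' @param ... Named scalar replacements, e.g. `c_eq = 3`.
#' @param rederive_S_max Recompute `S_max` from the release balance after the
#'   update (default `FALSE`).
#' @return The updated, validated `ec_params` object.
#' @export
update_params <- function(p, ..., rederive_S_max = FALSE) {
  repl <- list(...)
  if (length(repl)) {
    unknown <- setdiff(names(repl), names(p))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    p[names(repl)] <- repl
  }
  if (rederive_S_max) p$S_max <- derive_S_max(p)
  validate_ec_params(p)
  p
}

#' Read and write parameter sets as YAML or JSON
#'
#' Serializes one or more parameter sets to a config file with one section per
#' phenotype and keys named after the model symbols (`k`, `a_h`, `k1`, `k2`,
#' `M1`, `M2`, `M3`, `c_h`, `c_L`, `c_eq`, `lam`, `S_max`, `v_p`, `phi`,
#' `psi`, `a_sat`, `beta`, `L_min`, `L_max`). Format is inferred from the
#' file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param params A single `ec_params` object or a named list of them.
#' @param path File path.
#' @return `write_ec_params()` returns `path` invisibly; `read_ec_params()`
#'   returns a named list of `ec_params` objects (or a single object if the
#'   file holds one section and `simplify = TRUE`).
#' @param simplify Return the bare object when the file has one section.
#' @export
write_ec_params <- function(params, path) {
  if (inherits(params, "ec_params")) {
    params <- setNames(list(params),
                       if (is.na(params$phenotype)) "params" else params$phenotype)
  }
  out <- lapply(params, function(p) p[setdiff(names(p), "phenotype")])
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(out, path, precision = 15)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported config extension: ", path)
  invisible(path)
}

#' @rdname write_ec_params
#' @export
read_ec_params <- function(path, simplify = TRUE) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unsupported config extension: ", path)
  out <- lapply(names(raw), function(nm) {
    ph <- if (nm %in% c("REC", "UEC", "TEC")) nm else NA_character_
    do.call(ec_params, c(list(phenotype = ph), raw[[nm]]))
  })
  names(out) <- names(raw)
  if (simplify && length(out) == 1) out[[1]] else out
}
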