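# Binding-thermodynamics consistency arithmetic for calorimetric
# parameters (Kd, dG, dH, -TdS).

R_KCAL <- 1.987e-3  # kcal mol^-1 K^-1

#' Free energy of binding from a dissociation constant
#'
#' dG = R T ln(Kd / 1 M), standard state 1 M, R in kcal units.
#'
#' @param kd dissociation constant (M); > 0.
#' @param temperature absolute temperature (K); default 295.15 (22 C, the
#'   calorimetry temperature).
#' @return dG in kcal/mol (negative for sub-molar Kd).
#' @export
#' @examples
#' dg_from_kd(47e-6) # ~ -5.8 kcal/mol
dg_from_kd <- function(kd, temperature = 295.15) {
  if (any(kd <= 0)) stop("'kd' must be > 0")
  if (any(temperature <= 0)) stop("'temperature' must be > 0")
  R_KCAL * temperature * log(kd)
}

#' Dissociation constant from a binding free energy
#'
#' Inverse of [dg_from_kd()].
#'
#' @param dg binding free energy (kcal/mol).
#' @param temperature absolute temperature (K).
#' @return Kd in M.
#' @export
kd_from_dg <- function(dg, temperature = 295.15) {
  if (any(temperature <= 0)) stop("'temperature' must be > 0")
  exp(dg / (R_KCAL * temperature))
}

#' Entropic term of the thermodynamic decomposition
#'
#' -T dS = dG - dH. A dH more negative than dG yields a positive -T dS:
#' entropy opposes binding.
#'
#' @param dg binding free energy (kcal/mol).
#' @param dh binding enthalpy (kcal/mol).
#' @return -T dS in kcal/mol.
#' @export
#' @examples
#' entropy_term(-5.8, -5.9) # 0.1: enthalpy-driven binding
entropy_term <- function(dg, dh) dg - dh

#' Assemble a binding-thermodynamics record
#'
#' @param kd dissociation constant (M), or `NA`.
#' @param dg,dh,minus_tds decomposition terms (kcal/mol), any may be `NA`.
#' @param temperature absolute temperature (K).
#' @return object of class `binding_thermo` (a named list).
#' @export
binding_thermo <- function(kd = NA, dg = NA, dh = NA, minus_tds = NA,
                           temperature = 295.15) {
  structure(list(kd = kd, dg = dg, dh = dh, minus_tds = minus_tds,
                 temperature = temperature),
            class = "binding_thermo")
}

#' Check internal consistency of binding thermodynamics
#'
#' Verifies the two identities dG = dH + (-T dS) and dG = R T ln(Kd)
#' against stated tolerances (e.g. the printed error bars) and reports
#' the residuals. Missing fields yield a partial report rather than an
#' error.
#'
#' @param thermo a [binding_thermo()].
#' @param tol_decomposition tolerance (kcal/mol) on dG - (dH - T dS).
#' @param tol_kd tolerance (kcal/mol) on dG - R T ln(Kd).
#' @return list with per-identity entries `residual`, `tolerance`,
#'   `consistent` (`NA` when fields are missing) and overall `ok`.
#' @export
#' @examples
#' check_consistency(binding_thermo(kd = 47e-6, dg = -5.8, dh = -5.9,
#'                                  minus_tds = 0.1))
check_consistency <- function(thermo, tol_decomposition = 0.1, tol_kd = 0.1) {
  stopifnot(inherits(thermo, "binding_thermo"))
  rep1 <- list(residual = NA_real_, tolerance = tol_decomposition,
               consistent = NA)
  if (all(is.finite(c(thermo$dg, thermo$dh, thermo$minus_tds)))) {
    rep1$residual <- thermo$dg - (thermo$dh + thermo$minus_tds)
    rep1$consistent <- abs(rep1$residual) <= tol_decomposition
  }
  rep2 <- list(residual = NA_real_, tolerance = tol_kd, consistent = NA)
  if (all(is.finite(c(thermo$kd, thermo$dg)))) {
    rep2$residual <- thermo$dg - dg_from_kd(thermo$kd, thermo$temperature)
    rep2$consistent <- abs(rep2$residual) <= tol_kd
  }
  checks <- c(rep1$consistent, rep2$consistent)
  list(decomposition = rep1, kd_dg = rep2,
       ok = if (all(is.na(checks))) NA else all(checks, na.rm = TRUE))
}
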