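#' Van't Hoff thermodynamic analysis
#'
#' Fits ln Ka = -dH/(R T) + dS/R by ordinary least squares of ln Ka against
#' 1/T across temperatures, yielding the standard enthalpy change
#' dH = -slope * R and entropy change dS = intercept * R of complex
#' formation. The Gibbs energy dG(T) = dH - T dS is evaluated at every input
#' temperature. All energies are carried internally in cal mol^-1
#' (entropy in cal mol^-1 K^-1); reporting helpers convert dH and dG to
#' kcal mol^-1.
#'
#' @param temperatures_K distinct absolute temperatures (K), length >= 2.
#' @param ka_per_M association constants (M^-1) at those temperatures, > 0.
#' @param constants a [default_constants()] list supplying `R_cal_per_mol_K`.
#' @return Object of class `"thermo_params"`: list with `dH_cal_per_mol`,
#'   `dS_cal_per_mol_K`, `dG_cal_per_mol_by_T` (named numeric vector, names
#'   are the input temperatures), `fit_r_squared`, `slope_se`, `intercept_se`.
#' @examples
#' vant_hoff_fit(c(298, 303, 310), c(0.863e4, 0.980e4, 1.225e4))
#' @export
vant_hoff_fit <- function(temperatures_K, ka_per_M,
                          constants = default_constants()) {
  if (length(temperatures_K) != length(ka_per_M)) {
    stop("temperatures_K and ka_per_M must have equal length", call. = FALSE)
  }
  if (length(temperatures_K) < 2L) {
    stop("van't Hoff fit needs >= 2 temperatures", call. = FALSE)
  }
  if (anyDuplicated(temperatures_K)) {
    stop("duplicate temperatures in van't Hoff input", call. = FALSE)
  }
  if (any(temperatures_K <= 0)) stop("temperatures must be > 0 K", call. = FALSE)
  if (any(ka_per_M <= 0) || anyNA(ka_per_M)) {
    stop("all Ka values must be > 0", call. = FALSE)
  }
  R <- constants$R_cal_per_mol_K
  x <- 1 / temperatures_K
  y <- log(ka_per_M)
  fit <- stats::lm(y ~ x)
  s <- suppressWarnings(summary(fit))
  dH <- -unname(stats::coef(fit)[2L]) * R
  dS <- unname(stats::coef(fit)[1L]) * R
  dG <- dH - temperatures_K * dS
  names(dG) <- format(temperatures_K, trim = TRUE)
  # with exactly 2 points the fit is saturated and R2 is NaN; it is exact
  r2 <- if (is.finite(s$r.squared)) s$r.squared else 1
  structure(
    list(
      dH_cal_per_mol = dH,
      dS_cal_per_mol_K = dS,
      dG_cal_per_mol_by_T = dG,
      fit_r_squared = r2,
      slope_se = if (length(x) > 2L) unname(s$coefficients[2L, 2L]) * R else NA_real_,
      intercept_se = if (length(x) > 2L) unname(s$coefficients[1L, 2L]) * R else NA_real_
    ),
    class = "thermo_params"
  )
}

#' @export
print.thermo_params <- function(x, ...) {
  cat("Van't Hoff thermodynamic parameters\n")
  cat(sprintf("  dH = %.3f kcal mol^-1;  dS = %.3f cal mol^-1 K^-1;  R2 = %.4f\n",
              x$dH_cal_per_mol / 1000, x$dS_cal_per_mol_K, x$fit_r_squared))
  for (tn in names(x$dG_cal_per_mol_by_T)) {
    cat(sprintf("  dG(%s K) = %.3f kcal mol^-1\n", tn,
                x$dG_cal_per_mol_by_T[[tn]] / 1000))
  }
  invisible(x)
}

#' Classify the dominant binding forces from thermodynamic signs
#'
#' Applies the canonical sign-pattern rules for non-covalent drug-protein
#' association: positive dH and dS indicate hydrophobic interaction (water
#' release dominates); negative dH and dS indicate van der Waals forces and
#' hydrogen bonding; near-zero dH with positive dS indicates electrostatic
#' interaction. A positive dH is also sometimes read as evidence of hydrogen
#' bonding contributing alongside the hydrophobic term; setting
#' `report_h_bond_with_positive_dH = TRUE` adds `hydrogen_bond` to the
#' reported set in the (dH > 0, dS > 0) case without changing the canonical
#' call. Spontaneity requires dG < 0 at every stored temperature.
#'
#' @param thermo a [vant_hoff_fit()] result.
#' @param dH_zero_tol absolute tolerance (cal mol^-1) below which dH is
#'   treated as zero; default 500.
#' @param report_h_bond_with_positive_dH also report hydrogen bonding in the
#'   (dH > 0, dS > 0) case; default `FALSE` (canonical rule only).
#' @return Object of class `"force_typology"`: list with `dominant_forces`
#'   (character subset of hydrophobic, hydrogen_bond, van_der_waals,
#'   electrostatic), `rule_basis` (sign pattern string), `spontaneous`.
#' @export
classify_forces <- function(thermo, dH_zero_tol = 500,
                            report_h_bond_with_positive_dH = FALSE) {
  stopifnot(inherits(thermo, "thermo_params"))
  dH <- thermo$dH_cal_per_mol
  dS <- thermo$dS_cal_per_mol_K
  if (abs(dH) < dH_zero_tol && dS > 0) {
    forces <- "electrostatic"
    basis <- "dH ~ 0, dS > 0"
  } else if (dH > 0 && dS > 0) {
    forces <- "hydrophobic"
    if (report_h_bond_with_positive_dH) forces <- c(forces, "hydrogen_bond")
    basis <- "dH > 0, dS > 0"
  } else if (dH < 0 && dS < 0) {
    forces <- c("van_der_waals", "hydrogen_bond")
    basis <- "dH < 0, dS < 0"
  } else if (dH < 0 && dS > 0) {
    # enthalpy- and entropy-favourable: both electrostatic and hydrophobic
    forces <- c("electrostatic", "hydrophobic")
    basis <- "dH < 0, dS > 0"
  } else {
    forces <- character()
    basis <- "indeterminate"
  }
  structure(
    list(
      dominant_forces = forces,
      rule_basis = basis,
      spontaneous = all(thermo$dG_cal_per_mol_by_T < 0)
    ),
    class = "force_typology"
  )
}

#' @export
print.force_typology <- function(x, ...) {
  cat("Binding-force typology:", paste(x$dominant_forces, collapse = ", "),
      sprintf("(%s)\n", x$rule_basis))
  cat("  spontaneous (dG < 0 at all T):", x$spontaneous, "\n")
  invisible(x)
}
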