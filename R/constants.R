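#' Physical and assay constants
#'
#' Returns the set of physical constants and extinction coefficients used
#' throughout the binding and glycation analyses. Any entry can be overridden,
#' e.g. to use a different fluorophore lifetime or assay extinction
#' coefficient, by passing named values; unnamed entries keep their defaults.
#'
#' @details
#' Defaults:
#' \describe{
#'   \item{`tau0_s`}{Integral fluorescence lifetime of the tryptophan
#'     fluorophore, 5.78e-9 s. Divides the Stern-Volmer constant to give the
#'     bimolecular quenching rate constant.}
#'   \item{`R_cal_per_mol_K`}{Gas constant, 1.987 cal mol^-1 K^-1. All
#'     internal energies are in cal mol^-1.}
#'   \item{`kq_biopolymer_max_per_M_s`}{Diffusion-limited ceiling for
#'     collisional quenching of biopolymers, 2e10 M^-1 s^-1. Quenching rate
#'     constants above this indicate ground-state complex formation (static
#'     quenching).}
#'   \item{`eps_fructosamine_per_M_cm`}{Molar extinction coefficient for the
#'     nitro blue tetrazolium fructosamine assay read at 530 nm,
#'     12640 M^-1 cm^-1.}
#'   \item{`eps_carbonyl_per_M_cm`}{Molar extinction coefficient of the DNPH
#'     carbonyl adduct read at 360 nm, 22000 M^-1 cm^-1.}
#' }
#'
#' @param ... named overrides for any constant listed above.
#' @return A named list of constants with class `"gq_constants"`.
#' @examples
#' default_constants()
#' default_constants(tau0_s = 6.2e-9)
#' @export
default_constants <- function(...) {
  const <- list(
    tau0_s = 5.78e-9,
    R_cal_per_mol_K = 1.987,
    kq_biopolymer_max_per_M_s = 2e10,
    eps_fructosamine_per_M_cm = 12640,
    eps_carbonyl_per_M_cm = 22000
  )
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(const))
    if (length(unknown) || is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("unknown or unnamed constant override: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    for (nm in names(overrides)) {
      val <- overrides[[nm]]
      if (!is.numeric(val) || length(val) != 1L || !is.finite(val) || val <= 0) {
        stop("constant '", nm, "' must be a single positive finite number",
             call. = FALSE)
      }
      const[[nm]] <- val
    }
  }
  structure(const, class = "gq_constants")
}

#' @export
print.gq_constants <- function(x, ...) {
  cat("Physical/assay constants:\n")
  cat(sprintf("  tau0                 %g s\n", x$tau0_s))
  cat(sprintf("  R                    %g cal mol^-1 K^-1\n", x$R_cal_per_mol_K))
  cat(sprintf("  Kq biopolymer max    %g M^-1 s^-1\n", x$kq_biopolymer_max_per_M_s))
  cat(sprintf("  eps fructosamine     %g M^-1 cm^-1\n", x$eps_fructosamine_per_M_cm))
  cat(sprintf("  eps carbonyl         %g M^-1 cm^-1\n", x$eps_carbonyl_per_M_cm))
  invisible(x)
}

# internal: scalar checks used by constructors
stopifnot_scalar <- function(x, name, positive = TRUE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(name, " must be a single non-missing number", call. = FALSE)
  }
  if (finite && !is.finite(x)) stop(name, " must be finite", call. = FALSE)
  if (positive && x <= 0) stop(name, " must be > 0", call. = FALSE)
  invisible(x)
}
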