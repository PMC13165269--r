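#' @title Seeded synthetic-data generators
#' @description Generators producing every input the analysis consumes, with
#'   the statistical structure the downstream fits assume: static-quenching
#'   titrations obeying F0/F = 1 + KSV\[Q\] (or the binding isotherm
#'   (F0 - F)/F = Ka \[Q\]^n), van't Hoff-consistent association constants,
#'   four-group glycation panels and Hill-shaped dose-response curves.
#'   Measurement noise is multiplicative Gaussian, parameterised by its
#'   coefficient of variation, because fluorescence and absorbance errors
#'   scale with signal. Every generator takes an explicit seed and restores
#'   the caller's RNG state, so identical arguments always give identical
#'   output and no global state leaks.
#' @name simulate
NULL

# run code under a local RNG seeded with `seed`, restoring global state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# multiplicative noise with bounds enforced by redraw (not clamping), so
# small-CV means stay unbiased and the quenching invariants 0 < F <= F0 hold
noisy_positive <- function(true_values, cv, upper = Inf, max_tries = 1000L) {
  if (cv == 0) return(true_values)
  out <- true_values * (1 + stats::rnorm(length(true_values), 0, cv))
  bad <- which(out <= 0 | out > upper)
  tries <- 0L
  while (length(bad) && tries < max_tries) {
    out[bad] <- true_values[bad] * (1 + stats::rnorm(length(bad), 0, cv))
    bad <- bad[out[bad] <= 0 | out[bad] > upper]
    tries <- tries + 1L
  }
  if (length(bad)) stop("could not draw noise inside bounds; CV too large?",
                        call. = FALSE)
  out
}

#' Simulate a fluorescence quenching titration
#'
#' Generates intensities from either the Stern-Volmer static-quenching model
#' F = F0 / (1 + KSV \[Q\]) (supply `ksv_per_M`) or the binding isotherm
#' (F0 - F)/F = Ka \[Q\]^n (supply `ka_per_M` and `n_sites`), then applies
#' multiplicative Gaussian noise of coefficient of variation `noise_cv`.
#' Draws violating 0 < F <= F0 are redrawn. Exactly one of the two
#' parameterisations must be given.
#'
#' @param quencher_conc_M positive ascending quencher concentrations (M).
#' @param f0_au unquenched intensity F0.
#' @param ksv_per_M Stern-Volmer constant (M^-1), or `NULL`.
#' @param ka_per_M,n_sites association constant (M^-1) and binding-site
#'   number for the isotherm parameterisation, or `NULL`.
#' @param temperature_K temperature label of the series.
#' @param noise_cv coefficient of variation of the multiplicative noise;
#'   default 0.02 (typical instrument repeatability); 0 for noiseless data.
#' @param seed integer seed; `NULL` uses (and advances) the current RNG.
#' @param marker optional site-marker label carried into the series.
#' @return A [titration_series()].
#' @examples
#' simulate_titration(c(5, 10, 15, 20) * 1e-6, 1000, ksv_per_M = 1.5e4,
#'                    noise_cv = 0, seed = 1)
#' @export
simulate_titration <- function(quencher_conc_M, f0_au = 1000,
                               ksv_per_M = NULL, ka_per_M = NULL,
                               n_sites = NULL, temperature_K = 298,
                               noise_cv = 0.02, seed = NULL,
                               marker = "none") {
  if (!is.null(ksv_per_M) && (!is.null(ka_per_M) || !is.null(n_sites))) {
    stop("supply either ksv_per_M or (ka_per_M, n_sites), not both",
         call. = FALSE)
  }
  if (is.null(ksv_per_M) && (is.null(ka_per_M) || is.null(n_sites))) {
    stop("supply ksv_per_M, or both ka_per_M and n_sites", call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  f_true <- if (!is.null(ksv_per_M)) {
    stopifnot_scalar(ksv_per_M, "ksv_per_M", positive = FALSE)
    f0_au / (1 + ksv_per_M * quencher_conc_M)
  } else {
    stopifnot_scalar(ka_per_M, "ka_per_M")
    stopifnot_scalar(n_sites, "n_sites")
    f0_au / (1 + ka_per_M * quencher_conc_M^n_sites)
  }
  f <- with_seed(seed, noisy_positive(f_true, noise_cv, upper = f0_au))
  titration_series(quencher_conc_M, f, f0_au, temperature_K, marker = marker)
}

#' Simulate van't Hoff-consistent association constants
#'
#' Evaluates Ka(T) = exp(-dH / (R T) + dS / R) exactly at each temperature,
#' so a subsequent [vant_hoff_fit()] recovers (dH, dS) to machine precision.
#'
#' @param dH_cal_per_mol enthalpy change in cal mol^-1.
#' @param dS_cal_per_mol_K entropy change in cal mol^-1 K^-1.
#' @param temperatures_K positive temperatures (K).
#' @param constants a [default_constants()] list supplying the gas constant.
#' @return data frame with columns `temperature_K`, `ka_per_M`.
#' @examples
#' simulate_temperature_series(5396, 36.099, c(298, 303, 310))
#' @export
simulate_temperature_series <- function(dH_cal_per_mol, dS_cal_per_mol_K,
                                        temperatures_K,
                                        constants = default_constants()) {
  if (any(temperatures_K <= 0)) stop("temperatures must be > 0 K", call. = FALSE)
  R <- constants$R_cal_per_mol_K
  ka <- exp(-dH_cal_per_mol / (R * temperatures_K) + dS_cal_per_mol_K / R)
  data.frame(temperature_K = temperatures_K, ka_per_M = ka)
}

#' Simulate a glycation assay panel
#'
#' Draws replicate readings per group from Normal(mean, SD) truncated at
#' zero by redraw, so the configured group means stay unbiased at small SD.
#' The default regime emulates a four-dose fructosamine panel: native and
#' glycated baselines of 15.42 and 89.89 (raw units), treated groups whose
#' means interpolate a Hill-shaped inhibition curve, and an
#' aminoguanidine-like positive control.
#'
#' @param group_means named numeric vector of group means (raw readings).
#' @param group_sds named numeric vector of SDs (same names), >= 0.
#' @param roles named character vector of group roles (see [assay_panel()]).
#' @param doses_uM named doses for treated groups.
#' @param n_replicates replicates per group; default 4.
#' @param marker_kind marker type label for the panel.
#' @param seed integer seed.
#' @param ... passed to [assay_panel()] (protein concentration etc.).
#' @return An [assay_panel()].
#' @export
simulate_panel <- function(group_means, group_sds, roles, doses_uM = NULL,
                           n_replicates = 4, marker_kind = "fructosamine",
                           seed = NULL, ...) {
  # accept named lists (e.g. from a YAML config) as well as named vectors
  group_means <- unlist(group_means)
  group_sds <- unlist(group_sds)
  roles <- unlist(roles)
  if (!is.null(doses_uM)) doses_uM <- unlist(doses_uM)
  if (!setequal(names(group_means), names(group_sds))) {
    stop("group_means and group_sds must share names", call. = FALSE)
  }
  if (any(group_sds < 0)) stop("SDs must be >= 0", call. = FALSE)
  groups <- with_seed(seed, {
    gs <- lapply(names(group_means), function(g) {
      m <- group_means[[g]]
      s <- group_sds[[g]]
      if (s == 0) return(rep(m, n_replicates))
      draws <- stats::rnorm(n_replicates, m, s)
      bad <- which(draws < 0)
      tries <- 0L
      while (length(bad) && tries < 1000L) {
        draws[bad] <- stats::rnorm(length(bad), m, s)
        bad <- bad[draws[bad] < 0]
        tries <- tries + 1L
      }
      if (length(bad)) stop("cannot draw non-negative readings; SD too large",
                            call. = FALSE)
      draws
    })
    names(gs) <- names(group_means)
    gs
  })
  assay_panel(marker_kind, groups, roles, doses_uM = doses_uM, ...)
}

#' Simulate a dose-response inhibition table
#'
#' y = 100 / (1 + (IC50 / x)^h) plus multiplicative Gaussian noise.
#'
#' @param ic50_uM half-maximal inhibitory concentration (micromolar).
#' @param hill_slope Hill coefficient.
#' @param doses_uM ascending doses (micromolar).
#' @param noise_cv coefficient of variation of multiplicative noise.
#' @param seed integer seed.
#' @return data frame with columns `dose_uM`, `pct_inhibition`.
#' @examples
#' simulate_dose_response(130, 1.8, c(50, 100, 150, 200), noise_cv = 0)
#' @export
simulate_dose_response <- function(ic50_uM, hill_slope, doses_uM,
                                   noise_cv = 0, seed = NULL) {
  stopifnot_scalar(ic50_uM, "ic50_uM")
  stopifnot_scalar(hill_slope, "hill_slope")
  if (any(doses_uM <= 0)) stop("doses must be > 0", call. = FALSE)
  y <- 100 / (1 + (ic50_uM / doses_uM)^hill_slope)
  y <- with_seed(seed, noisy_positive(y, noise_cv, upper = Inf))
  data.frame(dose_uM = doses_uM, pct_inhibition = y)
}

#' Simulate a Gaussian emission band
#'
#' A Gaussian band of the given amplitude centred at `lambda_max_nm` on a
#' wavelength grid (default the 290-500 nm tryptophan emission scan), so
#' [peak_intensity()] reads back the amplitude at the band centre.
#'
#' @param lambda_max_nm band centre (nm).
#' @param width_nm Gaussian standard deviation (nm).
#' @param amplitude_au peak intensity.
#' @param grid_nm wavelength grid; default `seq(290, 500, by = 1)`.
#' @param label optional sample identifier.
#' @return An [emission_spectrum()].
#' @export
simulate_emission_spectrum <- function(lambda_max_nm = 335, width_nm = 25,
                                       amplitude_au = 1000,
                                       grid_nm = seq(290, 500, by = 1),
                                       label = NULL) {
  stopifnot_scalar(width_nm, "width_nm")
  stopifnot_scalar(amplitude_au, "amplitude_au")
  intens <- amplitude_au * exp(-0.5 * ((grid_nm - lambda_max_nm) / width_nm)^2)
  emission_spectrum(grid_nm, intens, excitation_nm = 280, label = label)
}
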