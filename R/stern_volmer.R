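#' Stern-Volmer quenching fit
#'
#' Fits the Stern-Volmer relation F0/F = 1 + KSV \[Q\] by ordinary least
#' squares of F0/F against quencher concentration. The slope is the
#' Stern-Volmer constant KSV (M^-1); the bimolecular quenching rate constant
#' Kq = KSV / tau0 is attached. The intercept is left free, mirroring how
#' the linearised plots are usually fitted; an intercept deviating from 1 by
#' more than 10% is flagged.
#'
#' @param series a [titration_series()] with at least 3 points.
#' @param constants a [default_constants()] list supplying `tau0_s`.
#' @return Object of class `"quenching_fit"`: list with `ksv_per_M`,
#'   `ksv_se`, `kq_per_M_s`, `intercept`, `r_squared`, `temperature_K`,
#'   `n_points`, `marker`, and character vector `flags` (possibly empty;
#'   `"no-quenching"` when the fitted slope is <= 0, `"intercept-deviation"`
#'   when |intercept - 1| > 0.1).
#' @examples
#' q <- c(5, 10, 15, 20, 25) * 1e-6
#' ts <- titration_series(q, 1000 / (1 + 1.5e4 * q), 1000, 298)
#' stern_volmer_fit(ts)
#' @export
stern_volmer_fit <- function(series, constants = default_constants()) {
  stopifnot(inherits(series, "titration_series"))
  if (nrow(series$points) < 3L) {
    stop("insufficient data: Stern-Volmer fit needs >= 3 titration points",
         call. = FALSE)
  }
  q <- series$points$quencher_conc_M
  y <- series$f0_au / series$points$f_au
  fit <- stats::lm(y ~ q)
  # noiseless synthetic data make summary() warn about a perfect fit
  s <- suppressWarnings(summary(fit))
  ksv <- unname(stats::coef(fit)[2L])
  ksv_se <- unname(s$coefficients[2L, 2L])
  flags <- character()
  if (ksv <= 0) {
    flags <- c(flags, "no-quenching")
    ksv <- max(ksv, 0)
  }
  intercept <- unname(stats::coef(fit)[1L])
  if (abs(intercept - 1) > 0.1) flags <- c(flags, "intercept-deviation")
  # r.squared is NaN for exactly constant y (no quenching); report 0 then
  r2 <- if (is.finite(s$r.squared)) s$r.squared else 0
  structure(
    list(
      ksv_per_M = ksv,
      ksv_se = ksv_se,
      kq_per_M_s = quenching_rate(ksv, constants$tau0_s),
      intercept = intercept,
      r_squared = r2,
      temperature_K = series$temperature_K,
      n_points = nrow(series$points),
      marker = series$marker,
      tau0_s = constants$tau0_s,
      flags = flags
    ),
    class = "quenching_fit"
  )
}

#' @export
print.quenching_fit <- function(x, ...) {
  cat(sprintf("Stern-Volmer fit at %g K (%d points)\n", x$temperature_K,
              x$n_points))
  cat(sprintf("  KSV = %.4g +/- %.2g M^-1;  Kq = %.4g M^-1 s^-1;  R2 = %.4f\n",
              x$ksv_per_M, x$ksv_se, x$kq_per_M_s, x$r_squared))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Bimolecular quenching rate constant
#'
#' Kq = KSV / tau0, where tau0 is the unquenched fluorophore lifetime.
#' Magnitudes far above the diffusion-controlled biopolymer ceiling
#' (~2e10 M^-1 s^-1) indicate static quenching via ground-state complex
#' formation rather than collisional quenching.
#'
#' @param ksv_per_M Stern-Volmer constant (M^-1), >= 0.
#' @param tau0_s fluorophore lifetime in seconds, > 0.
#' @return Kq in M^-1 s^-1.
#' @examples
#' quenching_rate(1.525e4, 5.78e-9)
#' @export
quenching_rate <- function(ksv_per_M, tau0_s) {
  stopifnot_scalar(tau0_s, "tau0_s")
  if (!is.numeric(ksv_per_M) || anyNA(ksv_per_M) || any(ksv_per_M < 0)) {
    stop("ksv_per_M must be numeric and >= 0", call. = FALSE)
  }
  ksv_per_M / tau0_s
}

#' Classify the quenching mode from multi-temperature fits
#'
#' Applies the two standard diagnostics jointly. The rate-magnitude rule:
#' static quenching when every Kq exceeds the diffusion-limited biopolymer
#' maximum, dynamic when none does. The temperature-trend rule: KSV falling
#' with temperature indicates static quenching (the ground-state complex
#' dissociates on heating); KSV rising indicates dynamic (collisions become
#' more frequent). The mode is called `static` or `dynamic` only when both
#' rules agree; any conflict or non-monotone trend yields `ambiguous`, with
#' per-rule evidence recorded. With a single temperature the trend is
#' unavailable and the Kq rule decides alone.
#'
#' @param fits list of [stern_volmer_fit()] results at distinct temperatures.
#' @param threshold Kq ceiling for biopolymers (M^-1 s^-1).
#' @return Object of class `"quenching_mode"`: list with `mode` (one of
#'   `"static"`, `"dynamic"`, `"ambiguous"`), and `evidence` (list with
#'   per-temperature logical `kq_exceeds_max`, and `ksv_trend` one of
#'   `"decreasing"`, `"increasing"`, `"non-monotone"`, `"unavailable"`).
#' @export
classify_quenching_mode <- function(fits,
                                    threshold = default_constants()$kq_biopolymer_max_per_M_s) {
  if (inherits(fits, "quenching_fit")) fits <- list(fits)
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "quenching_fit")))
  temps <- vapply(fits, `[[`, numeric(1), "temperature_K")
  ord <- order(temps)
  fits <- fits[ord]
  temps <- temps[ord]
  if (anyDuplicated(temps)) {
    stop("fits must be at distinct temperatures", call. = FALSE)
  }
  kq <- vapply(fits, `[[`, numeric(1), "kq_per_M_s")
  ksv <- vapply(fits, `[[`, numeric(1), "ksv_per_M")
  exceeds <- kq > threshold
  trend <- if (length(ksv) < 2L) {
    "unavailable"
  } else if (all(diff(ksv) < 0)) {
    "decreasing"
  } else if (all(diff(ksv) > 0)) {
    "increasing"
  } else {
    "non-monotone"
  }
  mode <- if (trend == "unavailable") {
    if (all(exceeds)) "static" else if (!any(exceeds)) "dynamic" else "ambiguous"
  } else if (all(exceeds) && trend == "decreasing") {
    "static"
  } else if (!any(exceeds) && trend == "increasing") {
    "dynamic"
  } else {
    "ambiguous"
  }
  structure(
    list(
      mode = mode,
      evidence = list(
        temperatures_K = temps,
        kq_per_M_s = kq,
        kq_exceeds_max = exceeds,
        kq_threshold = threshold,
        ksv_per_M = ksv,
        ksv_trend = trend
      )
    ),
    class = "quenching_mode"
  )
}

#' @export
print.quenching_mode <- function(x, ...) {
  cat("Quenching mode:", x$mode, "\n")
  cat("  Kq > biopolymer max:",
      paste(x$evidence$kq_exceeds_max, collapse = ", "), "\n")
  cat("  KSV temperature trend:", x$evidence$ksv_trend, "\n")
  invisible(x)
}
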