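#' Double-logarithmic binding fit
#'
#' Fits the double-logarithmic (modified Stern-Volmer) relation
#' log10((F0 - F)/F) = log10 Ka + n log10 \[Q\] by ordinary least squares on
#' the transformed variables. The slope estimates the apparent number of
#' binding sites n and the intercept gives the association constant
#' Ka = 10^intercept (M^-1).
#'
#' Points with F >= F0 have no defined left-hand side and are excluded with a
#' warning; at least 3 usable points are required.
#'
#' @param series a [titration_series()].
#' @return Object of class `"binding_fit"`: list with `ka_per_M`, `ka_se`
#'   (standard error propagated from the intercept SE on the log10 scale),
#'   `n_sites`, `n_se`, `r_squared`, `temperature_K`, `n_points_used`,
#'   `marker`.
#' @examples
#' q <- c(5, 10, 15, 20, 25) * 1e-6
#' f <- 1000 / (1 + 1e4 * q)   # Ka = 1e4, n = 1
#' double_log_fit(titration_series(q, f, 1000, 298))
#' @export
double_log_fit <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  q <- series$points$quencher_conc_M
  f <- series$points$f_au
  usable <- f < series$f0_au
  if (any(!usable)) {
    warning(sum(!usable), " point(s) with F >= F0 excluded from double-log fit",
            call. = FALSE)
  }
  if (sum(usable) < 3L) {
    stop("insufficient data: double-log fit needs >= 3 points with F < F0",
         call. = FALSE)
  }
  x <- log10(q[usable])
  y <- log10((series$f0_au - f[usable]) / f[usable])
  fit <- stats::lm(y ~ x)
  s <- suppressWarnings(summary(fit))
  log_ka <- unname(stats::coef(fit)[1L])
  log_ka_se <- unname(s$coefficients[1L, 2L])
  n_sites <- unname(stats::coef(fit)[2L])
  if (n_sites <= 0) {
    stop("fitted number of binding sites is not positive; ",
         "data are not consistent with a binding isotherm", call. = FALSE)
  }
  ka <- 10^log_ka
  structure(
    list(
      ka_per_M = ka,
      # delta method: SE(Ka) = Ka * ln(10) * SE(log10 Ka)
      ka_se = ka * log(10) * log_ka_se,
      n_sites = n_sites,
      n_se = unname(s$coefficients[2L, 2L]),
      r_squared = if (is.finite(s$r.squared)) s$r.squared else 0,
      temperature_K = series$temperature_K,
      n_points_used = sum(usable),
      marker = series$marker
    ),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("Double-log binding fit at %g K (%d points)\n",
              x$temperature_K, x$n_points_used))
  cat(sprintf("  Ka = %.4g +/- %.2g M^-1;  n = %.3f +/- %.3f;  R2 = %.4f\n",
              x$ka_per_M, x$ka_se, x$n_sites, x$n_se, x$r_squared))
  invisible(x)
}

#' Competitive site-marker displacement analysis
#'
#' Compares the binding constants of a drug-protein titration performed after
#' saturating the protein with a site-specific marker against those of the
#' marker-free titration. When both the Stern-Volmer constant and the
#' association constant drop by more than `displacement_threshold` in the
#' marker's presence, the drug is called displaced from that marker's site:
#' a warfarin-like marker maps to Sudlow site I (sub-domain IIA), an
#' ibuprofen-like marker to Sudlow site II (sub-domain IIIA).
#'
#' @param free_quench marker-free [stern_volmer_fit()].
#' @param free_bind marker-free [double_log_fit()].
#' @param marker_fits named list, one entry per marker, each a list with
#'   elements `quench` ([stern_volmer_fit()]) and `bind` ([double_log_fit()]).
#'   Names may be anything; the site assignment uses each fit's `marker`
#'   field (or the list name when that field is `"none"`).
#' @param displacement_threshold fractional joint drop in KSV and K required
#'   to call displacement; default 0.20.
#' @return Object of class `"site_marker_calls"`: data frame with one row
#'   per marker and columns `marker`, `ksv_ratio`, `k_ratio`, `displaced`,
#'   `assigned_site`.
#' @examples
#' q <- c(5, 10, 15, 20, 25) * 1e-6
#' free <- titration_series(q, 1000 / (1 + 1.525e4 * q), 1000, 298)
#' warf <- titration_series(q, 1000 / (1 + 0.680e4 * q), 1000, 298,
#'                          marker = "warfarin-like")
#' site_marker_analysis(
#'   stern_volmer_fit(free), double_log_fit(free),
#'   list(warfarin = list(quench = stern_volmer_fit(warf),
#'                        bind = double_log_fit(warf)))
#' )
#' @export
site_marker_analysis <- function(free_quench, free_bind, marker_fits,
                                 displacement_threshold = 0.20) {
  stopifnot(inherits(free_quench, "quenching_fit"),
            inherits(free_bind, "binding_fit"),
            is.list(marker_fits), length(marker_fits) >= 1L)
  if (free_quench$ksv_per_M <= 0 || free_bind$ka_per_M <= 0) {
    stop("marker-free constants must be > 0 for ratio computation",
         call. = FALSE)
  }
  if (!is.numeric(displacement_threshold) || displacement_threshold <= 0 ||
      displacement_threshold >= 1) {
    stop("displacement_threshold must be in (0, 1)", call. = FALSE)
  }
  site_for <- function(marker) {
    switch(marker,
           "warfarin-like" = "Sudlow site I (sub-domain IIA)",
           "ibuprofen-like" = "Sudlow site II (sub-domain IIIA)",
           NA_character_)
  }
  rows <- lapply(seq_along(marker_fits), function(i) {
    mf <- marker_fits[[i]]
    stopifnot(inherits(mf$quench, "quenching_fit"),
              inherits(mf$bind, "binding_fit"))
    marker <- mf$quench$marker
    if (identical(marker, "none") && !is.null(names(marker_fits))) {
      marker <- names(marker_fits)[i]
    }
    ksv_ratio <- mf$quench$ksv_per_M / free_quench$ksv_per_M
    k_ratio <- mf$bind$ka_per_M / free_bind$ka_per_M
    displaced <- (k_ratio < 1 - displacement_threshold) &&
      (ksv_ratio < 1 - displacement_threshold)
    data.frame(
      marker = marker,
      ksv_ratio = ksv_ratio,
      k_ratio = k_ratio,
      displaced = displaced,
      assigned_site = if (displaced) site_for(marker) else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "displacement_threshold") <- displacement_threshold
  class(out) <- c("site_marker_calls", "data.frame")
  out
}

#' @export
print.site_marker_calls <- function(x, ...) {
  cat(sprintf("Site-marker displacement calls (threshold %.0f%% joint drop)\n",
              attr(x, "displacement_threshold") * 100))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
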