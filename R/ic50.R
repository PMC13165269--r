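#' IC50 estimation from a dose-response inhibition curve
#'
#' Estimates the half-maximal inhibitory concentration from doses and
#' percent-inhibition values. Two methods:
#' \describe{
#'   \item{`hill`}{Least-squares fit of the two-parameter Hill curve
#'     y = 100 / (1 + (IC50 / x)^h) with bottom and top fixed at 0 and 100.
#'     With the typical four-dose design there are too few points for a
#'     four-parameter logistic, so the asymptotes are fixed.}
#'   \item{`loglinear`}{Linear interpolation of inhibition against
#'     log10(dose) between the two doses bracketing 50%.}
#' }
#' If no pair of observations brackets 50% and `extrapolate = FALSE`, the
#' result is flagged not estimable with a diagnostic rather than an error.
#'
#' @param doses_uM ascending drug doses in micromolar, > 0, length >= 3.
#' @param pct_inhibition percent inhibition at each dose, finite.
#' @param method `"hill"` (default) or `"loglinear"`.
#' @param extrapolate allow an estimate when 50% is not bracketed (`hill`
#'   extrapolates from the fitted curve; `loglinear` extends the terminal
#'   segment). Default `FALSE`.
#' @return Object of class `"dose_response"`: list with `doses_uM`,
#'   `pct_inhibition`, `ic50_uM` (`NA` when not estimable), `hill_slope`
#'   (`NA` for loglinear), `fit_method`, `estimable`, `diagnostic`.
#' @examples
#' d <- c(50, 100, 150, 200)
#' y <- 100 / (1 + (130 / d)^1.8)
#' ic50_estimate(d, y)
#' @export
ic50_estimate <- function(doses_uM, pct_inhibition,
                          method = c("hill", "loglinear"),
                          extrapolate = FALSE) {
  method <- match.arg(method)
  if (length(doses_uM) != length(pct_inhibition)) {
    stop("doses_uM and pct_inhibition must have equal length", call. = FALSE)
  }
  if (length(doses_uM) < 3L) {
    stop("IC50 estimation needs >= 3 doses", call. = FALSE)
  }
  if (any(doses_uM <= 0) || any(diff(doses_uM) <= 0)) {
    stop("doses must be > 0 and strictly ascending", call. = FALSE)
  }
  if (anyNA(pct_inhibition) || any(!is.finite(pct_inhibition))) {
    stop("pct_inhibition must be finite", call. = FALSE)
  }

  out <- list(doses_uM = as.numeric(doses_uM),
              pct_inhibition = as.numeric(pct_inhibition),
              ic50_uM = NA_real_, hill_slope = NA_real_,
              fit_method = method, estimable = FALSE, diagnostic = NULL)
  class(out) <- "dose_response"

  spans_50 <- min(pct_inhibition) < 50 && max(pct_inhibition) > 50
  crosses_exact <- any(pct_inhibition == 50)

  if (method == "loglinear") {
    if (!spans_50 && !crosses_exact && !extrapolate) {
      out$diagnostic <- "inhibition values do not bracket 50%"
      return(out)
    }
    lx <- log10(doses_uM)
    if (crosses_exact) {
      out$ic50_uM <- doses_uM[which(pct_inhibition == 50)[1L]]
    } else if (spans_50) {
      # first adjacent pair straddling 50%
      straddle <- which((pct_inhibition[-length(pct_inhibition)] - 50) *
                          (pct_inhibition[-1L] - 50) < 0)
      if (!length(straddle)) {
        out$diagnostic <- "no adjacent dose pair brackets 50%"
        return(out)
      }
      i <- straddle[1L]
      frac <- (50 - pct_inhibition[i]) /
        (pct_inhibition[i + 1L] - pct_inhibition[i])
      out$ic50_uM <- 10^(lx[i] + frac * (lx[i + 1L] - lx[i]))
    } else {
      # extrapolate along the terminal segment nearest 50%
      n <- length(doses_uM)
      i <- if (max(pct_inhibition) < 50) c(n - 1L, n) else c(1L, 2L)
      slope <- (pct_inhibition[i[2L]] - pct_inhibition[i[1L]]) /
        (lx[i[2L]] - lx[i[1L]])
      if (slope == 0) {
        out$diagnostic <- "flat terminal segment; cannot extrapolate"
        return(out)
      }
      out$ic50_uM <- 10^(lx[i[1L]] + (50 - pct_inhibition[i[1L]]) / slope)
    }
    out$estimable <- TRUE
    return(out)
  }

  # hill: requires an increasing tendency; a monotone-decreasing curve is
  # not a valid inhibition dose-response
  if (all(diff(pct_inhibition) <= 0)) {
    out$diagnostic <- "inhibition decreases with dose; not a valid curve"
    return(out)
  }
  if (!spans_50 && !crosses_exact && !extrapolate) {
    out$diagnostic <- "inhibition values do not bracket 50%"
    return(out)
  }
  # start values: loglinear crossing (or midpoint dose), slope 1
  start_ic50 <- tryCatch({
    ll <- ic50_estimate(doses_uM, pct_inhibition, method = "loglinear",
                        extrapolate = TRUE)
    if (ll$estimable && is.finite(ll$ic50_uM) && ll$ic50_uM > 0) {
      ll$ic50_uM
    } else {
      stats::median(doses_uM)
    }
  }, error = function(e) stats::median(doses_uM))
  df <- data.frame(x = doses_uM, y = pct_inhibition)
  fit <- tryCatch(
    stats::nls(y ~ 100 / (1 + (ic50 / x)^h), data = df,
               start = list(ic50 = start_ic50, h = 1),
               algorithm = "port",
               lower = c(ic50 = 1e-9, h = 1e-3),
               upper = c(ic50 = 1e9, h = 50),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    out$diagnostic <- "Hill fit did not converge"
    return(out)
  }
  cf <- stats::coef(fit)
  out$ic50_uM <- unname(cf["ic50"])
  out$hill_slope <- unname(cf["h"])
  out$estimable <- TRUE
  out
}

#' @export
print.dose_response <- function(x, ...) {
  cat(sprintf("Dose-response IC50 (%s method)\n", x$fit_method))
  if (x$estimable) {
    cat(sprintf("  IC50 = %.4g uM", x$ic50_uM))
    if (is.finite(x$hill_slope)) cat(sprintf(";  Hill slope = %.3f", x$hill_slope))
    cat("\n")
  } else {
    cat("  not estimable:", x$diagnostic, "\n")
  }
  invisible(x)
}
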