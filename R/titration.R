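#' Fluorescence titration series
#'
#' Container for a steady-state fluorescence quenching titration at one
#' temperature: the unquenched peak intensity F0 and the quenched peak
#' intensity F at each quencher concentration \[Q\].
#'
#' Invariants enforced at construction: quencher concentrations strictly
#' increasing and positive; all intensities positive; F never exceeds F0
#' (quenching only); temperature positive.
#'
#' @param quencher_conc_M numeric vector of quencher concentrations in mol/L,
#'   strictly increasing, all > 0.
#' @param f_au fluorescence peak intensities (arbitrary units) at each
#'   concentration, same length as `quencher_conc_M`.
#' @param f0_au unquenched peak intensity F0 (arbitrary units), > 0.
#' @param temperature_K absolute temperature in kelvin, > 0.
#' @param marker optional site-marker label, one of `"none"`,
#'   `"warfarin-like"`, `"ibuprofen-like"`.
#' @param label optional sample identifier.
#' @return An object of class `"titration_series"`: a list with elements
#'   `points` (data frame with columns `quencher_conc_M`, `f_au`), `f0_au`,
#'   `temperature_K`, `marker`, `label`.
#' @examples
#' ts <- titration_series(
#'   quencher_conc_M = c(5, 10, 15, 20) * 1e-6,
#'   f_au = 1000 / (1 + 1.5e4 * c(5, 10, 15, 20) * 1e-6),
#'   f0_au = 1000, temperature_K = 298
#' )
#' ts
#' @export
titration_series <- function(quencher_conc_M, f_au, f0_au, temperature_K,
                             marker = "none", label = NULL) {
  if (!is.numeric(quencher_conc_M) || !is.numeric(f_au)) {
    stop("quencher_conc_M and f_au must be numeric", call. = FALSE)
  }
  if (length(quencher_conc_M) != length(f_au)) {
    stop("quencher_conc_M and f_au must have equal length", call. = FALSE)
  }
  if (anyNA(quencher_conc_M) || anyNA(f_au)) {
    stop("titration data must not contain missing values", call. = FALSE)
  }
  bad <- which(quencher_conc_M <= 0)
  if (length(bad)) {
    stop("quencher concentrations must be > 0 (row ", bad[1L], ")",
         call. = FALSE)
  }
  d <- diff(quencher_conc_M)
  if (any(d <= 0)) {
    row <- which(d <= 0)[1L] + 1L
    if (any(d == 0)) {
      dup <- quencher_conc_M[which(d == 0)[1L]]
      stop("duplicated quencher concentration ", format(dup), " (row ",
           which(d == 0)[1L] + 1L, ")", call. = FALSE)
    }
    stop("quencher concentrations must be strictly increasing (row ", row,
         ")", call. = FALSE)
  }
  bad <- which(f_au <= 0)
  if (length(bad)) {
    stop("intensities must be > 0 (row ", bad[1L],
         "); zero intensity would make F0/F undefined", call. = FALSE)
  }
  stopifnot_scalar(f0_au, "f0_au")
  stopifnot_scalar(temperature_K, "temperature_K")
  bad <- which(f_au > f0_au)
  if (length(bad)) {
    stop("intensity exceeds F0 at row ", bad[1L],
         " (quenching-only data expected)", call. = FALSE)
  }
  marker <- match.arg(marker, c("none", "warfarin-like", "ibuprofen-like"))
  structure(
    list(
      points = data.frame(quencher_conc_M = as.numeric(quencher_conc_M),
                          f_au = as.numeric(f_au)),
      f0_au = as.numeric(f0_au),
      temperature_K = as.numeric(temperature_K),
      marker = marker,
      label = label
    ),
    class = "titration_series"
  )
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("Fluorescence titration series (%d points) at %g K\n",
              nrow(x$points), x$temperature_K))
  cat(sprintf("  F0 = %g a.u.; [Q] range %g - %g M; marker: %s\n",
              x$f0_au, min(x$points$quencher_conc_M),
              max(x$points$quencher_conc_M), x$marker))
  invisible(x)
}

# internal: parse "# key: value" metadata header lines
parse_meta_lines <- function(lines) {
  meta_lines <- grep("^\\s*#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    ln <- sub("^\\s*#\\s*", "", ln)
    if (!grepl(":", ln, fixed = TRUE)) next
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    meta[[key]] <- val
  }
  meta
}

#' Read a titration CSV file
#'
#' Reads a comma-separated titration table with a required header. The
#' quencher-concentration column declares its unit in the column name
#' (`quencher_conc_M` or `quencher_conc_uM`); micromolar values are converted
#' to molar on read. Temperature, F0 and the optional site-marker label are
#' given as leading comment lines of the form `# temperature_K: 298`,
#' `# f0_au: 1000`, `# marker: none`.
#'
#' An optional `dilution_factor` column supplies a per-point correction for
#' cumulative titrant addition: intensities are multiplied by it on read.
#' When the column is absent no correction is applied.
#'
#' @param path path to a CSV file (UTF-8, comma separator, dot decimal).
#' @return A validated [titration_series()].
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("# temperature_K: 298", "# f0_au: 1000",
#'              "quencher_conc_uM,f_au", "5,930", "10,870", "15,820"), tf)
#' read_titration_csv(tf)
#' @export
read_titration_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  meta <- parse_meta_lines(lines)
  if (is.null(meta$temperature_K)) {
    stop("missing '# temperature_K:' metadata line in ", path, call. = FALSE)
  }
  if (is.null(meta$f0_au)) {
    stop("missing '# f0_au:' metadata line in ", path, call. = FALSE)
  }
  body <- lines[!grepl("^\\s*#", lines)]
  body <- body[nzchar(trimws(body))]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  conc_col <- intersect(c("quencher_conc_M", "quencher_conc_uM"), names(df))
  if (length(conc_col) != 1L) {
    stop("expected exactly one of columns 'quencher_conc_M', ",
         "'quencher_conc_uM' in ", path, call. = FALSE)
  }
  if (!"f_au" %in% names(df)) {
    stop("missing column 'f_au' in ", path, call. = FALSE)
  }
  conc <- df[[conc_col]]
  if (conc_col == "quencher_conc_uM") conc <- conc * 1e-6
  f <- df$f_au
  if ("dilution_factor" %in% names(df)) {
    if (any(df$dilution_factor <= 0)) {
      stop("dilution_factor values must be > 0 in ", path, call. = FALSE)
    }
    f <- f * df$dilution_factor
  }
  titration_series(
    quencher_conc_M = conc,
    f_au = f,
    f0_au = as.numeric(meta$f0_au),
    temperature_K = as.numeric(meta$temperature_K),
    marker = if (is.null(meta$marker)) "none" else meta$marker,
    label = meta$label
  )
}

#' Write a titration series to CSV
#'
#' Inverse of [read_titration_csv()]: writes the metadata comment lines and
#' the data table with concentrations in molar at full double precision, so a
#' write-then-read round trip reproduces every numeric field exactly.
#'
#' @param series a [titration_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  hdr <- c(
    sprintf("# temperature_K: %s", format(series$temperature_K, digits = 17)),
    sprintf("# f0_au: %s", format(series$f0_au, digits = 17)),
    sprintf("# marker: %s", series$marker)
  )
  if (!is.null(series$label)) hdr <- c(hdr, sprintf("# label: %s", series$label))
  rows <- sprintf("%s,%s",
                  format(series$points$quencher_conc_M, digits = 17),
                  format(series$points$f_au, digits = 17))
  writeLines(c(hdr, "quencher_conc_M,f_au", rows), path)
  invisible(path)
}

#' Emission spectrum
#'
#' A fluorescence emission spectrum on an ascending wavelength grid, as
#' recorded after excitation at a fixed wavelength (280 nm for the tryptophan
#' emission of serum albumin, scanned over 290-500 nm).
#'
#' @param wavelengths_nm strictly increasing wavelength grid in nm.
#' @param intensities_au non-negative finite intensities, same length.
#' @param excitation_nm excitation wavelength in nm.
#' @param label optional sample identifier.
#' @return Object of class `"emission_spectrum"`.
#' @export
emission_spectrum <- function(wavelengths_nm, intensities_au,
                              excitation_nm = 280, label = NULL) {
  if (length(wavelengths_nm) != length(intensities_au)) {
    stop("wavelengths and intensities must have equal length", call. = FALSE)
  }
  if (any(diff(wavelengths_nm) <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (anyNA(intensities_au) || any(!is.finite(intensities_au)) ||
      any(intensities_au < 0)) {
    stop("intensities must be finite and >= 0", call. = FALSE)
  }
  stopifnot_scalar(excitation_nm, "excitation_nm")
  structure(
    list(wavelengths_nm = as.numeric(wavelengths_nm),
         intensities_au = as.numeric(intensities_au),
         excitation_nm = as.numeric(excitation_nm),
         label = label),
    class = "emission_spectrum"
  )
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf("Emission spectrum: %d points, %g-%g nm (ex %g nm)\n",
              length(x$wavelengths_nm), min(x$wavelengths_nm),
              max(x$wavelengths_nm), x$excitation_nm))
  invisible(x)
}

#' Inner-filter correction of a titration series
#'
#' Corrects observed intensities for absorption of the excitation and
#' emission beams by the titrant: F_corr = F * 10^((A_ex + A_em)/2), with
#' per-point absorbances at the excitation and emission wavelengths. This is
#' an opt-in hook; no correction is applied anywhere by default, matching
#' the common reporting practice for this assay family.
#'
#' @param series a [titration_series()].
#' @param a_ex,a_em absorbance at the excitation and emission wavelengths
#'   for each titration point (same length as the series), >= 0.
#' @return a new [titration_series()] with corrected intensities. The
#'   corrected F may exceed the uncorrected F0; F0 is rescaled by the
#'   correction of a hypothetical zero-absorbance point, i.e. left unchanged.
#' @export
inner_filter_correct <- function(series, a_ex, a_em) {
  stopifnot(inherits(series, "titration_series"))
  n <- nrow(series$points)
  if (length(a_ex) != n || length(a_em) != n) {
    stop("a_ex and a_em must have one value per titration point",
         call. = FALSE)
  }
  if (any(a_ex < 0) || any(a_em < 0)) {
    stop("absorbances must be >= 0", call. = FALSE)
  }
  f_corr <- series$points$f_au * 10^((a_ex + a_em) / 2)
  titration_series(series$points$quencher_conc_M,
                   pmin(f_corr, series$f0_au),
                   series$f0_au, series$temperature_K,
                   marker = series$marker, label = series$label)
}

#' Peak intensity of an emission spectrum
#'
#' Finds the emission maximum of a spectrum within a wavelength window
#' (default 320-350 nm, bracketing the ~335 nm tryptophan emission maximum of
#' serum albumin) and returns its wavelength and intensity. When `at_nm` is
#' supplied the intensity is instead read at that fixed wavelength, which is
#' how all titration points of one series are read at the wavelength of the
#' F0 peak.
#'
#' @param spectrum an [emission_spectrum()].
#' @param window length-2 numeric window (nm) searched for the maximum.
#' @param at_nm optional fixed wavelength (nm) at which to read intensity.
#' @return list with `lambda_nm` and `intensity_au`.
#' @export
peak_intensity <- function(spectrum, window = c(320, 350), at_nm = NULL) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  wl <- spectrum$wavelengths_nm
  if (!is.null(at_nm)) {
    i <- which.min(abs(wl - at_nm))
    return(list(lambda_nm = wl[i], intensity_au = spectrum$intensities_au[i]))
  }
  sel <- wl >= window[1] & wl <= window[2]
  if (!any(sel)) stop("no spectrum points inside the peak window", call. = FALSE)
  i <- which(sel)[which.max(spectrum$intensities_au[sel])]
  list(lambda_nm = wl[i], intensity_au = spectrum$intensities_au[i])
}
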