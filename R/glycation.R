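#' Fructosamine content from NBT assay absorbance
#'
#' Converts the 530 nm absorbance of the nitro blue tetrazolium reduction
#' assay to fructosamine content in nmol per mg protein via Beer-Lambert:
#' concentration (mol/L) = A * dilution / (eps * path), then normalised by
#' the protein concentration.
#'
#' @param a530 absorbance at 530 nm, >= 0.
#' @param protein_mg_per_ml protein concentration in mg/mL, > 0.
#' @param dilution_factor fold dilution applied before reading, > 0.
#' @param path_cm optical path length in cm, > 0.
#' @param eps molar extinction coefficient (M^-1 cm^-1).
#' @return fructosamine content in nmol per mg protein.
#' @examples
#' fructosamine_content(0.1, protein_mg_per_ml = 1)  # ~7.911 nmol/mg
#' @export
fructosamine_content <- function(a530, protein_mg_per_ml, dilution_factor = 1,
                                 path_cm = 1,
                                 eps = default_constants()$eps_fructosamine_per_M_cm) {
  beer_lambert_nmol_per_mg(a530, protein_mg_per_ml, dilution_factor, path_cm,
                           eps, "a530")
}

#' Protein carbonyl content from DNPH assay absorbance
#'
#' As [fructosamine_content()] but for the 2,4-dinitrophenylhydrazine
#' carbonyl assay read at 360 nm with eps = 22000 M^-1 cm^-1.
#'
#' @inheritParams fructosamine_content
#' @param a360 absorbance at 360 nm, >= 0.
#' @return carbonyl content in nmol per mg protein.
#' @examples
#' carbonyl_content(0.22, protein_mg_per_ml = 1)  # 10 nmol/mg
#' @export
carbonyl_content <- function(a360, protein_mg_per_ml, dilution_factor = 1,
                             path_cm = 1,
                             eps = default_constants()$eps_carbonyl_per_M_cm) {
  beer_lambert_nmol_per_mg(a360, protein_mg_per_ml, dilution_factor, path_cm,
                           eps, "a360")
}

# shared Beer-Lambert quantification: A -> mol/L -> nmol per mg protein
# mol/L * 1e9 nmol/mol / (mg/mL * 1000 mL/L) = A*dil/(eps*l) * 1e6 / (mg/mL)
beer_lambert_nmol_per_mg <- function(a, protein_mg_per_ml, dilution_factor,
                                     path_cm, eps, a_name) {
  if (!is.numeric(a) || anyNA(a) || any(a < 0)) {
    stop(a_name, " must be numeric and >= 0", call. = FALSE)
  }
  stopifnot_scalar(protein_mg_per_ml, "protein_mg_per_ml")
  stopifnot_scalar(dilution_factor, "dilution_factor")
  stopifnot_scalar(path_cm, "path_cm")
  stopifnot_scalar(eps, "eps")
  a * dilution_factor / (eps * path_cm) * 1e6 / protein_mg_per_ml
}

#' Percent modification of free lysine
#'
#' The TNBSA reagent reports free epsilon-amino groups; glycation consumes
#' them. Modification is expressed relative to the native sample's signal:
#' (1 - A335_sample / A335_native) * 100, clamped to \[0, 100\] with
#' out-of-range inputs flagged via the `"out_of_range"` attribute.
#'
#' @param a335_native optical density at 335 nm of the native sample, > 0.
#' @param a335_sample optical density at 335 nm of the test sample, >= 0.
#' @return percent of free lysine modified (vectorised over `a335_sample`).
#' @examples
#' lysine_modification(1.0, 0.25)  # 75
#' @export
lysine_modification <- function(a335_native, a335_sample) {
  stopifnot_scalar(a335_native, "a335_native")
  if (!is.numeric(a335_sample) || anyNA(a335_sample) || any(a335_sample < 0)) {
    stop("a335_sample must be numeric and >= 0", call. = FALSE)
  }
  pct <- (1 - a335_sample / a335_native) * 100
  oor <- pct < 0 | pct > 100
  pct <- pmin(pmax(pct, 0), 100)
  if (any(oor)) attr(pct, "out_of_range") <- which(oor)
  pct
}

#' Percent inhibition of a glycation marker
#'
#' Inhibition of marker formation relative to the glycation increment over
#' the native baseline: (glycated - treated) / (glycated - native) * 100.
#' Under this convention a treated value equal to the glycated level is 0%
#' inhibition and one restored to the native level is 100%. Values outside
#' \[0, 100\] (over-recovery or aggravation) are reported unchanged but
#' flagged via the `"out_of_range"` attribute. The simpler convention
#' (glycated - treated) / glycated * 100, which ignores the native baseline,
#' is available with `baseline = "zero"`.
#'
#' @param native_value marker level of the native (unglycated) group.
#' @param glycated_value marker level of the glycated, untreated group; must
#'   exceed `native_value` under `baseline = "native"`.
#' @param treated_value marker level(s) of treated group(s); vectorised.
#' @param baseline `"native"` (default, increment over native) or `"zero"`.
#' @return percent inhibition, same length as `treated_value`.
#' @examples
#' percent_inhibition(15.42, 89.89, 52.655)  # 50
#' @export
percent_inhibition <- function(native_value, glycated_value, treated_value,
                               baseline = c("native", "zero")) {
  baseline <- match.arg(baseline)
  stopifnot_scalar(native_value, "native_value", positive = FALSE)
  stopifnot_scalar(glycated_value, "glycated_value", positive = FALSE)
  if (!is.numeric(treated_value) || anyNA(treated_value)) {
    stop("treated_value must be numeric and non-missing", call. = FALSE)
  }
  denom <- if (baseline == "native") glycated_value - native_value else glycated_value
  ref <- if (baseline == "native") native_value else 0
  if (denom <= 0) {
    stop("degenerate baseline: glycated value must exceed ",
         if (baseline == "native") "the native value" else "zero",
         call. = FALSE)
  }
  pct <- (glycated_value - treated_value) / denom * 100
  oor <- pct < 0 | pct > 100
  if (any(oor)) attr(pct, "out_of_range") <- which(oor)
  attr(pct, "baseline") <- baseline
  pct
}

#' Percent inhibition of fluorescent AGE formation
#'
#' Identical functional form to [percent_inhibition()] applied to the
#' 440 nm AGE fluorescence readings (excitation 370 nm).
#'
#' @param f440_native,f440_glycated,f440_treated fluorescence intensities of
#'   the native, glycated and treated groups.
#' @inheritParams percent_inhibition
#' @return percent inhibition of AGE formation.
#' @export
age_inhibition <- function(f440_native, f440_glycated, f440_treated,
                           baseline = c("native", "zero")) {
  percent_inhibition(f440_native, f440_glycated, f440_treated,
                     baseline = baseline)
}

#' Glycation assay panel
#'
#' Groups of replicate readings for one glycation marker. The `roles` vector
#' assigns each group one of the experimental roles: `native`, `glycated`,
#' `treated` (with a dose in micromolar) or `positive_control`. Native and
#' glycated roles are required, since every derived percentage is computed
#' against them.
#'
#' @param marker_kind one of `"fructosamine"`, `"carbonyl"`, `"free_lysine"`,
#'   `"fluorescent_age"`.
#' @param groups named list of numeric replicate readings (>= 0), one entry
#'   per group.
#' @param roles named character vector, same names as `groups`, each one of
#'   `"native"`, `"glycated"`, `"treated"`, `"positive_control"`.
#' @param doses_uM named numeric vector of doses (micromolar) for the treated
#'   groups.
#' @param protein_mg_per_ml protein concentration used for normalisation
#'   (absorbance markers).
#' @param dilution_factor,path_cm assay dilution and optical path.
#' @return Object of class `"assay_panel"`.
#' @export
assay_panel <- function(marker_kind, groups, roles, doses_uM = NULL,
                        protein_mg_per_ml = 1, dilution_factor = 1,
                        path_cm = 1) {
  marker_kind <- match.arg(marker_kind,
                           c("fructosamine", "carbonyl", "free_lysine",
                             "fluorescent_age"))
  if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == "")) {
    stop("groups must be a named list of replicate readings", call. = FALSE)
  }
  if (!setequal(names(roles), names(groups))) {
    stop("roles must be named for exactly the groups present", call. = FALSE)
  }
  ok_roles <- c("native", "glycated", "treated", "positive_control")
  if (!all(roles %in% ok_roles)) {
    stop("roles must be one of: ", paste(ok_roles, collapse = ", "),
         call. = FALSE)
  }
  for (req in c("native", "glycated")) {
    if (!req %in% roles) {
      stop("panel is missing the required '", req, "' role", call. = FALSE)
    }
  }
  for (g in names(groups)) {
    v <- groups[[g]]
    if (!is.numeric(v) || length(v) < 1L || anyNA(v) || any(v < 0)) {
      stop("group '", g, "' must have >= 1 non-negative readings",
           call. = FALSE)
    }
  }
  treated <- names(roles)[roles == "treated"]
  if (length(treated)) {
    if (is.null(doses_uM) || !all(treated %in% names(doses_uM))) {
      stop("doses_uM must name every treated group", call. = FALSE)
    }
    if (any(doses_uM[treated] <= 0)) {
      stop("treated doses must be > 0", call. = FALSE)
    }
  }
  stopifnot_scalar(protein_mg_per_ml, "protein_mg_per_ml")
  stopifnot_scalar(dilution_factor, "dilution_factor")
  stopifnot_scalar(path_cm, "path_cm")
  structure(
    list(marker_kind = marker_kind, groups = groups,
         roles = roles[names(groups)],
         doses_uM = doses_uM,
         protein_mg_per_ml = protein_mg_per_ml,
         dilution_factor = dilution_factor, path_cm = path_cm),
    class = "assay_panel"
  )
}

#' @export
print.assay_panel <- function(x, ...) {
  cat(sprintf("Assay panel: %s, %d groups (%s)\n", x$marker_kind,
              length(x$groups),
              paste(sprintf("%s[%s]", names(x$groups), x$roles),
                    collapse = ", ")))
  invisible(x)
}

#' Summarise an assay panel into marker results
#'
#' Aggregates replicate readings per group (mean and SD), applies the
#' marker-appropriate quantification (Beer-Lambert normalisation for
#' fructosamine and carbonyl; relative signals for free lysine and AGE
#' fluorescence), and derives the percentages that the experimental design
#' asks of each marker: percent inhibition per treated dose and for the
#' positive control (fructosamine, AGE), percent recovery (carbonyl; same
#' increment formula), or percent lysine modification per group. A one-way
#' ANOVA across groups on the raw replicate readings is attached.
#'
#' @param panel an [assay_panel()].
#' @param constants a [default_constants()] list (extinction coefficients).
#' @param baseline inhibition convention, see [percent_inhibition()].
#' @return Object of class `"marker_result"`: list with `marker_kind`,
#'   `group_stats` (data frame: group, role, dose_uM, n, mean_raw, sd_raw,
#'   mean_value, sd_value — `*_value` on the marker's reporting scale),
#'   `pct_inhibition` (data frame for treated + positive-control groups, or
#'   `pct_modification` for the lysine marker), `anova_p`, `baseline`.
#' @export
panel_summary <- function(panel, constants = default_constants(),
                          baseline = c("native", "zero")) {
  stopifnot(inherits(panel, "assay_panel"))
  baseline <- match.arg(baseline)
  quantify <- switch(
    panel$marker_kind,
    fructosamine = function(a) fructosamine_content(
      a, panel$protein_mg_per_ml, panel$dilution_factor, panel$path_cm,
      constants$eps_fructosamine_per_M_cm),
    carbonyl = function(a) carbonyl_content(
      a, panel$protein_mg_per_ml, panel$dilution_factor, panel$path_cm,
      constants$eps_carbonyl_per_M_cm),
    function(a) a  # relative markers: raw arbitrary units
  )
  gn <- names(panel$groups)
  stats_df <- data.frame(
    group = gn,
    role = unname(panel$roles[gn]),
    dose_uM = vapply(gn, function(g) {
      if (panel$roles[[g]] == "treated") panel$doses_uM[[g]] else NA_real_
    }, numeric(1)),
    n = vapply(panel$groups, length, integer(1)),
    mean_raw = vapply(panel$groups, mean, numeric(1)),
    sd_raw = vapply(panel$groups, function(v) {
      if (length(v) > 1L) stats::sd(v) else 0
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  stats_df$mean_value <- vapply(stats_df$mean_raw, quantify, numeric(1))
  stats_df$sd_value <- vapply(seq_len(nrow(stats_df)), function(i) {
    # linear quantification: SD transforms by the same factor
    if (stats_df$mean_raw[i] > 0) {
      stats_df$sd_raw[i] * stats_df$mean_value[i] / stats_df$mean_raw[i]
    } else {
      quantify(stats_df$sd_raw[i])
    }
  }, numeric(1))

  native_mean <- stats_df$mean_value[stats_df$role == "native"][1L]
  glycated_mean <- stats_df$mean_value[stats_df$role == "glycated"][1L]
  eval_groups <- stats_df[stats_df$role %in% c("treated", "positive_control"), ]

  pct_inhibition <- NULL
  pct_modification <- NULL
  if (panel$marker_kind == "free_lysine") {
    # modification relative to native signal, per group
    native_raw <- stats_df$mean_raw[stats_df$role == "native"][1L]
    pct_modification <- data.frame(
      group = stats_df$group,
      role = stats_df$role,
      dose_uM = stats_df$dose_uM,
      pct_modified = as.numeric(lysine_modification(native_raw,
                                                    stats_df$mean_raw)),
      stringsAsFactors = FALSE, row.names = NULL
    )
  } else if (nrow(eval_groups)) {
    pct <- percent_inhibition(native_mean, glycated_mean,
                              eval_groups$mean_value, baseline = baseline)
    pct_inhibition <- data.frame(
      group = eval_groups$group,
      role = eval_groups$role,
      dose_uM = eval_groups$dose_uM,
      pct_inhibition = as.numeric(pct),
      stringsAsFactors = FALSE, row.names = NULL
    )
    ord <- order(!is.na(pct_inhibition$dose_uM), pct_inhibition$dose_uM)
    pct_inhibition <- pct_inhibition[ord, , drop = FALSE]
    row.names(pct_inhibition) <- NULL
  }

  # one-way ANOVA across groups (standard routine, plumbing only); needs
  # within-group residual df, else p is NA
  long <- data.frame(
    value = unlist(panel$groups, use.names = FALSE),
    group = factor(rep(gn, times = vapply(panel$groups, length, integer(1))))
  )
  anova_p <- NA_real_
  if (nrow(long) > length(gn) && length(gn) > 1L) {
    fit <- stats::aov(value ~ group, data = long)
    anova_p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
  }

  structure(
    list(marker_kind = panel$marker_kind,
         group_stats = stats_df,
         pct_inhibition = pct_inhibition,
         pct_modification = pct_modification,
         anova_p = anova_p,
         baseline = baseline),
    class = "marker_result"
  )
}

#' @export
print.marker_result <- function(x, ...) {
  cat(sprintf("Marker result: %s (inhibition baseline: %s)\n", x$marker_kind,
              x$baseline))
  print.data.frame(x$group_stats, row.names = FALSE, digits = 4)
  if (!is.null(x$pct_inhibition)) {
    cat("Percent inhibition/recovery:\n")
    print.data.frame(x$pct_inhibition, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$pct_modification)) {
    cat("Percent lysine modification:\n")
    print.data.frame(x$pct_modification, row.names = FALSE, digits = 4)
  }
  if (is.finite(x$anova_p)) cat(sprintf("One-way ANOVA p = %.3g\n", x$anova_p))
  invisible(x)
}
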