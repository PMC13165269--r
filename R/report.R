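# round half-up at `digits` decimals (report surface only; numeric outputs
# and tests never compare rounded strings)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# internal serialisers to plain lists for JSON output
as_report_list <- function(x) {
  if (inherits(x, "quenching_fit")) {
    list(type = "quenching_fit", temperature_K = x$temperature_K,
         ksv_per_M = x$ksv_per_M, ksv_se = x$ksv_se,
         kq_per_M_s = x$kq_per_M_s, intercept = x$intercept,
         r_squared = x$r_squared, marker = x$marker, flags = x$flags)
  } else if (inherits(x, "binding_fit")) {
    list(type = "binding_fit", temperature_K = x$temperature_K,
         ka_per_M = x$ka_per_M, ka_se = x$ka_se, n_sites = x$n_sites,
         n_se = x$n_se, r_squared = x$r_squared, marker = x$marker)
  } else if (inherits(x, "thermo_params")) {
    list(type = "thermo_params",
         dH_kcal_per_mol = x$dH_cal_per_mol / 1000,
         dS_cal_per_mol_K = x$dS_cal_per_mol_K,
         dG_kcal_per_mol_by_T = as.list(x$dG_cal_per_mol_by_T / 1000),
         fit_r_squared = x$fit_r_squared)
  } else if (inherits(x, "quenching_mode")) {
    list(type = "quenching_mode", mode = x$mode,
         ksv_trend = x$evidence$ksv_trend,
         kq_exceeds_max = x$evidence$kq_exceeds_max)
  } else if (inherits(x, "force_typology")) {
    list(type = "force_typology", dominant_forces = x$dominant_forces,
         rule_basis = x$rule_basis, spontaneous = x$spontaneous)
  } else if (inherits(x, "site_marker_calls")) {
    list(type = "site_marker_calls",
         threshold = attr(x, "displacement_threshold"),
         calls = lapply(seq_len(nrow(x)), function(i) as.list(x[i, ])))
  } else if (inherits(x, "marker_result")) {
    list(type = "marker_result", marker_kind = x$marker_kind,
         baseline = x$baseline, anova_p = x$anova_p,
         group_stats = x$group_stats,
         pct_inhibition = x$pct_inhibition,
         pct_modification = x$pct_modification)
  } else if (inherits(x, "dose_response")) {
    list(type = "dose_response", fit_method = x$fit_method,
         estimable = x$estimable, ic50_uM = x$ic50_uM,
         hill_slope = x$hill_slope, doses_uM = x$doses_uM,
         pct_inhibition = x$pct_inhibition, diagnostic = x$diagnostic)
  } else if (inherits(x, "cd_record")) {
    list(type = "cd_record", label = x$label, mre_208 = x$mre_208,
         pct_helix = x$pct_helix)
  } else if (is.list(x)) {
    lapply(x, as_report_list)
  } else {
    x
  }
}

#' Write an analysis report
#'
#' Writes a machine-readable JSON summary (`<prefix>.json`) and a
#' human-readable text report (`<prefix>.txt`) whose tables mirror the
#' standard presentation of this assay family: a CD table (sample, MRE208,
#' percent helix), a quenching/binding table per temperature (T, KSV, Kq, K,
#' n), a thermodynamics table (T, dG, dH, dS) and a site-marker table
#' (condition, KSV, K). Constants on the 1e4 (KSV, K) and 1e12 (Kq) scales
#' are rounded half-up to 3 decimals in the text tables; percentages to 2.
#'
#' @param results named list of analysis outputs; recognised elements:
#'   `quenching` (list of [stern_volmer_fit()]), `binding` (list of
#'   [double_log_fit()]), `mode`, `thermo`, `forces`, `site_markers`,
#'   `panels` (list of [panel_summary()] results), `ic50` (list of
#'   [ic50_estimate()] results), `cd` (list of [cd_record()]). At least one
#'   element must be present.
#' @param path_prefix output path without extension.
#' @return invisibly, the paths written (json, txt).
#' @export
write_report <- function(results, path_prefix) {
  if (!is.list(results) || length(results) == 0L) {
    stop("results must be a non-empty list", call. = FALSE)
  }
  dir <- dirname(path_prefix)
  if (!dir.exists(dir)) {
    stop("unwritable path: directory does not exist: ", dir, call. = FALSE)
  }
  json_path <- paste0(path_prefix, ".json")
  txt_path <- paste0(path_prefix, ".txt")
  jsonlite::write_json(as_report_list(results), json_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)

  lines <- c("Binding and antiglycation analysis report",
             strrep("=", 42), "")
  if (!is.null(results$cd)) {
    lines <- c(lines, "Secondary structure (CD at 208 nm)",
               sprintf("%-32s %14s %10s", "sample", "MRE208", "% helix"))
    for (r in results$cd) {
      lines <- c(lines, sprintf("%-32s %14.3f %10.2f",
                                if (is.null(r$label)) "-" else r$label,
                                round_half_up(r$mre_208, 3),
                                round_half_up(r$pct_helix, 2)))
    }
    lines <- c(lines, "")
  }
  if (!is.null(results$quenching)) {
    lines <- c(lines, "Quenching and binding constants",
               sprintf("%6s %14s %16s %14s %8s", "T (K)", "KSV (1e4/M)",
                       "Kq (1e12/M/s)", "K (1e4/M)", "n"))
    bind_by_T <- list()
    for (b in results$binding %||% list()) {
      bind_by_T[[format(b$temperature_K)]] <- b
    }
    for (qf in results$quenching) {
      b <- bind_by_T[[format(qf$temperature_K)]]
      lines <- c(lines, sprintf(
        "%6g %14.3f %16.3f %14s %8s", qf$temperature_K,
        round_half_up(qf$ksv_per_M / 1e4, 3),
        round_half_up(qf$kq_per_M_s / 1e12, 3),
        if (is.null(b)) "-" else sprintf("%.3f", round_half_up(b$ka_per_M / 1e4, 3)),
        if (is.null(b)) "-" else sprintf("%.3f", round_half_up(b$n_sites, 3))))
    }
    if (!is.null(results$mode)) {
      lines <- c(lines, sprintf("Quenching mode: %s (KSV trend %s)",
                                results$mode$mode,
                                results$mode$evidence$ksv_trend))
    }
    lines <- c(lines, "")
  }
  if (!is.null(results$thermo)) {
    th <- results$thermo
    lines <- c(lines, "Thermodynamic parameters (van't Hoff)",
               sprintf("%6s %18s %18s %22s", "T (K)", "dG (kcal/mol)",
                       "dH (kcal/mol)", "dS (cal/mol/K)"))
    for (tn in names(th$dG_cal_per_mol_by_T)) {
      lines <- c(lines, sprintf("%6s %18.3f %18.3f %22.3f", tn,
                                round_half_up(th$dG_cal_per_mol_by_T[[tn]] / 1000, 3),
                                round_half_up(th$dH_cal_per_mol / 1000, 3),
                                round_half_up(th$dS_cal_per_mol_K, 3)))
    }
    if (!is.null(results$forces)) {
      lines <- c(lines, sprintf(
        "Dominant forces: %s (%s); spontaneous: %s",
        paste(results$forces$dominant_forces, collapse = ", "),
        results$forces$rule_basis, results$forces$spontaneous))
    }
    lines <- c(lines, "")
  }
  if (!is.null(results$site_markers)) {
    sm <- results$site_markers
    lines <- c(lines, "Site-marker displacement",
               sprintf("%-18s %12s %12s %10s %s", "marker", "KSV ratio",
                       "K ratio", "displaced", "site"))
    for (i in seq_len(nrow(sm))) {
      lines <- c(lines, sprintf("%-18s %12.3f %12.3f %10s %s",
                                sm$marker[i],
                                round_half_up(sm$ksv_ratio[i], 3),
                                round_half_up(sm$k_ratio[i], 3),
                                sm$displaced[i],
                                if (is.na(sm$assigned_site[i])) "-"
                                else sm$assigned_site[i]))
    }
    lines <- c(lines, "")
  }
  if (!is.null(results$panels)) {
    for (mr in results$panels) {
      lines <- c(lines, sprintf("Glycation marker: %s", mr$marker_kind))
      tab <- if (!is.null(mr$pct_inhibition)) mr$pct_inhibition else mr$pct_modification
      if (!is.null(tab)) {
        pct_col <- intersect(c("pct_inhibition", "pct_modified"), names(tab))[1L]
        for (i in seq_len(nrow(tab))) {
          lines <- c(lines, sprintf("  %-24s %10s uM %10.2f %%",
                                    tab$group[i],
                                    ifelse(is.na(tab$dose_uM[i]), "-",
                                           format(tab$dose_uM[i])),
                                    round_half_up(tab[[pct_col]][i], 2)))
        }
      }
      if (is.finite(mr$anova_p)) {
        lines <- c(lines, sprintf("  one-way ANOVA p = %.3g", mr$anova_p))
      }
      lines <- c(lines, "")
    }
  }
  if (!is.null(results$ic50)) {
    for (dr in results$ic50) {
      lines <- c(lines, if (dr$estimable) {
        sprintf("IC50 (%s): %.2f uM%s", dr$fit_method,
                round_half_up(dr$ic50_uM, 2),
                if (is.finite(dr$hill_slope))
                  sprintf(" (Hill slope %.2f)", round_half_up(dr$hill_slope, 2))
                else "")
      } else {
        sprintf("IC50 (%s): not estimable (%s)", dr$fit_method, dr$diagnostic)
      })
    }
    lines <- c(lines, "")
  }
  writeLines(lines, txt_path)
  invisible(c(json = json_path, txt = txt_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
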