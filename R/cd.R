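#' Mean residue ellipticity at 208 nm
#'
#' Converts an observed circular-dichroism ellipticity (millidegrees) to
#' mean residue ellipticity: MRE = theta / (Cp * n * l * 10), with the
#' protein concentration Cp in mol/L, n the residue count and l the cuvette
#' path length in cm. Units: deg cm^2 dmol^-1.
#'
#' @param theta_mdeg observed ellipticity at 208 nm in millidegrees (signed).
#' @param protein_conc_M protein concentration in mol/L, > 0.
#' @param n_residues number of protein residues, > 1 (585 for mature human
#'   serum albumin).
#' @param path_cm cuvette path length in cm, > 0.
#' @return mean residue ellipticity (deg cm^2 dmol^-1).
#' @examples
#' mre_208(-61.12, 5e-6, 585, 0.1)  # ~ -20896
#' @export
mre_208 <- function(theta_mdeg, protein_conc_M, n_residues, path_cm) {
  if (!is.numeric(theta_mdeg) || anyNA(theta_mdeg)) {
    stop("theta_mdeg must be numeric and non-missing", call. = FALSE)
  }
  stopifnot_scalar(protein_conc_M, "protein_conc_M")
  if (!is.numeric(n_residues) || length(n_residues) != 1L || n_residues <= 1) {
    stop("n_residues must be a single value > 1", call. = FALSE)
  }
  stopifnot_scalar(path_cm, "path_cm")
  theta_mdeg / (protein_conc_M * n_residues * path_cm * 10)
}

#' Percent alpha-helix from mean residue ellipticity at 208 nm
#'
#' The standard single-wavelength estimator:
#' \%helix = (-MRE208 - 4000) / (33000 - 4000) * 100, where -33000 is the
#' 208 nm mean residue ellipticity of a pure helix and -4000 that of
#' beta-sheet/random-coil structure. Results below 0 (MRE less negative than
#' -4000) are outside the formula's range and are flagged via the
#' `"below_range"` attribute but returned unclamped.
#'
#' @param mre mean residue ellipticity at 208 nm (deg cm^2 dmol^-1),
#'   vectorised.
#' @return percent alpha-helix.
#' @examples
#' pct_alpha_helix(-20897.343)  # 58.27
#' @export
pct_alpha_helix <- function(mre) {
  if (!is.numeric(mre) || anyNA(mre)) {
    stop("mre must be numeric and non-missing", call. = FALSE)
  }
  pct <- (-mre - 4000) / (33000 - 4000) * 100
  below <- pct < 0
  if (any(below)) attr(pct, "below_range") <- which(below)
  pct
}

#' Circular-dichroism record
#'
#' Bundles a 208 nm ellipticity reading with the parameters needed for mean
#' residue ellipticity, and computes MRE208 and percent alpha-helix.
#'
#' @inheritParams mre_208
#' @param label sample identifier.
#' @return Object of class `"cd_record"`: list with the inputs plus
#'   `mre_208` and `pct_helix`.
#' @examples
#' cd_record(-61.12, 5e-6, 585, 0.1, label = "native")
#' @export
cd_record <- function(theta_mdeg, protein_conc_M, n_residues, path_cm,
                      label = NULL) {
  mre <- mre_208(theta_mdeg, protein_conc_M, n_residues, path_cm)
  structure(
    list(theta_mdeg_208 = theta_mdeg,
         protein_conc_M = protein_conc_M,
         n_residues = n_residues,
         path_cm = path_cm,
         mre_208 = mre,
         pct_helix = as.numeric(pct_alpha_helix(mre)),
         label = label),
    class = "cd_record"
  )
}

#' @export
print.cd_record <- function(x, ...) {
  cat(sprintf("CD record%s: MRE208 = %.3f deg cm^2 dmol^-1; %% helix = %.2f\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              x$mre_208, x$pct_helix))
  invisible(x)
}

#' Read circular-dichroism records from CSV
#'
#' Expects columns `label`, `theta_mdeg_208`, `protein_conc_M`,
#' `n_residues`, `path_cm`; one row per sample.
#'
#' @param path CSV file path.
#' @return list of [cd_record()] objects, named by label.
#' @export
read_cd_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "theta_mdeg_208", "protein_conc_M", "n_residues",
            "path_cm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  recs <- lapply(seq_len(nrow(df)), function(i) {
    cd_record(df$theta_mdeg_208[i], df$protein_conc_M[i], df$n_residues[i],
              df$path_cm[i], label = df$label[i])
  })
  names(recs) <- df$label
  recs
}
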