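---
title: "Methods: fluorescence-quenching binding analysis and antiglycation assay quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fluorescence-quenching binding analysis and antiglycation assay quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycoquench)
```

## Scope

glycoquench covers the downstream quantitative analysis of two linked
experimental programmes on serum albumin: (i) steady-state fluorescence
quenching titrations that characterise how a small molecule binds the
protein, and (ii) colorimetric/fluorometric assay panels that quantify
non-enzymatic glycation and its inhibition by that molecule. Everything the
package fits or derives is arithmetic on instrument readings; the package
does not model the photophysics or the glycation kinetics themselves.

## Binding model and assumptions

A titration records the tryptophan emission peak intensity F of a fixed
protein concentration as the quencher (drug) concentration [Q] rises,
together with the unquenched intensity F0. Two standard linearisations are
fitted, each by ordinary least squares on the transformed variables, exactly
as the corresponding plots are drawn:

* **Stern–Volmer**: F0/F = 1 + KSV·[Q]. The slope is the Stern–Volmer
  constant KSV (M^-1). The intercept is left free rather than fixed at 1; an
  intercept deviating from unity by more than 10 % is flagged on the result,
  since it indicates curvature (mixed quenching, inner-filter effects) that
  the linear model cannot absorb. The bimolecular quenching rate constant
  Kq = KSV / tau0 uses the unquenched fluorophore lifetime
  tau0 = 5.78e-9 s (configurable through `default_constants()`).
* **Double-logarithmic**: log10((F0−F)/F) = log10 Ka + n·log10 [Q], giving
  the association constant Ka (M^-1) as 10^intercept and the apparent
  binding-site number n as the slope. Points with F >= F0 have no defined
  left-hand side and are dropped with a warning.

Both forms assume the free-ligand approximation ([Q] total ≈ [Q] free) and a
single class of independent sites. Weighted or errors-in-variables fits are
deliberately not attempted: the field reports these constants from OLS on
the linearised plots, and keeping the estimator identical keeps the numbers
comparable.

**Quenching-mode call.** Static (ground-state complex) and dynamic
(collisional) quenching are distinguished by two rules applied jointly:
Kq above the diffusion-limited ceiling for biopolymer quenching
(2e10 M^-1 s^-1 by default) at every temperature, and KSV strictly
decreasing with temperature, together call *static*; Kq at or below the
ceiling everywhere with KSV strictly increasing calls *dynamic*; every other
pattern — including ties in the KSV sequence — is reported *ambiguous* with
the per-rule evidence attached. With a single temperature the trend rule is
unavailable and the magnitude rule decides alone.

**Thermodynamics.** With Ka measured at two or more temperatures, the van't
Hoff regression ln Ka = −ΔH°/(R·T) + ΔS°/R (R = 1.987 cal mol^-1 K^-1)
yields the enthalpy and entropy of association, and ΔG°(T) = ΔH° − T·ΔS° is
evaluated at each input temperature. All energies are carried internally in
cal mol^-1; the reporting layer prints ΔH° and ΔG° in kcal mol^-1 and ΔS°
in cal mol^-1 K^-1. The entropy unit deserves a note: reports in this assay
family sometimes label ΔS° in kcal mol^-1 K^-1 while printing values that
are only dimensionally consistent with cal mol^-1 K^-1 (as a check, ΔG° =
ΔH° − T·ΔS° reproduces the published free energies only under the cal
reading); this package uses cal mol^-1 K^-1 explicitly everywhere.

**Force typology.** The dominant non-covalent forces are read from the signs
of (ΔH°, ΔS°): both positive → hydrophobic interaction (the canonical
rule); both negative → van der Waals plus hydrogen bonding; ΔH° near zero
(|ΔH°| < 500 cal mol^-1 by default) with ΔS° > 0 → electrostatic. A positive
ΔH° is also sometimes interpreted as evidence that hydrogen bonds contribute
alongside the hydrophobic term; because the two readings genuinely coexist
in the literature, the package keeps the canonical call as the default and
exposes `report_h_bond_with_positive_dH = TRUE` to surface the second
reading explicitly, rather than silently choosing either.

**Site-marker displacement.** Binding-site assignment compares the
constants fitted with and without a saturating site-specific probe. A
marker call requires a *joint* drop of both KSV and Ka below 1 − threshold,
with threshold 0.20 by default. The default separates the two outcomes this
assay is designed to distinguish: a genuine competitive displacement
typically suppresses the binding constant by ~40 % or more, while a
non-competing probe perturbs it by ~10 % in either direction; 20 % sits
between the two regimes and is configurable. A displaced warfarin-like
probe maps to Sudlow site I (sub-domain IIA), an ibuprofen-like probe to
Sudlow site II (sub-domain IIIA).

## Glycation marker quantification

* **Fructosamine** (NBT reduction, A530) and **protein carbonyls** (DNPH,
  A360) convert absorbance to mol L^-1 via Beer–Lambert with molar
  extinction coefficients 12 640 and 22 000 M^-1 cm^-1 respectively, then
  normalise to nmol per mg protein using the measured protein concentration,
  dilution factor and path length. The fructosamine coefficient is sometimes
  printed without the per-molar unit; it is treated as M^-1 cm^-1 with the
  path length explicit.
* **Free lysine** (TNBSA, A335) is reported as percent modification relative
  to the native sample's signal, (1 − A_sample/A_native) × 100 — a relative
  quantity by design, with no extinction-coefficient conversion.
* **Fluorescent AGEs** use the 440 nm emission (370 nm excitation) as an
  arbitrary-unit signal.
* **Percent inhibition** for treated and positive-control groups is
  (G − T)/(G − N) × 100, the inhibition of the glycation *increment* over the
  native baseline. This convention makes "treated equals glycated" 0 % and
  "fully restored to native" 100 %. The alternative (G − T)/G × 100, which
  ignores the native baseline, is available via `baseline = "zero"`, and
  every result records which convention produced it. Carbonyl "percent
  recovery" is the same increment formula applied to carbonyl values.
  Values outside [0, 100] (over-recovery, aggravation) are flagged but not
  clamped, because they are diagnostically meaningful.
* **IC50** defaults to the two-parameter Hill fit y = 100/(1 + (IC50/x)^h)
  with bottom and top fixed at 0 and 100: four-dose designs leave too few
  degrees of freedom for a four-parameter logistic. A log-linear
  interpolation between the doses bracketing 50 % is available as a second
  method; when no observation pair brackets 50 % and extrapolation is not
  explicitly enabled, the result is a flagged "not estimable" object rather
  than an error or a silently extrapolated number.
* **CD helix content** uses MRE208 = theta/(10·Cp·n·l) and
  %helix = (−MRE208 − 4000)/(33 000 − 4000) × 100, the single-wavelength
  estimator anchored at −33 000 deg cm^2 dmol^-1 for pure helix and −4000
  for the helix-free baseline. Results below the formula's range are flagged.
  Serum-albumin fixtures use n = 585 residues (mature human serum albumin);
  the residue count is always an explicit argument, never assumed.

One-way ANOVA across panel groups is delegated to `stats::aov` and attached
to panel summaries as plumbing; the package adds no statistical theory
there.

## The synthetic-data generator

Because raw spectra and absorbances for studies of this kind are typically
unpublished, the package ships seeded generators that emulate the
experimental designs end to end:

* titrations from either F = F0/(1 + KSV[Q]) (static-quenching form) or
  (F0 − F)/F = Ka[Q]^n (binding-isotherm form) — the two linearisations are
  different idealisations of the same experiment, and a single generated
  curve cannot satisfy both exactly, so each analysis stage is driven by its
  own ground truth;
* van't Hoff-consistent Ka(T) series evaluated exactly from (ΔH°, ΔS°);
* replicate assay panels drawn from Normal(mean, SD) truncated at zero by
  redraw (clamping would bias small-SD means);
* Hill dose-response tables; and Gaussian emission bands on the 290–500 nm
  grid for peak-extraction round trips.

Measurement noise is multiplicative Gaussian with a configurable
coefficient of variation (default 0.02, typical spectrofluorometer
repeatability), because fluorescence and absorbance errors scale with
signal. Draws that would violate the physical bounds 0 < F ≤ F0 are redrawn.
All generators take an explicit seed and restore the caller's RNG state.

**Default titration design.** The default quencher grid is ten points,
100–1000 µM. The choice follows from the information content of the
isotherm: for Ka ≈ 1e4 M^-1 the binding transition sits at [Q] ≈ 1/Ka =
100 µM, and the double-log intercept — an extrapolation to [Q] = 1 M — is
well conditioned only when the titration actually spans that transition.
Grids confined to weak quenching (a few µM, where F0 − F is comparable to
the noise) leave Ka essentially unidentified at realistic noise levels.
With the default grid and 2 % noise, the replicate harness in the test
suite recovers KSV and Ka with median relative errors of a few percent and
n within ~1 %.

**What the generator does not emulate.** Real titrations carry inner-filter
attenuation, ligand depletion at high affinity, instrument drift and
correlated replicate structure; panels carry between-day batch effects. None
of these are modelled. Passing tests therefore demonstrate the correctness
of the estimators on data obeying the stated models, not robustness to
systematic instrument artefacts. An optional per-point dilution-correction
hook exists on the titration reader but defaults to off, and no
inner-filter correction is applied by default, matching the common
reporting practice for this assay family.

## Numerical choices

* All fits are OLS via `stats::lm` on the linearised variables; the Hill
  fit uses `stats::nls` (port algorithm, bounded below) started from the
  log-linear crossing estimate. Non-convergence yields a flagged
  not-estimable result.
* Quencher concentrations are molar internally (µM only at the I/O
  surface); energies are cal mol^-1 internally.
* The identities Kq·tau0 = KSV and ΔG = ΔH − T·ΔS hold to machine precision
  on every fit object, and the tests assert them at 1e-15 relative.
* Titration CSV round trips preserve all numeric fields exactly (17
  significant digits on write).
* Text reports round half-up — 3 decimals for constants on their
  customary 1e4/1e12 scales, 2 for percentages; JSON output is unrounded.
* Degenerate inputs (constant intensities, saturated two-point van't Hoff
  designs, identical replicates) return defined results with flags rather
  than NaN: KSV = 0 with a no-quenching flag, R² treated as exact for a
  saturated fit, SD 0 for identical replicates, ANOVA p = NA when there is
  no residual degree of freedom.

## End-to-end pipeline

`run_pipeline()` chains the stages (simulate → quench → binding → mode →
van't Hoff → forces → site markers → panels → IC50 → CD → report) from one
configuration list or YAML file, with one seed driving all randomness.
`demo_config()` encodes a complete reference regime: KSV falling
1.525 → 1.038 × 10^4 M^-1 over 298–310 K, Ka(T) generated from
ΔH° = +5396 cal mol^-1 and ΔS° = +36.099 cal mol^-1 K^-1 with n ≈ 0.98,
marker factors that displace the warfarin-like but not the ibuprofen-like
probe, four-group panels for all four markers (native/glycated baselines
such as 15.42/89.89 nmol mg^-1 fructosamine with dose-wise inhibition rising
to >70 %), a 130.34 µM IC50 Hill curve, and the three CD ellipticities
spanning 58 → 31 → 49 % helix. On a noiseless run the report reproduces
every configured ground truth; the test suite asserts this, and asserts the
qualitative outcomes (static mode, displacement pattern, dose-monotone
inhibition) under 2 % noise. Positive-control values not individually
published (carbonyl recovery of the reference inhibitor) are set to
plausible mid-70 % defaults and marked as such here.

Problem sizes throughout the suite — 10-point titrations, 100-seed recovery
harnesses, 50-case mode-classification sweeps, quadruplicate panels — were
chosen as the smallest designs at which the statistical assertions are
stable, and run in seconds.

## Known limitations

* Stern–Volmer and double-log estimates come from the same titration in
  practice but are fitted independently; no global multi-temperature or
  joint KSV/Ka fit is attempted.
* The van't Hoff slope over a narrow temperature span (here 12 K) is
  intrinsically sensitive: percent-level errors in Ka propagate to tens of
  percent in ΔH°. The package reports fit standard errors but cannot make a
  narrow-span design well conditioned.
* The helix estimator is single-wavelength; no CD deconvolution into sheet,
  turn and coil fractions is provided.
* IC50 values from four-dose designs with fixed asymptotes inherit the
  design's limitations; the not-estimable diagnostics are deliberately
  conservative.
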