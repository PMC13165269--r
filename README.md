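# glycoquench

Quantitative analysis of small-molecule binding to serum albumin by
steady-state fluorescence quenching, together with quantification of protein
glycation markers and their inhibition. The package is aimed at groups running
drug–protein interaction and antiglycation assay panels — fluorescence
titrations, NBT/DNPH/TNBSA colorimetric assays, AGE fluorescence and far-UV
circular dichroism — who want the downstream arithmetic to be scripted,
validated and reproducible rather than spreadsheet-bound.

## What it computes

**Binding spectroscopy.** For a titration of protein fluorescence F against
quencher concentration [Q] at temperature T:

- Stern–Volmer analysis: F₀/F = 1 + K_SV[Q], fitted by OLS on the linearised
  variables; the bimolecular quenching rate constant K_q = K_SV/τ₀
  (τ₀ = 5.78 × 10⁻⁹ s) is attached, and the quenching mode is classified as
  static or dynamic from the joint rule: K_q relative to the diffusion-limited
  biopolymer ceiling (~2 × 10¹⁰ M⁻¹s⁻¹) and the temperature trend of K_SV.
- Double-logarithmic (modified Stern–Volmer) analysis:
  log₁₀((F₀−F)/F) = log₁₀K_a + n·log₁₀[Q], giving the association constant K_a
  and binding-site number n.
- Van't Hoff thermodynamics: ln K_a = −ΔH°/(RT) + ΔS°/R across temperatures,
  then ΔG°(T) = ΔH° − TΔS°, with sign-pattern classification of the dominant
  non-covalent forces and a spontaneity call.
- Competitive site-marker displacement: ratios of K_SV and K_a with and
  without a saturating site probe (warfarin-like → Sudlow site I,
  ibuprofen-like → Sudlow site II); a joint drop beyond a 20 % threshold calls
  displacement.

**Glycation assays.** Beer–Lambert quantification of fructosamine
(ε = 12 640 M⁻¹cm⁻¹ at 530 nm) and protein carbonyls (ε = 22 000 M⁻¹cm⁻¹ at
360 nm) in nmol per mg protein; relative free-lysine modification (TNBSA,
335 nm); fluorescent AGE inhibition (370/440 nm); percent inhibition as
(G−T)/(G−N) × 100 over the glycation increment; IC₅₀ by a fixed-asymptote
Hill fit y = 100/(1 + (IC₅₀/x)^h) or by log-linear interpolation; and
α-helix content from CD via MRE₂₀₈ = θ/(10·C_p·n·l) and
%helix = (−MRE₂₀₈ − 4000)/29 000 × 100.

**Synthetic data.** Seeded generators produce every input the analyses
consume — static-quenching titrations, van't Hoff-consistent K_a(T) series,
replicate assay panels, Hill dose-response tables and Gaussian emission
bands — so the full pipeline is testable without instrument data.

## Worked example

```r
library(glycoquench)

# a bundled synthetic titration (2 % measurement noise, 298 K)
path <- system.file("extdata", "synthetic_titration_298K.csv",
                    package = "glycoquench")
ts  <- read_titration_csv(path)
stern_volmer_fit(ts)
#> Stern-Volmer fit at 298 K (10 points)
#>   KSV = 1.563e+04 +/- 2.6e+02 M^-1;  Kq = 2.704e+12 M^-1 s^-1;  R2 = 0.9978

# thermodynamics from association constants measured at three temperatures
th <- vant_hoff_fit(c(298, 303, 310), c(0.863e4, 0.980e4, 1.225e4))
th
#> Van't Hoff thermodynamic parameters
#>   dH = 5.391 kcal mol^-1;  dS = 36.083 cal mol^-1 K^-1;  R2 = 0.9948
#>   dG(298 K) = -5.361 kcal mol^-1
#>   dG(303 K) = -5.542 kcal mol^-1
#>   dG(310 K) = -5.794 kcal mol^-1
classify_forces(th)
#> Binding-force typology: hydrophobic (dH > 0, dS > 0)
#>   spontaneous (dG < 0 at all T): TRUE

# CD-based secondary structure
cd_record(-61.1247, 5e-6, 585, 0.1, label = "native")
#> CD record [native]: MRE208 = -20897.333 deg cm^2 dmol^-1; % helix = 58.27
```

The positive ΔH° with large positive ΔS° marks an entropy-driven,
spontaneous association dominated by hydrophobic contacts (a reading that
also admits a hydrogen-bonding contribution; see the vignette). K_q three
orders of magnitude above the biopolymer ceiling indicates static quenching,
i.e. ground-state complex formation.

A full simulate-and-analyse run over every stage (quenching, binding,
thermodynamics, site markers, four glycation panels, IC₅₀, CD) is one call:

```r
res <- run_pipeline(demo_config(seed = 1), out_prefix = "report/run1")
```

which writes `report/run1.json` and a four-table text report. A thin CLI
wrapper lives at `inst/scripts/run_pipeline.R`.

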