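# brachyaudit

Tools for **postal dosimetry audits of HDR brachytherapy sources**.

Remote (mailed-phantom) audits are how national and international dosimetry
services check that the Reference Air Kerma Rate (RAKR) a clinic uses for its
HDR ¹⁹²Ir or ⁶⁰Co afterloader source is accurate. A compact PMMA phantom with
two straight catheters is shipped to the clinic together with
radiophotoluminescent glass dosimeters (RPLDs) and a radiochromic film strip;
the clinic delivers a standardized 2 Gy plan, and the returned dosimeters and
films are analyzed centrally. This package implements that analysis chain end
to end, plus seeded synthetic generators for every input, so the whole
methodology can be exercised, tested and taught without physical data.

## What it computes

* **TG-43 dose engine** — the AAPM TG-43 formalism
  Ḋ(r,θ) = S_K · Λ · [G(r,θ)/G(r₀,θ₀)] · g(r) · F(r,θ)
  for point and line sources (G_P = 1/r², G_L = β/(L·r·sinθ)), with linear /
  bilinear table interpolation and superposition over dwell positions.
* **Reference plan** — the standardized two-catheter plan (13 dwells per
  catheter, 5 mm step, catheters 40 mm apart) with a uniform dwell time
  solved so the control point at the RPLD centre receives exactly 2 Gy, and
  dose metrics (D_min, D_max, D_mean) over the RPLD sensitive volume.
* **Correction factors** — k_s (lack of full scatter), k_m (non-water
  equivalence of the PMMA phantom) and k_Q (beam-quality transfer from the
  ⁶⁰Co calibration) as ratios of measurement-set means with SEM-propagated
  uncertainties, and the total audit factor
  k_tot = ½(k_m^exp + k_m^MC) · ½(k_s^exp + k_s^MC) · k_Q.
* **RPLD dosimetry** — the dose determination
  D = M · N · k_Q · k_s · k_m with the multiplicative signal-correction
  chain (background, sensitivity, fading, tray position) and duplicate
  averaging.
* **Uncertainty** — GUM-style quadrature combination of a relative
  standard-uncertainty budget, with coverage-factor expansion.
* **Film source-position verification** — track detection on scanned film
  strips (50 %-of-plateau edges with sub-pixel interpolation), shift against
  the fiducial, two-film combination with the 0.3 mm procedure floor, and
  ±3 mm / ±5 mm classification.
* **Audit pipeline** — per-set dose ratios D_IAEA/D_user and multicentre
  cohort summaries with ±3 % / ±5 % classification.

## Worked example

```r
library(brachyaudit)

# Reference plan for a generic Ir-192 line source at a clinical RAKR
src  <- brachy_source("ir192")
plan <- build_reference_plan(src, rakr = 40916)
plan
#> <ref_plan> 26 dwells (2 catheters), source ir192-generic-synthetic, RAKR 40916 U
#>   uniform dwell time: 3.92 s; prescription 2.000 Gy at the control point

glance(plan)[, c("d_min_Gy", "d_max_Gy", "d_mean_Gy")]
#>   d_min_Gy d_max_Gy d_mean_Gy
#> 1     1.99     2.00      2.00
```

The dwell-time solve puts the RPLD in a flat 2 Gy region: across its whole
sensitive volume the dose stays between 1.99 and 2.00 Gy, so the measured
dose reflects the source strength rather than small positioning errors.

```r
# Total correction factor for the Ir-192 audit setup
combine_total(
  correction_factor(0.993, 0.005, "k_m"),
  correction_factor(0.993, 0.009, "k_m", "mc"),
  correction_factor(1.054, 0.004, "k_s"),
  correction_factor(1.059, 0.008, "k_s", "mc"),
  correction_factor(0.981, 0.005, "k_Q"))
#> <correction_factor> k_tot = 1.0292 +/- 0.0087 (combined)

combine_budget(default_budget())
#> [1] 2.238169   # i.e. 2.24 % relative standard uncertainty (k = 1)
```

The measured dose must be corrected upward by ~2.9 % for the audit setup's
missing scatter, phantom material and beam quality; the full measurement
chain carries a 2.24 % standard uncertainty.

```r
# A synthetic 59-set pilot cohort through the audit pipeline
rec <- simulate_cohort(seed = 42)
glance(summarize_cohort(rec))[, c("ratio_mean", "ratio_sd", "n_within_3pct", "n_within_5pct")]
#>   ratio_mean ratio_sd n_within_3pct n_within_5pct
#> 1       1.01   0.0162            54            59
plot_cohort_ratios(rec)   # scatter with +/-3 % and +/-5 % action lines
```

A command-line front end over the same functions is in
`inst/cli/brachyaudit.R` (subcommands `dose`, `plan`, `factors`, `budget`,
`analyze-film`, `cohort-report`, `simulate`).

## Notes on bundled data

The bundled Ir-192 and Co-60 TG-43 tables are *synthetic consensus-style*
datasets (smooth, physically plausible g(r) and F(r,θ); see each file's
`provenance` field). They are intended for testing, simulation and teaching,
not for clinical dose calculation of any commercial source model.
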