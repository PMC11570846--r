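---
title: "Methods: postal HDR brachytherapy dosimetry audits with brachyaudit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: postal HDR brachytherapy dosimetry audits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brachyaudit)
```

# The audit problem

A postal brachytherapy audit checks one number above all: the Reference Air
Kerma Rate (RAKR) the clinic believes its HDR source has. The audited centre
irradiates a mailed phantom with a standardized plan that should deliver
2 Gy to a glass dosimeter (RPLD); the audit provider reads the dosimeter,
corrects it onto absorbed-dose-to-water in full scatter, and compares
against the user-stated dose. Because the plan places the dosimeter in a
deliberately flat dose region, any deviation in the measured/stated ratio
traces back principally to the RAKR, not to millimetre-level source
positioning. A radiochromic film above one catheter independently verifies
that the source actually travelled where the plan assumed.

`brachyaudit` implements each stage of that chain as a small set of
composable functions over data frames; this vignette records the models,
the default parameters, and the design decisions behind them.

# Dose model

The engine implements the AAPM TG-43 point- and line-source formalism,

$$\dot D(r, \theta) = S_K\,\Lambda\,
  \frac{G(r,\theta)}{G(r_0,\theta_0)}\, g(r)\, F(r,\theta),$$

with reference point $r_0 = 1$ cm, $\theta_0 = 90^\circ$, and the
line-source geometry function $G_L = \beta/(L\,r\sin\theta)$, where
$\beta$ is computed stably as a difference of `atan2` terms; on the long
axis the analytic limit $1/(r^2 - L^2/4)$ is used, and the tests check
continuity between the two branches. RAKR in U (µGy·m²·h⁻¹) is treated as
numerically equal to the air-kerma strength $S_K$ — the standard HDR
convention. Plan dose is plain superposition of dose rate × dwell time over
dwell positions, with the source long axis assumed parallel to the
catheter.

Assumptions inherited from TG-43: water-equivalent, full-scatter,
cylindrically symmetric conditions. The audit setup violates these on
purpose (compact PMMA phantom on a table); those deviations are *not*
modelled in the engine — they enter only through the measured correction
factors below. Monte-Carlo transport, heterogeneity corrections and
model-based algorithms are out of scope.

**Interpolation.** $g(r)$ is interpolated linearly in $r$, $F(r,\theta)$
bilinearly in $(r,\theta)$; clinical tables are dense enough that
higher-order schemes change nothing material. Outside the tabulated range
the nearest value is used with a warning (never extrapolated), with a hard
error beyond a 1.2× guard band. All plan geometry lives at $r \approx$
2–3.6 cm, well inside standard tables.

**Bundled datasets.** Three datasets ship with the package: an analytic
toy point source ($\Lambda = 1$, $g \equiv F \equiv 1$) used by the
oracle tests, and generic ¹⁹²Ir / ⁶⁰Co line sources. The Ir/Co tables are
*synthetic consensus-style* curves — smooth, realistically shaped, with the
required normalizations $g(1\,\mathrm{cm}) = 1$ and $F(r, 90^\circ) = 1$ —
because no real characterization tables are bundled; their files and
`provenance` fields say so explicitly. For the audit geometry the choice is
benign: the plan is renormalized at the control point, so only the *shape*
of $g$ and $F$ over a few centimetres matters to the flatness metrics.

# Reference plan

The coordinate frame puts the origin at the centre of the RPLD sensitive
volume (= the control point), catheters along $x$ at $y = \pm 20$ mm. Each
catheter holds 13 dwells at a 5 mm step, spanning $x = -30 \dots +30$ mm,
symmetric about the dosimeter — the plan's dwell span is centred on the
control point, consistent with the standardized plan's symmetric dose
distribution. The one free parameter, the uniform dwell time, is solved in
closed form:

$$t = \frac{D_\mathrm{presc}}{\sum_i \dot D_i(\mathbf{0})},$$

so the recomputed control-point dose equals the 2 Gy prescription to
numerical precision (tested at $10^{-9}$ relative).

Dose metrics over the RPLD are computed on a regular Cartesian grid
(default 0.1 mm, capped at 0.25 mm) clipped to the sensitive cylinder.
The sensitive volume is modelled as a 6 mm long, 1.5 mm diameter cylinder:
the rod is physically 12 mm long but its sensitive core is shorter; 6 mm is
an assumption exposed as `phantom_geometry(sensitive_length_mm = )`. With
any bundled source the resulting field is flat to better than 1 %
(D_min 1.99, D_max 2.00, D_mean 2.00 Gy at 0.01 Gy precision), and grid
refinement from 0.2 to 0.1 mm moves the mean by under 0.001 Gy.

# Correction factors and their uncertainties

Three experiments bracket the deviation from TG-43 conditions, each a
ratio of mean doses between two 20-dosimeter groups:

* $k_s = \bar D_{r,p} / \bar D_a$ — lack of full scatter (phantom in water
  vs on a table);
* $k_m = \bar D_{r,w} / \bar D_{r,p}$ — non-water equivalence of PMMA
  (near-water-equivalent phantom vs PMMA, both in water);
* $k_Q = \bar D_\mathrm{ref} / \bar D_{r,w}$ — beam-quality transfer from
  the ⁶⁰Co calibration beam.

Because the dosimeters are unpaired, the estimator is the **ratio of set
means** (not a mean of ratios), with standard uncertainty from the two
standard errors of the mean combined in relative quadrature. A $10^5$
-replicate bootstrap serves as an independent oracle in the tests and
agrees with the analytic form within 10 %.

The total factor averages the experimental and Monte-Carlo determinations
where both exist:

$$k_\mathrm{tot} = \frac{k_m^{exp}+k_m^{MC}}{2}\cdot
  \frac{k_s^{exp}+k_s^{MC}}{2}\cdot k_Q .$$

Each pair mean carries $u = \tfrac12\sqrt{u_1^2+u_2^2}$ (components taken
as uncorrelated — no correlation structure is published for such pairs),
and the two pair means and $k_Q$ combine in relative quadrature. With the
published component values this reproduces 1.029 ± 0.009 for ¹⁹²Ir; for
⁶⁰Co the rounded component inputs give 1.058 against a published 1.059
computed from unrounded components — a 0.1 % rounding artefact the
acceptance checks absorb explicitly. Whether published set uncertainties
are purely SEM-based is not stated anywhere we can check, so
`correction_factor()` accepts an override `u`.

The dose determination itself is the multiplicative chain
$D = M\,N\,k_Q\,k_s\,k_m$ with
$M = (\mathrm{raw} - \mathrm{background}) \times s \times f \times p$.
Background is subtracted from the raw signal *before* the multiplicative
factors; since the chain is a pure product after subtraction, the order of
the three factors is immaterial (tested), and only the subtraction point is
a real convention. Fading is a caller-supplied factor: audits are read
within a window where fading is negligible, and no fading model belongs in
this package.

# Uncertainty budget

The budget is a flat table of relative standard uncertainties (percent,
k = 1) combined in uncorrelated quadrature — standard GUM practice when no
covariances are stated. The bundled default has the ten components of an
RPLD audit system (calibration coefficient Type A and B, reading,
sensitivity, readout positioning, non-linearity, fading, RAKR, dose
calculation over the RPLD volume, and the total correction factor) and
combines to 2.24 %. One budget is shared by both radionuclides, carrying
the larger component where they differ. Sensitivity-coefficient
(derivative-based) propagation is deliberately out of scope: the inputs
are already expressed as relative uncertainties on multiplicative terms.

# Film analysis

Films are scanned in reflection (darker = more dose) at nominally 300 dpi.
The analyzer:

1. builds a per-column darkening profile (mean over rows);
2. takes a robust background (85th percentile of the profile) and plateau
   (10th percentile) — robust quantiles rather than min/max so isolated
   noisy pixels cannot define either level;
3. requires plateau-to-background contrast above `contrast_min` (default
   0.05 in [0,1] pixel units), else errors with "no track detected";
4. places each edge where the net darkening crosses 50 % of the plateau,
   with linear sub-pixel interpolation between the bracketing columns;
5. converts via mm = px · 25.4/dpi and reports the track midpoint.

The measured shift is midpoint − fiducial, signed positive towards the
proximal end (the afterloader) — the direction in which systematic
catheter-length errors push the track. Two films per set are averaged;
their uncertainty is $\sqrt{0.3^2 + s^2}$ mm where $s$ is the sample SD of
the two shifts and 0.3 mm is the fixed uncertainty of the analysis
procedure, adopted as a Type-B floor rather than re-derived (the in-house
macro it comes from is not reproducible from public information). The
±3 mm / ±5 mm classification treats boundaries inclusively, with a 10⁻⁹ mm
tolerance so representation error cannot flip a boundary case.

# Synthetic data: what it does and does not emulate

Every generator is a pure function of (parameters, seed), leaves the
caller's RNG untouched, and produces objects that satisfy the same
invariants the analysis functions validate.

* `simulate_measurement_set()` — lognormal readings by default (doses are
  positive by construction), mean-preserving at the stated CV; a truncated
  normal is available. Default audit-style sets are n = 20 at ~1 % CV.
* `simulate_film()` — the physical 32 × 140 mm strip at the requested dpi;
  a 60 mm track (the 13-dwell plan span) with logistic edges
  (0.3 mm scale), 8 mm width, 0.4 contrast on a 0.85 background, additive
  Gaussian pixel noise. It emulates geometry and noise, *not* film
  physics: no dose-response curve, no scanner colour response, no spatial
  nonuniformity, no dust or fiducial artefacts. Passing recovery tests
  therefore demonstrates the analyzer's geometric correctness, not
  robustness to every real-world scan defect.
* `simulate_cohort()` — per-set dose ratios and shifts drawn from normal
  distributions, split into the observable duplicate pairs (half-normal
  intra-set difference calibrated so its mean equals the stated percent;
  per-film scatter 0.3 mm SD). The defaults — 59 sets, ratio
  1.008 ± 0.014, shift 1.2 ± 2.5 mm, intra-set difference 1.6 %, 14/59
  ⁶⁰Co — are the operating point of an international pilot cohort and are
  treated as fixed study conditions, not tuning knobs. The generator does
  not model per-centre systematic clusters or outlier mechanisms
  (mis-reconstructed catheter tips, inexperienced users), only the
  marginal distributions.

Test problem sizes are chosen to keep the full suite under half a minute
on one core while leaving Monte-Carlo margins comfortable: 200 seeded film
trials across injected shifts of −5…+5 mm, 500 synthetic cohorts for the
classification-coverage check, 1000 repetitions for factor recovery, 10⁵
bootstrap replicates.

# Numerical choices and degenerate inputs

* Dwell/point coincidence is a hard error (the dose is singular there), as
  are r = 0, empty tables, non-finite dwell times, raw < background
  signals, and non-positive doses.
* On-axis line-source geometry switches to the analytic limit when
  $\sin\theta < 10^{-9}$.
* A single-set cohort reports SD = 0 with an `insufficient_n` flag rather
  than NA or an error, so bulk pipelines keep flowing.
* The degenerate one-point sensitive volume reproduces the prescription
  exactly, which pins the control-point normalization in tests.

# Known limitations

* TG-43 only; the engine is a planning/verification tool, not a
  transport code. Scatter and material effects are empirical inputs.
* The bundled source tables are synthetic stand-ins; swap in real
  consensus datasets via `read_source_dataset()` for any clinical use.
* Film analysis assumes one straight track parallel to the image axis;
  curved catheters or rotated scans need prior rectification.
* Cohort statistics are descriptive; no hierarchical modelling of centre
  effects is attempted.
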