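---
title: "Golgi resting pH: model, quantification and fingerprint methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Golgi resting pH: model, quantification and fingerprint methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(golgiph)
```

This vignette is the package's account of its science: the models and
statistics it implements, the assumptions they rest on, the parameters
that matter, what the synthetic-data generators do and do not emulate,
and the design choices made where the design was genuinely open. It
states no empirical result that the test suite or the acceptance script
does not itself compute.

## 1. The biological problem

The Golgi lumen is normally held ~1 pH unit more acidic than the
cytosol (pH ~6.0–6.7) by a balance of three fluxes: the V-ATPase pumps
protons in, a Cl⁻ channel supplies counter-ions so that no membrane
potential builds up, and a "proton leak" carries acid back out. The leak
sets the resting point, and the pathway modelled here identifies it
with the Golgi-resident AE2a Cl⁻/HCO₃⁻ exchanger: bicarbonate imported
in exchange for luminal chloride reacts with luminal protons
(H⁺ + HCO₃⁻ ⇌ H₂CO₃ ⇌ CO₂ + H₂O, pKa 6.4), and the CO₂ and water leave
by diffusion/aquaporins — so acid exits the lumen as gas and water
rather than as free H⁺. Raising AE2 density (overexpression, or the
constitutively high levels of some colorectal cancer lines) alkalinizes
the Golgi, which in turn perturbs glycosylation; lectin microarrays
read that perturbation out as a binding fingerprint.

## 2. Electrochemical feasibility

`nernst_slope()` is `2.303·R·T/F` in mV (61.5 at 310.15 K; CODATA
constants). Two potential conventions are deliberately exposed:

* `gradient_potential(lumen, cytosol)` — the **valence-free** form
  `slope · log10(c_lumen/c_cytosol)`. This operational convention
  reproduces the signs of the worked example as published: +61.5 mV for
  the proton gradient, −7 mV for K⁺ (107/140 mM), −54 mV residual for
  Cl⁻. It is the convention used by `decompose_proton_motive()`.
* `nernst_potential_signed(species)` — the textbook valence-signed
  form `slope/z · log10(c_lumen/c_cytosol)`, which flips the sign for
  anions (Cl⁻ at 0.53/4 mM gives +54.0 mV rather than −54).

The decomposition closes exactly by construction
(`proton + potassium + chloride_residual = 0`); the published −54 is
the rounded −61.5 + 7. The implied equilibrium luminal Cl⁻,
`equilibrium_luminal_conc(4, residual)` ≈ 0.52 mM, prints as 0.5.
Temperature defaults to 310.15 K because the 61.5 mV slope only arises
near 37 °C. No Goldman–Hodgkin–Katz treatment and no activity
coefficients: the point is the feasibility argument, not a full
electrodiffusion model.

## 3. The kinetic model

State (lumen): `pH_G`, `[Cl⁻]`, `[HCO₃⁻]`, `[CO₂]`, in mM and minutes.
Free-proton changes are absorbed by a constant intrinsic buffering
capacity β (default 20 mM/pH, a typical organelle value; the source
experiments do not report one), so `dpH/dt = −(J_pump − J_leak −
J_buffer)/β`. The bicarbonate system is explicit and kinetic:

* forward `k_f·[H⁺]·[HCO₃⁻]`, reverse `k_f·K_a·[CO₂]` with pKa 6.4;
* CO₂ escape first order, scaled by the cisternal surface-to-volume
  ratio (flattened cisternae, S/V = 20 µm⁻¹ by default — the geometry
  argument for why gas/water egress is fast);
* in the limit of fast buffering and fast CO₂ escape the steady state
  obeys Henderson–Hasselbalch, `pH = pKa + log10([HCO₃⁻]_G/[CO₂]_bath)`
  (verified to 0.05 pH units in the acceptance suite).

The membrane potential is clamped at 0 mV (counter-ion conductance
assumed non-limiting), so the Cl⁻ channel is a plain
concentration-gradient flux and the exchanger is electroneutral.

**Flux laws.** The source experiments give no rate laws; these are this
package's choices:

* Pump: Michaelis–Menten in ATP (Km 0.3 mM) times a linear
  back-pressure factor that vanishes at `pump_pH_floor` (4.8) and
  saturates at `pump_bp_ref` (7.2). The floor is placed so the
  anion-free plateau lands inside the observed 5.0–5.5 window.
  Concanamycin A sets the pump to zero.
* Passive H⁺ leak: first order in the free [H⁺] difference. It is
  deliberately small (≤0.35 ΔpH/min from an acidified lumen) — the
  observed efflux is dominated by the bicarbonate route.
* AE2: **saturable carrier (antiport) kinetics**,
  `turnover · density · gate(pH_G) ·
  (θ_HCO₃(bath)·θ_Cl(lumen) − θ_HCO₃(lumen)·θ_Cl(bath))`
  with site occupancies `θ(x) = x/(Km + x)` (Km 5 mM for HCO₃⁻, 10 mM
  for Cl⁻). A pure mass-action product difference normalized for the
  permeabilized bath (120 mM Cl⁻ / 20 mM HCO₃⁻) was tried first and
  rejected: it makes the exchanger irrelevant at intact cytosolic
  concentrations, so resting pH stops depending on AE2 density, which
  contradicts the central observation. The saturable form preserves
  detailed balance (zero flux at symmetric concentrations) and the
  1:1 electroneutral stoichiometry.
* pH gate: base-10 logistic in luminal pH, midpoint 5.0 ("active above
  pH 5.0"), steepness 4/pH unit, so the exchanger is <1% active half a
  unit below the midpoint — the safeguard that keeps mislocalized AE2
  from alkalinizing more acidic compartments.

**Integration.** No stiff ODE solver package is assumed; `R/ode.R`
implements the Shampine–Reichelt ode23s Rosenbrock scheme (order 2/3,
L-stable, cubic-Hermite dense output), rtol 1e-8 / atol 1e-10 by
default. Protocol events (permeabilization, bath exchange, ATP, CMA)
restart the integration exactly at the event time. With all membrane
fluxes off, `β·pH − [CO₂]` and `[HCO₃⁻] + [CO₂]` are linear invariants
of the system and are preserved by the scheme to well under 1e-6 pH.

**Presets and calibration.** `golgi_preset()` loads
`cos7_control`/`cos7_ae2plus`/`sw48` from JSON config files (densities
1/3/5). The free parameters were calibrated **once**, before the test
suite was written, against four anchors: anion-free plateau in
[5.0, 5.5]; permeabilized Cl⁻+HCO₃⁻ plateaus ~6.3 (control) and ~6.7
(overexpression); and a positive control→overexpression resting-pH
shift. With the shipped values the permeabilized anchors are met
(5.23; 6.31; 6.72) and the intact-cytosol resting pH comes out 6.16
(control) and 6.55 (overexpression): the 0.39-unit shift is inside the
observed ~0.5-unit effect band, but the absolute intact values sit
~0.25 units below the measured 6.4/6.9. The model cannot hit both the
permeabilized and the intact anchors simultaneously with one parameter
set — the permeabilized ones were preferred because those protocols are
what `simulate_golgi()` actually replays. This residual mismatch is a
known limitation, not a tuning target.

Three choices about compositions deserve a note:

* The intact "cytosol" bath uses 40 mM Cl⁻ (typical for cultured
  cells), not the 4 mM used in the electrochemical worked example: at
  4 mM the Cl⁻ channel cannot supply the counter-ion flux the pump
  needs, and luminal Cl⁻ pins at zero. Cytosolic HCO₃⁻ is kept at
  12 mM; permeabilized protocols use the 20 mM bath value.
* The "Cl⁻ only" bath preset carries 2 mM bicarbonate (plus its
  equilibrium CO₂). A strictly bicarbonate-free model cannot place the
  Cl⁻-only plateau above the anion-free one; the residual bicarbonate
  represents endogenous carbonic anhydrase activity, which is also the
  published interpretation of the Cl⁻-only effect.
* Leak (net acid efflux) rates are measured with
  `protocol_acid_leak()`: acidify in a bicarbonate-free bath, then
  switch to an ATP-free, CMA-containing bath with bicarbonate. Probing
  every preset from a common acidic start is what makes the efflux rate
  scale with AE2 density (SW-48-like vs control ratio > 2); measured at
  each preset's own plateau the initial efflux would simply equal the
  pump rate and be density-independent.

**Not modelled** (out of scope by design): membrane-potential dynamics,
NHE7/NHE8 acid loaders, GPHR gating, spatial cisternal structure,
osmotic water flux, and the observed density-dependent *acidification*
rates in anion-free baths — the stated mechanism provides no route for
that effect, and the model does not invent one.

## 4. pHluorin quantification

* **Calibration**: 4-parameter logistic in pH,
  `ratio = r_min + (r_max − r_min)/(1 + 10^(hill·(mid − pH)))` — the
  minimal invertible "sigmoidal" family. Fitted by `nls` (scaleOffset
  guards the zero-residual case); `ratio_to_ph()` is the analytic
  inverse, and ratios outside (r_min, r_max) are flagged `NA`, never
  clamped.
* **Initial rate**: monoexponential fit
  `pH(t) = p_∞ + (p₀ − p_∞)e^{−kt}`; the reported rate is the t = 0
  derivative `k(p₀ − p_∞)`, signed so acidification is negative.
  Whether the published "initial rate" was a derivative or an early
  secant is not stated; both are exposed (`method = "linear"` gives an
  OLS secant over the first 5 points) with the derivative as default.
  Flat/failed series return rate 0 with a flag rather than an error.
* **Binned regression**: left-closed right-open equal-width classes
  (default eight over 200–5000 AU, 600 AU each; a cell at exactly
  5000 AU is excluded — edge handling was unstated and had to be fixed
  somehow), OLS of bin-mean pH on bin midpoints, R² reported.
* **Subpopulations**: 1- vs 2-component Gaussian mixture by EM (k-means
  initialization, explicit seed, jittered restarts), selected by BIC.
  An EM run that exhausts its iterations with a plateaued log-likelihood
  is still used for BIC comparison; only total collapse errors. The
  seeded simulation suite checks ≤5% false splitting and ≥95% detection
  of 3σ-separated components at n = 4000.
* **Group statistics**: two-tailed Student's t (pooled variance, Welch
  optional) for two groups, one-way ANOVA beyond; distribution
  summaries are median with 10th/90th percentiles, the field's box-plot
  convention.

## 5. Lectin fingerprints

Spot intensities (assumed background-corrected by the scanner) are
averaged within replicate arrays, then summarized per condition
(mean ± SD, n = replicates). `subtract_fingerprints()` tests each
lectin with Student's t on the replicate means — respecting the
spots-within-arrays nesting — and reports `delta = mean_A − mean_B` and
a signed fold change (±max/min, so a twofold decrease is −2, matching
how decreases are reported as >1-fold magnitudes). **No
multiple-testing correction by default**, mirroring the published raw
p < 0.05 over 43 lectins; expect ~2 false positives per null panel —
the type-I simulation in the acceptance suite quantifies exactly this.
Benjamini–Hochberg is available (`adjust = "BH"`) but off by default.

`intersect_pairs()` operationalizes "comparable changes across cell
pairs" as *sign concordance* among lectins significant in both pairs;
no magnitude-similarity criterion was published, so none is imposed
(the per-pair fold changes are returned for anyone who wants one).
`heatmap_order()` sorts lectins by a reference condition's means,
breaking ties by panel order.

## 6. Synthetic data: what a green test establishes

Each generator takes a mandatory seed, uses one RNG stream, and
restores the caller's RNG state. Noise defaults — calibration CV 2%,
time-course noise equivalent to 0.02 pH, per-cell pH SD 0.15, lectin
spot CV 10%, n = 6 replicate arrays — are the stated working conditions
of the emulated assays and are not tuned against test outcomes.

The generators emulate the *statistical structure* the pipeline
assumes: a sigmoid ratio–pH response with multiplicative noise;
log-normal expression with a linear expression–pH trend or an explicit
two-component mixture; exponential (or simulated-trajectory) pH
relaxations sampled at 15-s intervals; log-normal lectin intensities
with planted fold changes. They do **not** emulate imaging artefacts
(focus drift, bleaching, segmentation errors), ratio saturation at the
calibration asymptotes, correlated noise across lectins, or array
spatial effects. A green test therefore establishes that the estimators
recover known truth under the assumed noise model at the stated sample
sizes — not that the assays themselves are unbiased.

## 7. Numerical and interface choices

* Configs are JSON first (YAML accepted when the `yaml` package is
  present). Presets ship as config files, not hard-coded constants.
* Every written table gets a `.meta.json` provenance sidecar (package
  version, seed, parameters, column order).
* CLI exit codes: 0 success, 2 input error, 3 numerical failure.
* Reporting rounds mV and mM to one decimal; computation is full
  precision throughout.
* Integrator tolerances rtol 1e-8/atol 1e-10; resting-pH detection uses
  a 20-min convergence window at 1e-5 pH with a hard 400–600 min cap
  (error on non-convergence, never a silent plateau).

## 8. Known limitations

* The intact-cell resting-pH anchors are met in shift but sit ~0.25 pH
  units low in absolute terms (Section 3).
* The kinetic model is a single well-mixed compartment; cis–trans pH
  gradients and cisternal heterogeneity are out of scope.
* The density-dependent anion-free acidification rates remain
  unexplained by the stated mechanism and are not reproduced.
* Lectin glycotope annotations are pass-through strings; no
  glycan-structure inference is attempted.
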