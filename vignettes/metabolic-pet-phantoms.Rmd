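---
title: "Methods: FDG/oxygen-15 PET metabolic analysis and its phantom verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FDG/oxygen-15 PET metabolic analysis and its phantom verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabpet)
```

`metabpet` analyses combined ¹⁸F-FDG and ¹⁵O PET of the injured brain:
kinetic modelling of glucose transport and phosphorylation, oxygen map
algebra, lesion-anchored and physiology-defined tissue classes, and the
nonparametric cohort statistics that connect them to blood and
microdialysis chemistry. This vignette is the package's own account of the
underlying models, the numerical choices, and what the synthetic phantom
generator does and does not establish.

## The compartment model and its analytic solution

FDG enters tissue from arterial plasma at rate K₁ (ml blood per ml tissue
per min), effluxes at k₂ (/min), and is trapped by hexokinase
phosphorylation at k₃ (/min); dephosphorylation k₄ is slow and set to zero
in the voxel-level model. With θ = k₂ + k₃ the tissue concentration
driven by a plasma input C_p(t) is

$$C_T(t) = \frac{K_1 k_3}{\theta}\int_0^t C_p(s)\,ds +
  \frac{K_1 k_2}{\theta}\left[e^{-\theta t} \ast C_p\right](t),$$

and the measured voxel adds a fractional blood signal:
C = (1 − V_b) C_T + V_b C_b. The k₄-inclusive model replaces the single
exponential with the bi-exponential impulse response whose eigenrates are
½[(k₂+k₃+k₄) ∓ √((k₂+k₃+k₄)² − 4k₂k₄)]; it reduces exactly to the
irreversible solution at k₄ = 0.

**Discretization.** Input functions are piecewise linear between samples
(zero before the first sample), and both the running integral and the
exponential convolution are evaluated *exactly* per segment, with series
expansions guarding θΔt → 0. Results are therefore independent of any
internal grid; the test suite checks the analytic curves against an
independent stiff ODE integration to a relative error (normalized by the
curve peak) below 10⁻⁴ across a 100-draw random parameter sweep.

**Units.** Time is minutes everywhere; activity units cancel in the fits
(K₁ estimation is scale-equivariant); glucose in mmol/l (numerically
µmol/ml); CBF in ml/100 ml/min; CMRG and CMRO₂ in µmol/100 ml/min; OEF is
stored as a fraction and printed as % in tables.

## Estimation

**Voxel level (basis functions).** For each candidate θ the model is linear
in a₀ = K₁k₃/θ (on ∫C_p) and a₁ = K₁k₂/θ (on the θ-convolution), plus a
whole-blood column whose coefficient estimates V_b. Coefficients are
constrained non-negative by an exact active-set solve (every support of the
≤3-column design is examined), not by post-hoc truncation. The default θ
grid is 60 logarithmically spaced values in [0.01, 2]/min — spanning all
plausible tissue θ with headroom — and ties in the weighted residual sum of
squares resolve to the smallest θ. Because a 60-point grid quantizes θ in
~9% steps, the scan is followed by a continuous 1-D refinement of θ between
the two neighbouring grid points, accepted only when it strictly lowers the
residual; this removes a ≈2% discretization bias in noiseless K₁ recovery
and changes nothing else. Frames are weighted uniformly by default
(duration weights are available); an all-zero or non-finite curve returns
zero parameters with a degeneracy flag and is excluded from summaries.
When no whole-blood curve is supplied the plasma input stands in for C_b,
and V_b may instead be fixed (default 0.05) rather than fitted — which of
the two the original voxel analyses used is not knowable from the outside,
so both are exposed.

**Region level (k₄ inclusive).** Region-mean curves are fitted by bounded
Levenberg-Marquardt over (K₁, k₂, k₃, k₄, V_b) from a coarse multi-start
grid (16 starts plus any user initialization), reporting the best weighted
residual and a convergence flag. On data simulated without
dephosphorylation the fitted k₄ pins to its lower bound and the influx
constant agrees with the basis fit within 3% — the k₄-robustness check one
runs before trusting irreversible-model summaries.

**Water flow.** A one-tissue stand-in, C_T = f·[e^{−(f/V_d)t} ⊛ C_p], fitted
by a grid-plus-refinement scan over f/V_d; this is a phantom-scale
simplification, not a full multi-tracer steady-state quantification.

## Macro-parameters

With conversion constants τ (transport preference of FDG over glucose,
applied to K₁ and k₂) and φ (phosphorylation preference, applied to k₃):

* K_i = K₁k₃/(k₂+k₃); defined 0 when k₂+k₃ = 0; always ≤ K₁.
* LC = (φk₂ + τk₃)/(k₂+k₃): a convex combination, so LC ∈ [φ, τ], → φ as
  k₃ → 0, and increasing in k₃ when τ > φ — high-phosphorylation lesion
  tissue carries the highest LC.
* CMRG = 100·G_p·K_i/LC.
* Brain glucose G_t = G_p·K₁/(k₂ + (τ/φ)k₃): transport in balancing efflux
  plus phosphorylation of the converted glucose constants; strictly
  decreasing in k₃.
* Phosphorylation fraction (k₃/φ)/(k₂/τ + k₃/φ).

The defaults τ = 1.10, φ = 0.32 reproduce a healthy-volunteer lumped
constant of 0.56 from typical volunteer rate constants (k₂ = 0.128,
k₃ = 0.057/min) and plausible values for all lesion classes; both are
configurable, and the supplementary formulations used by any particular
site may differ — the package's forms are stated here precisely so they
can be compared. Note that medians do not commute with ratios: applying
these formulas to published regional *medians* reproduces published LC and
CMRG values only approximately, which is expected behaviour rather than
error.

## Oxygen physiology

CaO₂ = 1.34·Hb·SaO₂ + 0.003·PaO₂[mmHg] (ml O₂/dl, converted to µmol/ml via
22.4 ml/mmol; kPa→mmHg at 7.50062). CMRO₂ = CBF·OEF·CaO₂ voxel-wise, so
OEF = CMRO₂/(CBF·CaO₂) round-trips to machine precision on every generated
map set. The metabolic ratio CMRO₂/CMRG is ≈6 for fully oxidative glucose
use; values below ~4 indicate a non-oxidative contribution. Full ¹⁵O
steady-state/bolus OEF estimation is out of scope: OEF maps are inputs or
phantom-generated, with the algebraic consistency enforced.

## Tissue classes

**Structural.** Lesion core and penumbra masks are supplied (or generated);
the peri-penumbra is the cuff of brain within 10 mm *Euclidean distance in
world mm* of the lesion — implemented as dilation by a millimetre-ball
offset set, so anisotropic voxels are handled correctly — and everything
else in the brain is normal-appearing. Precedence is core > penumbra >
peri-penumbra > normal; the labels always partition the brain mask. The
"10 mm circular cuff" around a microdialysis catheter tip is read as a
10 mm-radius sphere (a 5 mm radius reading is one argument away).

**k₃ hotspots.** Threshold = mean + 1.96·SD (population SD) of
normal-appearing k₃, computed per imaging session, with the mask drawn
over all brain voxels; a lesion-excluded variant takes an exclusion mask.
On hotspot-free Gaussian fields the flagged fraction matches the 2.28%
upper-tail mass, which the tests verify within binomial error over 50
seeds.

**Ischaemic brain volume.** The default venous-reserve threshold is
oef_crit = (CaO₂ − CvO₂_crit)/CaO₂ with CvO₂_crit evaluated at a critical
venous saturation (0.50) and venous PO₂ (4 kPa) at the patient's own
haemoglobin; a per-voxel demand-supply alternative,
CMRO₂_crit/(CBF·CaO₂), is provided. Both are conventional approximations
to site-specific derivations, and the strategy used is recorded in the
result. IBV is monotone non-increasing in the threshold by construction.

**Overlap.** Dice = 2|A∩B|/(|A|+|B|); two empty masks give 0 with an
explicit flag rather than NaN. Volumes are voxel count × voxel volume.

## Statistics

Spearman rank association uses average-rank ties and an exact permutation
p-value for n < 10 untied pairs (verified against brute-force enumeration),
a t-approximation otherwise. Two groups are compared by Mann-Whitney, more
by Kruskal-Wallis with Dunn's rank-sum z post-hocs (tie-corrected, raw
p-values); significance is flagged at 0.05 and at the 0.005 Bonferroni
level appropriate when eleven physiological variables are examined
together — the correction is applied across variables at the reporting
layer, not across pairs. Imaging epochs split at 24 h, 5 d and 12 d
post-injury, with later sessions flagged out-of-window.

Voxel-wise relationships (e.g. K₁ vs CBF) are summarized by LOWESS on a
seeded 2.5% simple random subsample of the paired voxels — the weighting
behind any particular published "weighted sample" being unstated, simple
random sampling is the documented stand-in, with the sampling hook
configurable — smoothed by degree-1 loess (span 0.3 by default, direct
surface so linear data are reproduced exactly), with a bootstrap 95% band
(200 resamples by default). Rows are sorted before sampling, making the
curve invariant to voxel ordering and reproducible under a fixed seed.
Breakpoints in piecewise relationships are located where the fitted slope
crosses halfway between its two plateau values; for a kink smoothed by a
symmetric kernel this crossing sits at the kink, and the tests recover
planted breakpoints at CBF 25 (for K₁) and 12 ml/100 ml/min (for k₃)
within ±3 ml/100 ml/min.

## The phantom generator

`build_phantom_maps()` embeds a spherical core (10 mm) and penumbral shell
(to 15 mm) in an ellipsoidal brain (85% of the half-extent per axis) on a
64³ grid of 2 mm voxels — large enough to host a 56 ml hotspot, small
enough to generate in seconds. Each region's K₁, k₂, k₃, CBF, CBV and OEF
voxels are drawn from truncated Gaussians whose means are the published
regional medians and whose SDs are IQR/1.35; K_i, LC, CMRG, CMRO₂ and MR
are then *derived*, never drawn, so every macro identity holds exactly and
recovery of any derived quantity is scoreable against the returned ground
truth. A k₃ hotspot (+6 SD, 56 ml by default, matching the scale of a
published single-patient example) and a high-OEF patch (OEF 0.60, 7 ml)
are planted as spheres in normal-appearing tissue. One master seed expands
into recorded child seeds for every stochastic component.

`simulate_cohort()` mirrors the cohort structure: 34 patient sessions
(12/8/14 early/intermediate/late) from 26 patients plus nine volunteers;
plasma glucose centred at 5.8 (patients) and 4.6 mmol/l (volunteers);
microdialysis in 10 sessions with glucose increasing in plasma glucose
(slope 0.55, noise SD 0.3 mmol/l — a dependence strong enough that a
positive rank correlation at n = 10 is significant in ≳90% of seeds, the
qualitative regime reported for real cohorts); and a negative coupling
(1 SD of k₃ per SD of brain-glucose availability) that reproduces in kind
the reported negative k₃-glucose rank correlations. Microdialysis lactate,
pyruvate and glutamate are drawn at published medians, and the
lactate/pyruvate ratio is always computed after converting lactate to
µmol/l.

**What the phantom does not emulate.** Voxel noise is spatially white,
whereas real parametric maps are smooth at the scanner's resolution; white
noise therefore *overstates* scattered threshold false positives. This
matters for plant-recovery checks: a planted hotspot inflates the very
normal-tissue moments that set its own detection threshold, so on white
noise the recovered volume stays within a one-voxel shell of the plant
only when the plant is an appreciable fraction of the brain. The recovery
tests accordingly pair the 56 ml plant with the default 64³ brain and the
7 ml plant with a 32³ brain, and the high-OEF recovery uses a uniform
background (the Table-derived OEF spread describes between-study
variation, not voxel noise; as a voxel SD it would scatter ~18% of voxels
above any clinically plausible threshold). The phantom also ignores
partial-volume effects, decay, scatter and motion — inputs are assumed
decay-corrected and co-registered — so passing tests establish the
correctness of the estimators and classifiers, not scanner-level accuracy.

## Pipeline and provenance

`run_pipeline()` chains phantom generation, region-median kinetic fits
(with 5% proportional TAC noise by default), structural and physiological
ROIs, overlap, and cohort statistics, writing CSV/JSON outputs plus a
provenance file holding the fully materialized configuration and all child
seeds. Outputs are deterministic: re-running from the stored YAML
configuration reproduces every table byte for byte. NIfTI is the single
volumetric format (maps float32, masks and labels uint8, voxel size in the
header); tables are CSV; configurations YAML.

## Numerical choices and edge cases

* Convolution: exact per piecewise-linear segment, `expm1`-based, series
  fallback below θΔt = 10⁻⁴; no FFT, hence grid-independent.
* Coincident eigenrates in the k₄ model (discriminant ≈ 0) are split by a
  10⁻⁷ relative perturbation — the t·e^{−αt} limit to O(10⁻⁹) — rather than
  special-cased.
* Non-negative least squares: exhaustive active-set over ≤3 coefficients
  (the exact NNLS optimum at this size); singular designs are flagged.
* Truncated-Gaussian draws use the inverse-CDF (exact, no rejection
  loops); rates truncate at 0, OEF at [0, 1].
* Degenerate inputs: all-zero TACs → zero parameters with a flag; empty
  regions → missing-value rows; constant vectors in Spearman → NA with a
  degeneracy flag; empty∧empty Dice → 0 with a flag.
* Test problem sizes (24³-64³ phantoms, 40-50 seed replications, 100-rep
  noise studies, 5000-rep null calibrations) were chosen so the entire
  suite verifies every stated property in about a minute on one core.

## Known limitations

The water-flow and blood-volume estimators are simplified stand-ins; the
critical-OEF strategies approximate site-specific derivations; LC
conversion constants are configurable defaults, not universal constants;
and the cohort generator plants monotone dependences without the
confounders (sedation depth, temperature, PaCO₂) that shape real TBI
physiology. The package quantifies what its inputs contain — it does not
register, segment, or reconstruct.
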