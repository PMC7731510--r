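---
title: "Models and methods behind valveoptics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind valveoptics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(valveoptics)
```

## The problem

Early calcific aortic valve disease (CAVD) remodels valve collagen and
deposits micro-calcifications — earliest at the commissures — well before
function degrades. Label-free optical readouts can track this without
exogenous probes: endogenous two-photon autofluorescence carries NADH, FAD,
collagen and mineral signal, and collagen birefringence is measurable by
quantitative polarized light imaging (QPLI). valveoptics implements the full
quantification path from raw channel images to group statistics, and ships a
synthetic phantom generator so that every stage can be validated against
known ground truth.

## TPEF autofluorescence ratios

Four co-registered channels are acquired per section, indexed by
excitation/emission in nm: $A_{755/460}$ (NADH-weighted), $A_{860/525}$
(FAD-weighted), $A_{810/460}$ (calcium-weighted) and $A_{810/525}$
(collagen-weighted). Two normalized ratios are evaluated **at each pixel**:

$$R_{755\text{–}860} = \frac{A_{860/525}}{A_{755/460} + A_{860/525}},
\qquad
R_{\mathrm{Col\text{–}Cal}} = \frac{A_{810/525}}{A_{810/460} + A_{810/525}}.$$

Both live in $[0,1]$ and are invariant to a common detector gain on their
channel pair. Region values are **means of per-pixel ratios**, not ratios of
region means: the ratios are defined pixel-wise and region figures report
their averages. The alternative (ratio of summed intensities) weighs bright
pixels more; with the normalized denominators the two differ little on
phantoms, but the pixel-mean convention is the one fixed here and worth
remembering when comparing absolute values across implementations.

Pixels whose channel-pair sum falls below an intensity floor are flagged
invalid rather than contributing noise-dominated ratios. The default floor
is data-driven: mean + 2 sd of the pair sum outside all annotated regions
(`estimate_intensity_floor()`), since background there is detector noise by
construction. No flat-field or spectral-bleed correction is applied — the
acquisition side is assumed to have handled gain consistency — but the floor
and all thresholds are arguments, not constants.

## QPLI: retardation, orientation, directional variance

A rotating linear polarizer with a fixed circular analyzer produces, under a
single-harmonic model (the simplest one in which both parameters are
identifiable), the per-pixel intensity series

$$I(\theta_k) = B\,\bigl(1 + \sin\delta\,\sin 2(\theta_k - \phi)\bigr),$$

with baseline $B>0$, retardation $\delta$ (proportional to local collagen
thickness) and axial orientation $\phi$. On an even grid of $K \ge 4$ angles
covering $[0°, 180°)$ — the second half-turn is redundant by axial symmetry —
the discrete Fourier component at frequency 2 recovers the parameters
exactly in the noiseless case:

$$\hat B = \tfrac1K\sum_k I_k,\qquad
\hat A = \tfrac2K\Bigl|\sum_k I_k e^{-2i\theta_k}\Bigr|,\qquad
\hat\delta = \arcsin\!\bigl(\mathrm{clamp}(\hat A/\hat B, 0, 1)\bigr),$$

with $\hat\phi$ from the complex phase, mapped to $[0°,180°)$. The estimator
is $O(K)$ per pixel and needs no iteration. Numerical choices:

- retardation is capped at 90° (the arcsin branch; thin-section assumption);
  the count of clamped pixels is returned for audit;
- pixels with $\hat B$ at or below the intensity floor are invalid, not
  errors (an all-zero pixel is a perfectly legal input);
- a constant series has $\hat A = 0$: retardation 0, orientation undefined
  and flagged, rather than an arbitrary angle;
- uneven angle grids are rejected — the DFT estimator is biased there, and
  supporting them would require a generalized least-squares fit that the
  even-grid hardware makes unnecessary.

At 2% Gaussian noise (the generator's default, as a fraction of the maximum
signal) the retardation RMSE over $10^4$ pixels with $\delta$ spanning
0–50° is below 1°, dominated by the $\sqrt{2/K}$ noise transfer of the
harmonic amplitude.

**Directional variance** treats orientations as axial data: angles are
doubled, so 0° and 180° coincide and orthogonal fibers cancel,

$$V = 1 - \Bigl|\frac1n\sum_k e^{2i\phi_k}\Bigr| \in [0,1].$$

It is computed over collagen-positive pixels (default: $\delta > 5°$; no
published threshold exists, so the default is validated against phantom
truth and exposed as an argument) in an odd sliding window, default 11 px
with at least 10 contributing pixels — "local" alignment at the scale of a
few fiber widths at typical 20x sampling. Windows are evaluated with an
integral image, so cost is independent of window size. For an axial von
Mises orientation field with concentration $\kappa$ the population value has
the closed form $1 - I_1(\kappa)/I_0(\kappa)$, which the test-suite checks
by Monte Carlo at $\kappa \in \{0.5, 2, 8\}$.

## Histology quantification

**ARS percent area** mirrors the ImageJ constant-threshold +
Analyze-Particles workflow: ITU-R 601 luminance conversion to 8-bit
grayscale, positive = darker than the threshold (deposits are dark red on a
bright background; default 100, configurable since no published value
exists), 8-connected component labelling, discard of particles below 4 px,
then percent positive area per region. Both knobs act monotonically —
stricter thresholds and larger size floors can only shrink the measured
area — which the suite asserts as a property.

**PSR composition** classifies collagen-positive pixels
(saturation ≥ 0.25, value ≥ 0.10 in HSV — floors that exclude unstained and
background pixels) into four hue bins, defaults in degrees: thick/red
$[0,10)\cup[350,360)$, thick-intermediate/orange $[10,40)$,
thin-intermediate/yellow $[40,60)$, thin/green $[60,140)$. Only the color
names are standard; the cut points follow common picrosirius
hue-segmentation practice and are overridable. Percentages are reported
among collagen-positive pixels and sum to 100 whenever any exist; an
unstained region is flagged undefined instead of reported as zeros.

## Echo formulas and score aggregation

Volumes use the Teichholz cube-correction $V = 7.0\,D^3/(2.4+D)$ (µL from
mm), $EF = (D_d^3 - D_s^3) \cdot 100 / D_d^3$, $CO = (EDV - ESV)\cdot HR$.
A literal variant $(7.0 + D^3)/(2.4+D)$ circulates in print where the
multiplication is typeset ambiguously; it is implemented behind
`formula = "printed"` so either convention can be audited, and EF — which is
volume-formula-independent — is identical under both.

Rater scores (three blinded raters, each 0/1/2) aggregate by mean into
grades $-/+/++/+++$ with boundaries at exactly $2/3$ and $4/3$. The
boundaries are compared as integers ($3s$ vs $2n$ and $4n$), because the
conventional rounded cut points 0.66/1.33 misgrade a mean of exactly
two-thirds under floating point. Boundary means resolve to the lower grade;
the 27 ordered rater triples enumerate to a gap-free, overlap-free map.

## Statistics layer

`compare_groups()` fits `value ~ diet * week`, tests residual normality
(Shapiro–Wilk at $\alpha = 0.05$ — a concrete choice where "passed normality
testing" is otherwise underspecified), and reports either Type-II two-way
ANOVA (robust to the unbalanced cells of small animal studies) with Tukey
HSD over all diet-by-week cells, or Kruskal–Wallis with Dunn-style rank
contrasts (z from the shared ranking, tie-corrected, Holm-adjusted).
Constant data raises an error rather than producing a spurious p-value. All
p-values are reported in full; no censoring and no multiplicity correction
across metrics or regions beyond the within-comparison adjustment. The null
type-I error of the gated procedure is calibrated by simulation (1,000
identically distributed two-group tables) in the acceptance checks.

`correlate()` uses Pearson for normal pairs and Spearman (midranks) for
ordinal or non-normal data; `auto` routes on an ordered-factor flag or a
Shapiro check of either side. Because some figure-level panels pool
anatomical regions and others do not, the report computes correlations both
pooled and per-region, labelled by scope.

## The phantom generator

The generator encodes the statistical structure the analysis assumes, with
truth retained:

- **Channels**: four source maps (NADH-, FAD-, collagen-, calcium-like),
  piecewise-constant per region, pushed through a nonnegative 4×4 mixing
  matrix, plus Gaussian noise (default sd = 2% of the maximum clean signal;
  optional Poisson shot noise), clipped at zero. The default mixing matrix
  loads calcium mostly on 460-nm emission, so raising the calcium source
  depresses both ratios — the disease signature. With zero noise the mixing
  inverse recovers the sources to machine precision, which pins down the
  forward model in tests.
- **Effect model**: the pro-calcific `effect_size` multiplies the calcium
  source and couples into the NADH-like source (factor $1 + 0.3(e-1)$),
  reflecting that a metabolic shift raises 460-nm signal while the ratio
  falls. In a study, pro-calcific animals at week $w$ get
  $e(w) = 1 + (e_{16}-1)\,w/16$: the configured effect at week 16, stronger
  at 28. The magnitudes are chosen so that a three-fold week-16 effect is a
  *large* standardized group difference, matching a setting in which 3–4
  animals per cell yield adjusted p-values near $10^{-2}$; per-animal
  biological variability is lognormal (sdlog 0.05) on all source weights.
- **Polarization stack**: the forward model above with $B = 50 +$ the
  collagen source, truth retardation per region (base 25/30/35° for
  leaflet/commissure/root, ramped 0.5–1.5× across the image within the
  0–50° display range) and truth orientation drawn from an axial von Mises
  field (base $\kappa$ 4/6/8 about mean directions 0/45/90°). A per-section
  thickness factor multiplies retardation and scales $\kappa$ with its
  square, coupling thickness and disorder so that retardation and
  directional variance anticorrelate across sections — thinner, more
  disordered collagen in remodeling tissue.
- **Stains**: PSR pixels draw a thickness bin per pixel from the configured
  fractions and render reference hues; ARS deposits are 2-px-radius disks
  placed within each region until the configured area fraction is covered,
  the final deposit trimmed so that the truth mask hits the target to one
  pixel. Deposits are dark red on a bright background so the default
  grayscale threshold separates them.
- **Tables**: echo records with EF easing down as effect rises, and
  7-marker rater scores whose latent means shift with effect (osteogenic
  markers RUNX2/osteopontin steepest).
- All blocks draw from independently derived sub-seeds, so generating a
  subset of components never changes another block's values, and everything
  is bit-reproducible from the master seed.

**What the phantom does not emulate** — and hence what passing tests do not
show about real data: optical point-spread and scatter, spectral bleed
between channels, wavelength-dependent birefringence, stitching artifacts,
within-region texture beyond the ramps described, staining batch variation,
and any nonlinearity in the source-to-channel map. The phantom validates the
*estimators and statistics*, not the biology; sensitivity of conclusions to
the mixing matrix or noise model should be explored through the config, not
assumed.

## Problem sizes and defaults

Default study conditions: 128×128 px sections at 2 µm/px, K = 18 polarizer
angles, 2 diets × weeks {4, 16, 28} × 4 animals, week-16 effect 3. The
acceptance checks run 200 replicate studies for the signature-reproduction
rate, 1,000 tables for type-I calibration, $10^4$ pixels for retardation
RMSE and $10^5$ draws for the circular-statistics closed form — sizes at
which the Monte-Carlo error is comfortably below each tolerance.

## Known limitations

- The QPLI estimator requires evenly spaced angles; uneven grids need a GLS
  fit that is deliberately out of scope.
- Spectral unmixing of NADH/FAD/collagen/calcium contributions is not
  attempted; the ratios are composite signals by design.
- ROI polygons are caller-supplied; there is no automatic valve
  segmentation.
- The Dunn fallback uses a normal approximation; exact small-sample rank
  inference is not implemented.
- Whether commissure ROIs should include adjacent root wall is an
  annotation convention left to the user.
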