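---
title: "Methods: cone morphometry, choroidal vascularity, and adaptive CSF estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cone morphometry, choroidal vascularity, and adaptive CSF estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`myoretina` implements the quantitative chain used in clinical studies that
relate retinal microstructure to spatial vision in high myopia: cone-mosaic
morphometry from adaptive-optics (AO) fundus images, choroidal vascularity
from OCT B-scans, adaptive contrast-sensitivity-function (CSF) estimation,
and the cohort statistics that tie them together. Because clinical images
and subjects cannot be redistributed, every stage ships with a synthetic
generator that emulates the relevant structure, so the full pipeline is
testable end to end. This vignette records the models, the tunable
parameters, and the design decisions, in that order of importance.

## Ocular magnification

All lateral (transverse) dimensions on the retina scale with axial length
(AL). We use Bennett's axial-length method: the retinal scaling factor is

$$q = 0.01306\,(\mathrm{AL} - 1.82)$$

with AL in mm; 1.82 mm is the distance from the cornea to the eye's second
principal point in the underlying schematic eye. Relative to a device
calibrated at a reference AL (default 24.0 mm, configurable — devices do not
document this constant), physical sizes are multiplied by
$(\mathrm{AL} - 1.82) / (\mathrm{AL}_{\mathrm{ref}} - 1.82)$. Both constants
are exposed as arguments so alternate calibrations can be tested. The
correction applies to lateral dimensions only: axial OCT distances are set by
the interferometer and the tissue group index, not by ocular magnification,
so `bscan` axial scales are taken as calibrated.

## Cone-mosaic morphometry

ROIs are 100 × 100 µm squares placed at 0.6 mm ("inner") and 1.2 mm
("outer") eccentricity along the four principal meridians, with manual
offsets available because avoiding blood vessels is the operator's call, not
the algorithm's.

**Detection** (`detect_cones`) is a standard spot-detection chain:
difference-of-Gaussians band-pass tuned to the expected cone period (sigmas
0.17 and 0.5 times the expected spacing), local maxima above a response
floor (2% of the ROI intensity range, which silences flat regions), greedy
minimum-separation thinning at half the expected spacing (strongest
response wins), and sub-pixel refinement by center of mass of the band-pass
response in a window of radius 0.25 spacing. All four constants live in
`detect_params()`. On synthetic mosaics at 20,000 cones/mm² with peak SNR
10 the detector's recall and precision both exceed 0.95 (matching radius:
half the lattice constant).

**Metrics** (`mosaic_metrics`) follow the field's definitions:

- *density* — raw count over ROI area, cones/mm²;
- *spacing* — mean length of retained Delaunay edges ("adjacent cones").
  Edges longer than 3 × the median edge length are discarded; they are
  convex-hull artifacts, not adjacencies. The mean nearest-neighbor
  distance is also reported (`spacing_nn`) because the literature is split
  between the two conventions;
- *regularity* — percentage of cones with 5–7 Voronoi neighbors. Cells
  clipped by the ROI border are excluded from numerator and denominator:
  a clipped cell's neighbor count is an undercount, not a measurement.

Tessellation is delegated to `deldir`. On a perfect hexagonal lattice with
constant $s$ these definitions recover the closed forms exactly: density
$2/(\sqrt{3}s^2)$, spacing $s$, interior regularity 100%.

## Choroidal vascularity

The choroid is the region between the RPE–Bruch's membrane complex and the
choroid–sclera interface. Boundaries arrive as per-column polylines
(annotation files); automatic intraretinal segmentation is deliberately out
of scope — it is a separate, cited literature and clinical pipelines consume
examiner-corrected boundaries anyway.

The scan is first *linearized* (`linearize`): each column is shifted by an
integer number of pixels so the RPE–Bruch boundary lies on one common row;
shifts are rounded, so the flattened boundary's residual is below half a
pixel. Pixels shifted in from outside the frame are `NA` and excluded from
every later mask. Binarization follows on the linearized scan, consistent
with the order clinical pipelines use.

*Niblack binarization* (`niblack_binarize`) computes a per-pixel threshold
$T = \mu_w + k\,\sigma_w$ over a square window $w$ and labels choroid
pixels with intensity strictly below $T$ as lumen (vessel lumens are
hyporeflective in OCT — the dark class). Defaults are $k = -0.2$, the
classic Niblack weight for dark-object segmentation, and $w = 51$ px,
chosen near the scale of medium choroidal vessels at our default 10 µm
lateral sampling; both are configurable since published protocols rarely
state them. Local moments come from integral images (exact sliding-window
sums, truncated windows at the borders). Because the rule compares the
pixel to an affine function of local mean and SD, the lumen mask — hence
CVI — is invariant under any positive affine rescaling of intensities.

Per subfield (inner 0.5–1.0 mm, outer 1.0–1.5 mm eccentricity, both sides
of the fovea pooled; the study's two scan lines give strips, not annuli):

- TCA = choroid pixel count × pixel area (mm²); LA likewise on the lumen
  mask; SA = TCA − LA, computed from the same counts, so LA + SA = TCA is a
  pixel-count identity, not an approximation;
- CVI = LA / TCA;
- CT = mean per-column boundary separation × axial scale (µm).

Sublayer thicknesses (OPL, HFL+ONL, IS, OS, IZ+RPE) are mean per-column
differences between consecutive interfaces. Equal interfaces (a
zero-thickness layer) are tolerated; crossing interfaces are rejected at
construction.

Repeatability (`agreement_stats`) reports the coefficient of repeatability,
$1.96 \times \mathrm{SD}$ of the paired differences, and ICC(2,1) — two-way
random effects, absolute agreement, single measurement — computed from the
two-way ANOVA mean squares.

## Adaptive CSF estimation

The response model is a Weibull psychometric function for a 2AFC
orientation task:

$$P(c) = \gamma + (1 - \gamma - \lambda)\left(1 - e^{-(c/\tau)^\beta}\right)$$

with guess rate $\gamma = 0.5$ and lapse rate $\lambda = 0.02$. At $c =
\tau$ this gives $0.5 + 0.48(1 - e^{-1}) = 0.8034$: the familiar
"80.3%-correct" threshold criterion is exactly the Weibull $1 - e^{-1}$
point under these rates, and that back-derivation anchors all simulated
observers.

The Psi procedure maintains a posterior over a grid of (log10 threshold,
slope): log10 τ from −3 to 0 in steps of 0.02, ten log-spaced slopes in
[0.5, 8], uniform prior, candidate contrasts equal to the threshold grid
(all configurable in `psi_init`). Each trial presents the candidate that
minimizes the expected posterior entropy over the two possible responses,
with ties broken toward the lower contrast; the posterior is then updated
by Bayes' rule. The expected-entropy computation is exact — a property test
checks it against brute-force enumeration on a small grid — and is
implemented as two matrix products against tables precomputed at
`psi_init` time, which is what makes simulation studies cheap.

**Threshold estimator.** We report the mode of the marginal posterior over
log10 threshold, not its mean. This is a deliberate choice made after
measurement: at 45 trials the threshold marginal is markedly left-skewed
(skewness near −1) because shallow-slope hypotheses are still alive, and
the posterior mean inherits that skew — about −0.018 log10 units of bias,
which translates to roughly −2.2 percentage points when the true
psychometric function is evaluated at the estimate. The marginal mode is
nearly unbiased in the same simulations and has *lower* RMSE (0.066 vs
0.070 log10 units), so it is the default; `psi_estimate(type = "mean")`
keeps the mean available for comparison. The bias is a property of the
estimator, not of stimulus placement: it persists when the true slope is on
the grid and when placement minimizes the entropy of the threshold marginal
instead of the joint posterior.

A session (`run_session`) runs one independent track per spatial frequency
— 1.5, 3, 6, 12, 18, 24 cpd at 45 trials each, 270 trials in total — and
summarizes:

- **AULCSF**: trapezoidal integral of $\max(\log_{10} S, 0)$ against
  $\log_{10} f$ over the measured range [1.5, 24] cpd. Published protocols
  state neither bounds nor clipping; we integrate the measured range and
  clip negative log-sensitivities at the nodes, and flag both choices here.
- **Cut-off SF**: the frequency where the log CSF reaches sensitivity 1,
  by linear inter-/extrapolation in (log10 f, log10 S) coordinates from the
  highest descending segment, reported in log10 cpd — the scale on which
  clinical values near 1.3–1.4 are coherent (≈ 20–26 cpd). A
  non-descending high-frequency tail is flagged and floored at the highest
  measured frequency.

## Synthetic generators

The generators emulate exactly the structure the analyses consume, no more:

- `gen_mosaic`: triangular lattice at the target density, Gaussian
  positional jitter (fraction of the lattice constant), Bernoulli dropout,
  rendered as unit-amplitude Gaussian spots plus Gaussian noise (peak SNR =
  1/noise SD). It does **not** model rods, vessel shadows, frame-averaging
  artifacts, or the eye's wavefront — so detector performance on it bounds,
  but does not certify, performance on clinical AO images.
- `gen_choroid_phantom`: a choroid band of constant thickness between
  smooth boundaries, dark elliptical lumens placed by rejection sampling
  until the labelled lumen fraction is within 0.01 of target, a simple
  layered retina above, additive speckle. Real choroids have graded vessel
  calibers by depth and multiplicative speckle; the phantom tests the
  binarization chain, not OCT physics.
- `gen_observer`: truncated log-parabola CSF,
  $\log_{10} S(f) = \log_{10} G - 4\log_{10}2\,((\log_{10} f -
  \log_{10} f_0)/w)^2$, floored at $\log_{10} G - \delta$ below the peak
  frequency — the standard observer model in the CSF-modelling literature.
  Defaults ($G = 60$, $f_0 = 2.5$ cpd, $w = 0.85$, $\delta = 0.4$,
  $\beta = 3.5$) put the true AULCSF near 1.58, inside the 1.5–1.9 range
  reported for young adults, with a cut-off slightly above 24 cpd.
- `gen_cohort`: 81 eyes in groups of 20/26/35 (emmetropia, low/moderate
  myopia, simple high myopia), SE/AL/age/IOP from truncated normals with
  the published group means, SDs and ranges, fixed sex counts, and group
  labels re-derived from the enrollment rule (SHM iff SE ≤ −6.00 D or AL ≥
  26.5 mm; mismatching draws are resampled). Outcomes are linear in AL plus
  Gaussian noise. Where the published unstandardized regression slopes are
  unit-coherent (AULCSF −0.066 per mm, cut-off −0.032, sublayers, flow,
  FAZ) they are the defaults; where printed slopes are inconsistent with
  the printed group means (cone density and spacing, CVI, the areas, CT),
  slopes were derived once from the group means across the AL span. Signs
  follow the reported associations: negative for cone density, CT, CVI,
  TCA, AULCSF; positive for spacing. LA is constructed as TCA × CVI so the
  luminal/stromal identities hold row-wise. The cohort is a
  *linear-Gaussian cartoon*: it has the right first-order correlation
  structure, not the conditional dependencies of real eyes.

Every generator seeds its own stream and is bit-reproducible.

## Statistics stage

Group comparisons use one-way ANOVA plus pairwise two-sample t-tests
(Student by default, Welch by flag), reported without multiplicity
correction as clinical tables typically are, labelled P1 = EM vs LM/MM,
P2 = EM vs SHM, P3 = LM/MM vs SHM — the natural reading of a three-group
table, kept configurable because published tables rarely define the
labels. Sex distributions use Pearson's chi-square without continuity
correction. The regression screen fits one OLS model per candidate
predictor, admits those with p < 0.05 into a joint model, and removes the
largest-p predictor until all survivors have p < 0.05 (the exact stepwise
criteria of commercial statistics packages are undocumented; 0.05/0.05
matches the narrative convention). Standardized coefficients are
$\beta\,\mathrm{SD}(x)/\mathrm{SD}(y)$. Mixed models are intentionally
absent: with one eye per subject there is no random-effects structure to
fit.

## Numerical choices and problem sizes

- Niblack comparisons use a 10⁻⁸ intensity tolerance so an exactly
  constant region yields an empty lumen mask despite floating-point
  rounding in the integral images.
- Posterior updates guard against zero total likelihood (numerical
  underflow) and renormalize every trial; normalization is asserted to
  10⁻⁹ in the tests.
- Degenerate inputs are flagged rather than guessed at: fewer than 3 cones
  (no spacing/regularity), empty choroid (no CVI), zero-variance
  repeatability series (no ICC), non-descending CSF tails (floored
  cut-off), all-flat groups (no ANOVA).
- Test and verification problem sizes are chosen so the whole suite runs
  in minutes on one core: hexagonal-lattice oracles on a 400 µm field
  (≈ 7,400 cones; boundary effects keep the realized density within 1% of
  the closed form), 500 single-track Psi runs for criterion calibration,
  200 for bias/RMSE, 1,000 simulated ANOVAs for the type-I rate.

## Known limitations

Vessel avoidance in ROI placement is manual by design. The intraretinal
segmentation itself is consumed, not computed. OCTA flow metrics and FAZ
area are device-reported columns of the cohort table, never recomputed.
The phantom's lumen fraction is a pixel-count target, so CVI recovery is
only meaningful to within the phantom's ±0.01 construction tolerance plus
binarization error. And all calibration statements above are statements
about the synthetic generators — the acceptance suite recomputes each one,
and nothing stronger is claimed about clinical data.
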