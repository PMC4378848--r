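---
title: "Methods: collagen hydrogel characterization and empirical property models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: collagen hydrogel characterization and empirical property models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelchar)
```

`gelchar` implements the four standard characterization analyses for
collagen I hydrogels and the empirical regression layer that turns their
outputs into a predictive fabrication → property model. This vignette is
the package's account of the underlying methods: the models and their
assumptions, the tunable parameters and why their defaults are what they
are, what the synthetic-data generators do and do not emulate, and the
numerical choices made where the design was genuinely open.

## Turbidity kinetics

Collagen fibrillogenesis produces a sigmoidal rise in optical turbidity.
`extract_kinetics()` reduces an absorbance-vs-time trace (405 nm, sampled
every 3.6 s by default) to four metrics: the total absorbance change
ΔAbs, the half-time $t_{1/2}$ (first crossing of the half-maximal level,
linearly interpolated between samples), the polymerization rate (slope of
the trace at $t_{1/2}$), and the lag time $t_L$, defined geometrically as
the intercept of the tangent at the half-max point with the initial
absorbance level: $t_L = t_{1/2} - (\Delta A / 2)/\text{rate}$.

Design choices:

* The initial and plateau levels are means of the first and last 5% of
  samples — robust to endpoint noise; the initial-window mean serves as
  the baseline against which the half-max level is defined (the raw
  signal is already zeroed against a water reference, but a residual
  offset is harmless under this convention).
* The derivative is computed on a lightly smoothed trace (centred moving
  average, default window 11 samples ≈ 40 s) via a local linear fit over
  the same window. On a noiseless logistic this recovers the analytic
  peak rate $\Delta A\,k/4$ to well under 1%; under 0.5% multiplicative
  noise all four metrics stay within 2% of the closed forms.
* Plateau detection compares the end-window slope, scaled by the
  end-window span, against 5% of ΔAbs; a non-plateaued trace yields a
  warning, not an error, since truncated traces still carry usable
  half-time information.
* A flat trace (ΔAbs ≤ threshold) or a non-positive rate marks the result
  invalid with the reason recorded.

The generator `sim_turbidity_trace()` uses a logistic sigmoid — any smooth
sigmoid family would emulate the observed shape; the logistic is chosen
because every metric has a closed form, which makes it a self-validating
ground truth. Defaults (ΔAbs = 0.8 AU, $t_{1/2}$ = 21.89 min, k = 0.01/s,
2 h duration) sit at the baseline fabrication condition of the empirical
model below.

## Confined compression

The modulus pipeline assumes a linear-elastic response under quasi-static
confined compression (0.1%/s over 0–20% strain), where the stress–strain
slope is the compression modulus E. `analyze_compression()` chains:

1. **Contact detection** — the first sample whose force deviates from the
   initial-window baseline by more than 5 × the sensor RMS noise
   (absolute deviation; the baseline and, when not supplied, the RMS are
   estimated from the first 5% of samples). For compliant gels the force
   rises slowly, so the threshold crossing trails true contact; at the
   default conditions (RMS 10⁻⁴ N, high-resolution transducer) this bias
   is tens of micrometres, far inside the thickness tolerance.
2. **Thickness validation** — measured thickness = platen start height −
   contact travel; samples deviating more than 5% (425 µm at 8.5 mm
   nominal) from nominal are rejected. The rule is two-sided, and a
   deviation exactly at the tolerance passes ("greater than").
3. **Stress–strain conversion** — stress = baseline-subtracted force /
   plug area (50.3 mm²); strain = travel past contact / *measured*
   thickness. Measured thickness is the more faithful denominator and
   differs from nominal by at most 5% for any sample that survives
   validation.
4. **Robust loess smoothing** — local quadratic regression with tricube
   weights and 5 bisquare iterations over a 75% kernel
   (`stats::loess(family = "symmetric", surface = "direct")`). The large
   span suppresses localized artifacts (escaping bubbles) while leaving
   the slow trend; exactly linear data pass through unchanged.
5. **Modulus regression** — OLS of smoothed stress on strain over the
   inclusive 5–15% strain window; the window R² is the linearity score.
6. **Rejection rules**, in order: thickness, E > 0, R² ≥ 0.5; the first
   failure is recorded. Batch means average valid samples only.

`sim_compression_trace()` emulates the rig geometry: the platen starts a
known gap (0.3 mm) above the *nominal* sample surface, so a sample that
is thinner than nominal shifts the contact position by exactly the
thickness deficit. Artifacts (bubble spikes, load drift, smooth
nonlinearity) are parameterized, not physically modelled — their purpose
is to exercise the rejection rules. Drift is applied over the compression
phase: a drifting pre-contact baseline would defeat any threshold
detector, which is a failure mode outside the scope of these rules.
Sampling is 10 Hz, giving ≈ 2,350 samples over the 200 s run.

## Fiber morphometry

Confocal reflectance images of the fiber network are analyzed by:

1. histogram equalization;
2. multi-scale 2-D Frangi vesselness: at each scale the scale-normalized
   Hessian eigenvalues ($|\lambda_1| \le |\lambda_2|$) give
   $R_B = \lambda_1/\lambda_2$ and $S = \sqrt{\lambda_1^2+\lambda_2^2}$,
   combined as $V = \exp(-R_B^2/2\beta^2)(1 - \exp(-S^2/2c^2))$ for
   bright ridges ($\lambda_2 < 0$), with β = 0.5 and c = half the maximum
   Hessian norm of the image at that scale; the response is the maximum
   over scales spanning 0.5–2 × the expected diameter $D_{exp}$ = 0.4 µm
   in steps of 0.5 $D_{exp}$;
3. Otsu binarization, removal of connected components smaller than a
   $D_{exp}$-diameter circle, then morphological opening and closing with
   a disk of diameter $D_{exp}/4$ (rounded up to ≥ 1 px);
4. fiber diameters: 2 × the Euclidean distance transform of the
   foreground evaluated on the Zhang–Suen skeleton (the distance of each
   fiber's central pixel to the nearest background pixel is its radius);
5. pore diameters: 2 × the distance transform of the background evaluated
   at the regional maxima of that map, one sample per maximum plateau —
   the inscribed-circle convention, and a documented, testable equivalent
   of an iterative shrink-to-point operator.

Open design points and how they were resolved:

* **Scale convention.** Whether filter "scales" are Gaussian σ values or
  expected diameters in pixels is ambiguous; both bracket the same
  octave. The default treats a scale as a ridge FWHM
  (σ = scale_px/2.355), since the scale range is specified in terms of an
  expected *diameter*; the alternative is selectable via
  `fiber_config(scale_convention = "sigma")`.
* **Hessian discretization.** Gaussian smoothing (`EBImage::gblur`)
  followed by central differences with *edge-replicated* borders —
  zero-padded differences fabricate enormous boundary curvature that
  would dominate the max-norm constant c.
* **Skeleton spurs** are not pruned by default; pruning is available via
  `fiber_config(prune_spurs = TRUE)`.
* Empty masks, all-background images, and constant images are flagged
  degenerate rather than erroring.

`sim_fiber_image()` renders gently curved chords with a Gaussian
cross-section whose FWHM is the ground-truth diameter, composited by
maximum intensity (reflectance ridges do not add), with random occlusion
gaps (20% of each fiber's length; reflectance fibers look discontinuous
because near-field fibers block reflected light) plus white detector
noise (SD 0.15 of the fiber peak — reflectance imaging of sub-resolution
fibers is genuinely low-SNR). The default density, 12 fibers across a
512-px (28 µm) field, was chosen so that the *true* mean pore diameter of
the rendered network (≈ 2.0 µm, measured on the noiseless, occlusion-free
half-maximum mask) matches the pore scale observed in real gels
(≈ 1.6–2.5 µm). The generator does not emulate out-of-plane structure,
intensity variation along fibers, or the optical point-spread function —
so passing tests demonstrate correct geometry recovery under noise and
occlusion, not full optical realism. On these networks the pipeline
recovers the 0.4 µm generating diameter to within ≈ 15% (slightly low:
Otsu cuts the vesselness ridge inside its half-maximum support) and mean
pore diameter within a few percent.

Test and acceptance runs use 512-px images; the problem sizes throughout
the suite were selected so the whole chain is exercised at full fidelity
while keeping simulation volumes modest.

## FRAP diffusivity

A horizontal stripe (10 px high, 150% of the image width, so the profile
depends only on the stripe-normal coordinate) is bleached into a
fluorescent dextran field; recovery is imaged every 1.5 s. The analysis:

1. **Pre-bleach subtraction** — the mean of the pre-bleach frames is
   subtracted from every post-bleach frame, cancelling static background
   heterogeneity exactly and leaving the stripe as a negative-going
   Gaussian on ≈ 0 background.
2. **Profile fits** — each frame is collapsed by averaging along the
   stripe; a Gaussian with free amplitude, centre, width, and offset is
   fitted by Levenberg–Marquardt least squares. Frames whose fitted dip
   is not resolvable above the residual noise (SNR < 3) are unusable.
3. **Variance growth** — for 1-D diffusion normal to the stripe,
   $\sigma^2(t) = \sigma_0^2 + 2Dt$, so D is half the slope of the OLS
   regression of σ² on time (time origin at the first post-bleach frame —
   the offset only moves the intercept). Width growth rather than
   amplitude decay is the estimator because it is robust to intensity
   scaling and residual background. Frames whose width jumps more than
   80% relative to the last accepted frame are dropped (a guard against
   unstable fits when diffusion outruns the frame rate); validity then
   requires regression R² ≥ 0.9 and D ≥ 0. A negative fitted slope is
   reported as `no_signal` (the rejection vocabulary has no separate
   negative-slope class; a high-R² negative slope means no resolvable
   spreading).

`sim_frap_sequence()` uses the exact analytic solution for a rectangular
initial deficit under 1-D diffusion (a superposition of error functions,
whose spatial variance is $h^2/12 + 2Dt$), plus a static smooth
heterogeneity field, frame noise, and a bleach-to-first-readout delay of
half a frame interval. The analytic forward model is validated in the
test suite against an independent explicit finite-difference integrator
with reflecting boundaries. Estimator recovery is within 10% for
D = 10–250 µm²/s at the default 512-px field; smaller fields truncate
the spread profile at high D and are used in tests only with slower
probes. `stokes_einstein_D()` provides the $k_B T / 6\pi\eta R_H$
reference for comparison.

## Empirical property models

Fabrication parameters are coded onto [0, 1] over the experimental
ranges: $C' = (C-4)/6$, $T' = (T-23)/14$, $pH' = pH - 7.4$, and
$(R_H^{-1})' = (R_H^{-1} - 1/8.5)/(1/1.4 - 1/8.5)$ — the inverse-radius
coding makes diffusivity approximately linear in the coded parameter
(Stokes–Einstein scaling). The packaged constants use the exact range
endpoints, so the design corners code exactly to 0 and 1 (published
renderings of the inverse-radius transform round them to 0.118 and
0.597).

`fit_property_model()` mirrors the two-pass screening procedure used to
derive the published models: pass 1 fits all coded main effects plus all
pairwise interactions by least squares; pass 2 refits keeping main
effects with p < 0.05 and interactions with p < 0.01. Hierarchy is
enforced — a main effect participating in a retained interaction stays
regardless of its own p-value (whether the original screening enforced
hierarchy is not documented; the published half-time model is consistent
with it). On zero-residual input, exactly-zero coefficients are treated
as non-significant and all others as significant, so noiseless tables
reproduce the generating structure identically. Rank-deficient designs
error, listing the aliased terms.

The packaged published models (`published_models()`) carry the printed
coefficients verbatim. One ambiguity is preserved rather than resolved:
the diffusivity model's pH × inverse-radius interaction is printed as
0.37, which equals its *normalized* sensitivity entry — either the
printed equation lists the already-normalized value (implying an
unnormalized coefficient of 0.37 × 190.23 ≈ 70.4) or the normalization
table is internally inconsistent. Both readings are packaged
(`interaction = "as_printed"` (default) or `"rescaled"`); the term
vanishes at the baseline condition either way. Similarly, the published
sensitivity table lists −0.78 for the half-time concentration term where
the coefficients give −12.69/17.45 ≈ −0.73; `sensitivity()` always
computes from the coefficients. Normalization is to the largest-magnitude
*non-intercept* coefficient per property — required for the temperature
terms to normalize to ±1, as the intercepts can exceed every slope.

Monte-Carlo calibration: with plausible replicate noise (SD 2 min, 500 Pa,
0.25 µm, 8 µm²/s — the order of the experimental scatter implied by the
reported standard errors) and 4 replicates per cell of the full factorial,
the true coefficients fall inside the pass-1 95% confidence intervals in
≈ 95% of coefficient × seed checks, comfortably above the 90% design
requirement. Coverage is assessed on the pass-1 (full) fit so that term
selection cannot bias it, and is aggregated over coefficient × run events
(joint all-coefficients-per-run coverage would be bounded near
$0.95^k$ by construction and would not measure calibration).

## Inverse design

`design_condition()` grid-searches the coded domain (step 0.01 on free
axes; temperature is restricted to the two experimental levels by
default, since polymerization temperature is set by available incubators)
maximizing a Derringer-type composite desirability: linear ramps
$d = \max(0, 1 - |pred - target|/band)$ for target objectives (band
defaulting to the 95% prediction half-interval for data-fitted models and
10% of the target for the packaged models, which carry no residual
information), min–max rescaled predictions for maximize/minimize, and a
weighted geometric mean composite — so any objective at zero desirability
zeroes the composite, and mutually unsatisfiable objectives produce an
explicit warning rather than a silent compromise. Ties within numerical
tolerance are reported. Targeting E = 2000 Pa at C = 6 mg/ml, T = 23 °C
returns pH 7.82, and E = 4000 Pa at T = 37 °C returns pH 7.50 — the
algebraic inversions of the modulus equation, recovered to grid
resolution.

## Known limitations

* The analysis pipelines are validated against synthetic data with known
  ground truth, not against the original instrument data (which is not
  published); agreement with the printed per-condition means is therefore
  out of scope.
* The fiber generator's occlusion and noise are statistical stand-ins;
  absolute diameter accuracy on real reflectance images depends on the
  optical transfer function, which is not modelled.
* The published-model layer is strictly an interpolation device: outside
  the coded unit box predictions are extrapolations and require an
  explicit override.
* Compression analysis assumes linear elasticity over the regression
  window; poroviscoelastic relaxation and stress-relaxation protocols are
  out of scope.
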