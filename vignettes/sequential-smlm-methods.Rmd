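---
title: "Sequential single-fluorophore SMLM: models, estimators and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential single-fluorophore SMLM: models, estimators and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(seqsmlm)
```

## The problem

Multi-target super-resolution imaging with organic dyes is limited by how
few fluorophores blink well: duty cycle, photon yield, switching fatigue and
buffer sensitivity all vary strongly between dyes, and multi-color optics
add chromatic registration errors at the nanometre scale.  An alternative is
*sequential* imaging: label target 1 with the one dye that blinks best
(e.g. AlexaFluor 647), image it by dSTORM, destroy the remaining
fluorophores (photobleaching plus chemical quenching), label target 2 with
the *same* dye, re-image, and overlay the reconstructions.  Two quantities
decide whether this works:

* **cross-talk** — the fraction of localizations from the previous target
  that survive photodestruction into the next round's image, and
* **overlay precision** — how accurately the sample can be re-registered
  between rounds, since no fiducial common to both images exists.

`seqsmlm` implements the full computational side of such an experiment:
synthetic data generation, maximum-likelihood localization, fiducial-free
brightfield registration, reconstruction/overlay, and the cross-talk and
shift estimators, each testable against ground truth.

## Imaging and localization model

Pixel $(i,j)$ of a raw frame holds ADU counts; photon conversion is
$n = \max\{0, (\mathrm{ADU} - \mathrm{offset}) \times g\}$ with $g$ the gain
factor in photons/ADU.  A candidate emitter becomes a $9\times9$ pixel
fitting region (0.92 µm² at the 0.1067 µm pixel).  The expected photon
count in ROI pixel $(i,j)$ is the pixel-integrated 2D Gaussian PSF

$$\mu_{ij}(\theta) = I\,\Delta E_x(i)\,\Delta E_y(j) + b,\qquad
\Delta E_x(i) = \tfrac12\left[\operatorname{erf}\!\left(\tfrac{i+1-x}{\sqrt2\sigma}\right)
 - \operatorname{erf}\!\left(\tfrac{i-x}{\sqrt2\sigma}\right)\right],$$

with $\theta = (x, y, I, b)$ and fixed, known PSF width $\sigma$ (default
1.0 px ≈ 107 nm; the PSF width is configuration, not a claim, since it is a
property of the instrument).  Pixel $i$ spans $[i, i+1)$ in continuous
pixel units — one convention, used everywhere in the package.

The fit maximizes the Poisson log-likelihood
$\mathcal L = \sum_k d_k \log \mu_k - \mu_k$ with per-parameter (diagonal)
Newton–Raphson updates, 20 iterations maximum, convergence at $10^{-4}$ px /
$10^{-2}$ photons.  Initialization: photon-weighted centroid for $(x,y)$,
ROI minimum for $b$, remaining mass for $I$.  Near the photon floor
(≈500 photons) a minority of fits reaches the iteration cap a hair short of
the step tolerance while already sitting at the optimum; they are flagged
unconverged and rejected by the filter, which costs a few percent of dim
localizations and no accuracy.

Precisions come from the Cramér–Rao lower bound: with Fisher information
$F_{ab} = \sum_k \mu_k^{-1} (\partial_a \mu_k)(\partial_b \mu_k)$, the
reported $\sigma_x, \sigma_y$ are $\sqrt{(F^{-1})_{aa}}$ scaled to nm.  The
Monte-Carlo efficiency of the fitter is checked against this bound (RMSE ≤
1.15·CRLB at 500–5000 photons).

### Candidate detection

Published MLE localization pipelines describe their two-step noise filter
only loosely; the package uses the difference of two separable boxcar smoothings
(radii 2 and 4 px), strict local maxima in a 5×5 neighborhood, merging
within one ROI half-width.  At the 4σ operating point (σ = the smoothed
pure-background noise level, `candidate_threshold_sigma()`), the measured
false-candidate rate on background-only frames is well below 0.1 per frame
while 250-photon emitters are still detected with probability ≈ 1.

### Goodness of fit

Overlapping emitters and other model violations are rejected through a
p-value threshold (0.01).  The statistic is the Poisson deviance
$D = 2\sum_k [\mu_k - d_k + d_k \log(d_k/\mu_k)]$.  Referred directly to
$\chi^2_{77}$, $D$ is miscalibrated at dSTORM count levels — at $I=1000$,
$b=5$ the null fraction with $p<0.01$ is ≈2%, because $E[D_k] > 1$ for
small Poisson means.  The package therefore rescales $D$ by its estimated
null expectation, $\sum_k E[D_k(\mu_k)]/81$, where $E[D_k(\mu)]$ is
computed exactly (by summation over the Poisson pmf on a cached grid)
before the $\chi^2_{77}$ reference.  This restores the stated calibration
(1.0% at the generator defaults) and leaves the two defining properties
untouched: $d=\mu$ gives $D=0$, $p=1$, and an unmodeled second emitter of
equal brightness 3 px away is rejected in >90% of draws.  At very low
backgrounds ($b \lesssim 1$) the corrected test is conservative (rejects
less than 1%), which only makes the filter milder there.

### Acceptance thresholds

A localization is accepted iff the fit converged, background ≤ 100
photons/pixel (upper end of the 50–100 working range; configurable),
total photons ≥ 250, and the goodness-of-fit p ≥ 0.01.  The three threshold
tests commute and are idempotent.

## Brightfield registration

Re-registration between rounds uses the cell's own brightfield contrast.
One iteration of `align()`:

1. acquire 21 brightfield images from −500 nm to +500 nm in 50 nm steps
   about the current z;
2. compute the NCC of each slice against the reference image, take the 9
   *consecutive* points centred on the argmax, fit a second-order
   polynomial, move to its vertex ("largest 9 points" is read as the
   contiguous window — the top-9 by value can be non-contiguous and break
   the fit; and the quadratic is preferred over the alternatively described
   Gaussian fit, being its small-offset logarithm and the method body's own
   wording);
3. estimate the lateral shift against the reference and move by it;
4. repeat until the per-iteration adjustments fall below 5 nm (x, y) and
   10 nm (z).

If the NCC is still rising at either end of the z scan the true peak was
not captured (e.g. an initial z error of 800 nm); the result is flagged and
marked non-converged rather than extrapolated.

The subpixel lateral estimator matters more than it looks.  On smooth
brightfield-like scenes the circular-FFT correlation peak is broad: its
curvature is tiny, edge effects bias the classic 3-point parabola, and the
resulting underestimation of small shifts (gain < 1) lets the iteration
stall at a fixed point up to tolerance/gain ≈ 7 nm from the truth.
`find_xy_shift()` therefore uses the FFT only for the integer peak
(hill-climbing on the overlap-region NCC guards against off-by-a-few
peaks), then estimates the fraction by Gauss–Newton minimization of the
resampled intensity difference — unbiased on smooth images — with the
parabola kept as a flagged fallback.  Verified accuracy is ≤ 0.05 px on
0.3 px shifts and ~0.002 px near zero.

Stage stabilization re-runs the alignment every 2000 frames against the
same reference; `simulate_stabilization()` returns the residual pose error
per frame under a linear + random-walk drift model.

## Synthetic world

All tests run against generated data; the simulator's defaults are fixed
once:

* **Structures**: lines with Gaussian cross-section (microtubules; default
  spread 20 nm ≈ antibody-decorated radius), rings (clathrin), uniform
  discs (receptor puncta).
* **Blinking**: discrete-frame two-state Markov chain, start dark,
  on-rate 5×10⁻⁴/frame, off-rate 0.5/frame, geometric bleaching at 0.1 per
  on→off transition, 1000 mean photons per on-frame, 5 background
  photons/pixel — typical dSTORM sparsity consistent with the 250-photon
  acceptance floor.  (The two-round experiment raises the on-rate to
  10⁻³/frame and lowers the mean to 500 photons so that 10 segments reach
  ≥2000 accepted localizations at ≈7–8 nm CRLB within 1500 frames.)
* **Camera**: 0.1067 µm pixel, 256×256 native frame (demo crops to
  128×128), offset 100 ADU, gain 0.5 photons/ADU.  Shot noise is Poisson
  only — EMCCD excess noise is deliberately *not* modelled, matching the
  analysis likelihood; real EMCCD data would show ≈√2 worse precision than
  the CRLB computed here.
* **Brightfield**: seeded Gaussian random field, correlation ≈1 µm
  laterally and 10 z-steps (500 nm) axially, strictly positive.  The
  lateral size defaults to the native 256×256 frame: on smaller textures
  the 9-point quadratic z fit inherits realization asymmetry of the NCC
  curve and can carry a texture-dependent z bias beyond the 10 nm
  tolerance (observed ≈11 nm on one 128×128 realization, coupling ≈5 nm
  into x–y through slice interpolation).  At 256×256 the asymmetry
  averages out and 50-pose recovery passes on every texture tried.
* **Photodestruction**: per-emitter independent survival with probability
  equal to the residual fraction (`inject_residuals()`), giving movies
  with exactly known cross-talk.

What a green test therefore establishes: estimator correctness against
this stated world.  What it does not: robustness to EMCCD excess noise,
sCMOS pixel maps, sample deformation between rounds, defocus, or
structured (non-Gaussian) brightfield contrast.

## Reconstruction and overlay

Each accepted localization is rendered as a 2D Gaussian with σ equal to
its CRLB precisions and **unit integral** (truncated at 4σ), on a 10 nm
grid by default.  "Unit intensity" is read as unit integral rather than
unit amplitude so that image mass counts localizations — this makes
count-based quantities (e.g. cross-talk) computable from images as well as
tables.  Precisions below a quarter SR pixel are floored and flagged.
Multi-color composition assigns each image a color index [R,G,B] ∈ [0,1]³,
scales it per pixel by the max-normalized image, sums across targets, and
renormalizes any pixel exceeding [1,1,1] by its maximum digit.  Normalizing each
channel by its maximum (rather than a fixed photon scale) is a choice;
per-image max is used and configurable contrast factors (the
3× residual-image boost) are applied via `contrast_scale()`.

## Quantification

**Cross-talk** — `crosstalk()` counts accepted localizations in ~2×2 µm
subregions before and after photodestruction and reports
$100 \cdot n_\text{after}/n_\text{before}$ per region plus the mean.
Regions are a regular grid masked by a minimum before-count (default 50),
standing in for the manual subregion selection done on real cells.
The estimator is verified unbiased at survival fractions 0.002–0.126 (the
published 0.2%–12.6% scale).

**Global shift** — subpixel image shift between the two reconstructions
(same estimator as the registration), scaled by the SR pixel.  The
magnitude convention is $\sqrt{dx^2+dy^2}$.

**Local shift** — two endpoints on a straight segment define a rectangle
(half-width 150 nm by default: microtubule width plus localization
spread; no canonical width exists, so it is configuration).  Both channels'
in-rectangle localizations are rotated by −arctan(slope) about the first
endpoint, the perpendicular coordinates
are histogrammed in 5 nm bins (zero bins retained, matching the
histogram-plus-curve depiction rather than a raw-coordinate MLE), a
3-parameter Gaussian is least-squares fitted per channel, and the shift is
the difference of fitted means, signed toward increasing rotated
perpendicular coordinate.  Fit failures and σ exceeding the half-width are
flagged; moment estimates serve as the fallback.

## The two-round acceptance experiment

`overlay_precision_experiment()` chains everything: 10 line segments
imaged twice (1500 frames each round), a uniform random pose error
(±250 nm lateral, ±300 nm axial) injected between rounds and corrected by
`align()` at the 5/5/10 nm tolerances, the *uncorrected residual* applied
to round-B ground truth, both movies localized, and the per-segment local
shifts measured.  The acceptance criterion asks for a median absolute
local shift ≤ 10 nm over 10 replicates; the measured value is typically
≈0.5–1 nm, dominated by the registration residual (≤ ~3 nm per axis) and
the profile-fit error (≈0.5 nm at N = 2000).

## Numerical choices and degenerate inputs

* All-zero ROIs return an $I=0$ fit rather than an error; border-clipped
  ROIs are discarded (only full 9×9 regions are fitted).
* Singular Fisher matrices flag the record; flagged and unconverged
  records never pass the filter.
* ADU values clip at 0 and 65535 (16-bit camera); photon conversion clamps
  at zero.
* `ncc()` refuses zero-variance images; `global_shift()` refuses
  featureless reconstructions.
* Every stochastic function takes an explicit seed and restores the
  caller's RNG state; equal seeds give bit-identical output.
* TIFF I/O is a minimal baseline codec (little-endian, uncompressed,
  grayscale, uint16/float32, multi-page) written for this package because
  no TIFF-capable R package is available in the target environment; it
  was validated against Python's `tifffile` during development.

## Known limitations

* Single-emitter fitting only; overlapping emitters are rejected, not
  deconvolved.
* 2D localization; axial structure enters only through registration.
* No EMCCD excess noise or sCMOS per-pixel noise models.
* Rigid translation registration only — no rotation or scale estimation.
* The brightfield texture is a statistical stand-in, not an optical model
  of phase contrast.
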