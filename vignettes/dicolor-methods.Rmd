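---
title: "Digital-image colorimetry with PLS1 calibration: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital-image colorimetry with PLS1 calibration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

A molecularly imprinted polymer (MIP) sensor patch adsorbs a colored
analyte — here the yellow azo dye tartrazine — and deepens in color with
concentration. A smartphone photograph of the patch, taken under fixed
illumination in a closed holder, is the entire instrument: the mean color
of a 16 × 16 pixel region of interest (ROI) is the raw signal, and a
multivariate calibration maps color to concentration in mg/L.

`dicolor` implements that pipeline end to end: ROI statistics from the
image, expansion of RGB into an eight-channel color feature vector,
a PLS1 calibration with cross-validated model-order selection and
working-range truncation, and the figures of merit used to judge such a
method (limit of detection, repeatability, relative error against a
chromatographic reference).

## The color feature vector

From a real-valued RGB triple $(R, G, B) \in [0,255]^3$ (replicate means
are fractional) the package computes, with $\max = \max(R,G,B)$ and
$\min = \min(R,G,B)$:

* **Intensity** $I = (R+G+B)/3$, kept on the 0–255 scale;
* **Hue** $H$ (degrees): the usual piecewise hexagonal formula,
  $60 (G-B)/(\max-\min) \bmod 360$ when $\max = R$, plus the
  $120^\circ$ / $240^\circ$ sectors for $\max = G$ and $\max = B$;
* **Saturation** $S = (1 - \min/\max) \cdot 100$ (percent; 0 for black);
* **Value** $V = \max / 255 \cdot 100$ (percent);
* **Lightness** $L = (\max+\min)/2/255 \cdot 100$ (percent).

Two conventions are deliberately pinned. First, the scaling: $S$, $V$,
$L$ are reported in percent and $I$ raw on 0–255, matching how channel
tables are conventionally printed in digital-image colorimetry (and the
packaged benchmark table). Second, the achromatic case: when
$\max = \min$ the hue is mathematically undefined, and the package
returns `NA` rather than a fabricated angle. The sentinel is resolved to
0° only when a feature matrix is assembled, with a warning — gray
patches should be conspicuous, not silently absorbed.

Conversion is applied to the ROI *mean* RGB, not per pixel: the sensor
patch is nominally uniform, and the mean is the quantity replicated in
practice. The channel math itself is exact on real inputs; integer
quantization is a property of image capture and is modeled in the
synthetic generator, not in the conversion.

## Imaging conventions

Images are height × width × 3 arrays on the 0–255 scale. The ROI is a
square window specified by a 0-based center and side length (default 16),
half-open on both axes, so an even side places the center at the top-left
pixel of the central 2 × 2 block. The default center is the image center,
reflecting a fixed sample-holder geometry; off-center captures use an
explicit `roi_spec()`. Per-channel summary statistics use the arithmetic
mean and the $n-1$ standard deviation, matching replicate-SD semantics of
triplicate tables. PNG and TIFF are treated as first-class (lossless);
JPEG is read but warns, because lossy compression perturbs exactly the
statistics being measured.

## PLS1 calibration

The calibration relates the $n \times 8$ channel matrix $X$ to
concentration $y$ with single-response partial least squares, fitted by
NIPALS. Choices that the literature leaves open are fixed as follows:

* **Preprocessing: autoscaling** (column mean-centering and unit-SD
  scaling). The channels live on wildly different scales — blue is
  ≈ 1–3 while red is ≈ 200 — so covariance-maximization without scaling
  would be dominated by the red channel. Autoscaling is the standard
  chemometric default, and it buys an exact invariance: multiplying any
  feature column by a positive constant leaves predictions unchanged.
* **Deflation of X only.** For a single response, deflating $y$ is
  redundant; scores are orthogonal either way. An independent SIMPLS
  implementation in the test suite cross-checks the predictions.
* **Saturation.** All eight channels are smooth functions of three RGB
  levels, so the effective rank of $X$ is often well below 8. When
  deflation exhausts the covariance (residual norm below $10^{-8}$ of
  the first component's), the decomposition has saturated; requesting
  more components returns the saturated solution rather than dividing by
  numerical zero. The fitted object records both the requested and the
  effective order.
* **Model order by leave-one-out CV.** With ~15–21 training samples,
  LOO is the conventional, deterministic choice. Each fold refits the
  centering and scaling as well — anything less leaks the held-out
  sample. The selected order maximizes the validation $R^2$, with exact
  ties broken toward the smaller model.
* **Working range.** `working_range_scan()` re-runs the whole selection
  pipeline on each candidate upper concentration bound and keeps the
  bound with the best cross-validated model. Truncation is explicit: the
  model object carries its training range, and predictions outside it
  are flagged (`below-range` / `above-range`) but never clipped —
  clipping would bias the detection-limit estimate.

## Figures of merit

* **LOD** = $3.3 \, s_\mathrm{res} / b$, where $s_\mathrm{res}$ and $b$
  are the residual SD and slope of the straight line fitted to predicted
  versus measured concentration over the training set. The 3.3
  multiplier is the ICH detection-limit convention; it is exposed as a
  parameter (10 gives a quantification limit) because reports frequently
  differ on it.
* **Repeatability** is the percent relative SD, $100 \cdot s/\bar{x}$
  with the $n-1$ SD, of replicate found concentrations; the denominator
  is the mean found value, not the nominal.
* **Relative error** against a reference method is signed,
  $100 (x_\mathrm{found} - x_\mathrm{ref}) / x_\mathrm{ref}$. Note it is
  antisymmetric under exchanging the two methods only up to the change
  of denominator.

## The synthetic generator, and what passing tests mean

No raw per-replicate data exist for the benchmark study; only triplicate
means ± SDs per concentration level are published. The generator
therefore *reconstructs* plausible replicate sets rather than replaying
real ones, and every stochastic entry point takes a mandatory seed.

**Channel-table reconstruction** (`reconstruct_replicates()`) has two
modes, and the distinction matters:

* `consistent` (default): replicate RGB triples are drawn from
  Gaussian(mean, SD) per level using the published R/G/B columns,
  clipped to [0, 255], and the five derived channels are recomputed from
  each replicate's RGB. Every generated row is a valid channel vector
  ($I$ exactly the RGB mean, $V \ge L$, and so on).
* `independent`: all eight channels are drawn independently from their
  published means and SDs. This breaks the functional link between RGB
  and the derived channels — deliberately. The original workflow
  converted each replicate's *integer* RGB with an external tool and
  rounded the result, so the published derived channels carry
  per-channel conversion noise that the consistent mode cannot and
  should not reproduce. The published sample rows (M1–M5) are data of
  exactly this kind.

That last point drives a subtle design decision. A consistent-mode
calibration has essentially no variance in the directions orthogonal to
the RGB manifold, so a high-order PLS model assigns those directions
enormous coefficients; feeding it a *printed* channel vector — which
sits slightly off the manifold because of conversion rounding — produces
wild predictions. This is a train/test mismatch, not a property of the
method: the original calibration data carried the same conversion noise
as the sample rows (their printed derived-channel SDs embed it visibly).
Experiments that predict printed sample vectors therefore reconstruct
the calibration in `independent` mode, so that training and test data
share the same noise structure. Experiments on calibration statistics
($R^2$, LOD), which never leave the reconstruction, use the consistent
default.

**Image rendering** (`render_patch()`) fills a frame (default 64 × 64)
with the color interpolated from a piecewise-linear
concentration-to-RGB response, adds per-pixel Gaussian sensor noise
(default SD 1), an optional linear illumination ramp, and optional 8-bit
quantization. Repeated renders at one concentration differ only by
sensor noise; an optional capture-level color offset (drawn from the
per-level replicate SDs) is available for stress tests that need
replicate-scale variation of whole captures. The response knots default
to the published standards from 5 mg/L upward. The 1 mg/L row is
excluded from the knots: its printed intensity is inconsistent with its
printed RGB by ~6 units, its blue SD (23.4) is an order of magnitude
above every other entry, and its red mean breaks the monotone decrease
the other standards follow. The row is nevertheless kept verbatim in the
packaged table, and the calibration-reconstruction grid retains the
1 mg/L level (only its anomalous *derived* values are sidestepped by
recomputation). `response_model(extend_lower = 0)` extends the first
segment linearly downward when patches below 5 mg/L must be rendered.

What the generator does *not* emulate: LED spectra or any physically
based optics, camera response nonlinearity, patch texture or
segmentation error, and inter-device variation. Passing tests
demonstrate that the algorithms are correct and that the published
summary statistics are recoverable from their own noise model — not
that the method generalizes across hardware.

Clipping note: truncating Gaussian draws at [0, 255] biases moments only
where the Gaussian mass outside the range is non-negligible; with the
published SDs that occurs only for the blue channel of the anomalous
1 mg/L row. Generator-fidelity tests therefore check moments at levels
where the clipped mass is negligible.

## Recorded discrepancies in the benchmark tables

Three internal inconsistencies in the published tables affect what can
be reproduced, and are handled as follows:

* The repeatability table lists four components for the 0–20 mg/L model
  while the range-summary table and abstract say five; the package
  follows the latter (A = 5 for 0–20 mg/L, A = 4 for 0–30 mg/L).
* The printed relative error for sample M5 (15.9 %) does not follow from
  its own printed found/reference pair (14.0 vs 12.6 mg/L gives
  11.1 %); the recomputation is asserted as arithmetic dictates, and the
  corresponding benchmark assertion documents the mismatch.
* The published model-order choice (five components on 0–20 mg/L) is
  checked as a modal outcome of seeded reconstructions; because the
  reconstruction cannot restore the original data's full effective rank,
  the mode can land at four, adjacent to the published choice.

## Problem sizes and numerical settings

Stochastic benchmark checks use 100 seeded reconstructions of the
triplicate design (15 samples for the 0–20 mg/L range, 21 for 0–30) and
compare medians; generator fidelity uses 10⁴ draws per level;
colorspace oracle comparisons use 10³ random triples at $10^{-6}$;
PLS-vs-least-squares and CV-vs-brute-force oracles are held to
$10^{-8}$–$10^{-9}$. Repeatability simulations run 10 capture cycles per
concentration on 64 × 64 frames. Model files store all constants at 17
significant digits, so a save/load round trip reproduces predictions
bit-for-bit.

## Limitations

* The calibration is empirical and range-bound; nothing constrains
  predictions outside the training span beyond the range flags.
* The hue sentinel resolution (0° at feature assembly) is a convention;
  calibrations mixing chromatic and achromatic patches get a data-quality
  warning and deserve suspicion.
* LOD inherits the uncertainty of the 3.3σ/slope convention; with
  reconstruction noise in place of raw replicates it is a bracket, not a
  point estimate.
* JPEG inputs are supported for convenience, but quantitative work
  should use lossless captures.
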