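---
title: "Correcting pixel quantum-efficiency artifacts in sCMOS SMLM analysis"
author: "sCMOSrqe package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting pixel quantum-efficiency artifacts in sCMOS SMLM analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sCMOSrqe)
```

## The problem

Scientific CMOS cameras read every pixel through its own amplifier, so the
offset $o_i$, gain $g_i$ (ADU per photo-electron) and read-noise variance
$var_i$ differ from pixel to pixel, and single-molecule localization
microscopy (SMLM) analysis routinely compensates for them.  The pixels of
some sensors additionally differ in their *relative quantum efficiency*
(RQE): the probability that an incident photon is converted to a
photo-electron varies by a few percent between neighboring pixels, with a
characteristic vertically striped spatial pattern, and tends to be
anti-correlated with the gain (pixels that convert fewer photons amplify
more, so flat-field images look deceptively uniform).  An analysis that
models every pixel as equally sensitive then

* preferentially *detects* emitters that happen to sit on high-RQE pixels
  whenever the detection threshold cuts into the bulk of the significance
  distribution, imprinting the sensor's stripe pattern on the
  reconstruction; and
* *biases the fitted position* of every emitter, because the RQE gradient
  across the PSF masquerades as a shift of the photon distribution.  With
  vertical stripes the bias is concentrated in the x coordinate and can
  reach several nanometers -- comparable to the localization precision
  itself.

This package implements the camera calibration that measures
$(o_i, var_i, g_i, rqe_i)$ per pixel, a forward simulator of such a
camera, detection and fitting with and without the RQE correction, the
matching Cramer-Rao lower bound (CRLB), and the evaluation metrics that
quantify the artifacts.  Everything runs on synthetic data generated by
the package itself.

## Camera model and calibration

The forward model for the ADU count of pixel $i$ given an expected photon
image $\lambda_i$ is

$$ x_{raw,i} = g_i \cdot \mathrm{Pois}(rqe_i\,\lambda_i)
   + \mathcal{N}(0, \sqrt{var_i}) + o_i . $$

Calibration uses one dark movie and $K$ movies at increasing flat
illumination (`calibrateCamera()`):

* **Offset / read noise** -- per-pixel temporal mean and *population*
  variance (divisor $M$) of the dark movie.
* **Lamp correction** -- the variance of the per-frame spatial-average
  intensity is subtracted from every pixel's temporal variance before dark
  subtraction, removing common-mode illumination flicker (a few percent of
  the variance at high intensity); corrected variances are clipped at zero
  and the clip count is reported.
* **Gain** -- the photon-transfer method: for each pixel a straight line is
  fit (equal weights) to corrected variance vs corrected mean over the $K$
  levels plus an appended origin point; the slope is $g_i$.  The intercept
  is retained as a diagnostic only.  No mean-variance non-linearity is
  modeled.
* **RQE** -- the highest-level mean image is converted to photo-electrons,
  divided by itself smoothed with a normalized 10 x 10 uniform kernel.
  The local normalization cancels smooth illumination non-uniformity, so
  the result is *relative* QE with local mean 1.  For the even-sized
  kernel the averaging window of output pixel $i$ spans input pixels
  $i-5 \dots i+4$ (the convention of the standard n-dimensional uniform
  filter), and edges use replicate padding so edge pixels still see a
  full-weight kernel; both choices are configurable and documented so
  results are bit-reproducible.

At 20k frames per movie the per-pixel RQE measurement uncertainty is at
the 1% level, dominated by the gain estimate (relative error
$\sim\sqrt{2/M}$ through the variance estimates); the round-trip test
with the package's own simulator checks the $1/\sqrt{M}$ scaling.

## Synthetic sensors

`synthCalibration()` generates calibration maps emulating a measured
camera: RQE standard deviation 4% by default, split into broad vertical
bands (Gaussian-correlated column profile, correlation length 3 columns,
45% of the variance), sharp column-to-column structure (35%) and pixel
noise (20%); gain std 4% with correlation $-0.9$ to the RQE field;
per-pixel read-noise variance uniform in 2-10 ADU^2 (0.7-1.6 e- rms at
the default gain of 2 ADU/e-); offset ~100 ADU.  The column-oriented
structure is what concentrates fitting bias in x.  Each map is a
deterministic function of its seed.

The emitter simulator provides the two study layouts: uniformly placed
blinking emitters (0.15 per um^2; two-state kinetics with geometric dwell
times, mean off 2 frames, mean on 1 frame) and a constant grid (20 px
spacing, margin half a spacing, on in every frame, uniform sub-pixel
jitter so the set spans sub-pixel phases -- without jitter the bias
measurement would sample only one phase).  Defaults: 250 photons per
frame per emitter, 20 background photons per pixel, Gaussian PSF of
sigma 1.5 px at 100 nm pixels.  The PSF is integrated over each pixel
(an error-function product); a center-sampled variant is available, and
simulator and fitter always use the same convention.  ADU are kept
real-valued by default (integer rounding is a flag): quantization adds
nothing to the questions studied here.

What the generator does *not* emulate: dark current and hot pixels,
non-linearity near saturation, rolling-shutter timing, emitter dipole
orientation, astigmatism or 3-D PSFs, and spatially structured
backgrounds.  Passing tests on this generator therefore demonstrate the
correctness of the estimators under the stated model, not robustness to
every property of real movies.

## Detection and the significance statistic

Frames are pre-processed to photo-electrons either ignoring RQE,
$x_{pre,i} = (x_{raw,i}-o_i)/g_i$, or correcting it,
$x_{pre,i} = (x_{raw,i}-o_i)/(g_i\,rqe_i)$.  Candidates are strict
8-neighbor maxima of the frame smoothed with a Gaussian of the PSF sigma
(ties are broken by the strictness; duplicates within $2\sigma$ keep the
higher significance).  Because of this smoothing, detection responds to
the *smoothed* RQE/gain maps, which the package computes with the same
kernel.

The SNSMIL-style significance of a candidate is defined precisely as:
signal = sum of the pre-processed image over a disk of radius $2\sigma$
minus the local background level (median of a $3\sigma$-$5\sigma$
annulus) times the disk area; noise = $\sqrt{b_{ref} A}$, the shot noise
of the background over the aperture with $b_{ref}$ the frame-global
median.  The global noise scale reflects the SNSMIL viewpoint that under
uniform illumination the noise level is a property of the imaging
conditions, and it is what makes uncorrected detection fully sensitive to
the local RQE (significance $\propto rqe$); an annulus-based noise
estimate would cancel half of the effect ($\propto\sqrt{rqe}$) and
cannot reproduce the observed severalfold count enrichment.  The aperture
radii are exposed in the function signatures.

In the grid (detection-bias) study the significance is instead computed
from the *fitted* parameters of each localization -- total fitted photons
$\theta_1 2\pi\sigma^2$ over $\sqrt{\theta_4 A}$ -- because that study
fits every emitter and thresholds afterwards.

A significance of 6 corresponds to a two-sided Gaussian tail probability
of $2\,\Phi(-6) \approx 2.0\times10^{-9}$.

## Fitting

Three estimators share one Levenberg-Marquardt core (compiled; damping
start $10^{-3}$, x10 / /10 schedule, convergence when the relative
objective decrease stays below $10^{-6}$ for two consecutive accepted
steps, at most 200 iterations; analytic gradients; Gauss-Newton
curvature):

* **Uncorrected Poisson MLE** -- minimizes the deviance
  $2\sum(f_i-x_i) - 2\sum x_i\ln(f_i/x_i)$ with the read-noise shift
  $f_i = f(\theta)+var_i$, $x_i = x_{pre,i}+var_i$, treating all pixels
  as equally sensitive.
* **RQE-corrected Poisson MLE** -- same data, model scaled per pixel:
  $f_i = rqe_i f(\theta)+var_i$.  Scaling the model rather than the data
  preserves the Poisson mean-variance relation, which is why this
  estimator restores CRLB performance.
* **Flat-field WLS** -- data divided by $flat_i\langle g\rangle$ with
  $flat_i = g_i rqe_i/\langle g\rangle$, model unscaled, weights
  $1/(x_i+var_i)$.

Unit convention (stated once, used everywhere): measured variances are
ADU^2; they enter the e- domain as $var_i/g_i^2$ (WLS:
$var_i/(flat_i\langle g\rangle)^2$).  MLE data values are clamped at
$10^{-6}$ e- (the deviance needs $x>0$); WLS weight denominators at
$10^{-3}$.  The background parameter is clamped at zero with a flag;
heights at $10^{-3}$.  ROIs are $2\lceil 3\sigma\rceil+1 = 11$ px;
initialization is deterministic (border-median background, peak minus
background height, intensity centroid position).  $\sigma$ is fixed at
1.5 px in all studies.

## CRLB

The Fisher information under the model $\mu_i = rqe_i f(\theta)+var_i$ is
$F_{mn} = \sum_i rqe_i^2/\mu_i \, \partial_m f \,\partial_n f$ over the
same 11 px ROI the fitter uses (so the bound describes the estimator
actually run), for the 4-parameter fixed-sigma set (bg, h, x, y) with an
optional fifth sigma parameter.  Bounds are the square roots of the
inverted matrix's diagonal; because they depend on where an emitter sits
on the striped sensor, figure-style numbers average the bounds over all
simulated emitter positions (median also reported).  Sanity limits: with
$rqe\equiv1$, $var\equiv0$ the matrix reduces to the plain Poisson form,
and the background-free x bound approaches $\sigma/\sqrt{N}$.

## The three studies and their design choices

`detectionBiasExperiment()` (grid layout) fits every emitter in every
frame with the uncorrected MLE, scores fit-based significances,
thresholds at their mean, and splits localizations by the smoothed-gain
quintile (top/bottom 20% of pixels) of their center pixel ("centered on"
= `round()` of the fitted position, the consistent reading under the
center-at-integer coordinate convention).  The RQE-corrected arm folds
the correction into the conversion (gain $\leftarrow g_i rqe_i$).
Independent replicates -- each with a fresh calibration draw -- are
pooled by summing counts, averaging over stripe realizations.  Whether
the two categories are still distinguishable after correction is tested
with a two-proportion test on the discard fractions (the claim under
test is threshold bias); the KS p-value on the full distributions is
also reported, but at pooled sample sizes KS responds to second-order
differences (the residual $\sqrt{rqe}$ spread modulation) that are not
threshold bias.

`enrichmentExperiment()` (blinking layout) identifies localizations
blindly and compares total counts on the top vs bottom smoothed-RQE
pixel quintiles.  The paper-style artifact appears when the typical
emitter significance is comparable to the threshold, so the operating
threshold is placed in the upper shoulder of the single-emitter
significance population: mean + 1 SD of the candidates above a 6-sigma
floor (the floor separates emitters from smoothed-noise maxima at this
photon budget; the floor-then-threshold pass is deterministic).  This
keeps detection partial (~15% efficiency) while leaving enough counts
for stable ratios.

`fittingBiasExperiment()` (grid layout, detection bypassed by seeding
ROIs at the known grid pixels) measures per-emitter precision (SD of
fitted positions over frames) and the precision-corrected RMS bias
$\sqrt{\max(0,\ \overline{d^2} - \overline{s^2/K})}$ per axis, where $d$
is the per-emitter mean deviation from truth and $s^2/K$ the sampling
variance of a $K$-frame mean.  The correction removes the finite-$K$
inflation; the statistic still has a positive noise floor of roughly
$\overline{s^2}/K\,\sqrt{2/n_E}$ in squared units, which is what "bias
consistent with zero" is measured against.  Error bars are
across-replicate SDs.

Problem sizes used by the reproduction script: 320 px frames, 150
frames x 4 replicates for the detection-bias study; 256 px frames, 800
frames x 3 movies for the enrichment study; 160 px frames, 500 frames x
5 replicates at 250 photons for the fitting study.  These are the sizes
at which the reported fractions and ratios are stable to a few percent
across seeds.

## Known limitations

* The significance aperture and noise conventions are one defensible
  reading of an underspecified published metric; absolute significance
  values (and hence discard fractions) shift by a few points under other
  apertures, which is why the studies report category *contrasts*.
* The RQE stripe generator is a three-component stochastic model chosen
  to match summary statistics (std, anti-correlation, stripe geometry),
  not a fitted model of any particular sensor.
* WLS weight denominators use the measured data, so at very low signal
  the WLS estimator inherits the usual small-count weighting bias; this
  is intrinsic to the method, not compensated.
* Only 2-D fixed- or free-sigma Gaussian PSFs; no multi-emitter
  deconvolution; no drift or registration.

## Reproducing the numbers

`scripts/acceptance.R --seed S --out results.json` reruns the three
studies at the sizes above and writes the headline quantities; the
package's test suite runs smaller versions of the same studies plus the
per-module unit and property tests.
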