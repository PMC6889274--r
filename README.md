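# sCMOSrqe

Quantum-efficiency-aware analysis of single-molecule localization
microscopy (SMLM) data from scientific CMOS (sCMOS) cameras.

Every pixel of an sCMOS sensor has its own amplifier, so offset `o_i`,
gain `g_i` and read-noise variance `var_i` vary pixel to pixel and are
routinely calibrated away.  Some sensors additionally show pixel-to-pixel
differences of ~4% in *relative quantum efficiency* (RQE), organized in
vertical stripes and anti-correlated with the gain.  Analyses that assume
uniform sensitivity then (a) preferentially detect emitters sitting on
high-RQE pixels — imprinting the stripe pattern on the super-resolution
reconstruction — and (b) systematically shift fitted positions by several
nanometers, mostly along x.  This package implements the calibration,
simulation, detection, fitting and bound calculations needed to measure
and remove these artifacts:

- **Calibration** (`calibrateCamera`): per-pixel offset and read-noise
  variance from a dark movie; gain by the photon-transfer method (line
  fit of temporal variance vs mean over illumination levels plus an
  origin point, with lamp-fluctuation variance correction); RQE as the
  converted flat image divided by its 10×10 uniform-filtered version
  (locally normalized to 1).
- **Simulation** (`synthCalibration`, `simulateMovie`): striped synthetic
  sensors (4% gain/RQE std, correlation −0.9) and pixel-faithful movies,
  `ADU = g·Pois(rqe·λ) + N(0, √var) + o`, with blinking-uniform or
  constant-grid emitters.
- **Identification** (`identifyMovie`): SNSMIL-style candidate detection
  on Gaussian-smoothed, pre-processed frames, with
  `x_pre = (x_raw − o)/g` (uncorrected) or `x_pre = (x_raw − o)/(g·rqe)`
  (RQE-corrected).
- **Fitting** (`batchFit`): sub-pixel 2-D Gaussian fits by
  Levenberg–Marquardt for three estimators — uncorrected Poisson MLE
  (deviance `2Σ(f−x) − 2Σ x ln(f/x)` with the read-noise variance shift),
  RQE-corrected MLE (`f_i = rqe_i·f(θ) + var_i`, which preserves Poisson
  statistics), and flat-field weighted least squares
  (`flat_i = g_i·rqe_i/⟨g⟩`).
- **CRLB** (`crlbBounds`, `crlbForEmitters`): Fisher information
  `F_mn = Σ rqe_i²/(rqe_i f(θ)+var_i) ∂f/∂θ_m ∂f/∂θ_n` and per-parameter
  lower bounds, position-dependent on a striped sensor.
- **Metrics** (`renderImage`, `countsVsRQE`, `precisionBias`,
  `detectionBiasReport`): super-resolution rendering, count–RQE
  correlation and quintile enrichment, precision and precision-corrected
  RMS bias against ground truth.

## Worked example

Round-trip a synthetic sensor through calibration, then quantify the
fitting bias of the uncorrected estimator:

```r
library(sCMOSrqe)

truth <- synthCalibration(c(64, 64), seed = 1)
series <- simulateIlluminationSeries(truth, nFrames = 3000, seed = 2)
cal <- calibrateCamera(series)
cal
#> CalibrationMap: 64 x 64 pixels
#>   offset   mean 99.96 ADU
#>   variance mean 6.01 ADU^2
#>   gain     mean 1.9978 ADU/e- (std 4.65%)
#>   rqe      std 3.88%
#>   gain-rqe correlation -0.824

ex <- fittingBiasExperiment(shape = c(160, 160), nFrames = 300,
                            replicates = 3, seed = 1)
round(rbind(mle       = ex$mle$biasNm,
            `mle-rqe` = ex$`mle-rqe`$biasNm,
            wls       = ex$wls$biasNm), 2)
#>            x    y
#> mle     9.56 2.60
#> mle-rqe 0.32 0.52
#> wls     0.28 0.57
round(c(precision_mle = mean(ex$mle$precisionNm), crlb = ex$crlbNm), 1)
#> precision_mle          crlb
#>          25.6          25.0
```

At 250 photons/frame on a 20 e-/px background the RQE-ignoring MLE is
biased by ~10 nm (concentrated in x, the direction across the RQE
stripes) while its random precision (~25 nm) sits within a few percent of
the CRLB; including the per-pixel RQE in the fit model removes the bias
without costing precision.

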