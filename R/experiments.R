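# The three simulation studies that quantify RQE-driven analysis
# artifacts on a synthetic striped calibration.  These encode the study
# conditions (emitter layout, photon budget, background, camera model) in
# one place; tests and the reproduction script call them at chosen sizes.

#' Detection-bias study (grid emitters, significance by gain category)
#'
#' Simulates grid emitters (20 px spacing, sub-pixel jitter, 250
#' photons/frame, 20 photons/px background) on a striped anti-correlated
#' calibration and fits every emitter in every frame with the Poisson MLE
#' on pre-processed data, once without RQE correction (plain
#' photo-electron conversion) and once with the RQE term included in the
#' pre-processing.  Each fit is scored with the SNSMIL significance
#' computed from the fitted parameters: total fitted photons
#' (height * 2*pi*sigma^2) divided by the shot noise of the fitted
#' background over the 2-sigma signal aperture.  A threshold at the mean
#' significance is then applied and the discarded fraction is reported by
#' the smoothed-gain category (top/bottom pixel quintiles) of the pixel
#' each localization is centered on.
#'
#' Several independent replicates (each with its own calibration draw and
#' movie) are pooled by summing per-category localization counts, so the
#' reported fractions average over stripe realizations of the synthetic
#' sensor as well as over emitter sub-pixel phases.
#'
#' @param shape frame shape (default \code{c(320, 320)}: 256 emitters).
#' @param nFrames frames to simulate per replicate.
#' @param replicates independent calibration + movie replicates pooled
#'   into the reported fractions.
#' @param photons,background photons per frame per emitter and background
#'   photons per pixel.
#' @param psfSigmaPx PSF sigma in pixels.
#' @param seed master seed.
#' @return list with elements \code{uncorrected} and \code{corrected},
#'   each containing pooled \code{discardHigh}, \code{discardLow},
#'   category counts, a pooled two-proportion p-value and the pooled KS
#'   p-value, plus \code{perReplicate} reports.
#' @export
detectionBiasExperiment <- function(shape = c(320, 320), nFrames = 150,
                                    replicates = 3, photons = 250,
                                    background = 20,
                                    psfSigmaPx = 1.5, seed = 1) {
    A <- nrow(diskOffsets(2 * psfSigmaPx))
    oneReplicate <- function(rseed) {
        calib <- synthCalibration(shape, seed = rseed)
        cfg <- simulationConfig(nFrames = nFrames,
                                photonsPerFrame = photons,
                                backgroundPhotons = background,
                                psfSigmaPx = psfSigmaPx, seed = rseed + 1L)
        sim <- simulateMovie(calib, "constant-grid", cfg, seed = rseed + 1L)
        cands <- candidatesFromTruth(sim$truth)
        smRqe <- smoothMap(calib@rqe, psfSigmaPx)
        smGain <- smoothMap(calib@gain, psfSigmaPx)
        idx <- cands$col * shape[1] + cands$row + 1L
        cands$smoothedRqe <- smRqe[idx]
        cands$smoothedGain <- smGain[idx]
        # RQE-corrected pre-processing folded into the conversion:
        # dividing the raw image by rqe is equivalent to a camera whose
        # gain is g * rqe and whose sensitivity is uniform
        calibC <- CalibrationMap(calib@offset, calib@variance,
                                 calib@gain * calib@rqe,
                                 matrix(1, shape[1], shape[2]))
        score <- function(cl) {
            locs <- batchFit(sim$movie, cl, cands, "mle", psfSigmaPx)
            locs <- locs[locs$converged & locs$background > 0, ]
            locs$significance <- heightToPhotons(locs$height, psfSigmaPx) /
                sqrt(locs$background * A)
            locs
        }
        locsU <- score(calib)
        locsC <- score(calibC)
        list(uncorrected = detectionBiasReport(locsU, calib, psfSigmaPx),
             corrected = detectionBiasReport(locsC, calib, psfSigmaPx))
    }
    reps <- lapply(seq_len(replicates), function(i)
        oneReplicate(seed + 1000L * (i - 1L)))
    pool <- function(mode) {
        g <- lapply(reps, function(r) r[[mode]]$gain)
        nLow <- sum(vapply(g, `[[`, 0, "nLow"))
        nHigh <- sum(vapply(g, `[[`, 0, "nHigh"))
        dLow <- sum(vapply(g, `[[`, 0, "nDiscardLow"))
        dHigh <- sum(vapply(g, `[[`, 0, "nDiscardHigh"))
        list(discardLow = dLow / nLow, discardHigh = dHigh / nHigh,
             nLow = nLow, nHigh = nHigh,
             propPValue = suppressWarnings(
                 stats::prop.test(c(dHigh, dLow),
                                  c(nHigh, nLow))$p.value),
             ksPValue = median(vapply(g, `[[`, 0, "ksPValue")))
    }
    list(uncorrected = pool("uncorrected"), corrected = pool("corrected"),
         perReplicate = reps)
}

#' Localization-count enrichment study (blinking emitters)
#'
#' Simulates movies of uniformly placed blinking emitters (0.15 per um^2,
#' 250 photons/frame while on, 20 photons/px background, mean off time 2
#' frames) on a striped calibration, identifies localizations blindly,
#' and measures how strongly localization counts per pixel are enriched
#' on high smoothed-RQE pixels.
#'
#' The operating threshold targets the marginal-detection regime where
#' the artifact matters: the typical localization significance is
#' comparable to the threshold.  It is set to mean + 1 standard
#' deviation of the single-emitter significance population (candidates
#' above a 6-sigma floor, which separates emitters from smoothed-noise
#' maxima at this photon budget), estimated from the uncorrected
#' analysis and then applied to both analyses.
#'
#' @param shape frame shape per movie.
#' @param nFrames frames per movie.
#' @param nMovies independent movies (fresh emitter draws) to aggregate.
#' @param psfSigmaPx PSF sigma in pixels.
#' @param seed master seed.
#' @return list with \code{uncorrected} and \code{corrected}
#'   \code{\link{countsVsRQE}} reports (counts aggregated over movies),
#'   the threshold used, and the per-movie candidate counts.
#' @export
enrichmentExperiment <- function(shape = c(256, 256), nFrames = 1200,
                                 nMovies = 3, psfSigmaPx = 1.5,
                                 seed = 1) {
    calib <- synthCalibration(shape, seed = seed)
    cfg <- simulationConfig(nFrames = nFrames, psfSigmaPx = psfSigmaPx,
                            seed = seed + 1L)
    sims <- lapply(seq_len(nMovies), function(i)
        simulateMovie(calib, "blinking-uniform", cfg,
                      seed = seed + 10L * i))
    floorSigma <- 6
    candsU <- lapply(sims, function(s)
        identifyMovie(s$movie, calib, "none", psfSigmaPx, floorSigma))
    thr <- {
        sig <- unlist(lapply(candsU, `[[`, "significance"))
        mean(sig) + sd(sig)
    }
    candsC <- lapply(sims, function(s)
        identifyMovie(s$movie, calib, "rqe", psfSigmaPx, floorSigma))
    keep <- function(tabs) {
        t <- do.call(rbind, tabs)
        t[t$significance >= thr, ]
    }
    locU <- keep(candsU); locC <- keep(candsC)
    list(uncorrected = countsVsRQE(locU, calib, psfSigmaPx),
         corrected = countsVsRQE(locC, calib, psfSigmaPx),
         threshold = thr,
         nLocalizations = c(uncorrected = nrow(locU),
                            corrected = nrow(locC)),
         calibration = calib)
}

#' Fitting precision and bias study (intensity protocol)
#'
#' Grid emitters with sub-pixel offsets at a fixed photon budget are
#' simulated over several independent replicates on a striped
#' calibration; each emitter is fit in every frame (ROIs seeded at the
#' known grid pixels, so detection is not a confounder) with the chosen
#' estimators, and the per-emitter precision and precision-corrected RMS
#' bias are measured against ground truth, alongside the average
#' Cramer-Rao lower bound over the same emitter positions.
#'
#' @param shape frame shape (default \code{c(160, 160)}: 64 emitters).
#' @param nFrames frames per replicate.
#' @param replicates independent simulation replicates (error bars).
#' @param photons expected photons per frame per emitter.
#' @param background background photons per pixel.
#' @param estimators subset of \code{c("mle", "mle-rqe", "wls")}.
#' @param psfSigmaPx PSF sigma in pixels.
#' @param pixelSizeNm pixel size in nm.
#' @param seed master seed.
#' @return list keyed by estimator, each a \code{\link{precisionBias}}
#'   report, plus \code{crlbNm}: the mean CRLB position bound (nm),
#'   averaged over emitters and replicates.
#' @export
fittingBiasExperiment <- function(shape = c(160, 160), nFrames = 500,
                                  replicates = 5, photons = 250,
                                  background = 20,
                                  estimators = c("mle", "mle-rqe", "wls"),
                                  psfSigmaPx = 1.5, pixelSizeNm = 100,
                                  seed = 1) {
    calib <- synthCalibration(shape, seed = seed)
    cfg <- simulationConfig(nFrames = nFrames, photonsPerFrame = photons,
                            backgroundPhotons = background,
                            psfSigmaPx = psfSigmaPx,
                            pixelSizeNm = pixelSizeNm, seed = seed)
    sims <- lapply(seq_len(replicates), function(i)
        simulateMovie(calib, "constant-grid", cfg, seed = seed + 1000L * i))
    truths <- lapply(sims, `[[`, "truth")
    cands <- lapply(truths, candidatesFromTruth)
    out <- list()
    for (est in estimators) {
        locs <- Map(function(s, cd)
            batchFit(s$movie, calib, cd, est, psfSigmaPx), sims, cands)
        out[[est]] <- precisionBias(locs, truths, pixelSizeNm)
    }
    crlbs <- vapply(truths, function(tr)
        mean(crlbForEmitters(tr, calib, photons, background, psfSigmaPx,
                             pixelSizeNm)$meanNm), numeric(1))
    out$crlbNm <- mean(crlbs)
    out$calibration <- calib
    out
}
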