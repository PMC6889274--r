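# Pre-processing, candidate detection and significance scoring.

test_that("pre-processing converts ADU to e- with and without RQE", {
    cal <- uniformCalib(1, 1, offset = 100, variance = 4, gain = 2,
                        rqe = 0.8)
    expect_equal(preprocessFrame(matrix(200), cal, "none")$values[1, 1], 50)
    expect_equal(preprocessFrame(matrix(200), cal, "rqe")$values[1, 1],
                 62.5)
    calU <- uniformCalib(4, 4, rqe = 1)
    fr <- matrix(rnorm(16, 150, 5), 4, 4)
    expect_identical(preprocessFrame(fr, calU, "rqe")$values,
                     preprocessFrame(fr, calU, "none")$values)
    expect_error(preprocessFrame(matrix(1, 2, 2), cal, "none"),
                 "dimensions")
})

test_that("flat frames produce no candidates", {
    pre <- structure(list(values = matrix(20, 40, 40), mode = "none"),
                     class = "PreprocessedFrame")
    expect_equal(nrow(findCandidates(pre, 1.5, 0.5)), 0)
})

test_that("significance matches the aperture definition on constructed data", {
    # flat 100-e- background with an extra 60 e- concentrated at one pixel:
    # signal/sqrt(background-in-aperture) with |disk(3 px)| = 29 pixels
    v <- matrix(100, 41, 41)
    v[21, 21] <- v[21, 21] + 60
    pre <- structure(list(values = v, mode = "none"),
                     class = "PreprocessedFrame")
    sig <- scoreCandidates(pre, cbind(20L, 20L), 1.5)
    expect_equal(sig, 60 / sqrt(100 * 29), tolerance = 1e-12)
    # peaks too close to the border are not scored
    expect_true(is.na(scoreCandidates(pre, cbind(2L, 2L), 1.5)))
})

test_that("a clean emitter is detected at its pixel with high significance", {
    img <- oneEmitterImage(c(41, 41), 20.2, 19.8, 5000, 20)
    pre <- structure(list(values = img, mode = "none"),
                     class = "PreprocessedFrame")
    cands <- findCandidates(pre, 1.5, 3)
    expect_equal(nrow(cands), 1)
    expect_equal(cands$row, 20)      # zero-based
    expect_equal(cands$col, 20)
    expect_gt(cands$significance, 50)
})

test_that("detection on a noisy camera finds most grid emitters once", {
    cal <- synthCalibration(c(96, 96), seed = 41)
    cfg <- simulationConfig(nFrames = 2, photonsPerFrame = 1500)
    sim <- simulateMovie(cal, "constant-grid", cfg, seed = 42)
    cands <- identifyMovie(sim$movie, cal, "none", 1.5, 6)
    perFrame <- table(cands$frame)
    expect_true(all(perFrame >= 0.8 * nEmitters(sim$truth)))
    expect_true(all(perFrame <= 1.2 * nEmitters(sim$truth)))
    expect_true(all(is.finite(cands$smoothedRqe)))
    # identical analysis twice: identical candidates (pure function)
    cands2 <- identifyMovie(sim$movie, cal, "none", 1.5, 6)
    expect_identical(cands, cands2)
})

test_that("detection-bias report splits categories at pixel quantiles", {
    set.seed(6)
    cal <- synthCalibration(c(48, 48), seed = 6)
    sm <- smoothMap(gainMap(cal), 1.5)
    cands <- data.frame(frame = 1,
                        row = rep(10:37, 4), col = rep(10:37, each = 4),
                        significance = rnorm(112, 8),
                        smoothedRqe = 1,
                        smoothedGain = sm[cbind(rep(10:37, 4) + 1,
                                                rep(10:37, each = 4) + 1)])
    rep1 <- detectionBiasReport(cands, cal, 1.5)
    expect_equal(rep1$threshold, mean(cands$significance))
    expect_identical(rep1, detectionBiasReport(cands, cal, 1.5))
    expect_true(rep1$gain$nLow + rep1$gain$nHigh <= nrow(cands))
    expect_warning(out <- detectionBiasReport(cands[0, ], cal, 1.5),
                   "empty")
    expect_true(is.na(out$threshold))
    expect_error(detectionBiasReport(cands, cal, 1.5, quantile = 0.7),
                 "quantile")
})
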