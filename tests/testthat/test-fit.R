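# Objectives, term assembly and the Levenberg-Marquardt fitters.

test_that("Poisson deviance is zero at equality and positive elsewhere", {
    expect_equal(chi2MLE(c(1, 5, 9), c(1, 5, 9)), 0)
    expect_equal(chi2MLE(2, 1), 2 - 2 * log(2))
    set.seed(12)
    for (i in 1:20) {
        f <- runif(30, 0.1, 50); x <- runif(30, 0.1, 50)
        expect_gte(chi2MLE(f, x), 0)
    }
    expect_error(chi2MLE(c(1, -1), c(1, 1)), "positive")
})

test_that("term assembly reduces to identities in the uniform limits", {
    raw <- matrix(rpois(121, 140) + 0, 11, 11)
    # g = 2, rqe = 1, <g> = 2: flat = 1 and WLS data reduce to (raw-o)/g
    roi <- uniformCalibRoi(11, offset = 100, variance = 0, gain = 2,
                           rqe = 1)
    wls <- buildTerms(raw, roi, "wls")
    mle <- buildTerms(raw, roi, "mle")
    expect_equal(wls$x, (raw - 100) / 2)
    expect_equal(mle$x, pmax((raw - 100) / 2, 1e-6))
    # rqe == 1: "mle-rqe" terms equal "mle" terms exactly
    rqe1 <- buildTerms(raw, roi, "mle-rqe")
    expect_identical(rqe1$x, mle$x)
    expect_equal(rqe1$a, mle$a)
    # zero read noise, rqe as given: pure e- conversion and scaled model
    roi2 <- uniformCalibRoi(11, offset = 100, variance = 0, gain = 2,
                            rqe = 0.9)
    t2 <- buildTerms(raw, roi2, "mle-rqe")
    expect_equal(t2$c, matrix(0, 11, 11))
    expect_equal(t2$a, matrix(0.9, 11, 11))
    # ADU^2 variance enters in e-^2 units: var/g^2
    roi3 <- uniformCalibRoi(11, offset = 100, variance = 8, gain = 2)
    expect_equal(buildTerms(raw, roi3, "mle")$c, matrix(2, 11, 11))
    expect_error(buildTerms(raw[1:5, 1:5], roi3, "mle"), "inconsistent")
})

test_that("all three estimators recover truth exactly on noise-free data", {
    img <- oneEmitterImage(c(11, 11), 5.3, 4.8, 500, 5)
    roi <- uniformCalibRoi(11)
    hTrue <- 500 / (2 * pi * 1.5^2)
    for (est in c("mle", "mle-rqe", "wls")) {
        f <- fitEmitter(img, roi, est, theta0 = c(hTrue * 0.8, 5.0, 5.1, 4))
        expect_true(f$converged)
        expect_equal(unname(f$theta["x"]), 5.3, tolerance = 1e-6)
        expect_equal(unname(f$theta["y"]), 4.8, tolerance = 1e-6)
        expect_equal(unname(f$theta["h"]), hTrue, tolerance = 1e-5)
        expect_equal(unname(f$theta["bg"]), 5, tolerance = 1e-4)
    }
})

test_that("the RQE-corrected model undoes a pure RQE distortion", {
    # data generated with an rqe gradient, fit with the matching model:
    # recovered position must not shift
    rqe <- outer(rep(1, 11), 1 + 0.04 * ((0:10) - 5) / 5)  # x-gradient
    img <- oneEmitterImage(c(11, 11), 5.4, 5.0, 800, 10) * rqe
    roi <- uniformCalibRoi(11)
    roi$rqe <- rqe
    f <- fitEmitter(img, roi, "mle-rqe",
                    theta0 = c(20, 5.0, 5.0, 10))
    expect_equal(unname(f$theta["x"]), 5.4, tolerance = 1e-5)
    # the uncorrected model on the same data is pulled sideways
    fU <- fitEmitter(img, roi, "mle", theta0 = c(20, 5.0, 5.0, 10))
    expect_gt(abs(unname(fU$theta["x"]) - 5.4), 5e-3)
})

test_that("fitted scatter tracks the CRLB on a uniform Poisson camera", {
    cal <- uniformCalib(33, 33, offset = 100, variance = 4, gain = 2)
    cfg <- simulationConfig(nFrames = 250, photonsPerFrame = 400,
                            backgroundPhotons = 10)
    em <- new("EmitterSet", positions = cbind(x = 16.3, y = 15.8),
              intensity = 400, onState = matrix(TRUE, 1, 250),
              layout = "grid")
    sim <- simulateMovie(cal, emitters = em, config = cfg, seed = 77)
    locs <- batchFit(sim$movie, cal, candidatesFromTruth(em), "mle-rqe")
    expect_gt(mean(locs$converged), 0.99)
    b <- crlbBounds(c(bg = 10, h = 400 / (2 * pi * 1.5^2), x = 5.3,
                      y = 4.8), 1.5, matrix(1, 11, 11),
                    matrix(4, 11, 11), matrix(2, 11, 11))
    ratio <- sd(locs$x) / unname(b$bounds["x"])
    expect_gt(ratio, 0.85)
    expect_lt(ratio, 1.2)
})

test_that("batch fitting skips clipped ROIs and is deterministic", {
    cal <- uniformCalib(20, 20)
    cfg <- simulationConfig(nFrames = 2, photonsPerFrame = 2000)
    em <- new("EmitterSet", positions = cbind(x = c(9.5, 1.0),
                                              y = c(10.2, 1.0)),
              intensity = c(2000, 2000), onState = matrix(TRUE, 2, 2),
              layout = "grid")
    sim <- simulateMovie(cal, emitters = em, config = cfg, seed = 3)
    cands <- candidatesFromTruth(em)
    locs <- batchFit(sim$movie, cal, cands, "mle")
    expect_equal(attr(locs, "nSkipped"), 2)   # edge emitter, both frames
    expect_equal(nrow(locs), 2)
    expect_identical(locs, batchFit(sim$movie, cal, cands, "mle"))
    expect_error(batchFit(sim$movie, cal, cands[0, ], "mle"), "empty")
})
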