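# Synthetic calibration generator, emitter layouts, PSF rendering and the
# camera forward model.

test_that("synthetic calibration hits requested statistics and is seeded", {
    cal <- synthCalibration(c(64, 64), rqeStdFrac = 0.04,
                            gainRqeCorr = -0.9, seed = 13)
    expect_true(sd(rqeMap(cal)) > 0.035 && sd(rqeMap(cal)) < 0.045)
    corr <- cor(as.vector(gainMap(cal)), as.vector(rqeMap(cal)))
    expect_true(corr > -0.95 && corr < -0.85)
    expect_identical(rqeMap(synthCalibration(c(64, 64), seed = 13)),
                     rqeMap(cal))
    # zero-noise limit
    cal0 <- synthCalibration(c(16, 16), gainStdFrac = 0, rqeStdFrac = 0,
                             seed = 1)
    expect_equal(rqeMap(cal0), matrix(1, 16, 16))
    expect_equal(gainMap(cal0), matrix(2, 16, 16))
    expect_error(synthCalibration(c(16, 16), rqeStdFrac = 0.5), "0.2")
    expect_error(synthCalibration(c(16, 16), gainRqeCorr = -2), "<= 1")
})

test_that("RQE stripes are column-oriented", {
    cal <- synthCalibration(c(64, 64), seed = 3)
    r <- rqeMap(cal)
    colProfile <- colMeans(r)         # along-stripe average survives
    rowProfile <- rowMeans(r)
    expect_gt(sd(colProfile), 2 * sd(rowProfile))
})

test_that("grid emitters count and blinking kinetics match the config", {
    cfg <- simulationConfig(nFrames = 2000, offRateFrames = 2)
    grid <- makeEmitters("constant-grid", c(300, 300),
                         simulationConfig(nFrames = 3), seed = 1)
    expect_equal(nEmitters(grid), 225)   # 15 x 15 at 20 px spacing
    expect_true(all(onState(grid)))
    # uniform density: 64 px at 100 nm -> 40.96 um^2 -> lambda ~6.1
    counts <- vapply(1:40, function(s)
        nEmitters(makeEmitters("blinking-uniform", c(64, 64),
                               simulationConfig(nFrames = 1), seed = s)),
        numeric(1))
    expect_equal(mean(counts), 0.15 * 40.96, tolerance = 0.2)
    # mean off duration ~2 frames
    em <- makeEmitters("blinking-uniform", c(128, 128), cfg, seed = 5)
    offLens <- unlist(apply(onState(em), 1, function(s) {
        r <- rle(s); r$lengths[!r$values & seq_along(r$values) > 1 &
                               seq_along(r$values) < length(r$values)]
    }))
    expect_equal(mean(offLens), 2, tolerance = 0.25)
    expect_error(makeEmitters("blinking-uniform", c(4, 4),
                              simulationConfig(nFrames = 1,
                                               density = 1e-6), seed = 1),
                 "zero emitters")
})

test_that("expectation images conserve photon mass", {
    cfg <- simulationConfig(nFrames = 1, photonsPerFrame = 250,
                            backgroundPhotons = 0)
    img <- oneEmitterImage(c(61, 61), 30, 30, 250, 0)
    expect_equal(sum(img), 250, tolerance = 250 * 1e-3)
    expect_true(all(img >= 0))
    # sampled convention: closed-form peak amplitude N/(2 pi sigma^2)
    imgS <- oneEmitterImage(c(61, 61), 30, 30, 250, 0,
                            convention = "sampled")
    expect_equal(imgS[31, 31], 250 / (2 * pi * 1.5^2), tolerance = 1e-6)
    # no emitters: constant background
    em <- makeEmitters("constant-grid", c(64, 64),
                       simulationConfig(nFrames = 1), seed = 1)
    off <- em; off@onState[] <- FALSE
    expect_equal(renderExpectation(off, 1, c(64, 64),
                                   simulationConfig(nFrames = 1)),
                 matrix(20, 64, 64))
})

test_that("camera forward model has the closed-form pixel moments", {
    cal0 <- uniformCalib(2, 2, offset = 100, variance = 0, gain = 2)
    expect_equal(cameraForward(matrix(0, 2, 2), cal0), matrix(100, 2, 2))
    cal <- uniformCalib(1, 1, offset = 100, variance = 9, gain = 2,
                        rqe = 0.96)
    set.seed(8)
    draws <- vapply(1:1e5, function(i)
        cameraForward(matrix(100, 1, 1), cal)[1, 1], numeric(1))
    # mean 100 + 2*96 = 292, var 4*96 + 9 = 393
    expect_equal(mean(draws), 292, tolerance = 3 * sqrt(393 / 1e5) / 292)
    expect_equal(var(draws), 393,
                 tolerance = 3 * 393 * sqrt(2 / 1e5) / 393)
    expect_error(cameraForward(matrix(-1, 1, 1), cal), "non-negative")
})

test_that("pre-processing inverts the forward model in expectation", {
    cal <- synthCalibration(c(10, 10), seed = 17)
    set.seed(18)
    acc <- matrix(0, 10, 10)
    n <- 3000
    for (i in seq_len(n))
        acc <- acc + preprocessFrame(cameraForward(matrix(50, 10, 10), cal),
                                     cal, "none")$values
    expect_equal(acc / n, 50 * rqeMap(cal), tolerance = 0.02)
})

test_that("movie simulation is deterministic given the seed", {
    cal <- synthCalibration(c(64, 64), seed = 2)
    cfg <- simulationConfig(nFrames = 4)
    s1 <- simulateMovie(cal, "blinking-uniform", cfg, seed = 9)
    s2 <- simulateMovie(cal, "blinking-uniform", cfg, seed = 9)
    expect_identical(frames(s1$movie), frames(s2$movie))
    expect_identical(emitterPositions(s1$truth),
                     emitterPositions(s2$truth))
})
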