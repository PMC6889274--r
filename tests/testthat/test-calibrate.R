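# Camera calibration: offset/variance, lamp correction, photon-transfer
# gain fit, RQE normalization, and the full round trip.

test_that("offset and variance are the temporal mean and population variance", {
    expect_equal(computeOffsetVariance(constantMovie(100))$offset,
                 matrix(100, 8, 8))
    expect_equal(computeOffsetVariance(constantMovie(100))$variance,
                 matrix(0, 8, 8))
    mv <- CameraMovie(array(c(99, 101), c(1, 1, 2)))
    ov <- computeOffsetVariance(mv)
    expect_equal(ov$offset[1, 1], 100)
    expect_equal(ov$variance[1, 1], 1)   # (99^2 + 101^2)/2 - 100^2
    expect_error(computeOffsetVariance(CameraMovie(array(1, c(2, 2, 1)))),
                 "at least 2")
})

test_that("population variance matches the direct sum-of-squares form", {
    set.seed(4)
    fr <- array(rnorm(5 * 5 * 40, 100, 3), c(5, 5, 40))
    ov <- computeOffsetVariance(CameraMovie(fr))
    direct <- apply(fr, c(1, 2), function(s) mean((s - mean(s))^2))
    expect_equal(ov$variance, direct, tolerance = 1e-9)
})

test_that("offset and variance converge at Monte-Carlo rate", {
    set.seed(11)
    fr <- array(rnorm(4 * 4 * 20000, 100, 2), c(4, 4, 20000))
    ov <- computeOffsetVariance(CameraMovie(fr))
    expect_true(max(abs(ov$offset - 100)) < 3 * 2 / sqrt(20000) * 4)
    expect_true(max(abs(ov$variance - 4)) < 0.2)
})

test_that("lamp-fluctuation correction removes common-mode variance", {
    set.seed(5)
    base <- matrix(1000, 12, 12)
    facs <- 1 + rnorm(400, sd = 0.01)
    fr <- array(0, c(12, 12, 400))
    for (f in 1:400) fr[, , f] <- base * facs[f]
    dark0 <- matrix(0, 12, 12)
    st <- lampCorrectedStats(CameraMovie(fr), dark0, dark0)
    rawVar <- computeOffsetVariance(CameraMovie(fr))$variance
    expect_gt(mean(rawVar), 50)             # uncorrected: ~(1000*0.01)^2
    expect_lt(mean(st$variance), 1e-6)      # corrected: common mode removed
    # stable lamp: correction term is zero and stats equal plain ones
    frc <- array(500, c(12, 12, 50))
    stc <- lampCorrectedStats(CameraMovie(frc), matrix(100, 12, 12),
                              matrix(2, 12, 12))
    expect_equal(stc$lampVariance, 0)
    expect_equal(stc$mean, matrix(400, 12, 12))
    expect_equal(stc$nClipped, 144)         # 0 - 2 clipped to 0
    expect_error(lampCorrectedStats(CameraMovie(frc), dark0[1:3, 1:3],
                                    dark0[1:3, 1:3]), "dimensions")
})

test_that("corrected stats of a Poisson+gain movie match g*N and g^2*N", {
    cal <- uniformCalib(6, 6, offset = 100, variance = 0, gain = 2)
    set.seed(9)
    fr <- array(0, c(6, 6, 6000))
    for (f in 1:6000)
        fr[, , f] <- cameraForward(matrix(100, 6, 6), cal)
    st <- lampCorrectedStats(CameraMovie(fr), cal@offset, cal@variance)
    expect_equal(mean(st$mean), 200, tolerance = 0.01)
    expect_equal(mean(st$variance), 400, tolerance = 0.05)
})

test_that("gain fit matches exact lines and a normal-equations oracle", {
    mk <- function(m, v) list(mean = matrix(m), variance = matrix(v))
    expect_equal(fitGain(list(mk(100, 200), mk(200, 400)))$gain[1, 1], 2)
    expect_equal(fitGain(list(mk(100, 200), mk(200, 400)))$intercept[1, 1],
                 0)
    expect_equal(fitGain(list(mk(50, 100)))$gain[1, 1], 2)
    set.seed(2)
    x <- c(80, 160, 240, 320)
    y <- 2.3 * x + 5 + rnorm(4)
    got <- fitGain(lapply(1:4, function(k) mk(x[k], y[k])))
    X <- cbind(1, c(0, x))                       # origin point appended
    beta <- solve(t(X) %*% X, t(X) %*% c(0, y))  # brute-force oracle
    expect_equal(got$gain[1, 1], beta[2], tolerance = 1e-9)
    expect_equal(got$intercept[1, 1], beta[1], tolerance = 1e-9)
    expect_error(fitGain(list()), "at least one")
    deg <- fitGain(list(mk(100, 5), mk(100, 7)))
    expect_true(deg$degenerate[1, 1] || !is.na(deg$gain[1, 1]))
})

test_that("RQE is unity for uniform images and localizes perturbations", {
    fr <- array(600, c(24, 24, 4))
    rqe <- computeRQE(CameraMovie(fr), matrix(100, 24, 24),
                      matrix(2, 24, 24))
    expect_equal(rqe, matrix(1, 24, 24), tolerance = 1e-12)
    # one interior pixel 4% above its neighbours: its own excess enters
    # the 10x10 window mean at weight 1/100
    fr2 <- fr
    fr2[12, 12, ] <- 600 + 0.04 * 500   # +4% of the converted 250 e-
    rqe2 <- computeRQE(CameraMovie(fr2), matrix(100, 24, 24),
                       matrix(2, 24, 24))
    expect_equal(rqe2[12, 12], 1.04 / (1 + 0.04 / 100), tolerance = 1e-6)
    expect_error(computeRQE(CameraMovie(fr), matrix(700, 24, 24),
                            matrix(2, 24, 24)), "not positive")
})

test_that("RQE block means stay within 2% of unity on smooth illumination", {
    set.seed(3)
    nr <- 40
    illum <- outer(seq(900, 1100, length.out = nr),
                   seq(950, 1050, length.out = nr)) / 1000
    fr <- array(0, c(nr, nr, 3))
    for (f in 1:3) fr[, , f] <- illum * 2 + 100
    rqe <- computeRQE(CameraMovie(fr), matrix(100, nr, nr),
                      matrix(2, nr, nr))
    for (i in seq(6, 26, 10))
        for (j in seq(6, 26, 10))
            expect_true(abs(mean(rqe[i:(i + 9), j:(j + 9)]) - 1) < 0.02)
})

test_that("calibration round trip recovers the generating camera", {
    truth <- synthCalibration(c(20, 20), seed = 21)
    ser <- simulateIlluminationSeries(truth, nFrames = 4000,
                                      maxPhotons = 2000,
                                      lampSdFrac = 0.005, seed = 22)
    cal <- calibrateCamera(ser)
    M <- 4000
    expect_true(max(abs(offsetMap(cal) - offsetMap(truth)) /
                    (sqrt(varianceMap(truth) / M))) < 5)
    expect_lt(mean(abs(varianceMap(cal) - varianceMap(truth)) /
                   varianceMap(truth)), 0.1)
    expect_lt(mean(abs(gainMap(cal) - gainMap(truth)) / gainMap(truth)),
              0.03)
    expect_gt(cor(as.vector(rqeMap(cal)), as.vector(rqeMap(truth))), 0.5)
    # built-in anti-correlation is recovered in sign
    expect_lt(calibrationStats(cal)$gainRqeCorrelation, 0)
    expect_equal(meanGain(cal), mean(gainMap(cal)))
    expect_error(IlluminationSeries(truthMovie <- ser@dark, list()),
                 "at least one")
})

test_that("round-trip errors shrink with the number of frames", {
    truth <- synthCalibration(c(12, 12), seed = 31)
    err <- vapply(c(500, 8000), function(M) {
        ser <- simulateIlluminationSeries(truth, nFrames = M,
                                          maxPhotons = 2000, seed = 32)
        cal <- calibrateCamera(ser)
        mean(abs(gainMap(cal) - gainMap(truth)) / gainMap(truth))
    }, numeric(1))
    # 16x more frames: expect roughly 4x smaller errors; allow slack 2x
    expect_lt(err[2], err[1] / 2)
})
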