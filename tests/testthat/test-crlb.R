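# Fisher information and Cramer-Rao bounds under the sCMOS + RQE model.

refTheta <- c(bg = 20, h = 17.7, x = 5.2, y = 4.7)

test_that("Fisher matrix is symmetric and matches a finite-difference oracle", {
    set.seed(14)
    rqe <- matrix(runif(121, 0.9, 1.1), 11, 11)
    varE <- matrix(runif(121, 0.3, 2), 11, 11)
    Fm <- fisherMatrix(refTheta, 1.5, rqe, varE)
    expect_identical(Fm, t(Fm))
    # oracle: numeric partials of the PSF model assembled independently
    modelAt <- function(th) th["h"] *
        psfShape(0:10, 0:10, th["x"], th["y"], 1.5)$shape + th["bg"]
    mu <- rqe * modelAt(refTheta) + varE
    eps <- 1e-5
    ds <- lapply(names(refTheta), function(p) {
        tp <- refTheta; tm <- refTheta
        tp[p] <- tp[p] + eps; tm[p] <- tm[p] - eps
        (modelAt(tp) - modelAt(tm)) / (2 * eps)
    })
    Ffd <- matrix(0, 4, 4)
    for (m in 1:4) for (n in 1:4)
        Ffd[m, n] <- sum(rqe^2 / mu * ds[[m]] * ds[[n]])
    expect_equal(unname(Fm), Ffd, tolerance = 1e-4)
})

test_that("uniform camera reduces to the plain Poisson Fisher matrix", {
    ones <- matrix(1, 11, 11); zeros <- matrix(0, 11, 11)
    Fm <- fisherMatrix(refTheta, 1.5, ones, zeros)
    p <- psfShape(0:10, 0:10, refTheta["x"], refTheta["y"], 1.5,
                  deriv = TRUE)
    f <- refTheta["h"] * p$shape + refTheta["bg"]
    d <- list(ones, p$shape, refTheta["h"] * p$dx0,
              refTheta["h"] * p$dy0)
    Fref <- matrix(0, 4, 4)
    for (m in 1:4) for (n in 1:4)
        Fref[m, n] <- sum(d[[m]] * d[[n]] / f)
    expect_equal(unname(Fm), Fref, tolerance = 1e-9)
})

test_that("position bound scales as 1/sqrt(N) and hits sigma/sqrt(N)", {
    h <- function(N) N / (2 * pi * 1.5^2)
    roiN <- function() matrix(1, 15, 15)
    bAt <- function(N) crlbBounds(c(bg = 1e-9, h = h(N), x = 7, y = 7),
                                  1.5, roiN(), matrix(0, 15, 15),
                                  roiN())$bounds["x"]
    expect_equal(unname(bAt(1e4)), 1.5 / sqrt(1e4), tolerance = 0.02)
    expect_equal(unname(bAt(2e4) / bAt(1e4)), 1 / sqrt(2),
                 tolerance = 1e-6)
})

test_that("read noise never improves the bounds", {
    b0 <- crlbBounds(refTheta, 1.5, matrix(1, 11, 11),
                     matrix(0, 11, 11), matrix(1, 11, 11))$bounds
    b1 <- crlbBounds(refTheta, 1.5, matrix(1, 11, 11),
                     matrix(4, 11, 11), matrix(1, 11, 11))$bounds
    expect_true(all(b1 >= b0))
})

test_that("bounds vary with position on a striped camera only", {
    cal <- synthCalibration(c(40, 40), seed = 19)
    atX <- function(x, rqe) crlbBounds(
        c(bg = 20, h = 17.7, x = x, y = 5), 1.5, rqe,
        matrix(4, 11, 11), matrix(2, 11, 11))$bounds["x"]
    striped <- vapply(c(5, 5.5, 6), function(dx)
        atX(5, rqeMap(cal)[10:20, (10:20) + round(2 * dx)]), numeric(1))
    expect_gt(diff(range(striped)) / mean(striped), 1e-4)
    uniformB <- vapply(1:3, function(i)
        atX(5, matrix(1, 11, 11)), numeric(1))
    expect_equal(max(uniformB) - min(uniformB), 0)
})

test_that("variable-sigma parameter set extends the matrix", {
    th <- c(refTheta)
    Fm <- fisherMatrix(th, 1.5, matrix(1, 11, 11), matrix(1, 11, 11),
                       freeSigma = TRUE)
    expect_equal(dim(Fm), c(5, 5))
    expect_identical(Fm, t(Fm))
    expect_gt(Fm["sigma", "sigma"], 0)
})

test_that("averaged bounds follow the emitter-set protocol", {
    cal <- synthCalibration(c(64, 64), seed = 20)
    em <- makeEmitters("constant-grid", c(64, 64),
                       simulationConfig(nFrames = 1), seed = 21)
    out <- crlbForEmitters(em, cal, photons = 250, background = 20)
    expect_equal(unname(out$meanNm["x"]), mean(out$perEmitter[, "x"]))
    expect_true(all(out$perEmitter > 0))
    # more photons, tighter bounds
    out2 <- crlbForEmitters(em, cal, photons = 1000, background = 20)
    expect_true(all(out2$meanNm < out$meanNm))
})
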