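# Pixel-faithful sCMOS forward simulation: synthetic calibration maps that
# emulate a measured camera (striped RQE, gain anti-correlated with RQE,
# heteroscedastic read noise), ground-truth emitter configurations, photon
# expectation images, and the camera noise model
#   ADU_i = gain_i * Poisson(rqe_i * expectation_i) + N(0, sqrt(var_i)) + o_i.

#' Synthetic sCMOS calibration map
#'
#' Generates a \linkS4class{CalibrationMap} emulating a measured sCMOS
#' sensor.  The RQE field is the sum of three zero-mean components, each
#' normalized to unit sample variance before weighting: broad vertical
#' bands (a per-column profile smoothed with a Gaussian of
#' \code{stripeSigmaPx} columns, circular boundary), sharp column-to-column
#' structure (i.i.d. per column), and i.i.d. pixel noise, with variance
#' shares 0.45 / 0.35 / 0.20.  Column-oriented structure dominates, which
#' reproduces the vertically striped appearance of real sensors and makes
#' analysis artifacts concentrate in the x coordinate.  The gain field
#' shares the requested correlation with the RQE field; per-pixel read
#' noise is drawn uniformly from \code{readnoiseVarRange}.
#'
#' @param shape integer(2): rows, cols.
#' @param gainMean mean gain in ADU per photo-electron.
#' @param gainStdFrac fractional std of the gain field (default 0.04).
#' @param rqeStdFrac fractional std of the RQE field (default 0.04).
#' @param gainRqeCorr correlation between gain and RQE deviations
#'   (default -0.9; real sensors are anti-correlated).
#' @param stripeSigmaPx correlation length (columns) of the band component.
#' @param readnoiseVarRange range of per-pixel read-noise variance, ADU^2.
#' @param offsetMean mean offset in ADU (per-pixel offsets are jittered by
#'   a few ADU around it).
#' @param seed integer seed; the map is a deterministic function of it.
#' @return a \linkS4class{CalibrationMap}.
#' @examples
#' cal <- synthCalibration(c(64, 64), seed = 1)
#' sd(rqeMap(cal))    # ~0.04
#' @export
synthCalibration <- function(shape, gainMean = 2, gainStdFrac = 0.04,
                             rqeStdFrac = 0.04, gainRqeCorr = -0.9,
                             stripeSigmaPx = 3,
                             readnoiseVarRange = c(2, 10),
                             offsetMean = 100, seed = 1) {
    if (gainStdFrac < 0 || gainStdFrac >= 0.2 ||
        rqeStdFrac < 0 || rqeStdFrac >= 0.2)
        stop("gain/rqe std fractions must lie in [0, 0.2)")
    if (abs(gainRqeCorr) > 1) stop("|gainRqeCorr| must be <= 1")
    nr <- shape[1]; nc <- shape[2]
    old <- .Random.seed.exists()
    set.seed(seed)
    unit <- function(m) if (sd(m) > 0) (m - mean(m)) / sd(m) else m * 0
    bands <- unit(matrix(smoothVecCircular(rnorm(nc), stripeSigmaPx),
                         nr, nc, byrow = TRUE))
    cols <- unit(matrix(rnorm(nc), nr, nc, byrow = TRUE))
    px <- unit(matrix(rnorm(nr * nc), nr, nc))
    zR <- unit(sqrt(0.45) * bands + sqrt(0.35) * cols + sqrt(0.20) * px)
    rqe <- 1 + rqeStdFrac * zR
    zG <- unit(gainRqeCorr * zR +
               sqrt(max(0, 1 - gainRqeCorr^2)) * unit(matrix(rnorm(nr * nc),
                                                             nr, nc)))
    gain <- gainMean * (1 + gainStdFrac * zG)
    variance <- matrix(runif(nr * nc, readnoiseVarRange[1],
                             readnoiseVarRange[2]), nr, nc)
    offset <- offsetMean + matrix(rnorm(nr * nc, sd = 2), nr, nc)
    restoreSeed(old)
    if (any(rqe <= 0) || any(gain <= 0))
        stop("generated rqe/gain not positive; reduce the std fractions")
    CalibrationMap(offset, variance, gain, rqe,
                   stats = list(stdGain = sd(gain), stdRqe = sd(rqe),
                                gainRqeCorrelation =
                                    if (sd(gain) > 0 && sd(rqe) > 0)
                                        cor(as.vector(gain),
                                            as.vector(rqe))
                                    else NA_real_,
                                seed = seed))
}

# Save/restore the global RNG state so generators are pure functions of
# their seed argument without clobbering the caller's stream.
.Random.seed.exists <- function() {
    if (exists(".Random.seed", envir = globalenv()))
        get(".Random.seed", envir = globalenv())
    else NULL
}
restoreSeed <- function(old) {
    if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
}

#' Simulation configuration
#'
#' Bundles the simulation parameters with their defaults: 250 expected
#' photons per frame per emitter, 20 background photons per pixel,
#' PSF sigma 1.5 pixels at 100 nm pixel size, and, for blinking emitters,
#' a mean off time of 2 frames with a mean on time of 1 frame.
#'
#' @param nFrames number of frames to simulate.
#' @param photonsPerFrame expected photons per frame while an emitter is on.
#' @param backgroundPhotons uniform background, photons per pixel per frame.
#' @param psfSigmaPx PSF sigma in pixels.
#' @param pixelSizeNm pixel size in nm.
#' @param offRateFrames mean off-state duration in frames.
#' @param onFrames mean on-state duration in frames (geometric, minimum 1).
#' @param density emitter density for the uniform-random layout, per um^2.
#' @param gridSpacingPx grid spacing for the grid layout, pixels.
#' @param convention PSF pixelization convention (see \code{\link{psfShape}}).
#' @param seed RNG seed recorded with the configuration.
#' @return a list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(nFrames = 100, photonsPerFrame = 250,
                             backgroundPhotons = 20, psfSigmaPx = 1.5,
                             pixelSizeNm = 100, offRateFrames = 2,
                             onFrames = 1, density = 0.15,
                             gridSpacingPx = 20,
                             convention = "integrated", seed = 1) {
    cfg <- as.list(environment())
    stopifnot(nFrames >= 1, photonsPerFrame >= 0, backgroundPhotons >= 0,
              psfSigmaPx > 0, pixelSizeNm > 0, offRateFrames > 0)
    class(cfg) <- "SimulationConfig"
    cfg
}

#' Ground-truth emitter configurations
#'
#' Two layouts: \code{"blinking-uniform"} draws a Poisson number of
#' emitters uniformly over the frame at \code{config$density} emitters per
#' um^2 and gives each a two-state on/off trajectory (geometric dwell
#' times: mean on \code{onFrames}, mean off \code{offRateFrames}; initial
#' state drawn from the stationary distribution); \code{"constant-grid"}
#' places emitters on a square grid of \code{gridSpacingPx} spacing
#' (margin half a spacing) that are on in every frame, each jittered by a
#' uniform sub-pixel offset in [-0.5, 0.5) so the set spans sub-pixel
#' phases.
#'
#' @param mode \code{"blinking-uniform"} or \code{"constant-grid"}.
#' @param frameShape integer(2): rows, cols of the frame.
#' @param config a \code{\link{simulationConfig}}.
#' @param seed RNG seed (defaults to \code{config$seed}).
#' @param subPixelJitter logical; jitter grid positions within the pixel
#'   (default TRUE).
#' @return an \linkS4class{EmitterSet}.
#' @export
makeEmitters <- function(mode = c("blinking-uniform", "constant-grid"),
                         frameShape, config = simulationConfig(),
                         seed = config$seed, subPixelJitter = TRUE) {
    mode <- match.arg(mode)
    nr <- frameShape[1]; nc <- frameShape[2]
    old <- .Random.seed.exists()
    set.seed(seed)
    on.exit(restoreSeed(old))
    if (mode == "constant-grid") {
        sp <- config$gridSpacingPx
        m <- sp / 2
        gx <- seq(m, nc - m + 1e-9, by = sp)
        gy <- seq(m, nr - m + 1e-9, by = sp)
        if (!length(gx) || !length(gy))
            stop("frame too small for the requested grid spacing")
        pos <- as.matrix(expand.grid(x = gx, y = gy))
        if (subPixelJitter)
            pos <- pos + matrix(runif(length(pos), -0.5, 0.5 - 1e-9),
                                nrow(pos), 2)
        on <- matrix(TRUE, nrow(pos), config$nFrames)
        layout <- "grid"
        meta <- list(spacing = sp, jitter = subPixelJitter, seed = seed)
    } else {
        areaUm2 <- nr * nc * (config$pixelSizeNm / 1000)^2
        n <- rpois(1, config$density * areaUm2)
        if (n < 1)
            stop("density too low: zero emitters drawn for this frame size")
        pos <- cbind(x = runif(n, -0.5, nc - 0.5),
                     y = runif(n, -0.5, nr - 0.5))
        pOffOn <- 1 / config$offRateFrames
        pOnOff <- 1 / max(config$onFrames, 1)
        dutyOn <- pOffOn / (pOffOn + pOnOff)
        on <- matrix(FALSE, n, config$nFrames)
        state <- runif(n) < dutyOn
        for (f in seq_len(config$nFrames)) {
            on[, f] <- state
            flip <- runif(n) < ifelse(state, pOnOff, pOffOn)
            state <- xor(state, flip)
        }
        layout <- "uniform-random"
        meta <- list(density = config$density, seed = seed,
                     dutyCycle = dutyOn)
    }
    new("EmitterSet", positions = pos,
        intensity = rep(config$photonsPerFrame, nrow(pos)),
        onState = on, layout = layout, meta = meta)
}

#' Photon-expectation image for one frame
#'
#' Sum over emitters that are on in the frame of a 2-D Gaussian PSF
#' carrying \code{intensity} total photons (sigma \code{psfSigmaPx},
#' integrated over pixels by default), plus the uniform background.
#'
#' @param emitters an \linkS4class{EmitterSet}.
#' @param frameIndex frame number (1-based).
#' @param frameShape integer(2): rows, cols.
#' @param config a \code{\link{simulationConfig}}.
#' @return numeric matrix of expected photons per pixel.
#' @export
renderExpectation <- function(emitters, frameIndex, frameShape,
                              config = simulationConfig()) {
    nr <- frameShape[1]; nc <- frameShape[2]
    img <- matrix(config$backgroundPhotons, nr, nc)
    onIdx <- which(emitters@onState[, frameIndex])
    r <- ceiling(5 * config$psfSigmaPx)
    for (e in onIdx) {
        x0 <- emitters@positions[e, 1]; y0 <- emitters@positions[e, 2]
        h <- photonsToHeight(emitters@intensity[e], config$psfSigmaPx)
        xs <- max(0, floor(x0) - r):min(nc - 1, floor(x0) + r)
        ys <- max(0, floor(y0) - r):min(nr - 1, floor(y0) + r)
        img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] +
            h * psfShape(xs, ys, x0, y0, config$psfSigmaPx,
                         config$convention)$shape
    }
    img
}

#' sCMOS camera forward model
#'
#' Applies the pixel-wise camera model to a photon-expectation image:
#' photo-electrons are Poisson with expectation \code{rqe_i *
#' expectation_i}, multiplied by the pixel gain, plus Gaussian read noise
#' of variance \code{var_i}, plus the pixel offset.  Output ADU are
#' real-valued by default; set \code{quantize = TRUE} to round to integers.
#'
#' @param expectation numeric matrix of expected photons per pixel (>= 0).
#' @param calib a \linkS4class{CalibrationMap} of matching dimension.
#' @param seed optional RNG seed for this frame (NULL: use current stream).
#' @param quantize round ADU to integers (default FALSE).
#' @return numeric matrix of ADU values.
#' @export
cameraForward <- function(expectation, calib, seed = NULL,
                          quantize = FALSE) {
    if (any(expectation < 0)) stop("expectation must be non-negative")
    if (!identical(dim(expectation), dim(calib@offset)))
        stop("expectation and calibration dimensions differ")
    if (!is.null(seed)) {
        old <- .Random.seed.exists(); set.seed(seed)
        on.exit(restoreSeed(old))
    }
    n <- length(expectation)
    e <- rpois(n, calib@rqe * expectation)
    adu <- calib@gain * e + rnorm(n, sd = sqrt(calib@variance)) +
        calib@offset
    if (quantize) adu <- round(adu)
    matrix(adu, nrow(expectation), ncol(expectation))
}

#' Simulate a full SMLM movie with ground truth
#'
#' Draws an emitter set, renders each frame's photon expectation and passes
#' it through the camera forward model.  Deterministic given the seed.
#'
#' @param calib a \linkS4class{CalibrationMap}; its dimensions set the
#'   frame size.
#' @param mode emitter layout, as in \code{\link{makeEmitters}}.
#' @param config a \code{\link{simulationConfig}}.
#' @param seed master seed (defaults to \code{config$seed}).
#' @param emitters optionally, a pre-built \linkS4class{EmitterSet}.
#' @return list with \code{movie} (\linkS4class{CameraMovie}) and
#'   \code{truth} (\linkS4class{EmitterSet}).
#' @examples
#' cal <- synthCalibration(c(48, 48), seed = 1)
#' sim <- simulateMovie(cal, "constant-grid",
#'                      simulationConfig(nFrames = 5), seed = 2)
#' @export
simulateMovie <- function(calib, mode = "blinking-uniform",
                          config = simulationConfig(), seed = config$seed,
                          emitters = NULL) {
    shape <- dim(calib@offset)
    if (is.null(emitters))
        emitters <- makeEmitters(mode, shape, config, seed = seed)
    old <- .Random.seed.exists()
    set.seed(seed + 1L)
    on.exit(restoreSeed(old))
    stack <- array(0, c(shape, config$nFrames))
    for (f in seq_len(config$nFrames))
        stack[, , f] <- cameraForward(
            renderExpectation(emitters, f, shape, config), calib)
    list(movie = CameraMovie(stack, pixelSizeNm = config$pixelSizeNm),
         truth = emitters)
}

#' Simulate a calibration acquisition
#'
#' Generates the dark movie plus K flat-illumination movies from a known
#' \linkS4class{CalibrationMap}, for round-trip testing of
#' \code{\link{calibrateCamera}}.  Level expectations default to 0.25,
#' 0.5, 0.75 and 1 times \code{maxPhotons}, spanning the linear regime.
#' Optionally the lamp intensity fluctuates frame to frame by a common
#' multiplicative factor.
#'
#' @param calib the generating \linkS4class{CalibrationMap}.
#' @param nFrames frames per movie.
#' @param maxPhotons expectation (photo-electrons at RQE 1) of the highest
#'   level.
#' @param levels vector of level fractions of \code{maxPhotons}.
#' @param lampSdFrac fractional frame-to-frame lamp fluctuation (default 0).
#' @param seed RNG seed.
#' @return an \linkS4class{IlluminationSeries}.
#' @export
simulateIlluminationSeries <- function(calib, nFrames = 2000,
                                       maxPhotons = 2000,
                                       levels = c(0.25, 0.5, 0.75, 1),
                                       lampSdFrac = 0, seed = 1) {
    shape <- dim(calib@offset)
    old <- .Random.seed.exists()
    set.seed(seed)
    on.exit(restoreSeed(old))
    darkExp <- matrix(0, shape[1], shape[2])
    mk <- function(expect) {
        stack <- array(0, c(shape, nFrames))
        for (f in seq_len(nFrames)) {
            fac <- if (lampSdFrac > 0) max(0, 1 + rnorm(1, sd = lampSdFrac))
                   else 1
            stack[, , f] <- cameraForward(expect * fac, calib)
        }
        CameraMovie(stack)
    }
    dark <- mk(darkExp)
    lvls <- lapply(levels, function(fr) mk(darkExp + fr * maxPhotons))
    IlluminationSeries(dark, lvls)
}
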