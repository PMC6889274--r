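# Shared fixtures: small uniform and structured calibrations built in code.

uniformCalib <- function(nr = 16, nc = 16, offset = 100, variance = 4,
                         gain = 2, rqe = 1) {
    CalibrationMap(matrix(offset, nr, nc), matrix(variance, nr, nc),
                   matrix(gain, nr, nc), matrix(rqe, nr, nc))
}

# calibration ROI list in the shape buildTerms()/fitEmitter() expect
uniformCalibRoi <- function(S = 11, offset = 0, variance = 0, gain = 1,
                            rqe = 1, meanGain = gain) {
    list(offset = matrix(offset, S, S), variance = matrix(variance, S, S),
         gain = matrix(gain, S, S), rqe = matrix(rqe, S, S),
         meanGain = meanGain)
}

# movie with every frame identical
constantMovie <- function(value, nr = 8, nc = 8, frames = 3)
    CameraMovie(array(value, c(nr, nc, frames)))

# single-emitter expectation image via the simulator
oneEmitterImage <- function(shape, x, y, photons, background, sigma = 1.5,
                            convention = "integrated") {
    cfg <- simulationConfig(nFrames = 1, photonsPerFrame = photons,
                            backgroundPhotons = background,
                            psfSigmaPx = sigma, convention = convention)
    em <- new("EmitterSet", positions = cbind(x = x, y = y),
              intensity = photons, onState = matrix(TRUE, 1, 1),
              layout = "grid")
    renderExpectation(em, 1, shape, cfg)
}
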