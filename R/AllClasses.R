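#' @import methods
#' @importFrom stats median quantile rnorm rpois runif rgeom sd var cor
#'   cor.test ks.test dnorm pnorm coef
#' @importFrom utils write.csv read.csv packageVersion
#' @useDynLib sCMOSrqe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' CameraMovie: a stack of camera frames in ADU
#'
#' Container for a raw (or simulated) camera movie.  Frames are stored as a
#' numeric 3-D array indexed \code{[row, col, frame]}.  Values are analog to
#' digital units (ADU) as read from the camera; they may be real-valued for
#' simulated data.
#'
#' Coordinate convention used throughout the package: positions are
#' continuous, zero-based pixel coordinates \code{(x, y) = (col, row)} with
#' the center of matrix element \code{[i + 1, j + 1]} at \code{(x = j,
#' y = i)}; pixel \code{j} covers \code{[j - 0.5, j + 0.5)}.
#'
#' @slot frames numeric 3-D array \code{[row, col, frame]} of ADU counts.
#' @slot pixelSizeNm numeric(1), physical pixel size in nm (metadata).
#' @export
setClass("CameraMovie",
         representation(frames = "array", pixelSizeNm = "numeric"),
         prototype(pixelSizeNm = 100))

setValidity("CameraMovie", function(object) {
    f <- object@frames
    if (length(dim(f)) != 3L)
        return("'frames' must be a 3-D array [row, col, frame]")
    if (!all(is.finite(f)))
        return("frame values must be finite")
    if (length(object@pixelSizeNm) != 1L || object@pixelSizeNm <= 0)
        return("'pixelSizeNm' must be a positive scalar")
    TRUE
})

#' IlluminationSeries: dark movie plus ordered illuminated movies
#'
#' A calibration acquisition: one dark movie and K movies at increasing
#' illumination, all with identical pixel dimensions.
#'
#' @slot dark a \linkS4class{CameraMovie} acquired with no light.
#' @slot levels list of \linkS4class{CameraMovie}, ordered by increasing
#'   mean intensity.
#' @export
setClass("IlluminationSeries",
         representation(dark = "CameraMovie", levels = "list"))

setValidity("IlluminationSeries", function(object) {
    if (length(object@levels) < 1L)
        return("at least one illuminated level is required")
    dd <- dim(object@dark@frames)[1:2]
    for (lv in object@levels) {
        if (!is(lv, "CameraMovie"))
            return("'levels' must be a list of CameraMovie objects")
        if (!identical(dim(lv@frames)[1:2], dd))
            return("all movies must share identical pixel dimensions")
        if (mean(lv@frames) <= mean(object@dark@frames))
            return("each illuminated level must exceed the dark mean ADU")
    }
    TRUE
})

#' CalibrationMap: per-pixel sCMOS camera model
#'
#' Per-pixel camera characterization: offset (ADU), read-noise variance
#' (ADU^2), gain (ADU per photo-electron), relative quantum efficiency
#' (dimensionless, locally normalized to ~1), and the diagnostic intercept
#' of the photon-transfer line fit.
#'
#' @slot offset numeric matrix, mean dark level per pixel (ADU).
#' @slot variance numeric matrix, dark temporal variance per pixel (ADU^2).
#' @slot gain numeric matrix, ADU per photo-electron per pixel.
#' @slot rqe numeric matrix, relative quantum efficiency per pixel.
#' @slot intercept numeric matrix, photon-transfer fit intercept (ADU^2),
#'   diagnostic only.
#' @slot meanGain numeric(1), arithmetic mean of \code{gain}.
#' @slot stats list of summary statistics (std of gain and RQE, gain-RQE
#'   correlation, clipped-variance counter).
#' @export
setClass("CalibrationMap",
         representation(offset = "matrix", variance = "matrix",
                        gain = "matrix", rqe = "matrix",
                        intercept = "matrix", meanGain = "numeric",
                        stats = "list"),
         prototype(stats = list()))

setValidity("CalibrationMap", function(object) {
    d <- dim(object@offset)
    for (s in c("variance", "gain", "rqe", "intercept"))
        if (!identical(dim(slot(object, s)), d))
            return(sprintf("'%s' dimensions differ from 'offset'", s))
    if (any(!is.finite(object@gain)) || any(object@gain <= 0))
        return("gain must be positive and finite everywhere")
    if (any(!is.finite(object@variance)) || any(object@variance < 0))
        return("read-noise variance must be non-negative")
    if (any(!is.finite(object@rqe)) || any(object@rqe <= 0))
        return("rqe must be positive and finite everywhere")
    if (length(object@meanGain) != 1L ||
        abs(object@meanGain - mean(object@gain)) >
            1e-8 * max(1, abs(object@meanGain)))
        return("meanGain must equal the arithmetic mean of 'gain'")
    TRUE
})

#' EmitterSet: ground-truth emitters for simulation and scoring
#'
#' Ground-truth emitter configuration: sub-pixel positions (zero-based pixel
#' coordinates), per-emitter photon rate while on, and the per-frame on/off
#' state matrix.
#'
#' @slot positions numeric matrix with columns \code{x}, \code{y}
#'   (zero-based pixel units).
#' @slot intensity numeric vector, expected photons per frame while on.
#' @slot onState logical matrix \code{[emitter, frame]}.
#' @slot layout character(1), \code{"uniform-random"} or \code{"grid"}.
#' @slot meta list of generator metadata (density, spacing, seed, ...).
#' @export
setClass("EmitterSet",
         representation(positions = "matrix", intensity = "numeric",
                        onState = "matrix", layout = "character",
                        meta = "list"),
         prototype(layout = "uniform-random", meta = list()))

setValidity("EmitterSet", function(object) {
    n <- nrow(object@positions)
    if (ncol(object@positions) != 2L)
        return("'positions' must have two columns (x, y)")
    if (length(object@intensity) != n)
        return("'intensity' length must match the number of emitters")
    if (any(object@intensity < 0))
        return("intensities must be non-negative")
    if (nrow(object@onState) != n)
        return("'onState' must have one row per emitter")
    if (!object@layout %in% c("uniform-random", "grid"))
        return("'layout' must be 'uniform-random' or 'grid'")
    TRUE
})
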