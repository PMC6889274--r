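# Generics, accessors and show() methods for the core classes.

#' @rdname CameraMovie-class
#' @param frames numeric 3-D array \code{[row, col, frame]}, or a list of
#'   equally sized matrices.
#' @param pixelSizeNm physical pixel size in nm.
#' @return \code{CameraMovie()} returns a \linkS4class{CameraMovie}.
#' @examples
#' mv <- CameraMovie(array(100, c(4, 4, 3)))
#' nFrames(mv)
#' @export
CameraMovie <- function(frames, pixelSizeNm = 100) {
    if (is.list(frames))
        frames <- array(unlist(frames),
                        c(dim(frames[[1]]), length(frames)))
    new("CameraMovie", frames = frames, pixelSizeNm = pixelSizeNm)
}

#' @rdname IlluminationSeries-class
#' @param dark dark \linkS4class{CameraMovie}.
#' @param levels list of illuminated \linkS4class{CameraMovie} objects.
#' @return an \linkS4class{IlluminationSeries}.
#' @export
IlluminationSeries <- function(dark, levels) {
    if (is(levels, "CameraMovie")) levels <- list(levels)
    new("IlluminationSeries", dark = dark, levels = levels)
}

#' Number of frames in a movie
#' @param x a \linkS4class{CameraMovie}.
#' @return integer frame count.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname nFrames
#' @export
setMethod("nFrames", "CameraMovie", function(x) dim(x@frames)[3L])

#' Pixel dimensions (rows, cols)
#' @param x a \linkS4class{CameraMovie} or \linkS4class{CalibrationMap}.
#' @return integer(2): rows, cols.
#' @export
setGeneric("frameDim", function(x) standardGeneric("frameDim"))

#' @rdname frameDim
#' @export
setMethod("frameDim", "CameraMovie", function(x) dim(x@frames)[1:2])

#' @rdname frameDim
#' @export
setMethod("frameDim", "CalibrationMap", function(x) dim(x@offset))

#' Frame stack of a movie
#' @param x a \linkS4class{CameraMovie}.
#' @param i optional frame index; if given a single matrix is returned.
#' @return the 3-D frame array, or one frame as a matrix.
#' @export
frames <- function(x, i = NULL) {
    stopifnot(is(x, "CameraMovie"))
    if (is.null(i)) x@frames else x@frames[, , i, drop = TRUE]
}

#' Calibration map accessors
#'
#' Per-pixel maps and scalar attributes of a \linkS4class{CalibrationMap}.
#'
#' @param x a \linkS4class{CalibrationMap}.
#' @return \code{offsetMap}, \code{varianceMap}, \code{gainMap},
#'   \code{rqeMap} and \code{interceptMap} return numeric matrices;
#'   \code{meanGain} a scalar; \code{calibrationStats} a list.
#' @name calibration-accessors
NULL

#' @rdname calibration-accessors
#' @export
offsetMap <- function(x) x@offset
#' @rdname calibration-accessors
#' @export
varianceMap <- function(x) x@variance
#' @rdname calibration-accessors
#' @export
gainMap <- function(x) x@gain
#' @rdname calibration-accessors
#' @export
rqeMap <- function(x) x@rqe
#' @rdname calibration-accessors
#' @export
interceptMap <- function(x) x@intercept
#' @rdname calibration-accessors
#' @export
meanGain <- function(x) x@meanGain
#' @rdname calibration-accessors
#' @export
calibrationStats <- function(x) x@stats

#' @rdname CalibrationMap-class
#' @param offset,variance,gain,rqe numeric matrices of identical dimension.
#' @param intercept optional numeric matrix (photon-transfer intercept).
#' @param stats optional list of summary statistics.
#' @return a \linkS4class{CalibrationMap}.
#' @export
CalibrationMap <- function(offset, variance, gain, rqe,
                           intercept = NULL, stats = list()) {
    if (is.null(intercept))
        intercept <- matrix(0, nrow(offset), ncol(offset))
    new("CalibrationMap", offset = offset, variance = variance,
        gain = gain, rqe = rqe, intercept = intercept,
        meanGain = mean(gain), stats = stats)
}

#' Emitter set accessors
#' @param x an \linkS4class{EmitterSet}.
#' @return \code{emitterPositions}: matrix of (x, y); \code{onState}:
#'   logical matrix [emitter, frame]; \code{nEmitters}: integer count.
#' @name emitter-accessors
NULL

#' @rdname emitter-accessors
#' @export
emitterPositions <- function(x) x@positions
#' @rdname emitter-accessors
#' @export
onState <- function(x) x@onState
#' @rdname emitter-accessors
#' @export
nEmitters <- function(x) nrow(x@positions)

setMethod("show", "CameraMovie", function(object) {
    d <- dim(object@frames)
    cat(sprintf("CameraMovie: %d x %d pixels, %d frames (%.0f nm pixels)\n",
                d[1], d[2], d[3], object@pixelSizeNm))
    cat(sprintf("  ADU range [%.1f, %.1f], mean %.1f\n",
                min(object@frames), max(object@frames),
                mean(object@frames)))
})

setMethod("show", "IlluminationSeries", function(object) {
    cat(sprintf("IlluminationSeries: dark (%d frames) + %d levels\n",
                nFrames(object@dark), length(object@levels)))
    for (k in seq_along(object@levels))
        cat(sprintf("  level %d: %d frames, mean %.1f ADU\n", k,
                    nFrames(object@levels[[k]]),
                    mean(object@levels[[k]]@frames)))
})

setMethod("show", "CalibrationMap", function(object) {
    d <- dim(object@offset)
    cat(sprintf("CalibrationMap: %d x %d pixels\n", d[1], d[2]))
    cat(sprintf("  offset   mean %.2f ADU\n", mean(object@offset)))
    cat(sprintf("  variance mean %.2f ADU^2\n", mean(object@variance)))
    cat(sprintf("  gain     mean %.4f ADU/e- (std %.2f%%)\n",
                object@meanGain,
                100 * sd(object@gain) / object@meanGain))
    cat(sprintf("  rqe      std %.2f%%\n", 100 * sd(object@rqe)))
    if (!is.null(object@stats$gainRqeCorrelation))
        cat(sprintf("  gain-rqe correlation %.3f\n",
                    object@stats$gainRqeCorrelation))
})

setMethod("show", "EmitterSet", function(object) {
    cat(sprintf("EmitterSet (%s): %d emitters, %d frames\n",
                object@layout, nrow(object@positions),
                ncol(object@onState)))
    cat(sprintf("  mean intensity %.1f photons/frame, duty cycle %.2f\n",
                mean(object@intensity), mean(object@onState)))
})
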