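# Per-pixel camera calibration from dark and illuminated movies:
# offset and read-noise variance from the dark movie, gain from the
# photon-transfer (temporal variance vs mean) line fit across illumination
# levels, and RQE from the locally normalized highest-level image.

# Temporal mean and population variance (divisor M) per pixel.
temporalStats <- function(frames) {
    M <- dim(frames)[3L]
    mu <- rowMeans(frames, dims = 2L)
    mu2 <- rowMeans(frames^2, dims = 2L)
    list(mean = mu, var = mu2 - mu^2, M = M)
}

#' Offset and read-noise variance from a dark movie
#'
#' The per-pixel offset is the temporal mean of the dark movie; the
#' read-noise variance is the temporal population variance (divisor M,
#' i.e. mean of squares minus squared mean).
#'
#' @param dark a \linkS4class{CameraMovie} acquired with no light.
#' @return list with matrices \code{offset} (ADU) and \code{variance}
#'   (ADU^2), and \code{M} the frame count.
#' @examples
#' mv <- CameraMovie(array(c(99, 101), c(1, 1, 2)))
#' computeOffsetVariance(mv)   # offset 100, variance 1
#' @export
computeOffsetVariance <- function(dark) {
    stopifnot(is(dark, "CameraMovie"))
    if (nFrames(dark) < 2L)
        stop("at least 2 dark frames are required")
    if (!all(is.finite(dark@frames)))
        stop("non-finite pixel values in dark movie")
    temporalStats(dark@frames)[c("mean", "var", "M")] |>
        stats::setNames(c("offset", "variance", "M"))
}

#' Lamp-fluctuation-corrected statistics of an illuminated movie
#'
#' Computes per-pixel temporal mean and population variance of an
#' illuminated calibration movie, subtracts the variance of the per-frame
#' spatial-average intensity from every pixel's variance (correcting for
#' fluctuations of the illumination source), then subtracts the dark
#' offset from the mean and the dark variance from the variance.  Corrected
#' variances below zero are clipped to zero.
#'
#' @param level an illuminated \linkS4class{CameraMovie}.
#' @param darkOffset,darkVariance matrices from
#'   \code{\link{computeOffsetVariance}}.
#' @return list with matrices \code{mean} (dark-subtracted ADU) and
#'   \code{variance} (corrected ADU^2), scalar \code{lampVariance}, and
#'   \code{nClipped}, the number of pixels clipped at zero variance.
#' @export
lampCorrectedStats <- function(level, darkOffset, darkVariance) {
    stopifnot(is(level, "CameraMovie"))
    if (!identical(dim(level@frames)[1:2], dim(darkOffset)))
        stop("level and dark maps must share dimensions")
    st <- temporalStats(level@frames)
    frameMeans <- colMeans(level@frames, dims = 2L)
    lampVar <- mean(frameMeans^2) - mean(frameMeans)^2
    v <- st$var - lampVar - darkVariance
    nClipped <- sum(v < 0)
    if (nClipped > 0) v[v < 0] <- 0
    list(mean = st$mean - darkOffset, variance = v,
         lampVariance = lampVar, nClipped = nClipped)
}

#' Per-pixel gain from the photon-transfer line
#'
#' For each pixel, fits a straight line (equal weights) of corrected
#' temporal variance against corrected temporal mean over the K
#' illumination levels plus an appended origin point (0, 0).  The slope is
#' the gain in ADU per photo-electron; the intercept is kept as a
#' diagnostic.
#'
#' @param stats list of K lists with matrices \code{mean} and
#'   \code{variance}, as returned by \code{\link{lampCorrectedStats}}.
#' @return list with matrices \code{gain}, \code{intercept}, and a logical
#'   matrix \code{degenerate} flagging pixels whose abscissa had no spread
#'   (gain left NA there).
#' @examples
#' st <- list(list(mean = matrix(100), variance = matrix(200)),
#'            list(mean = matrix(200), variance = matrix(400)))
#' fitGain(st)$gain      # 2
#' @export
fitGain <- function(stats) {
    K <- length(stats)
    if (K < 1L) stop("at least one illumination level is required")
    d <- dim(stats[[1]]$mean)
    # running sums over the K points plus the origin (which adds zeros)
    n <- K + 1
    Sx <- Sy <- Sxx <- Sxy <- matrix(0, d[1], d[2])
    for (st in stats) {
        Sx <- Sx + st$mean;            Sy <- Sy + st$variance
        Sxx <- Sxx + st$mean^2;        Sxy <- Sxy + st$mean * st$variance
    }
    den <- n * Sxx - Sx^2
    degenerate <- den <= .Machine$double.eps * pmax(1, Sxx)
    den[degenerate] <- NA_real_
    gain <- (n * Sxy - Sx * Sy) / den
    intercept <- (Sy - gain * Sx) / n
    list(gain = gain, intercept = intercept, degenerate = degenerate)
}

#' Relative quantum efficiency map
#'
#' Converts the temporal mean of the highest-illumination movie to
#' photo-electrons, \code{im = (mean - offset) / gain}, smooths it with the
#' normalized \code{kernelSize x kernelSize} uniform filter, and returns
#' the ratio \code{im / smoothed(im)}.  The local normalization removes
#' long-range illumination non-uniformity, so the result is a relative
#' (locally unit-mean) quantum efficiency.
#'
#' @param highest the highest-illumination \linkS4class{CameraMovie}.
#' @param offset,gain calibration matrices.
#' @param kernelSize side of the uniform smoothing kernel (default 10).
#' @param pad boundary mode for the uniform filter (\code{"nearest"} or
#'   \code{"reflect"}).
#' @return matrix of per-pixel RQE values.
#' @export
computeRQE <- function(highest, offset, gain, kernelSize = 10L,
                       pad = "nearest") {
    stopifnot(is(highest, "CameraMovie"))
    if (any(gain <= 0, na.rm = TRUE) || anyNA(gain))
        stop("gain must be positive everywhere")
    im <- (temporalStats(highest@frames)$mean - offset) / gain
    sm <- uniformFilter(im, kernelSize, pad = pad)
    if (any(sm <= 0))
        stop("smoothed image is not positive everywhere; ",
             "illumination too low or offset miscalibrated")
    im / sm
}

#' Full camera calibration from an illumination series
#'
#' Composes \code{\link{computeOffsetVariance}},
#' \code{\link{lampCorrectedStats}}, \code{\link{fitGain}} and
#' \code{\link{computeRQE}}: per-pixel offset and read-noise variance from
#' the dark movie, gain from the photon-transfer line over all levels, and
#' RQE from the highest level.
#'
#' @param series an \linkS4class{IlluminationSeries}.
#' @param kernelSize uniform-filter size for the RQE normalization.
#' @param pad boundary mode for the uniform filter.
#' @return a \linkS4class{CalibrationMap}; its \code{stats} list carries
#'   the gain and RQE standard deviations, their correlation, and the
#'   clipped-variance counter.
#' @examples
#' \donttest{
#' truth <- synthCalibration(c(32, 32), seed = 1)
#' series <- simulateIlluminationSeries(truth, nFrames = 500, seed = 2)
#' cal <- calibrateCamera(series)
#' }
#' @export
calibrateCamera <- function(series, kernelSize = 10L, pad = "nearest") {
    stopifnot(is(series, "IlluminationSeries"))
    dk <- computeOffsetVariance(series@dark)
    stats <- lapply(series@levels, lampCorrectedStats,
                    darkOffset = dk$offset, darkVariance = dk$variance)
    gf <- fitGain(stats)
    if (anyNA(gf$gain))
        stop(sum(is.na(gf$gain)), " pixels had a degenerate gain fit")
    rqe <- computeRQE(series@levels[[length(series@levels)]],
                      dk$offset, gf$gain, kernelSize, pad)
    mg <- mean(gf$gain)
    CalibrationMap(dk$offset, dk$variance, gf$gain, rqe,
                   intercept = gf$intercept,
                   stats = list(
                       stdGain = sd(gf$gain),
                       stdRqe = sd(rqe),
                       gainRqeCorrelation = cor(as.vector(gf$gain),
                                                as.vector(rqe)),
                       nClippedVariance = sum(vapply(stats,
                           function(s) s$nClipped, numeric(1)))))
}
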