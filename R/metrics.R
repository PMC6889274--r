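# Evaluation surfaces: super-resolution rendering of localization tables,
# per-pixel localization counts against smoothed RQE, and precision/bias
# scoring against ground truth.

#' Render localizations as a super-resolution image
#'
#' Adds a unit-height Gaussian of sigma \code{renderSigma} (default 1
#' pixel, sampled at pixel centers) at each fitted position.  A pixel
#' value of N then corresponds to roughly N localizations in or very near
#' the pixel.
#'
#' @param locs data.frame with zero-based pixel positions \code{x},
#'   \code{y} (e.g. from \code{\link{batchFit}}).
#' @param shape integer(2): rows, cols of the output image.
#' @param renderSigma Gaussian sigma of the rendering kernel, pixels.
#' @return numeric matrix; attribute \code{nDropped} counts localizations
#'   outside the frame.
#' @export
renderImage <- function(locs, shape, renderSigma = 1) {
    img <- matrix(0, shape[1], shape[2])
    if (nrow(locs) == 0) return(img)
    inb <- locs$x > -0.5 & locs$x < shape[2] - 0.5 &
           locs$y > -0.5 & locs$y < shape[1] - 0.5
    r <- ceiling(5 * renderSigma)
    for (i in which(inb)) {
        x0 <- locs$x[i]; y0 <- locs$y[i]
        xs <- max(0, round(x0) - r):min(shape[2] - 1, round(x0) + r)
        ys <- max(0, round(y0) - r):min(shape[1] - 1, round(y0) + r)
        img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] +
            psfShape(xs, ys, x0, y0, renderSigma, "sampled")$shape
    }
    attr(img, "nDropped") <- sum(!inb)
    img
}

#' Localization counts versus smoothed RQE
#'
#' Counts localizations by center pixel (the pixel containing the fitted
#' position under the center-at-integer convention, i.e. \code{round}),
#' pairs each pixel's count with its smoothed RQE, and reports the
#' Pearson correlation and its p-value over all pixels.  The top/bottom
#' smoothed-RQE quintile count ratio quantifies detection enrichment on
#' high-RQE pixels.
#'
#' @param locs localization or candidate data.frame with \code{x},
#'   \code{y} (zero-based pixels), or \code{row}, \code{col} for raw
#'   candidates.
#' @param calib a \linkS4class{CalibrationMap}.
#' @param psfSigmaPx sigma of the smoothing kernel.
#' @param quantile quintile width for the enrichment ratio (default 0.2).
#' @return list: \code{counts} (matrix), \code{smoothedRqe},
#'   \code{pearsonR}, \code{pValue}, \code{quintileRatio} (top/bottom
#'   total counts), \code{nTop}, \code{nBottom}.
#' @export
countsVsRQE <- function(locs, calib, psfSigmaPx = 1.5, quantile = 0.2) {
    d <- dim(calib@offset)
    if (!is.null(locs$x)) {
        px <- as.integer(round(locs$x)); py <- as.integer(round(locs$y))
    } else {
        px <- as.integer(locs$col); py <- as.integer(locs$row)
    }
    inb <- px >= 0 & px <= d[2] - 1 & py >= 0 & py <= d[1] - 1
    counts <- matrix(0L, d[1], d[2])
    idx <- (px[inb]) * d[1] + py[inb] + 1L
    tab <- tabulate(idx, nbins = d[1] * d[2])
    counts[] <- tab
    smRqe <- smoothMap(calib@rqe, psfSigmaPx)
    ct <- cor.test(as.vector(counts), as.vector(smRqe))
    qs <- quantile(as.vector(smRqe), c(quantile, 1 - quantile),
                   names = FALSE)
    top <- sum(counts[smRqe >= qs[2]])
    bottom <- sum(counts[smRqe <= qs[1]])
    list(counts = counts, smoothedRqe = smRqe,
         pearsonR = unname(ct$estimate), pValue = ct$p.value,
         quintileRatio = if (bottom > 0) top / bottom else Inf,
         nTop = top, nBottom = bottom)
}

#' Precision and precision-corrected bias against ground truth
#'
#' For each emitter, the localization precision is the standard deviation
#' of its fitted positions over frames and the raw deviation is its mean
#' fitted position minus the true position.  The bias estimate removes
#' the sampling variance of the K-frame mean:
#' \code{bias^2 = max(0, mean(dev^2) - mean(prec^2 / K))}, per axis.
#' With several replicates, across-replicate standard deviations provide
#' error bars.
#'
#' @param locs localization data.frame with \code{x}, \code{y} and an
#'   \code{emitter} column (e.g. via \code{\link{candidatesFromTruth}} +
#'   \code{\link{batchFit}}), or a list of such tables (replicates).
#' @param truth matching \linkS4class{EmitterSet} (or list, one per
#'   replicate).
#' @param pixelSizeNm pixel size for nm output.
#' @param correctPrecision subtract the precision term (default TRUE).
#' @return list with per-axis precision and bias in nm
#'   (\code{precisionNm}, \code{biasNm}, \code{biasMagnitudeNm}),
#'   across-replicate standard deviations (\code{precisionSdNm},
#'   \code{biasSdNm}, \code{biasMagnitudeSdNm}), the per-replicate values,
#'   and the number of emitters excluded for having fewer than two fits.
#' @export
precisionBias <- function(locs, truth, pixelSizeNm = 100,
                          correctPrecision = TRUE) {
    if (is.data.frame(locs)) { locs <- list(locs); truth <- list(truth) }
    oneRep <- function(tab, tru) {
        pos <- tru@positions
        sp <- split(tab, tab$emitter)
        sp <- sp[vapply(sp, nrow, 0L) >= 2L]
        nExcluded <- nEmitters(tru) - length(sp)
        stats <- t(vapply(sp, function(s) {
            e <- s$emitter[1]
            c(mx = mean(s$x) - unname(pos[e, 1]),
              my = mean(s$y) - unname(pos[e, 2]),
              sx = sd(s$x), sy = sd(s$y), K = nrow(s))
        }, numeric(5)))
        prec <- c(x = mean(stats[, "sx"]), y = mean(stats[, "sy"]))
        biasSq <- function(dev, s, K)
            max(0, mean(dev^2) -
                   if (correctPrecision) mean(s^2 / K) else 0)
        bias <- c(x = sqrt(biasSq(stats[, "mx"], stats[, "sx"],
                                  stats[, "K"])),
                  y = sqrt(biasSq(stats[, "my"], stats[, "sy"],
                                  stats[, "K"])))
        list(precision = prec * pixelSizeNm, bias = bias * pixelSizeNm,
             biasMagnitude = sqrt(sum((bias * pixelSizeNm)^2)),
             nExcluded = nExcluded)
    }
    reps <- Map(oneRep, locs, truth)
    pm <- t(vapply(reps, `[[`, numeric(2), "precision"))
    bm <- t(vapply(reps, `[[`, numeric(2), "bias"))
    mag <- vapply(reps, `[[`, numeric(1), "biasMagnitude")
    sdOr0 <- function(v) if (length(v) > 1) apply(as.matrix(v), 2, sd)
                         else rep(NA_real_, ncol(as.matrix(v)))
    list(precisionNm = colMeans(pm), biasNm = colMeans(bm),
         biasMagnitudeNm = mean(mag),
         precisionSdNm = sdOr0(pm), biasSdNm = sdOr0(bm),
         biasMagnitudeSdNm = if (length(mag) > 1) sd(mag) else NA_real_,
         perReplicate = reps,
         nExcluded = sum(vapply(reps, `[[`, numeric(1), "nExcluded")))
}
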