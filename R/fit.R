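# Sub-pixel emitter fitting.  Three estimators share one Levenberg-
# Marquardt core (src/fitters.cpp):
#   "mle"     - Poisson MLE ignoring RQE: data (x_raw - o)/g + var_e,
#               model f(theta) + var_e            (variance-shift trick)
#   "mle-rqe" - Poisson MLE with the model scaled per pixel by rqe_i:
#               model rqe_i * f(theta) + var_e, same data as "mle"
#   "wls"     - weighted least squares on flat-field corrected data:
#               data (x_raw - o)/(flat_i * <g>), flat_i = g_i*rqe_i/<g>,
#               weights 1/(x_i + var_i)
# All variance terms are converted from ADU^2 to e-^2 before use
# (var/g^2 for the MLE forms, var/(flat*<g>)^2 for WLS) so model and data
# share units.

#' Poisson MLE chi-square (deviance)
#'
#' \code{2*sum(f - x) - 2*sum(x*log(f/x))}: twice the Kullback-Leibler
#' discrepancy between model and data under Poisson statistics.
#' Non-negative, zero iff \code{f == x} element-wise.
#'
#' @param f,x positive numeric vectors/matrices of equal length (model and
#'   data values, each already carrying the variance shift).
#' @return scalar deviance.
#' @examples
#' chi2MLE(2, 1)   # 2 - 2*log(2)
#' @export
chi2MLE <- function(f, x) {
    if (any(f <= 0) || any(x <= 0))
        stop("chi2MLE requires strictly positive model and data values")
    2 * sum(f - x) - 2 * sum(x * log(f / x))
}

#' Weighted least-squares chi-square
#'
#' \code{sum((f - x)^2 / (x + varE))}, the flat-field WLS objective; the
#' weight denominators are clamped at \code{minDenom} to guard against
#' non-positive values in dim pixels.
#'
#' @param f,x model and data values (flat-field corrected e-).
#' @param varE read-noise variance in the same squared units as x.
#' @param minDenom lower clamp for the weight denominator.
#' @return scalar chi-square.
#' @export
chi2WLS <- function(f, x, varE, minDenom = 1e-3) {
    sum((f - x)^2 / pmax(x + varE, minDenom))
}

#' Assemble per-pixel fitting terms for an ROI
#'
#' Returns the data, model scale and shift arrays that define each
#' estimator's objective on an ROI, with all variances converted to
#' squared photo-electrons.
#'
#' @param rawRoi raw ADU matrix.
#' @param calibRoi list with matrices \code{offset}, \code{variance},
#'   \code{gain}, \code{rqe} cropped to the same ROI, plus scalar
#'   \code{meanGain}.
#' @param estimator \code{"mle"}, \code{"mle-rqe"} or \code{"wls"}.
#' @param minData lower clamp applied to the MLE data values (the deviance
#'   needs x > 0).
#' @return list with \code{x} (data), \code{a} (per-pixel model scale:
#'   rqe for "mle-rqe", 1 otherwise), \code{c} (additive model shift:
#'   var_e for the MLE forms, 0 for WLS) and \code{w} (WLS weights; 1 for
#'   the MLE forms).
#' @export
buildTerms <- function(rawRoi, calibRoi,
                       estimator = c("mle", "mle-rqe", "wls"),
                       minData = 1e-6) {
    estimator <- match.arg(estimator)
    if (!identical(dim(rawRoi), dim(calibRoi$offset)))
        stop("ROI shapes are inconsistent")
    ones <- array(1, dim(rawRoi))
    if (estimator == "wls") {
        flat <- calibRoi$gain * calibRoi$rqe / calibRoi$meanGain
        den <- flat * calibRoi$meanGain
        x <- (rawRoi - calibRoi$offset) / den
        varE <- calibRoi$variance / den^2
        w <- 1 / pmax(x + varE, 1e-3)
        return(list(x = x, a = ones, c = 0 * ones, w = w))
    }
    varE <- calibRoi$variance / calibRoi$gain^2
    x <- pmax((rawRoi - calibRoi$offset) / calibRoi$gain + varE, minData)
    a <- if (estimator == "mle-rqe") calibRoi$rqe else ones
    list(x = x, a = a, c = varE, w = ones)
}

cropCalib <- function(calib, rows, cols) {
    list(offset = calib@offset[rows, cols],
         variance = calib@variance[rows, cols],
         gain = calib@gain[rows, cols],
         rqe = calib@rqe[rows, cols],
         meanGain = calib@meanGain)
}

# Default deterministic initialization from an ROI: background from the
# border median, height from peak minus background, position from the
# intensity centroid of the background-subtracted ROI.
initTheta <- function(xRoi) {
    S <- nrow(xRoi)
    border <- c(xRoi[1, ], xRoi[S, ], xRoi[, 1], xRoi[, S])
    bg <- median(border)
    sub <- pmax(xRoi - bg, 0)
    tot <- sum(sub)
    cx <- if (tot > 0) sum(sub %*% cbind(0:(S - 1))) / tot else (S - 1) / 2
    cy <- if (tot > 0) sum(cbind(0:(S - 1)) * rowSums(sub)) / tot
          else (S - 1) / 2
    c(h = max(max(xRoi) - bg, 1e-3), x = cx, y = cy, bg = max(bg, 0))
}

#' Fit one emitter in an ROI
#'
#' Minimizes the chosen estimator's objective over theta = (height,
#' x-center, y-center, background) by Levenberg-Marquardt with analytic
#' gradients (damping start 1e-3, x10 / /10 schedule, convergence when the
#' relative objective decrease stays below \code{tol} for two consecutive
#' accepted steps).  The PSF sigma is fixed (1.5 px default).  Positions
#' are local, zero-based ROI coordinates.
#'
#' @param rawRoi raw ADU matrix (square).
#' @param calibRoi cropped calibration list (see \code{\link{buildTerms}}).
#' @param estimator \code{"mle"}, \code{"mle-rqe"} or \code{"wls"}.
#' @param theta0 optional initial (h, x, y, bg); default from
#'   \code{\link{initTheta}}.
#' @param psfSigmaPx fixed PSF sigma in pixels.
#' @param convention PSF pixelization convention.
#' @param maxIter,tol,lambda0 optimizer controls.
#' @return list: \code{theta} (named), \code{converged}, \code{iterations},
#'   \code{chi2}, \code{boundHit}.
#' @export
fitEmitter <- function(rawRoi, calibRoi,
                       estimator = c("mle", "mle-rqe", "wls"),
                       theta0 = NULL, psfSigmaPx = 1.5,
                       convention = "integrated",
                       maxIter = 200L, tol = 1e-6, lambda0 = 1e-3) {
    estimator <- match.arg(estimator)
    S <- nrow(rawRoi)
    terms <- buildTerms(rawRoi, calibRoi, estimator)
    if (is.null(theta0)) theta0 <- initTheta(terms$x - terms$c)
    res <- cpp_fit_rois(matrix(terms$x, ncol = 1),
                        matrix(terms$a, ncol = 1),
                        matrix(terms$c, ncol = 1),
                        matrix(terms$w, ncol = 1),
                        matrix(theta0, ncol = 1),
                        mode = if (estimator == "wls") 1L else 0L,
                        sigma = psfSigmaPx, roiSide = S,
                        convention = if (convention == "integrated") 0L
                                     else 1L,
                        maxIter = maxIter, tol = tol, lambda0 = lambda0)
    list(theta = stats::setNames(res$theta[, 1], c("h", "x", "y", "bg")),
         converged = res$converged[1], iterations = res$iterations[1],
         chi2 = res$chi2[1], boundHit = res$boundHit[1])
}

#' Batch-fit candidates across a movie
#'
#' Extracts a square ROI around each candidate peak (side
#' \code{2*ceiling(3*sigma) + 1}, 11 px at sigma 1.5), fits every
#' candidate with the chosen estimator in one compiled pass, and returns a
#' localization table in both pixel and nm units.  Candidates whose ROI
#' would be clipped by the frame edge are skipped (counted in the
#' attribute \code{nSkipped}).
#'
#' @param movie a \linkS4class{CameraMovie}.
#' @param calib a \linkS4class{CalibrationMap}.
#' @param candidates data.frame with columns \code{frame}, \code{row},
#'   \code{col} (zero-based peak pixel), e.g. from
#'   \code{\link{identifyMovie}}; extra columns are carried through.
#' @param estimator \code{"mle"}, \code{"mle-rqe"} or \code{"wls"}.
#' @param psfSigmaPx fixed PSF sigma in pixels.
#' @param convention PSF pixelization convention.
#' @param maxIter,tol,lambda0 optimizer controls.
#' @return data.frame with one row per fit: \code{frame}, \code{x},
#'   \code{y} (zero-based pixels), \code{xNm}, \code{yNm}, \code{height},
#'   \code{background}, \code{chi2}, \code{converged}, \code{iterations},
#'   \code{boundHit}, plus carried-through candidate columns.
#' @export
batchFit <- function(movie, calib, candidates,
                     estimator = c("mle", "mle-rqe", "wls"),
                     psfSigmaPx = 1.5, convention = "integrated",
                     maxIter = 200L, tol = 1e-6, lambda0 = 1e-3) {
    estimator <- match.arg(estimator)
    if (nrow(candidates) == 0) stop("candidate list is empty")
    r <- ceiling(3 * psfSigmaPx)
    S <- 2L * r + 1L
    d <- frameDim(movie)
    ok <- candidates$row >= r & candidates$row <= d[1] - 1L - r &
          candidates$col >= r & candidates$col <= d[2] - 1L - r
    nSkipped <- sum(!ok)
    cand <- candidates[ok, , drop = FALSE]
    n <- nrow(cand)
    if (n == 0) stop("all candidate ROIs are clipped by the frame edge")
    npx <- S * S
    X <- A <- C <- W <- matrix(0, npx, n)
    theta0 <- matrix(0, 4, n)
    for (j in seq_len(n)) {
        rows <- (cand$row[j] - r):(cand$row[j] + r) + 1L
        cols <- (cand$col[j] - r):(cand$col[j] + r) + 1L
        terms <- buildTerms(movie@frames[rows, cols, cand$frame[j]],
                            cropCalib(calib, rows, cols), estimator)
        X[, j] <- terms$x; A[, j] <- terms$a
        C[, j] <- terms$c; W[, j] <- terms$w
        theta0[, j] <- initTheta(matrix(terms$x - terms$c, S, S))
    }
    res <- cpp_fit_rois(X, A, C, W, theta0,
                        mode = if (estimator == "wls") 1L else 0L,
                        sigma = psfSigmaPx, roiSide = S,
                        convention = if (convention == "integrated") 0L
                                     else 1L,
                        maxIter = maxIter, tol = tol, lambda0 = lambda0)
    px <- movie@pixelSizeNm
    out <- data.frame(frame = cand$frame,
                      x = res$theta[2, ] + cand$col - r,
                      y = res$theta[3, ] + cand$row - r,
                      height = res$theta[1, ],
                      background = res$theta[4, ],
                      chi2 = res$chi2,
                      converged = res$converged,
                      iterations = res$iterations,
                      boundHit = res$boundHit,
                      estimator = estimator)
    out$xNm <- out$x * px
    out$yNm <- out$y * px
    extra <- setdiff(names(cand), c("frame", "row", "col"))
    for (nm in extra) out[[nm]] <- cand[[nm]]
    attr(out, "nSkipped") <- nSkipped
    attr(out, "convergenceRate") <- mean(out$converged)
    out
}

#' Candidate table from ground-truth emitters
#'
#' Builds a candidate table (one row per emitter per on-frame, peak at the
#' pixel nearest the true position) from an \linkS4class{EmitterSet}, for
#' accuracy studies where detection is not under test.
#'
#' @param truth an \linkS4class{EmitterSet}.
#' @param frames optional frame subset (default all).
#' @return data.frame with \code{frame}, \code{row}, \code{col},
#'   \code{emitter}.
#' @export
candidatesFromTruth <- function(truth, frames = NULL) {
    nf <- ncol(truth@onState)
    if (is.null(frames)) frames <- seq_len(nf)
    out <- lapply(frames, function(f) {
        e <- which(truth@onState[, f])
        if (!length(e)) return(NULL)
        data.frame(frame = f,
                   row = as.integer(round(truth@positions[e, 2])),
                   col = as.integer(round(truth@positions[e, 1])),
                   emitter = e)
    })
    do.call(rbind, out)
}
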