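# Cramer-Rao lower bound on localization precision under the sCMOS + RQE
# noise model.  The per-pixel model is mu_i = rqe_i * f(theta) + var_i
# (variances in e-^2), and the Fisher information is
#   F_mn = sum_i rqe_i^2 / mu_i * df/dtheta_m * df/dtheta_n,
# the Poisson (Stirling-approximated) information of the shifted model.
# Parameter order follows the fitting convention (bg, h, x0, y0[, sigma]).

#' Fisher information matrix for a Gaussian PSF on an sCMOS ROI
#'
#' @param theta named vector with \code{bg}, \code{h}, \code{x}, \code{y}
#'   (e- and zero-based pixel units).
#' @param sigma PSF sigma in pixels.
#' @param rqeRoi matrix of per-pixel RQE over the ROI.
#' @param varRoi matrix of read-noise variance over the ROI, in e-^2
#'   (ADU^2 variances must be divided by gain^2 first; see
#'   \code{\link{crlbBounds}}).
#' @param freeSigma include sigma as a fifth free parameter.
#' @param convention PSF pixelization convention.
#' @return the 4x4 (or 5x5) Fisher matrix, dimnames \code{bg, h, x, y
#'   [, sigma]}.
#' @examples
#' F <- fisherMatrix(c(bg = 2, h = 15, x = 5, y = 5), 1.5,
#'                   matrix(1, 11, 11), matrix(0, 11, 11))
#' @export
fisherMatrix <- function(theta, sigma, rqeRoi, varRoi,
                         freeSigma = FALSE, convention = "integrated") {
    S <- dim(rqeRoi)
    xs <- 0:(S[2] - 1); ys <- 0:(S[1] - 1)
    p <- psfShape(xs, ys, theta["x"], theta["y"], sigma,
                  convention, deriv = TRUE)
    f <- theta["h"] * p$shape + theta["bg"]
    mu <- rqeRoi * f + varRoi
    if (any(mu <= 0))
        stop("model expectation non-positive at ", sum(mu <= 0),
             " pixels; need positive background or read noise")
    d <- list(bg = matrix(1, S[1], S[2]),
              h = p$shape,
              x = theta["h"] * p$dx0,
              y = theta["h"] * p$dy0)
    if (freeSigma) d$sigma <- theta["h"] * p$dsigma
    w <- rqeRoi^2 / mu
    np <- length(d)
    Fm <- matrix(0, np, np, dimnames = list(names(d), names(d)))
    for (m in seq_len(np))
        for (n in m:np)
            Fm[m, n] <- Fm[n, m] <- sum(w * d[[m]] * d[[n]])
    Fm
}

#' Cramer-Rao lower bounds for one emitter configuration
#'
#' Inverts the Fisher matrix and returns the square roots of its diagonal:
#' the lower-bound standard deviations of background and height (e-) and
#' of the position (pixels, and nm when \code{pixelSizeNm} is given).
#'
#' @param theta named vector (\code{bg}, \code{h}, \code{x}, \code{y}), in
#'   e- and zero-based ROI pixel coordinates.
#' @param sigma PSF sigma in pixels.
#' @param rqeRoi,varAduRoi,gainRoi calibration matrices over the ROI; the
#'   ADU^2 read-noise variance is converted to e-^2 via \code{gain^2}.
#' @param pixelSizeNm optional pixel size for nm output.
#' @param freeSigma include sigma as a free parameter.
#' @param convention PSF pixelization convention.
#' @return list with \code{bounds} (named std-dev vector), \code{boundsNm}
#'   (positions in nm, if requested), and \code{fisher}.
#' @export
crlbBounds <- function(theta, sigma, rqeRoi, varAduRoi, gainRoi,
                       pixelSizeNm = NULL, freeSigma = FALSE,
                       convention = "integrated") {
    varE <- varAduRoi / gainRoi^2
    Fm <- fisherMatrix(theta, sigma, rqeRoi, varE, freeSigma, convention)
    Finv <- tryCatch(solve(Fm), error = function(e) {
        dg <- diag(Fm)
        stop("singular Fisher matrix; weakest parameter: ",
             names(dg)[which.min(dg)])
    })
    dg <- diag(Finv)
    if (any(dg < 0)) stop("Fisher inverse has negative diagonal entries")
    bounds <- sqrt(dg)
    out <- list(bounds = bounds, fisher = Fm)
    if (!is.null(pixelSizeNm))
        out$boundsNm <- bounds[c("x", "y")] * pixelSizeNm
    out
}

#' Average CRLB over a set of emitter positions
#'
#' Figure-style protocol: evaluates the position bounds for each emitter
#' of an \linkS4class{EmitterSet} on its own fitting ROI (the same window
#' the fitter uses) and returns the mean and median bound per axis.
#'
#' @param truth an \linkS4class{EmitterSet}.
#' @param calib a \linkS4class{CalibrationMap}.
#' @param photons expected photons per frame per emitter.
#' @param background background photons per pixel.
#' @param sigma PSF sigma in pixels.
#' @param pixelSizeNm pixel size for nm output.
#' @param convention PSF pixelization convention.
#' @return list with per-emitter bound matrix \code{perEmitter} (nm),
#'   and \code{meanNm}, \code{medianNm} (named x/y).
#' @export
crlbForEmitters <- function(truth, calib, photons = 250, background = 20,
                            sigma = 1.5, pixelSizeNm = 100,
                            convention = "integrated") {
    r <- ceiling(3 * sigma)
    d <- dim(calib@offset)
    pos <- truth@positions
    keep <- round(pos[, 2]) >= r & round(pos[, 2]) <= d[1] - 1 - r &
            round(pos[, 1]) >= r & round(pos[, 1]) <= d[2] - 1 - r
    pos <- pos[keep, , drop = FALSE]
    h <- photonsToHeight(photons, sigma)
    per <- t(vapply(seq_len(nrow(pos)), function(i) {
        rr <- (round(pos[i, 2]) - r):(round(pos[i, 2]) + r) + 1
        cc <- (round(pos[i, 1]) - r):(round(pos[i, 1]) + r) + 1
        th <- c(bg = background, h = h,
                x = unname(pos[i, 1] - (round(pos[i, 1]) - r)),
                y = unname(pos[i, 2] - (round(pos[i, 2]) - r)))
        crlbBounds(th, sigma, calib@rqe[rr, cc], calib@variance[rr, cc],
                   calib@gain[rr, cc], pixelSizeNm,
                   convention = convention)$boundsNm
    }, numeric(2)))
    colnames(per) <- c("x", "y")
    list(perEmitter = per,
         meanNm = colMeans(per),
         medianNm = apply(per, 2, median))
}
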