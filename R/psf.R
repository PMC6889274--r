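# 2-D Gaussian PSF on a pixel grid, in the two pixelization conventions:
#  - "integrated": the Gaussian is integrated over each pixel's unit square
#    (the physically faithful model, the default everywhere);
#  - "sampled": the Gaussian is evaluated at the pixel center.
# The peak-height parameterization is shared: a PSF of height h and sigma s
# carries h * 2*pi*s^2 expected photons in total (exactly, for the
# integrated model on an infinite grid).

erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# One-axis integrated profile I(x) = P(pixel x receives the photon | axis),
# its derivatives wrt center and sigma.  x are integer pixel coordinates.
axisProfile <- function(x, center, sigma, deriv = FALSE) {
    up <- (x - center + 0.5) / sigma
    lo <- (x - center - 0.5) / sigma
    I <- 0.5 * (erf(up / sqrt(2)) - erf(lo / sqrt(2)))
    if (!deriv) return(list(I = I))
    eUp <- exp(-up^2 / 2); eLo <- exp(-lo^2 / 2)
    list(I = I,
         dC = -(eUp - eLo) / (sigma * sqrt(2 * pi)),
         dS = -(up * eUp - lo * eLo) / (sigma * sqrt(2 * pi)))
}

#' Gaussian PSF shape on a pixel grid
#'
#' Evaluates the unit-height PSF shape (and optionally its partial
#' derivatives) on the grid \code{xs} x \code{ys} of integer pixel
#' coordinates.  The model value of a pixel is \code{h * shape + bg}.
#'
#' @param xs,ys integer (zero-based) pixel coordinates of the grid columns
#'   and rows.
#' @param x0,y0 emitter center in pixel units.
#' @param sigma PSF sigma in pixels.
#' @param convention \code{"integrated"} (per-pixel integral, default) or
#'   \code{"sampled"} (center-sampled exponential).
#' @param deriv if TRUE, also return \code{dx0}, \code{dy0}, \code{dsigma}
#'   matrices of partial derivatives of the shape.
#' @return list with matrix \code{shape} \code{[length(ys), length(xs)]}
#'   and, when requested, its derivatives.
#' @examples
#' psfShape(0:10, 0:10, 5, 5, 1.5)$shape[6, 6]   # ~1 at the peak
#' @export
psfShape <- function(xs, ys, x0, y0, sigma,
                     convention = c("integrated", "sampled"),
                     deriv = FALSE) {
    convention <- match.arg(convention)
    if (convention == "sampled") {
        dx <- outer(rep(1, length(ys)), xs - x0)
        dy <- outer(ys - y0, rep(1, length(xs)))
        shape <- exp(-(dx^2 + dy^2) / (2 * sigma^2))
        if (!deriv) return(list(shape = shape))
        return(list(shape = shape,
                    dx0 = shape * dx / sigma^2,
                    dy0 = shape * dy / sigma^2,
                    dsigma = shape * (dx^2 + dy^2) / sigma^3))
    }
    px <- axisProfile(xs, x0, sigma, deriv)
    py <- axisProfile(ys, y0, sigma, deriv)
    s2p <- 2 * pi * sigma^2
    shape <- s2p * outer(py$I, px$I)
    if (!deriv) return(list(shape = shape))
    list(shape = shape,
         dx0 = s2p * outer(py$I, px$dC),
         dy0 = s2p * outer(py$dC, px$I),
         dsigma = 4 * pi * sigma * outer(py$I, px$I) +
             s2p * (outer(py$I, px$dS) + outer(py$dS, px$I)))
}

# Model values h * shape + bg for a parameter vector theta = (h, x0, y0, bg).
psfModel <- function(theta, xs, ys, sigma, convention = "integrated") {
    theta[1] * psfShape(xs, ys, theta[2], theta[3], sigma,
                        convention)$shape + theta[4]
}

# Height <-> total photons conversion for the shared parameterization.
heightToPhotons <- function(h, sigma) h * 2 * pi * sigma^2
photonsToHeight <- function(N, sigma) N / (2 * pi * sigma^2)
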