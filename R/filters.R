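# Small 2-D convolution helpers.  All smoothing in the package goes through
# these so that boundary handling and even-kernel centering are in one place
# and bit-reproducible.

# Pad a matrix by replicating (mode "nearest") or mirroring (mode "reflect")
# its edges.  `left`/`right` give the padding on the low/high side of each
# dimension (even kernels need asymmetric padding).
padMatrix <- function(m, left, right, mode = c("nearest", "reflect")) {
    mode <- match.arg(mode)
    nr <- nrow(m); nc <- ncol(m)
    idx <- function(n, lo, hi) {
        if (mode == "nearest") {
            c(rep(1L, lo), seq_len(n), rep(n, hi))
        } else {
            # reflect about the edge pixel centers (scipy mode "reflect"
            # duplicates the edge sample; we mirror without duplication
            # capped at the array size, adequate for small kernels)
            c(rev(seq_len(min(lo, n))) + 0L,
              seq_len(n), n - seq_len(min(hi, n)) + 0L)[seq_len(lo + n + hi)]
        }
    }
    m[idx(nr, left[1], right[1]), idx(nc, left[2], right[2]), drop = FALSE]
}

# 1-D convolution of each column (axis = 1) or row (axis = 2) with `kernel`.
# `origin` is the index of the kernel tap aligned with the output sample
# (1-based).  For an odd kernel the center is (L+1)/2; for an even kernel of
# length L the default origin floor(L/2)+1 places the window
# [-floor(L/2), L-floor(L/2)-1] around the output sample (left-heavy, the
# convention of the common n-d image uniform filter).
convolve1dAxis <- function(m, kernel, axis, origin = NULL,
                           pad = "nearest") {
    L <- length(kernel)
    if (is.null(origin)) origin <- L %/% 2 + 1L
    lo <- origin - 1L
    hi <- L - origin
    padded <- if (axis == 1L) padMatrix(m, c(lo, 0L), c(hi, 0L), pad)
              else            padMatrix(m, c(0L, lo), c(0L, hi), pad)
    out <- matrix(0, nrow(m), ncol(m))
    for (t in seq_len(L)) {
        w <- kernel[t]
        if (w == 0) next
        off <- t - origin     # in [-lo, hi]
        if (axis == 1L) {
            rows <- (1L + lo + off):(nrow(m) + lo + off)
            out <- out + w * padded[rows, , drop = FALSE]
        } else {
            cols <- (1L + lo + off):(ncol(m) + lo + off)
            out <- out + w * padded[, cols, drop = FALSE]
        }
    }
    out
}

#' Uniform (box) filter
#'
#' Convolve a matrix with a normalized \code{size x size} uniform kernel,
#' as used to build the locally normalized RQE map.  For an even
#' \code{size} the window is left-heavy: it spans \code{-size/2 ..
#' size/2 - 1} pixels around each output pixel.  Edges are handled by
#' replicate ("nearest") padding by default so that edge pixels still see a
#' full-weight kernel.
#'
#' @param m numeric matrix.
#' @param size kernel side length in pixels (default 10).
#' @param pad boundary mode, \code{"nearest"} (default) or \code{"reflect"}.
#' @return matrix of the same dimension.
#' @examples
#' uniformFilter(matrix(1, 20, 20))        # stays 1 everywhere
#' @export
uniformFilter <- function(m, size = 10L, pad = "nearest") {
    k <- rep(1 / size, size)
    convolve1dAxis(convolve1dAxis(m, k, 1L, pad = pad), k, 2L, pad = pad)
}

# Discrete Gaussian kernel, truncated at `radius` (default ceil(4*sigma)),
# normalized to sum 1.
gaussianKernel1d <- function(sigma, radius = NULL) {
    if (is.null(radius)) radius <- ceiling(4 * sigma)
    k <- dnorm(seq(-radius, radius), sd = sigma)
    k / sum(k)
}

#' Gaussian smoothing of a per-pixel map
#'
#' Separable Gaussian convolution with standard deviation \code{sigma}
#' pixels, replicate padding at the edges.  Used both to reduce noise
#' before localization identification and to compute the "smoothed RQE" and
#' "smoothed gain" maps that detection statistics are conditioned on.
#'
#' @param m numeric matrix.
#' @param sigma Gaussian sigma in pixels (typically the expected PSF sigma).
#' @param pad boundary mode passed to the convolution.
#' @return matrix of the same dimension.
#' @examples
#' smoothMap(diag(10), 1.5)
#' @export
smoothMap <- function(m, sigma, pad = "nearest") {
    stopifnot(sigma > 0)
    k <- gaussianKernel1d(sigma)
    convolve1dAxis(convolve1dAxis(m, k, 1L, pad = pad), k, 2L, pad = pad)
}

# Smooth a vector with a 1-D Gaussian, circular boundary.  Used for the
# striped component of synthetic calibrations.
smoothVecCircular <- function(v, sigma) {
    n <- length(v)
    r <- min(ceiling(4 * sigma), n %/% 2)
    k <- dnorm(seq(-r, r), sd = sigma); k <- k / sum(k)
    idx <- function(i) ((i - 1) %% n) + 1
    out <- numeric(n)
    for (t in seq_along(k))
        out <- out + k[t] * v[idx(seq_len(n) + (t - r - 1L))]
    out
}
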