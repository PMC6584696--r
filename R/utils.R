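# Shared numeric helpers: Gaussian (derivative) kernels, separable
# filtering, histogram equalization, and similarity-transform algebra.

GMAX <- 255

#' Gaussian derivative kernels
#'
#' Sampled Gaussian kernel and its first and second derivatives at standard
#' deviation `sigma`, truncated at `3.5 sigma`. The second derivative is
#' g''_sigma(x) = ((x^2 - sigma^2) / (sqrt(2*pi) * sigma^5)) * exp(-x^2 / (2 sigma^2)).
#' The zeroth-order kernel is renormalized to unit sum; derivative kernels
#' are normalized so that filtering a linear (resp. quadratic) ramp returns
#' its exact first (resp. second) derivative.
#'
#' @param sigma standard deviation, px (> 0).
#' @param order derivative order 0, 1 or 2.
#' @return numeric kernel of odd length.
#' @export
gaussKernel <- function(sigma, order = 0L) {
  stopifnot(sigma > 0, order %in% 0:2)
  h <- max(1L, ceiling(3.5 * sigma))
  x <- seq.int(-h, h)
  g <- exp(-x^2 / (2 * sigma^2)) / (sqrt(2 * pi) * sigma)
  if (order == 0L) return(g / sum(g))
  if (order == 1L) {
    k <- -x / sigma^2 * g
    # unit correlation response to a unit ramp: sum(x * k) == 1
    s <- sum(x * k)
    return(k / s)
  }
  k <- (x^2 - sigma^2) / (sqrt(2 * pi) * sigma^5) * exp(-x^2 / (2 * sigma^2))
  # zero DC, unit response to x^2/2
  k <- k - mean(k)
  k / sum(x^2 / 2 * k)
}

# Separable filtering: kernel kr along rows (vertical), kc along columns.
sepFilter <- function(img, kr, kc) {
  cpp_sep_filter(img, kr, kc)
}

#' Gaussian smoothing of a raster
#'
#' @param img numeric matrix.
#' @param sigma standard deviation, px.
#' @return smoothed matrix of identical size (replicated borders).
#' @export
gaussSmooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussKernel(sigma, 0L)
  sepFilter(img, k, k)
}

#' Global brightness histogram equalization
#'
#' Maps gray levels through the scaled cumulative distribution,
#' `round(255 * cdf(s))`, on 8-bit levels (input is rounded and clamped to
#' [0, 255] first). A constant image is returned unchanged.
#'
#' @param img numeric matrix with values in [0, 255].
#' @param gmax maximum gray level (255 for 8-bit data).
#' @return equalized matrix, values in [0, 255].
#' @export
histEqualize <- function(img, gmax = GMAX) {
  s <- pmin(pmax(round(img), 0), gmax)
  h <- tabulate(s + 1L, nbins = gmax + 1L)
  if (sum(h > 0) <= 1L) return(img)  # degenerate histogram
  cdf <- cumsum(h) / length(s)
  lut <- round(gmax * cdf)
  m <- matrix(lut[s + 1L], nrow(img), ncol(img))
  m
}

# ---- similarity transform algebra ------------------------------------------
# A FrameTransform is the parameter vector c(tx, ty, theta, scale) of the
# similarity map p' = scale * R(theta) %*% p + t acting on 0-based (row, col)
# coordinates. Identity is c(0, 0, 0, 1).

transformMatrix <- function(par) {
  s <- par[4L]; th <- par[3L]
  rbind(c(s * cos(th), -s * sin(th), par[1L]),
        c(s * sin(th),  s * cos(th), par[2L]))
}

matrixToTransform <- function(M) {
  th <- atan2(M[2L, 1L], M[1L, 1L])
  s <- sqrt(M[1L, 1L]^2 + M[2L, 1L]^2)
  c(M[1L, 3L], M[2L, 3L], th, s)
}

composeTransforms <- function(a, b) {
  # returns the transform equivalent to applying b first, then a
  A <- transformMatrix(a); B <- transformMatrix(b)
  M <- cbind(A[, 1:2] %*% B[, 1:2], A[, 1:2] %*% B[, 3L] + A[, 3L])
  matrixToTransform(M)
}

invertTransform <- function(par) {
  M <- transformMatrix(par)
  Ri <- solve(M[, 1:2])
  matrixToTransform(cbind(Ri, -Ri %*% M[, 3L]))
}

applyTransformToPoints <- function(par, pts) {
  M <- transformMatrix(par)
  t(M[, 1:2] %*% t(pts) + M[, 3L])
}

clampGray <- function(img, gmax = GMAX) pmin(pmax(img, 0), gmax)

# integer block-mean downsampling by a power-of-two-free integer factor
downsampleBy <- function(img, factor) {
  factor <- as.integer(factor)
  if (factor <= 1L) return(img)
  out <- img
  f <- factor
  while (f %% 2L == 0L) { out <- cpp_downsample2(out); f <- f %/% 2L }
  if (f > 1L) {
    nr <- nrow(out) %/% f; nc <- ncol(out) %/% f
    out <- out[seq_len(nr * f), seq_len(nc * f), drop = FALSE]
    ridx <- (seq_len(nr * f) - 1L) %/% f + 1L
    cidx <- (seq_len(nc * f) - 1L) %/% f + 1L
    out <- rowsum(out, ridx)
    out <- t(rowsum(t(out), cidx)) / f^2
  }
  out
}
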