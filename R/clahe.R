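#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' The raster is divided into a grid of contextual tiles. For every tile a
#' brightness-histogram equalization mapping is computed after limiting the
#' histogram slope: bins exceeding `clipLimit` times the mean bin height are
#' clipped and the excess is redistributed uniformly, which bounds local
#' contrast amplification and prevents noise blow-up. Every pixel's output
#' gray value is the bilinear blend of the four surrounding tile mappings
#' g_A..g_D evaluated at the pixel's input value s:
#' \deqn{s' = (1-y)((1-x) g_A(s) + x g_B(s)) + y((1-x) g_C(s) + x g_D(s))}
#' with x, y the pixel's normalized distances from tile center A. Pixels
#' outside the outermost tile centers use the nearest tile row/column.
#'
#' With a single tile and no clipping (`clipLimit = Inf`) the operation
#' reduces to global histogram equalization.
#'
#' @param img numeric matrix, values in [0, 255] (rounded internally).
#' @param clipLimit relative histogram slope limit (>= 1); `Inf` disables
#'   clipping.
#' @param tiles integer vector `c(nx, ny)`: tile grid (columns, rows).
#' @return equalized matrix, values in [0, 255].
#' @examples
#' img <- matrix(runif(64 * 64, 0, 255), 64)
#' out <- clahe(img, clipLimit = 3, tiles = c(4, 4))
#' range(out)
#' @export
clahe <- function(img, clipLimit = 3, tiles = c(8L, 8L)) {
  stopifnot(clipLimit >= 1, length(tiles) == 2L, all(tiles >= 1))
  nr <- nrow(img); nc <- ncol(img)
  ny <- as.integer(tiles[2L]); nx <- as.integer(tiles[1L])
  th <- nr / ny; tw <- nc / nx
  if (th < 2 || tw < 2) stop("tiles must be at least 2 x 2 px")
  s <- pmin(pmax(round(img), 0), GMAX)

  # per-tile clipped-histogram equalization mappings (LUTs)
  luts <- array(0, dim = c(ny, nx, GMAX + 1L))
  rowTile <- pmin(floor((seq_len(nr) - 1) / th), ny - 1L) + 1L
  colTile <- pmin(floor((seq_len(nc) - 1) / tw), nx - 1L) + 1L
  for (ty in seq_len(ny)) for (tx in seq_len(nx)) {
    vals <- s[rowTile == ty, colTile == tx]
    h <- tabulate(vals + 1L, nbins = GMAX + 1L)
    if (is.finite(clipLimit)) {
      limit <- clipLimit * length(vals) / (GMAX + 1L)
      excess <- sum(pmax(h - limit, 0))
      h <- pmin(h, limit) + excess / (GMAX + 1L)
    }
    cdf <- cumsum(h) / sum(h)
    luts[ty, tx, ] <- GMAX * cdf
  }

  # bilinear blend of the four surrounding tile mappings
  cy <- (seq_len(ny) - 0.5) * th  # tile centers (1-based coords)
  cx <- (seq_len(nx) - 0.5) * tw
  ri <- seq_len(nr); ci <- seq_len(nc)
  iy <- pmin(pmax(findInterval(ri, cy), 1L), max(ny - 1L, 1L))
  ix <- pmin(pmax(findInterval(ci, cx), 1L), max(nx - 1L, 1L))
  fy <- if (ny > 1L) pmin(pmax((ri - cy[iy]) / (cy[iy + 1L] - cy[iy]), 0), 1) else rep(0, nr)
  fx <- if (nx > 1L) pmin(pmax((ci - cx[ix]) / (cx[ix + 1L] - cx[ix]), 0), 1) else rep(0, nc)

  sv <- as.vector(s) + 1L
  IY <- rep(iy, times = nc); FY <- rep(fy, times = nc)
  IX <- rep(ix, each = nr); FX <- rep(fx, each = nr)
  lu <- function(ty, tx) luts[cbind(ty, tx, sv)]
  up <- ny > 1L; rt <- nx > 1L
  gA <- lu(IY, IX)
  gB <- if (rt) lu(IY, IX + 1L) else gA
  gC <- if (up) lu(IY + 1L, IX) else gA
  gD <- if (up && rt) lu(IY + 1L, IX + 1L) else if (up) gC else gB
  out <- (1 - FY) * ((1 - FX) * gA + FX * gB) + FY * ((1 - FX) * gC + FX * gD)
  matrix(out, nr, nc)
}
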