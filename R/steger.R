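#' Principal-curvature (Steger) line-point detection
#'
#' Detects subpixel points on dark curvilinear structures. The raster is
#' convolved with first- and second-derivative Gaussian kernels at scale
#' `sigma`; at every pixel the Hessian of the smoothed intensity is formed
#' and the eigenvector of its largest (most positive, since vessels are
#' dark on a bright background) eigenvalue gives the direction of the line
#' normal. A subpixel line point is accepted where the first directional
#' derivative along the normal vanishes within the pixel; the
#' scale-normalized second-derivative response `sigma^2 * lambda` (intensity
#' scaled to [0, 1]) is thresholded with hysteresis: points above
#' `lowThresh` are kept, but a linked line must contain at least one point
#' above `highThresh` (enforced by [linkLinePoints()]).
#'
#' The local line width (diameter) is estimated from edge localization: the
#' gradient magnitude along the normal is sampled on both sides and its
#' extremum located; the detector-scale broadening is removed per side by
#' sqrt(d^2 - sigma^2). When no interior edge extremum is found the side
#' defaults to 2.5 sigma (uncorrected), capping the width at 2 * 2.5 sigma.
#'
#' A `sigma` of at least about w / (2 sqrt(3)) is required to detect lines
#' of width w.
#'
#' @param img numeric matrix, gray values in [0, 255].
#' @param sigma Gaussian scale, px (> 0.5).
#' @param highThresh,lowThresh hysteresis thresholds on the
#'   scale-normalized response (`highThresh >= lowThresh >= 0`).
#' @param borderMargin detections closer than this to the raster border are
#'   discarded (px).
#' @return data.frame with one row per line point: `row`, `col` (0-based
#'   subpixel), `angle` (normal direction, radians in [0, pi)), `response`
#'   (scale-normalized), `strong` (above `highThresh`), `width` (px).
#' @examples
#' img <- matrix(200, 60, 60)
#' img[29:31, ] <- 120  # dark horizontal line
#' pts <- stegerDetect(img, sigma = 1.5, highThresh = 0.03, lowThresh = 0.01)
#' nrow(pts) > 0
#' @export
stegerDetect <- function(img, sigma, highThresh, lowThresh,
                         borderMargin = max(2, ceiling(sigma))) {
  stopifnot(sigma > 0.5, highThresh >= lowThresh, lowThresh >= 0)
  z <- img / GMAX
  g0 <- gaussKernel(sigma, 0L)
  g1 <- gaussKernel(sigma, 1L)
  g2 <- gaussKernel(sigma, 2L)
  rr  <- sepFilter(z, g1, g0)   # d/drow
  rc  <- sepFilter(z, g0, g1)   # d/dcol
  rrr <- sepFilter(z, g2, g0)
  rcc <- sepFilter(z, g0, g2)
  rrc <- sepFilter(z, g1, g1)

  disc <- sqrt((rrr - rcc)^2 + 4 * rrc^2)
  lam <- (rrr + rcc + disc) / 2          # largest eigenvalue (dark line > 0)
  resp <- lam * sigma^2
  cand <- which(resp >= lowThresh)
  if (!length(cand))
    return(data.frame(row = numeric(), col = numeric(), angle = numeric(),
                      response = numeric(), strong = logical(),
                      width = numeric()))

  a <- rrr[cand]; b <- rrc[cand]; c2 <- rcc[cand]; l1 <- lam[cand]
  # eigenvector of the largest eigenvalue = line normal
  n1 <- ifelse(abs(b) > 1e-12, b, ifelse(a >= c2, 1, 0))
  n2 <- ifelse(abs(b) > 1e-12, l1 - a, ifelse(a >= c2, 0, 1))
  nn <- sqrt(n1^2 + n2^2)
  ok <- nn > 0
  n1 <- n1 / pmax(nn, 1e-300); n2 <- n2 / pmax(nn, 1e-300)
  tval <- -(rr[cand] * n1 + rc[cand] * n2) / pmax(l1, 1e-300)
  pr <- tval * n1; pc <- tval * n2
  inside <- ok & abs(pr) <= 0.5 & abs(pc) <= 0.5 & l1 > 0
  cand <- cand[inside]
  if (!length(cand))
    return(data.frame(row = numeric(), col = numeric(), angle = numeric(),
                      response = numeric(), strong = logical(),
                      width = numeric()))
  n1 <- n1[inside]; n2 <- n2[inside]
  pr <- pr[inside]; pc <- pc[inside]

  nr <- nrow(img); nc <- ncol(img)
  prow <- (cand - 1) %% nr + pr        # 0-based subpixel row
  pcol <- (cand - 1) %/% nr + pc
  keep <- prow >= borderMargin & prow <= nr - 1 - borderMargin &
    pcol >= borderMargin & pcol <= nc - 1 - borderMargin
  cand <- cand[keep]
  if (!length(cand))
    return(data.frame(row = numeric(), col = numeric(), angle = numeric(),
                      response = numeric(), strong = logical(),
                      width = numeric()))
  n1 <- n1[keep]; n2 <- n2[keep]; prow <- prow[keep]; pcol <- pcol[keep]
  response <- resp[cand]

  width <- .stegerWidth(rr, rc, prow, pcol, n1, n2, sigma)
  angle <- atan2(n2, n1) %% pi

  data.frame(row = prow, col = pcol, angle = angle, response = response,
             strong = response >= highThresh, width = width)
}

# Edge localization along the normal on both sides of each line point.
.stegerWidth <- function(rr, rc, prow, pcol, n1, n2, sigma) {
  dmax <- 2.5 * sigma
  step <- max(0.3, dmax / 24)
  d <- seq(step, dmax, by = step)
  n <- length(prow)
  half <- matrix(NA_real_, n, 2L)
  for (side in 1:2) {
    sgn <- if (side == 1L) 1 else -1
    # gradient magnitude projected on the normal, |e(d)|, points x steps
    E <- matrix(0, n, length(d))
    for (k in seq_along(d)) {
      r <- prow + sgn * d[k] * n1
      c <- pcol + sgn * d[k] * n2
      gr <- cpp_bilinear(rr, r, c)
      gc <- cpp_bilinear(rc, r, c)
      E[, k] <- abs(gr * n1 + gc * n2)
    }
    E[is.na(E)] <- 0
    imax <- max.col(E, ties.method = "first")
    interior <- imax > 1L & imax < length(d)
    dstar <- d[imax]
    # parabolic subpixel refinement of the extremum
    ii <- which(interior)
    if (length(ii)) {
      y0 <- E[cbind(ii, imax[ii] - 1L)]
      y1 <- E[cbind(ii, imax[ii])]
      y2 <- E[cbind(ii, imax[ii] + 1L)]
      den <- y0 - 2 * y1 + y2
      off <- ifelse(abs(den) > 1e-12, 0.5 * (y0 - y2) / den, 0)
      dstar[ii] <- dstar[ii] + pmin(pmax(off, -0.5), 0.5) * step
    }
    h <- ifelse(interior,
                sqrt(pmax(dstar^2 - sigma^2, 0.25)),  # remove scale broadening
                dmax)                                  # fallback: cap at 2.5 sigma
    half[, side] <- h
  }
  half[, 1L] + half[, 2L]
}

#' Link line points into polylines
#'
#' Chains detected line points into maximal polylines. Starting from the
#' strongest unused point above the high threshold, the chain is extended in
#' both tangent directions: a candidate must lie within distance `l`, ahead
#' of the current direction of travel, and differ in tangent orientation by
#' less than `h`; among candidates the nearest wins, with the tangent-angle
#' difference as tie-break weight, so at junctions the continuation with the
#' minimal angle difference is preferred. Leftover isolated points are
#' dropped, and polylines shorter than `minLength` (arclength, px) are
#' discarded.
#'
#' @param points data.frame from [stegerDetect()].
#' @param h maximum tangent-angle difference, radians in (0, pi/2].
#' @param l maximum link distance, px (> 0).
#' @param minLength minimum accepted polyline arclength, px.
#' @param minPoints minimum number of points per polyline.
#' @param maxWeakTail maximum arclength (px) a chain may extend beyond its
#'   outermost point above the high threshold; weak tails longer than this
#'   tend to follow unrelated faint ridges (background texture) and are cut
#'   back. Use about twice the detection sigma; `Inf` disables the cut.
#' @return list of data.frames (ordered subsets of `points`).
#' @export
linkLinePoints <- function(points, h, l, minLength = 10, minPoints = 3L,
                           maxWeakTail = Inf) {
  stopifnot(h > 0, h <= pi / 2 + 1e-9, l > 0)
  n <- nrow(points)
  if (!n) return(list())
  pr <- points$row; pc <- points$col
  tau <- (points$angle + pi / 2) %% pi   # tangent orientation
  # spatial hash with cell size l
  cr <- floor(pr / l); cc <- floor(pc / l)
  key <- paste(cr, cc)
  cellIdx <- split(seq_len(n), key)
  neighbors <- function(i) {
    ks <- as.vector(outer(cr[i] + (-1:1), cc[i] + (-1:1), paste))
    unlist(cellIdx[ks], use.names = FALSE)
  }
  angDiff <- function(a, b) {
    d <- abs(a - b) %% pi
    pmin(d, pi - d)
  }
  used <- logical(n)
  seeds <- order(-points$response)
  seeds <- seeds[points$strong[seeds]]
  out <- list()
  for (s in seeds) {
    if (used[s]) next
    used[s] <- TRUE
    chain <- list(forward = integer(), backward = integer())
    for (dirn in c(1, -1)) {
      cur <- s
      dvec <- dirn * c(cos(tau[s]), sin(tau[s]))
      acc <- integer()
      repeat {
        cand <- neighbors(cur)
        cand <- cand[!used[cand]]
        if (!length(cand)) break
        dr <- pr[cand] - pr[cur]; dc <- pc[cand] - pc[cur]
        dist <- sqrt(dr^2 + dc^2)
        fwd <- dr * dvec[1L] + dc * dvec[2L]
        ad <- angDiff(tau[cand], tau[cur])
        # candidates must lie in a forward cone (within ~60 deg of the
        # direction of travel): sideways jumps to parallel neighbours zigzag
        sel <- dist <= l & dist > 1e-9 & fwd > 0.5 * dist & ad < h
        if (!any(sel)) break
        cand <- cand[sel]
        score <- dist[sel] + 1.0 * ad[sel]
        nxt <- cand[which.min(score)]
        used[nxt] <- TRUE
        acc <- c(acc, nxt)
        # orient the new tangent along the direction of travel
        step <- c(pr[nxt] - pr[cur], pc[nxt] - pc[cur])
        tv <- c(cos(tau[nxt]), sin(tau[nxt]))
        if (sum(step * tv) < 0) tv <- -tv
        dvec <- tv
        cur <- nxt
      }
      if (dirn == 1) chain$forward <- acc else chain$backward <- acc
    }
    idx <- c(rev(chain$backward), s, chain$forward)
    if (is.finite(maxWeakTail)) {
      # cut weak tails extending far beyond the outermost strong points
      st <- which(points$strong[idx])
      steps <- sqrt(diff(points$row[idx])^2 + diff(points$col[idx])^2)
      arc <- c(0, cumsum(steps))
      lo2 <- arc[st[1L]] - maxWeakTail; hi2 <- arc[st[length(st)]] + maxWeakTail
      idx <- idx[arc >= lo2 & arc <= hi2]
    }
    if (length(idx) < minPoints) next
    seg <- points[idx, , drop = FALSE]
    arclen <- sum(sqrt(diff(seg$row)^2 + diff(seg$col)^2))
    if (arclen < minLength) next
    out[[length(out) + 1L]] <- seg
  }
  out
}
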