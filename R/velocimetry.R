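#' Per-frame enhancement for velocimetry
#'
#' Every frame is independently brightness-histogram-equalized and then
#' Gaussian-smoothed. Per-frame equalization removes global inter-frame
#' brightness differences (flicker), which would otherwise imprint vertical
#' stripes on the space-time diagrams; the smoothing suppresses sensor
#' noise.
#'
#' @param seq an [ImageSequence-class].
#' @param smoothSigma Gaussian smoothing SD, px.
#' @return enhanced [ImageSequence-class].
#' @export
enhanceFrames <- function(seq, smoothSigma = 1) {
  fr <- lapply(frames(seq), function(f) gaussSmooth(histEqualize(f), smoothSigma))
  imageSequence(fr, frameRate = frameRate(seq), pixelPitch = pixelPitch(seq))
}

# Resample a centerline at ~1 px arclength spacing; returns (row, col) matrix.
.resampleCenterline <- function(cl) {
  seglen <- sqrt(diff(cl[, 1L])^2 + diff(cl[, 2L])^2)
  s <- c(0, cumsum(seglen))
  L <- s[length(s)]
  S <- max(2L, round(L))
  si <- seq(0, L, length.out = S)
  cbind(stats::approx(s, cl[, 1L], xout = si)$y,
        stats::approx(s, cl[, 2L], xout = si)$y)
}

#' Build the space-time diagram of a vessel
#'
#' For every frame, intensities are sampled (bilinear) at equidistant
#' arclength positions (about 1 px apart) along the vessel centerline and
#' appended as one column, producing an S x T map whose sloped dark bands
#' are moving red blood cells. Centerline samples falling outside the frame
#' are trimmed (with a warning). The finished diagram is
#' histogram-equalized.
#'
#' @param seq enhanced [ImageSequence-class] (see [enhanceFrames()]).
#' @param vessel a [VesselSegment-class].
#' @param endTrim arclength (px) trimmed from both centerline ends before
#'   sampling: line-point localization is least reliable at the vessel
#'   tips, and sampling past the true end reads static background that
#'   imprints stationary bands on the diagram.
#' @return a [SpaceTimeDiagram-class].
#' @export
buildSpaceTimeDiagram <- function(seq, vessel, endTrim = 0) {
  fr <- frames(seq)
  stopifnot(length(fr) >= 2L)
  pts <- .resampleCenterline(centerline(vessel))
  if (endTrim > 0 && nrow(pts) > 4 * endTrim) {
    k <- round(endTrim)
    pts <- pts[(1L + k):(nrow(pts) - k), , drop = FALSE]
  }
  d <- dim(fr[[1L]])
  inside <- pts[, 1L] >= 0 & pts[, 1L] <= d[1L] - 1 &
    pts[, 2L] >= 0 & pts[, 2L] <= d[2L] - 1
  if (!all(inside)) {
    warning("centerline exits the field of view; trimming to interior part")
    runs <- rle(inside)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    k <- which(runs$values)
    if (!length(k)) stop("centerline entirely outside the field of view")
    k <- k[which.max(runs$lengths[k])]
    pts <- pts[starts[k]:ends[k], , drop = FALSE]
  }
  if (nrow(pts) < 2L) stop("centerline too short inside the field of view")
  m <- vapply(fr, function(f) cpp_bilinear(f, pts[, 1L], pts[, 2L]),
              numeric(nrow(pts)))
  m <- histEqualize(m)
  new("SpaceTimeDiagram", matrix = m, pixelPitch = pixelPitch(seq),
      frameRate = frameRate(seq), vesselId = vessel@id)
}

#' Detect raw red blood cell paths in a space-time diagram
#'
#' The same principal-curvature line detector and linking used for vessel
#' recognition is applied to the diagram (with diagram-specific scale and
#' thresholds); each resulting centerline in (space, time) becomes a raw
#' path ordered by time.
#'
#' @param std a [SpaceTimeDiagram-class].
#' @param params parameter list from [hvmParams()].
#' @return list of [RBCPath-class] with velocity and curvature index set
#'   and `pathType` still unset ("raw").
#' @export
detectRBCPaths <- function(std, params = hvmParams()) {
  pts <- stegerDetect(std@matrix, params$std_sigma, params$std_high,
                      params$std_low, borderMargin = 1)
  lines <- linkLinePoints(pts, params$std_link_h, params$std_link_l,
                          minLength = 3, minPoints = 3L)
  lapply(lines, function(seg) {
    p <- cbind(space = seg$row, time = seg$col)
    p <- p[order(p[, 2L]), , drop = FALSE]
    v <- pathVelocity(p, std@pixelPitch, std@frameRate)
    new("RBCPath", points = p, velocity = v, curvatureIndex = curvatureIndex(p),
        pathType = "raw", vesselId = std@vesselId)
  })
}

#' Red blood cell path velocity
#'
#' The velocity magnitude is the mean of the path's first derivative of
#' space with respect to time, converted to um/s by the pixel pitch and the
#' frame rate. Subpixel path samples are first collapsed to one mean space
#' position per frame so that near-vertical (fast) paths do not produce
#' unstable pairwise slopes; the mean |delta space| / |delta time| over
#' consecutive frame samples is then scaled by `pitch * f`.
#'
#' @param points n x 2 matrix (space px, time frames), time nondecreasing,
#'   or an [RBCPath-class].
#' @param pitch um per pixel.
#' @param f frame rate, 1/s.
#' @return velocity, um/s (magnitude); `NA` if the path spans no time
#'   (artifact).
#' @examples
#' p <- cbind(seq(0, 40, by = 4), 0:10)  # 4 px per frame
#' pathVelocity(p, pitch = 1, f = 25)    # 100 um/s
#' @export
pathVelocity <- function(points, pitch, f) {
  if (is(points, "RBCPath")) points <- points@points
  stopifnot(pitch > 0, f > 0, nrow(points) >= 2L)
  tbin <- round(points[, 2L])
  sp <- tapply(points[, 1L], tbin, mean)
  tt <- as.numeric(names(sp))
  if (length(sp) < 4L) {
    # very steep paths span only a few frames; per-frame centroids truncate
    # the crossing and ordinary regression is corrupted by within-column
    # detection wiggle, so use the principal-axis (total least squares)
    # slope of the raw subpixel samples
    cv <- stats::cov(points)
    if (sum(diag(cv)) < 1e-12) return(NA_real_)
    ev <- eigen(cv, symmetric = TRUE)$vectors[, 1L]
    if (abs(ev[2L]) < 1e-9) return(NA_real_)  # zero time span
    return(abs(ev[1L] / ev[2L]) * pitch * f)
  }
  # the outermost bins cover only part of a frame interval and bias the
  # slope toward zero on steep paths; drop them when enough bins remain
  sp <- sp[-c(1L, length(sp))]
  tt <- tt[-c(1L, length(tt))]
  dt <- diff(tt)
  slopes <- abs(diff(sp)) / dt
  stats::weighted.mean(slopes, dt) * pitch * f
}

#' Curvature index of a path
#'
#' Ratio of the straight-line distance between the start and end points of
#' the path to the actual cumulative path length. Straight paths score 1;
#' the index decreases toward 0 for meandering or looping trajectories,
#' which flags detection artifacts.
#'
#' @param points n x 2 matrix of path samples, or an [RBCPath-class].
#' @return dimensionless value in [0, 1].
#' @examples
#' th <- seq(0, pi, length.out = 200)
#' arc <- cbind(cos(th), sin(th))
#' curvatureIndex(arc)  # ~ 2 / pi
#' @export
curvatureIndex <- function(points) {
  if (is(points, "RBCPath")) points <- points@points
  stopifnot(nrow(points) >= 2L)
  L <- sum(sqrt(diff(points[, 1L])^2 + diff(points[, 2L])^2))
  if (L <= 0) stop("degenerate single-point path")
  chord <- sqrt(sum((points[nrow(points), ] - points[1L, ])^2))
  min(chord / L, 1)
}

#' Maximum detectable red blood cell velocity
#'
#' A cell must stay visible inside the vessel for at least a few frames to
#' produce a measurable sloped band, so the measurable velocity is bounded
#' by the vessel length l (um) and the frame rate f (1/s):
#' \deqn{v_{max} = l \cdot f / 3}
#'
#' @param lengthUm vessel length, um (>= 0).
#' @param f frame rate, 1/s (> 0).
#' @return v_max, um/s.
#' @examples
#' computeVmax(300, 25)  # 2500
#' @export
computeVmax <- function(lengthUm, f) {
  stopifnot(lengthUm >= 0, f > 0)
  lengthUm * f / 3
}

#' Classify red blood cell paths
#'
#' Applies the artifact discard rules — path shorter than `minPathLength`
#' px, curvature index below `ciCutoff`, velocity above the vessel's
#' `vmax`, or a time span below two frame intervals (a first derivative
#' with respect to time is not measurable from fewer than three time
#' samples) — and classifies the remaining paths as `no_low_flow`
#' (velocity below `lowFlowCutoff`) or `normal_flow`.
#'
#' @param paths list of [RBCPath-class].
#' @param vmax maximum detectable velocity of the host vessel, um/s.
#' @param minPathLength minimum path length, px.
#' @param ciCutoff curvature-index cutoff.
#' @param lowFlowCutoff species-specific low-flow velocity cutoff, um/s.
#' @return the paths with `pathType` set.
#' @export
classifyPaths <- function(paths, vmax, minPathLength = 10, ciCutoff = 0.8,
                          lowFlowCutoff = 25) {
  lapply(paths, function(p) {
    L <- sum(sqrt(diff(p@points[, 1L])^2 + diff(p@points[, 2L])^2))
    tspan <- diff(range(p@points[, 2L]))
    p@pathType <-
      if (L < minPathLength || is.na(p@velocity) || tspan < 2 ||
          p@curvatureIndex < ciCutoff || p@velocity > vmax) "artifact"
      else if (p@velocity < lowFlowCutoff) "no_low_flow"
      else "normal_flow"
    p
  })
}

#' Resolve near-horizontal paths against the vessel's path population
#'
#' Near-horizontal traces in a space-time diagram are ambiguous: they are
#' genuine non-moving cells in a stalled vessel, but detection artifacts
#' (e.g. residual static structure along the centerline) in a flowing one.
#' The ambiguity is resolved on the per-vessel velocity distribution: if
#' more than `fraction` (default 0.95) of the non-artifact path velocities
#' lie below `lowFlowCutoff`, the slow paths are genuine (`no_low_flow`,
#' the barcode situation) and are kept; otherwise they are reclassified as
#' artifacts.
#'
#' @param paths list of classified [RBCPath-class] (see [classifyPaths()]).
#' @param lowFlowCutoff um/s.
#' @param fraction majority threshold (default 0.95).
#' @return the paths, with minority slow paths relabeled "artifact".
#' @export
resolveSlowPaths <- function(paths, lowFlowCutoff = 25, fraction = 0.95) {
  keep <- vapply(paths, function(p) p@pathType != "artifact", logical(1))
  if (!any(keep)) return(paths)
  v <- vapply(paths[keep], function(p) p@velocity, numeric(1))
  if (mean(v < lowFlowCutoff) > fraction) return(paths)
  lapply(paths, function(p) {
    if (p@pathType == "no_low_flow") p@pathType <- "artifact"
    p
  })
}

#' Vessel red blood cell velocity
#'
#' Arithmetic mean of the velocities of all non-artifact paths in the
#' vessel's space-time diagram; `NA` when none remain (the vessel is then
#' excluded from the field RBCv).
#'
#' @param paths list of classified [RBCPath-class].
#' @return um/s, or `NA`.
#' @export
vesselRBCV <- function(paths) {
  v <- vapply(paths, function(p) p@velocity, numeric(1))
  keep <- vapply(paths, function(p) p@pathType != "artifact", logical(1))
  if (!any(keep)) return(NA_real_)
  mean(v[keep])
}

#' Classify vessel perfusion from its path population
#'
#' Decision on the per-vessel velocity density distribution rather than the
#' mean velocity, for robustness to path artifacts. In the default
#' "fraction" mode: if more than `fraction` (default 0.95) of the
#' non-artifact path velocities lie below `lowFlowCutoff`, the vessel is
#' non-perfused unconditionally — the "barcode" rule: a stationary cell
#' column dominates regardless of a fast minority. Otherwise the vessel is
#' perfused if and only if the proportion of normal-flow paths exceeds
#' `fraction` (strictly greater than 95 percent). In "normal_fit" mode a
#' normal distribution is fitted to the velocity sample and the probability
#' masses below/above the cutoff replace the empirical fractions. Vessels
#' with no non-artifact path are non-perfused by convention.
#'
#' @param paths list of classified [RBCPath-class].
#' @param lowFlowCutoff um/s.
#' @param fraction decision threshold (default 0.95).
#' @param mode "fraction" (default) or "normal_fit".
#' @return "perfused" or "non_perfused".
#' @export
classifyPerfusion <- function(paths, lowFlowCutoff = 25, fraction = 0.95,
                              mode = c("fraction", "normal_fit")) {
  mode <- match.arg(mode)
  keep <- vapply(paths, function(p) p@pathType != "artifact", logical(1))
  if (!any(keep)) return("non_perfused")
  v <- vapply(paths[keep], function(p) p@velocity, numeric(1))
  types <- vapply(paths[keep], function(p) p@pathType, character(1))
  if (mode == "fraction") {
    fracSlow <- mean(v < lowFlowCutoff)
    if (fracSlow > fraction) return("non_perfused")
    fracNormal <- mean(types == "normal_flow")
    if (fracNormal > fraction) "perfused" else "non_perfused"
  } else {
    mu <- mean(v); sd <- stats::sd(v)
    if (is.na(sd) || sd < 1e-9)
      return(if (mu < lowFlowCutoff) "non_perfused"
             else if (mu >= lowFlowCutoff) "perfused")
    pSlow <- stats::pnorm(lowFlowCutoff, mu, sd)
    if (pSlow > fraction) return("non_perfused")
    if (1 - pSlow > fraction) "perfused" else "non_perfused"
  }
}

#' Run velocimetry for a set of vessels
#'
#' Builds the space-time diagram of every vessel from the enhanced
#' sequence, detects and classifies its red blood cell paths, and fills in
#' the vessel's `vmax`, RBCv and perfusion state.
#'
#' @param seq stabilized [ImageSequence-class] (raw gray values; enhanced
#'   internally).
#' @param vessels list of [VesselSegment-class].
#' @param params parameter list from [hvmParams()].
#' @return list with `vessels` (updated) and `paths` (flat list of all
#'   classified [RBCPath-class]).
#' @export
analyzeVelocimetry <- function(seq, vessels, params = hvmParams()) {
  enh <- enhanceFrames(seq, params$enhance_sigma)
  allPaths <- list()
  for (i in seq_along(vessels)) {
    v <- vessels[[i]]
    v@vmax <- computeVmax(v@lengthUm, frameRate(seq))
    paths <- tryCatch({
      std <- buildSpaceTimeDiagram(enh, v,
                                   endTrim = params$sigma_capillary)
      detectRBCPaths(std, params)
    }, error = function(e) list())
    paths <- classifyPaths(paths, v@vmax, params$min_path_length,
                           params$curvature_index_cutoff,
                           params$low_flow_cutoff)
    paths <- resolveSlowPaths(paths, params$low_flow_cutoff,
                              params$perfusion_fraction)
    v@rbcv <- vesselRBCV(paths)
    v@perfusion <- classifyPerfusion(paths, params$low_flow_cutoff,
                                     params$perfusion_fraction,
                                     params$perfusion_mode)
    vessels[[i]] <- v
    allPaths <- c(allPaths, paths)
  }
  list(vessels = vessels, paths = allPaths)
}
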