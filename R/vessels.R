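#' Temporal mean image
#'
#' Per-pixel arithmetic mean of gray values over all frames. Averaging over
#' time fills the apparent vessel discontinuities caused by plasma gaps
#' between moving red blood cells, so that the whole vessel appears as a
#' contiguous dark band.
#'
#' @param seq an [ImageSequence-class].
#' @return numeric matrix of the same H x W.
#' @export
computeMeanImage <- function(seq) {
  fr <- frames(seq)
  Reduce(`+`, fr) / length(fr)
}

#' Classify a vessel by mean diameter
#'
#' @param meanDiameterUm mean diameter, um (> 0).
#' @param capillaryMaxUm capillary cutoff, um; vessels with mean diameter at
#'   or below it are capillaries (boundary inclusive), larger vessels
#'   venules.
#' @return "capillary" or "venule".
#' @examples
#' classifyVesselType(10)   # capillary
#' classifyVesselType(20)   # capillary (boundary inclusive)
#' classifyVesselType(150)  # venule
#' @export
classifyVesselType <- function(meanDiameterUm, capillaryMaxUm = 20) {
  stopifnot(all(meanDiameterUm > 0))
  ifelse(meanDiameterUm <= capillaryMaxUm, "capillary", "venule")
}

# Build a VesselSegment from a linked polyline (full-resolution px units).
.polylineToVessel <- function(seg, id, pitch, capillaryMaxUm) {
  cl <- cbind(seg$row, seg$col)
  lengthUm <- sum(sqrt(diff(cl[, 1L])^2 + diff(cl[, 2L])^2)) * pitch
  meanDiam <- mean(seg$width) * pitch
  new("VesselSegment", id = as.integer(id), centerline = cl,
      normalAngle = seg$angle, widthPx = seg$width, lengthUm = lengthUm,
      meanDiameterUm = meanDiam,
      vesselType = classifyVesselType(meanDiam, capillaryMaxUm),
      rbcv = NA_real_, vmax = NA_real_, perfusion = NA_character_)
}

#' Detect vessels on the mean image
#'
#' Runs two line-detection passes over the CLAHE-enhanced mean image: a
#' capillary pass at `sigma_capillary`, and a venule pass at `sigma_venule`
#' executed on an image downsampled by `venule_downsample` (coordinates and
#' widths are scaled back). Contrast enhancement is applied per pass.
#' Venule-pass line points lying within one local vessel width of a
#' capillary-pass centerline point are removed before linking, so a vessel
#' found by both passes yields a single segment. Final segments carry the
#' subpixel centerline, per-point diameters, arclength and mean diameter in
#' um, and the capillary/venule classification.
#'
#' @param meanImage numeric matrix in [0, 255].
#' @param pitch pixel pitch, um per pixel.
#' @param params parameter list from [hvmParams()].
#' @return list of [VesselSegment-class].
#' @export
detectVessels <- function(meanImage, pitch, params = hvmParams()) {
  stopifnot(pitch > 0)
  enh <- clahe(meanImage, params$clahe_clip, params$clahe_tiles)
  capPts <- stegerDetect(enh, params$sigma_capillary, params$steger_high,
                         params$steger_low)
  capLines <- linkLinePoints(capPts, params$link_h, params$link_l,
                             minLength = params$min_centerline_px,
                             maxWeakTail = 2 * params$sigma_capillary)
  # points that survived linking define the capillary-pass map
  capKept <- if (length(capLines)) do.call(rbind, capLines) else capPts[0, ]

  ds <- as.integer(params$venule_downsample)
  small <- downsampleBy(meanImage, ds)
  enhV <- clahe(small, params$clahe_clip, params$clahe_tiles)
  venPts <- stegerDetect(enhV, params$sigma_venule / ds, params$steger_high,
                         params$steger_low)
  if (nrow(venPts)) {
    # back to full-resolution coordinates (block centers)
    venPts$row <- venPts$row * ds + (ds - 1) / 2
    venPts$col <- venPts$col * ds + (ds - 1) / 2
    venPts$width <- venPts$width * ds
  }
  if (nrow(venPts) && nrow(capKept)) {
    keep <- !.nearCenterline(venPts, capKept)
    venPts <- venPts[keep, , drop = FALSE]
  }
  venLines <- linkLinePoints(venPts, params$link_h, params$link_l * ds,
                             minLength = params$min_centerline_px,
                             maxWeakTail = 2 * params$sigma_venule)

  segs <- c(capLines, venLines)
  out <- vector("list", length(segs))
  for (i in seq_along(segs))
    out[[i]] <- .polylineToVessel(segs[[i]], i, pitch,
                                  params$capillary_max_diameter_um)
  out
}

# TRUE for venule-pass points lying within one local vessel width of any
# capillary-pass point (chunked distance computation).
.nearCenterline <- function(venPts, capPts) {
  nv <- nrow(venPts)
  res <- logical(nv)
  cr <- capPts$row; cc <- capPts$col; cw <- capPts$width
  chunk <- 500L
  for (st in seq(1L, nv, by = chunk)) {
    en <- min(st + chunk - 1L, nv)
    idx <- st:en
    d2 <- outer(venPts$row[idx], cr, `-`)^2 + outer(venPts$col[idx], cc, `-`)^2
    j <- max.col(-d2, ties.method = "first")
    dmin <- sqrt(d2[cbind(seq_along(idx), j)])
    lim <- pmax(venPts$width[idx], cw[j])
    res[idx] <- dmin < lim
  }
  res
}
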