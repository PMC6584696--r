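#' @useDynLib hvmflow, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Device calibration profile
#'
#' Describes the optical calibration of a handheld vital microscopy (HVM)
#' device: the pixel pitch at the object plane (the physical size of one
#' pixel, micrometres per pixel) which converts pixel measurements to
#' real-world units, the native sensor raster, and the default acquisition
#' frame rate.
#'
#' @slot name device name.
#' @slot pixelPitch pixel pitch, um per pixel (> 0).
#' @slot nativeWidth,nativeHeight native frame size in pixels.
#' @slot frameRate default frame rate, 1/s (> 0).
#' @export
setClass("DeviceProfile",
  representation(name = "character", pixelPitch = "numeric",
                 nativeWidth = "integer", nativeHeight = "integer",
                 frameRate = "numeric"),
  validity = function(object) {
    if (length(object@pixelPitch) != 1L || !is.finite(object@pixelPitch) ||
        object@pixelPitch <= 0) return("pixelPitch must be a positive number")
    if (length(object@frameRate) != 1L || !is.finite(object@frameRate) ||
        object@frameRate <= 0) return("frameRate must be a positive number")
    TRUE
  })

#' Calibrated grayscale image sequence
#'
#' The universal pipeline carrier: an ordered list of equally sized grayscale
#' frames (numeric matrices with values in [0, 255]) together with the frame
#' rate and the pixel pitch. The field-of-view area in mm^2 is derived from
#' the raster size and the pitch.
#'
#' @slot frames list of H x W numeric matrices, values in [0, 255].
#' @slot frameRate frames per second (> 0).
#' @slot pixelPitch um per pixel (> 0).
#' @export
setClass("ImageSequence",
  representation(frames = "list", frameRate = "numeric",
                 pixelPitch = "numeric"),
  validity = function(object) {
    if (length(object@frames) < 1L) return("at least one frame required")
    if (!all(vapply(object@frames, is.matrix, logical(1))))
      return("frames must be numeric matrices")
    d <- dim(object@frames[[1L]])
    same <- vapply(object@frames, function(f) identical(dim(f), d), logical(1))
    if (!all(same)) return("inconsistent frame size")
    if (object@frameRate <= 0) return("frameRate must be positive")
    if (object@pixelPitch <= 0) return("pixelPitch must be positive")
    TRUE
  })

#' A detected vessel segment
#'
#' A subpixel centerline with, at every line point, the direction of the
#' normal vector and the local vessel diameter. Length is the cumulative
#' Euclidean arclength of the centerline converted by the pixel pitch; the
#' mean diameter is the mean of the per-point width estimates. Vessels with a
#' mean diameter at or below the capillary cutoff (20 um by default) are
#' capillaries, larger vessels venules. Red blood cell velocity (RBCv) and
#' the perfusion state are filled in by the velocimetry stage (NA before
#' that, or when no usable RBC path exists).
#'
#' @slot id integer vessel identifier, unique within a field of view.
#' @slot centerline n x 2 matrix of 0-based subpixel (row, col) positions.
#' @slot normalAngle per-point normal direction, radians in [0, pi).
#' @slot widthPx per-point vessel width (diameter), pixels.
#' @slot lengthUm centerline arclength, um.
#' @slot meanDiameterUm mean of per-point diameters, um.
#' @slot vesselType "capillary" or "venule".
#' @slot rbcv mean red blood cell velocity, um/s (NA if undefined).
#' @slot vmax maximum measurable velocity for this vessel, um/s.
#' @slot perfusion "perfused", "non_perfused" or NA.
#' @export
setClass("VesselSegment",
  representation(id = "integer", centerline = "matrix",
                 normalAngle = "numeric", widthPx = "numeric",
                 lengthUm = "numeric", meanDiameterUm = "numeric",
                 vesselType = "character", rbcv = "numeric",
                 vmax = "numeric", perfusion = "character"),
  validity = function(object) {
    if (ncol(object@centerline) != 2L) return("centerline must be n x 2")
    if (nrow(object@centerline) < 2L) return("centerline needs >= 2 points")
    if (any(object@widthPx < 0)) return("widths must be >= 0")
    if (!object@vesselType %in% c("capillary", "venule"))
      return("vesselType must be capillary or venule")
    TRUE
  })

#' Space-time diagram (kymograph) of one vessel
#'
#' Two-dimensional intensity map of a straightened vessel: rows are
#' equidistant arclength positions along the centerline (about 1 px apart),
#' columns are frames. Moving red blood cells appear as sloped dark bands
#' whose slope encodes velocity; stationary cells produce horizontal banding
#' (the "barcode sign").
#'
#' @slot matrix S x T intensity matrix.
#' @slot pixelPitch um per pixel along the space axis.
#' @slot frameRate frames per second along the time axis.
#' @slot vesselId id of the originating vessel.
#' @export
setClass("SpaceTimeDiagram",
  representation(matrix = "matrix", pixelPitch = "numeric",
                 frameRate = "numeric", vesselId = "integer"),
  validity = function(object) {
    if (nrow(object@matrix) < 2L || ncol(object@matrix) < 2L)
      return("diagram must be at least 2 x 2")
    if (object@pixelPitch <= 0 || object@frameRate <= 0)
      return("axis scales must be positive")
    TRUE
  })

#' One tracked red blood cell path
#'
#' A single cell trajectory detected inside a space-time diagram: ordered
#' subpixel (space px, time frames) samples with nondecreasing time, the
#' velocity magnitude (mean first derivative of space with respect to time,
#' converted to um/s), the curvature index (straight-line endpoint distance
#' over actual path length, in (0, 1]; low values flag artifacts) and the
#' path classification.
#'
#' @slot points n x 2 matrix, columns (space px, time frames).
#' @slot velocity um/s, magnitude.
#' @slot curvatureIndex dimensionless in [0, 1].
#' @slot pathType "normal_flow", "no_low_flow" or "artifact".
#' @slot vesselId id of the host vessel.
#' @export
setClass("RBCPath",
  representation(points = "matrix", velocity = "numeric",
                 curvatureIndex = "numeric", pathType = "character",
                 vesselId = "integer"),
  validity = function(object) {
    if (ncol(object@points) != 2L) return("points must be n x 2")
    if (is.unsorted(object@points[, 2L])) return("time must be nondecreasing")
    if (!is.na(object@velocity) && object@velocity < 0)
      return("velocity is a magnitude, must be >= 0")
    TRUE
  })

#' Consensus field-of-view metrics
#'
#' The per-field microcirculation parameters: total vessel density (TVD, sum
#' of capillary centerline lengths over the field-of-view area, mm/mm^2),
#' functional capillary density (FCD, same sum restricted to perfused
#' capillaries), proportion of perfused vessels (PPV = FCD/TVD, the
#' length-weighted fraction of perfused capillaries) and the length-weighted
#' mean capillary RBCv.
#'
#' @slot tvd total vessel density, mm mm^-2.
#' @slot fcd functional capillary density, mm mm^-2.
#' @slot ppv proportion of perfused vessels in [0, 1].
#' @slot rbcv length-weighted field RBCv, um/s (NA if undefined).
#' @slot fovArea field-of-view area, mm^2.
#' @slot nCapillaries,nVenules,nPaths entity counts.
#' @export
setClass("FieldMetrics",
  representation(tvd = "numeric", fcd = "numeric", ppv = "numeric",
                 rbcv = "numeric", fovArea = "numeric",
                 nCapillaries = "integer", nVenules = "integer",
                 nPaths = "integer"),
  validity = function(object) {
    if (object@fcd > object@tvd + 1e-9) return("fcd cannot exceed tvd")
    if (object@ppv < -1e-12 || object@ppv > 1 + 1e-12)
      return("ppv must lie in [0, 1]")
    TRUE
  })

#' Synthetic scene specification
#'
#' Declarative description of an HVM-like synthetic scene: raster and
#' acquisition geometry, background level, per-vessel tube definitions
#' (centerline control points, diameter, velocity, cell spacing, contrast,
#' optional per-frame on/off intermittency pattern) and the confounder
#' amplitudes (sensor noise, global brightness flicker, translational
#' jitter). Rendering is deterministic given the seed.
#'
#' @slot width,height raster size, px.
#' @slot nFrames number of frames.
#' @slot frameRate frames per second.
#' @slot pixelPitch um per pixel.
#' @slot backgroundLevel background gray level.
#' @slot vessels list of vessel descriptions (see [sceneVessel()]).
#' @slot noiseSd additive Gaussian sensor noise SD, gray levels.
#' @slot flickerAmplitude global per-frame brightness flicker amplitude.
#' @slot jitterAmplitude translational jitter amplitude, px.
#' @slot textureAmplitude static tissue texture amplitude, gray levels.
#' @slot seed integer seed driving all stochastic elements.
#' @export
setClass("SceneSpec",
  representation(width = "integer", height = "integer", nFrames = "integer",
                 frameRate = "numeric", pixelPitch = "numeric",
                 backgroundLevel = "numeric", vessels = "list",
                 noiseSd = "numeric", flickerAmplitude = "numeric",
                 jitterAmplitude = "numeric", textureAmplitude = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (object@nFrames < 1L) return("need at least one frame")
    if (object@frameRate <= 0 || object@pixelPitch <= 0)
      return("frameRate and pixelPitch must be positive")
    for (v in object@vessels)
      if (v$velocity < 0) return("vessel velocities must be >= 0")
    TRUE
  })

#' Ground truth accompanying a rendered synthetic scene
#'
#' Exact per-vessel truth (subpixel centerline, length, diameter, velocity,
#' perfusion label), the injected per-frame jitter, and the analytic field
#' metrics recomputable from the per-vessel fields by the aggregation
#' formulas.
#'
#' @slot vessels list with per-vessel truth (centerline, lengthUm,
#'   diameterUm, velocity, perfused, type).
#' @slot jitter nFrames x 2 matrix of injected (row, col) shifts, px.
#' @slot metrics named list with analytic tvd, fcd, ppv, rbcv, fovArea.
#' @export
setClass("GroundTruth",
  representation(vessels = "list", jitter = "matrix", metrics = "list"))
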