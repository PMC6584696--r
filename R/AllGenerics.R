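#' @rdname ImageSequence-accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname ImageSequence-accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname ImageSequence-accessors
#' @export
setGeneric("pixelPitch", function(x) standardGeneric("pixelPitch"))
#' @rdname ImageSequence-accessors
#' @export
setGeneric("fovArea", function(x) standardGeneric("fovArea"))
#' @rdname ImageSequence-accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname VesselSegment-accessors
#' @export
setGeneric("centerline", function(x) standardGeneric("centerline"))
#' @rdname VesselSegment-accessors
#' @export
setGeneric("vesselType", function(x) standardGeneric("vesselType"))
#' @rdname VesselSegment-accessors
#' @export
setGeneric("vesselLength", function(x) standardGeneric("vesselLength"))
#' @rdname VesselSegment-accessors
#' @export
setGeneric("meanDiameter", function(x) standardGeneric("meanDiameter"))
#' @rdname VesselSegment-accessors
#' @export
setGeneric("rbcv", function(x) standardGeneric("rbcv"))
#' @rdname VesselSegment-accessors
#' @export
setGeneric("perfusion", function(x) standardGeneric("perfusion"))

#' Accessors for ImageSequence
#'
#' @param x an [ImageSequence-class] object.
#' @return `frames()` the list of frame matrices; `frameRate()` frames per
#'   second; `pixelPitch()` um per pixel; `fovArea()` the field-of-view area
#'   in mm^2 (H * W * pitch^2 * 1e-6); `nFrames()` the frame count.
#' @name ImageSequence-accessors
NULL

#' @rdname ImageSequence-accessors
setMethod("frames", "ImageSequence", function(x) x@frames)
#' @rdname ImageSequence-accessors
setMethod("frameRate", "ImageSequence", function(x) x@frameRate)
#' @rdname ImageSequence-accessors
setMethod("pixelPitch", "ImageSequence", function(x) x@pixelPitch)
#' @rdname ImageSequence-accessors
setMethod("nFrames", "ImageSequence", function(x) length(x@frames))
#' @rdname ImageSequence-accessors
setMethod("fovArea", "ImageSequence", function(x) {
  d <- dim(x@frames[[1L]])
  d[1L] * d[2L] * x@pixelPitch^2 * 1e-6
})
#' @rdname ImageSequence-accessors
setMethod("dim", "ImageSequence", function(x) dim(x@frames[[1L]]))

#' Accessors for VesselSegment
#'
#' @param x a [VesselSegment-class] object.
#' @return `centerline()` the n x 2 subpixel (row, col) matrix;
#'   `vesselType()` "capillary" or "venule"; `vesselLength()` arclength in
#'   um; `meanDiameter()` mean diameter in um; `rbcv()` vessel RBCv in um/s
#'   (NA when undefined); `perfusion()` "perfused"/"non_perfused"/NA.
#' @name VesselSegment-accessors
NULL

#' @rdname VesselSegment-accessors
setMethod("centerline", "VesselSegment", function(x) x@centerline)
#' @rdname VesselSegment-accessors
setMethod("vesselType", "VesselSegment", function(x) x@vesselType)
#' @rdname VesselSegment-accessors
setMethod("vesselLength", "VesselSegment", function(x) x@lengthUm)
#' @rdname VesselSegment-accessors
setMethod("meanDiameter", "VesselSegment", function(x) x@meanDiameterUm)
#' @rdname VesselSegment-accessors
setMethod("rbcv", "VesselSegment", function(x) x@rbcv)
#' @rdname VesselSegment-accessors
setMethod("perfusion", "VesselSegment", function(x) x@perfusion)

setMethod("show", "ImageSequence", function(object) {
  d <- dim(object@frames[[1L]])
  cat(sprintf(
    "ImageSequence: %d frames of %d x %d px, %.3g fps, %.3g um/px, FOV %.4g mm^2\n",
    length(object@frames), d[1L], d[2L], object@frameRate,
    object@pixelPitch, fovArea(object)))
})

setMethod("show", "VesselSegment", function(object) {
  cat(sprintf(
    "VesselSegment #%d (%s): length %.1f um, mean diameter %.1f um, RBCv %s, %s\n",
    object@id, object@vesselType, object@lengthUm, object@meanDiameterUm,
    if (is.na(object@rbcv)) "undefined" else sprintf("%.0f um/s", object@rbcv),
    if (is.na(object@perfusion)) "perfusion unclassified" else object@perfusion))
})

setMethod("show", "SpaceTimeDiagram", function(object) {
  cat(sprintf("SpaceTimeDiagram (vessel #%d): %d space px x %d frames\n",
              object@vesselId, nrow(object@matrix), ncol(object@matrix)))
})

setMethod("show", "RBCPath", function(object) {
  cat(sprintf("RBCPath (vessel #%d, %s): v = %.1f um/s, CI = %.3f, %d points\n",
              object@vesselId, object@pathType, object@velocity,
              object@curvatureIndex, nrow(object@points)))
})

setMethod("show", "FieldMetrics", function(object) {
  cat(sprintf(
    paste0("FieldMetrics: TVD %.2f mm/mm^2, FCD %.2f mm/mm^2, PPV %.3f,",
           " field RBCv %s\n  %d capillaries, %d venules, %d RBC paths,",
           " FOV %.4g mm^2\n"),
    object@tvd, object@fcd, object@ppv,
    if (is.na(object@rbcv)) "undefined" else sprintf("%.0f um/s", object@rbcv),
    object@nCapillaries, object@nVenules, object@nPaths, object@fovArea))
})

setMethod("show", "DeviceProfile", function(object) {
  cat(sprintf("DeviceProfile '%s': %.3g um/px, %d x %d px, %.3g fps\n",
              object@name, object@pixelPitch, object@nativeWidth,
              object@nativeHeight, object@frameRate))
})
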