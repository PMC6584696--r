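#' Total vessel density (TVD)
#'
#' Sum of the centerline lengths of all capillaries (venules excluded),
#' converted to mm, divided by the field-of-view area.
#'
#' @param vessels list of [VesselSegment-class].
#' @param fovAreaMm2 field-of-view area, mm^2 (> 0).
#' @return TVD, mm mm^-2.
#' @examples
#' # two capillaries of 500 and 300 um in 0.1 mm^2 -> 8 mm/mm^2
#' @export
totalVesselDensity <- function(vessels, fovAreaMm2) {
  stopifnot(fovAreaMm2 > 0)
  caps <- Filter(function(v) v@vesselType == "capillary", vessels)
  if (!length(caps)) return(0)
  sum(vapply(caps, function(v) v@lengthUm, numeric(1))) / 1000 / fovAreaMm2
}

#' Functional capillary density (FCD) and proportion of perfused vessels (PPV)
#'
#' FCD is the summed length of perfused capillaries per area; PPV is the
#' length-weighted fraction of perfused capillaries and equals FCD / TVD
#' (0 when TVD is 0). Capillaries with an undefined perfusion state count
#' as non-perfused.
#'
#' @param vessels list of [VesselSegment-class] with perfusion states set.
#' @param fovAreaMm2 field-of-view area, mm^2.
#' @return named list with `fcd` (mm mm^-2) and `ppv` (in [0, 1]).
#' @export
functionalCapillaryDensity <- function(vessels, fovAreaMm2) {
  stopifnot(fovAreaMm2 > 0)
  caps <- Filter(function(v) v@vesselType == "capillary", vessels)
  tvd <- totalVesselDensity(vessels, fovAreaMm2)
  perf <- Filter(function(v) isTRUE(v@perfusion == "perfused"), caps)
  fcd <- if (length(perf))
    sum(vapply(perf, function(v) v@lengthUm, numeric(1))) / 1000 / fovAreaMm2
  else 0
  list(fcd = fcd, ppv = if (tvd > 0) fcd / tvd else 0)
}

#' Length-weighted field red blood cell velocity
#'
#' Weighted mean of the per-capillary RBCv with the capillary centerline
#' lengths as weights; capillaries with undefined RBCv are excluded from
#' numerator and denominator. `NA` when no capillary has a defined RBCv.
#' Length weighting makes the result invariant to a capillary being split
#' into several abutting segments, e.g. by the focal plane.
#'
#' @param vessels list of [VesselSegment-class] with RBCv set.
#' @return field RBCv, um/s, or `NA`.
#' @export
fieldRBCV <- function(vessels) {
  caps <- Filter(function(v) v@vesselType == "capillary" && !is.na(v@rbcv),
                 vessels)
  if (!length(caps)) return(NA_real_)
  len <- vapply(caps, function(v) v@lengthUm, numeric(1))
  vel <- vapply(caps, function(v) v@rbcv, numeric(1))
  sum(len * vel) / sum(len)
}

#' Aggregate per-vessel results into field metrics
#'
#' @param vessels list of [VesselSegment-class] (velocimetry done).
#' @param fovAreaMm2 field-of-view area, mm^2.
#' @param nPaths number of non-artifact RBC paths (informational).
#' @return a [FieldMetrics-class].
#' @export
fieldMetrics <- function(vessels, fovAreaMm2, nPaths = NA_integer_) {
  tvd <- totalVesselDensity(vessels, fovAreaMm2)
  fp <- functionalCapillaryDensity(vessels, fovAreaMm2)
  types <- vapply(vessels, function(v) v@vesselType, character(1))
  new("FieldMetrics", tvd = tvd, fcd = fp$fcd, ppv = fp$ppv,
      rbcv = fieldRBCV(vessels), fovArea = fovAreaMm2,
      nCapillaries = sum(types == "capillary"),
      nVenules = sum(types == "venule"),
      nPaths = as.integer(nPaths))
}
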