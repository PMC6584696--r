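#' Run the full analysis pipeline on an image sequence
#'
#' Chains all stages: optional quality gate on an operator-supplied Massey
#' score, stabilization (estimate, smooth, warp, crop), temporal mean image,
#' two-pass vessel detection, per-capillary space-time velocimetry with
#' artifact filtering and perfusion classification, and aggregation into
#' the field-of-view metrics (TVD, FCD, PPV, length-weighted field RBCv).
#'
#' @param seq an [ImageSequence-class] (>= 2 frames).
#' @param params parameter list from [hvmParams()].
#' @param masseyScore optional operator quality score; when supplied, a
#'   score of 10 or above aborts with an error.
#' @param stabilize run the stabilization stage (default TRUE; turn off
#'   for pre-stabilized input).
#' @param verbose log per-stage timings to stderr.
#' @return list with `metrics` ([FieldMetrics-class]), `vessels`, `paths`,
#'   `meanImage`, `stabilized` (the stabilized [ImageSequence-class]) and
#'   `trajectory` (stabilization diagnostics, or NULL).
#' @examples
#' \donttest{
#' sc <- renderScene(defaultSuite(seed = 7)$normal_flow$spec)
#' res <- analyzeSequence(sc$sequence, stabilize = FALSE)
#' res$metrics
#' }
#' @export
analyzeSequence <- function(seq, params = hvmParams(), masseyScore = NULL,
                            stabilize = TRUE, verbose = FALSE) {
  stopifnot(is(seq, "ImageSequence"), nFrames(seq) >= 2L)
  if (!is.null(masseyScore) && qualityGate(masseyScore) == "reject")
    stop("sequence rejected by quality gate (Massey score ", masseyScore,
         " >= 10)")
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, t0) {
    if (verbose) message(sprintf("[hvmflow] %-14s %6.2f s", name, tic() - t0))
  }
  traj <- NULL
  t0 <- tic()
  if (stabilize) {
    st <- stabilizeSequence(seq, params)
    seq <- st$sequence
    traj <- st[c("raw", "smoothed", "corrections")]
    stage("stabilize", t0)
  }
  t0 <- tic()
  mi <- computeMeanImage(seq)
  vessels <- detectVessels(mi, pixelPitch(seq), params)
  stage("vessels", t0)
  t0 <- tic()
  vm <- analyzeVelocimetry(seq, vessels, params)
  stage("velocimetry", t0)
  nPaths <- sum(vapply(vm$paths, function(p) p@pathType != "artifact",
                       logical(1)))
  metrics <- fieldMetrics(vm$vessels, fovArea(seq), nPaths)
  list(metrics = metrics, vessels = vm$vessels, paths = vm$paths,
       meanImage = mi, stabilized = seq, trajectory = traj)
}
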