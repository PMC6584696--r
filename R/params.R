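#' Analysis parameters
#'
#' Returns the full flat parameter set driving the pipeline, optionally
#' overriding individual entries. All tunables of every stage are exposed
#' here so a single configuration file can reproduce an analysis.
#'
#' Key entries (units in brackets):
#' \describe{
#'   \item{sigma_capillary [px]}{Gaussian scale of the capillary-pass line
#'     detector; detects lines of width up to about 2*sqrt(3)*sigma.}
#'   \item{sigma_venule [px]}{scale of the venule pass, expressed at full
#'     resolution; the pass runs on an image downsampled by
#'     `venule_downsample`.}
#'   \item{steger_high, steger_low}{hysteresis thresholds on the
#'     scale-normalized second-derivative response (sigma^2 * |eigenvalue|,
#'     intensity normalized to [0, 1]).}
#'   \item{link_h [rad], link_l [px]}{maximum tangent-angle difference and
#'     maximum link distance of the point-linking stage.}
#'   \item{clahe_clip, clahe_tiles}{relative histogram slope limit and tile
#'     grid of contrast-limited adaptive histogram equalization.}
#'   \item{capillary_max_diameter_um [um]}{capillary/venule cutoff (vessels
#'     with mean diameter at or below it are capillaries).}
#'   \item{min_centerline_px [px]}{minimum accepted vessel polyline length.}
#'   \item{std_sigma, std_high, std_low}{line-detector settings for
#'     space-time diagrams.}
#'   \item{min_path_length [px], curvature_index_cutoff, low_flow_cutoff
#'     [um/s]}{RBC-path artifact and flow-classification rules.}
#'   \item{perfusion_fraction, perfusion_mode}{fraction threshold (default
#'     0.95) and mode ("fraction" or "normal_fit") of the perfusion
#'     classifier.}
#'   \item{stab_* , smoothing_window}{stabilization settings: feature
#'     budget, minimum feature count, Lucas-Kanade window half-size, pyramid
#'     levels, iterations, and the trajectory smoothing window (frames,
#'     odd).}
#' }
#'
#' @param ... named overrides of individual defaults.
#' @return named list of parameters.
#' @examples
#' p <- hvmParams(sigma_capillary = 4)
#' p$sigma_capillary
#' @export
hvmParams <- function(...) {
  p <- list(
    # vessel detection
    sigma_capillary = 5,
    sigma_venule = 28,
    venule_downsample = 4L,
    steger_high = 0.105,
    steger_low = 0.08,
    link_h = 0.5,
    link_l = 2.5,
    clahe_clip = 3,
    clahe_tiles = c(8L, 8L),
    capillary_max_diameter_um = 20,
    min_centerline_px = 10,
    border_margin_px = 3,
    # per-frame enhancement and space-time diagrams
    enhance_sigma = 1,
    std_sigma = 1.5,
    std_high = 0.10,
    std_low = 0.05,
    std_link_h = 0.6,
    std_link_l = 2.5,
    min_path_length = 10,
    curvature_index_cutoff = 0.8,
    low_flow_cutoff = 25,
    perfusion_fraction = 0.95,
    perfusion_mode = "fraction",
    # stabilization
    stab_max_features = 500L,
    stab_min_features = 20L,
    stab_min_spacing = 8,
    stab_window = 10L,
    stab_pyr_levels = 3L,
    stab_iterations = 30L,
    stab_eps = 0.01,
    smoothing_window = 15L
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  p
}

#' Read or write a parameter configuration file
#'
#' Parameters are stored as a flat YAML key-value file; unknown keys are
#' rejected so stale configurations fail loudly.
#'
#' @param path file path.
#' @param params named list as returned by [hvmParams()].
#' @return `readHvmConfig` returns a full parameter list (file values
#'   override defaults); `writeHvmConfig` returns `path` invisibly.
#' @export
readHvmConfig <- function(path) {
  stopifnot(file.exists(path))
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$clahe_tiles)) vals$clahe_tiles <- as.integer(vals$clahe_tiles)
  do.call(hvmParams, vals)
}

#' @rdname readHvmConfig
#' @export
writeHvmConfig <- function(params, path) {
  yaml::write_yaml(params, path)
  invisible(path)
}
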