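#' Construct a device profile
#'
#' @param name device name.
#' @param pixelPitch pixel pitch, um per pixel.
#' @param nativeWidth,nativeHeight native raster size, px.
#' @param frameRate default frame rate, 1/s.
#' @return a [DeviceProfile-class].
#' @examples
#' deviceProfile("idf-example", pixelPitch = 1.3, nativeWidth = 720,
#'               nativeHeight = 576, frameRate = 25)
#' @export
deviceProfile <- function(name, pixelPitch, nativeWidth = NA_integer_,
                          nativeHeight = NA_integer_, frameRate = 25) {
  new("DeviceProfile", name = as.character(name),
      pixelPitch = as.numeric(pixelPitch),
      nativeWidth = as.integer(nativeWidth),
      nativeHeight = as.integer(nativeHeight),
      frameRate = as.numeric(frameRate))
}

#' Construct an image sequence
#'
#' @param frames list of H x W numeric matrices with values in [0, 255], or
#'   an H x W x T numeric array.
#' @param frameRate frames per second.
#' @param pixelPitch um per pixel.
#' @return an [ImageSequence-class].
#' @export
imageSequence <- function(frames, frameRate, pixelPitch) {
  if (is.array(frames) && length(dim(frames)) == 3L)
    frames <- lapply(seq_len(dim(frames)[3L]), function(t) frames[, , t])
  new("ImageSequence", frames = frames, frameRate = as.numeric(frameRate),
      pixelPitch = as.numeric(pixelPitch))
}

# BT.601 luminance conversion of an H x W x C array in [0, 1] scale
luminance <- function(a) {
  if (length(dim(a)) == 2L) return(a)
  ch <- dim(a)[3L]
  if (ch >= 3L)
    0.299 * a[, , 1L] + 0.587 * a[, , 2L] + 0.114 * a[, , 3L]
  else a[, , 1L]
}

#' Load an image sequence from disk
#'
#' Supported containers: a multi-page TIFF file, a single PNG/TIFF image, or
#' a directory of numbered PNG/TIFF frames (sorted by file name). Color
#' input is converted to grayscale by standard BT.601 luminance weighting;
#' intensities are scaled to [0, 255]. Pixel pitch and frame rate are taken
#' from the device profile.
#'
#' @param path file or directory path.
#' @param profile a [DeviceProfile-class] supplying the unit calibration.
#' @return an [ImageSequence-class].
#' @export
loadSequence <- function(path, profile) {
  stopifnot(is(profile, "DeviceProfile"))
  readOne <- function(f) {
    ext <- tolower(tools::file_ext(f))
    a <- switch(ext,
      png = png::readPNG(f),
      tif = ,
      tiff = tiff::readTIFF(f, all = TRUE),
      stop("unsupported container: .", ext,
           " (supported: multi-page TIFF, PNG, or a directory of them)"))
    if (!is.list(a)) a <- list(a)
    lapply(a, function(x) round(luminance(x) * GMAX))
  }
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (!length(files)) stop("empty sequence: no frames found in ", path)
    fr <- unlist(lapply(sort(files), readOne), recursive = FALSE)
  } else {
    if (!file.exists(path)) stop("path does not exist: ", path)
    fr <- readOne(path)
  }
  if (!length(fr)) stop("empty sequence")
  d <- dim(fr[[1L]])
  if (!all(vapply(fr, function(f) identical(dim(f), d), logical(1))))
    stop("inconsistent frame size")
  imageSequence(fr, frameRate = profile@frameRate,
                pixelPitch = profile@pixelPitch)
}

#' Write an image sequence losslessly
#'
#' Frames (rounded to 8-bit) are written either as one multi-page TIFF
#' (path ending in .tif/.tiff) or as a numbered PNG stack into a directory.
#' Both paths are lossless: reloading reproduces the frames bit-identically.
#'
#' @param seq an [ImageSequence-class].
#' @param path output file (.tif/.tiff) or directory (PNG stack).
#' @return `path`, invisibly.
#' @export
writeSequence <- function(seq, path) {
  fr <- lapply(frames(seq), function(f) clampGray(round(f)) / GMAX)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(fr, path, bits.per.sample = 8L, compression = "deflate")
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(fr))
      png::writePNG(fr[[i]], file.path(path, sprintf("frame_%05d.png", i)))
  }
  invisible(path)
}

#' Image-quality gate on the Massey score
#'
#' HVM image sequences are judged analyzable when the operator-supplied
#' Massey quality score is below 10. The score itself is an input (automated
#' quality scoring is out of scope).
#'
#' @param masseyScore non-negative quality score.
#' @return "accept" if the score is < 10, otherwise "reject".
#' @examples
#' qualityGate(9)   # accept
#' qualityGate(10)  # reject
#' @export
qualityGate <- function(masseyScore) {
  stopifnot(length(masseyScore) == 1L, is.finite(masseyScore))
  if (masseyScore < 0) stop("Massey score must be non-negative")
  if (masseyScore < 10) "accept" else "reject"
}

#' Tabulate vessels, paths and field metrics
#'
#' Flatten analysis results into the three per-entity tables (one row per
#' field of view / vessel / RBC path) with units as reported: densities in
#' mm mm^-2, velocities in um/s, lengths and diameters in um.
#'
#' @param metrics a [FieldMetrics-class].
#' @param vessels list of [VesselSegment-class].
#' @param paths list of [RBCPath-class].
#' @return a `data.frame`.
#' @export
fieldTable <- function(metrics) {
  data.frame(
    tvd_mm_per_mm2 = metrics@tvd, fcd_mm_per_mm2 = metrics@fcd,
    ppv = metrics@ppv, field_rbcv_um_per_s = metrics@rbcv,
    fov_area_mm2 = metrics@fovArea, n_capillaries = metrics@nCapillaries,
    n_venules = metrics@nVenules, n_rbc_paths = metrics@nPaths)
}

#' @rdname fieldTable
#' @export
vesselTable <- function(vessels) {
  if (!length(vessels))
    return(data.frame(vessel_id = integer(), vessel_type = character(),
                      length_um = numeric(), mean_diameter_um = numeric(),
                      rbcv_um_per_s = numeric(), v_max_um_per_s = numeric(),
                      perfusion = character()))
  do.call(rbind, lapply(vessels, function(v) data.frame(
    vessel_id = v@id, vessel_type = v@vesselType, length_um = v@lengthUm,
    mean_diameter_um = v@meanDiameterUm, rbcv_um_per_s = v@rbcv,
    v_max_um_per_s = v@vmax, perfusion = v@perfusion)))
}

#' @rdname fieldTable
#' @export
pathTable <- function(paths) {
  if (!length(paths))
    return(data.frame(vessel_id = integer(), path_id = integer(),
                      velocity_um_per_s = numeric(),
                      curvature_index = numeric(), path_type = character(),
                      n_points = integer()))
  do.call(rbind, lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    data.frame(vessel_id = p@vesselId, path_id = i,
               velocity_um_per_s = p@velocity,
               curvature_index = p@curvatureIndex, path_type = p@pathType,
               n_points = nrow(p@points))
  }))
}

#' Write the three result files
#'
#' Writes `field.csv`, `vessels.csv` and `paths.csv` (comma-separated,
#' header row, UTF-8, "." decimal) into `outDir`, plus optionally the
#' stabilized sequence (lossless multi-page TIFF) and a vessel-overlay PNG.
#'
#' @param metrics a [FieldMetrics-class].
#' @param vessels list of [VesselSegment-class].
#' @param paths list of [RBCPath-class].
#' @param outDir output directory (created if missing).
#' @param stabilized optional [ImageSequence-class] written losslessly to
#'   `stabilized.tif`.
#' @param meanImage optional mean image on which a vessel overlay
#'   (`overlay.png`) is drawn.
#' @return named character vector of the files written, invisibly.
#' @export
writeOutputs <- function(metrics, vessels, paths, outDir,
                         stabilized = NULL, meanImage = NULL) {
  ok <- dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("unwritable output directory: ", outDir)
  files <- c(field = file.path(outDir, "field.csv"),
             vessels = file.path(outDir, "vessels.csv"),
             paths = file.path(outDir, "paths.csv"))
  utils::write.csv(fieldTable(metrics), files["field"], row.names = FALSE)
  utils::write.csv(vesselTable(vessels), files["vessels"], row.names = FALSE)
  utils::write.csv(pathTable(paths), files["paths"], row.names = FALSE)
  if (!is.null(stabilized)) {
    f <- file.path(outDir, "stabilized.tif")
    writeSequence(stabilized, f)
    files <- c(files, stabilized = f)
  }
  if (!is.null(meanImage)) {
    f <- file.path(outDir, "overlay.png")
    writeVesselOverlay(meanImage, vessels, f)
    files <- c(files, overlay = f)
  }
  invisible(files)
}

#' Render a vessel-centerline overlay image
#'
#' Draws detected centerlines on top of the (grayscale) mean image:
#' capillaries in red, venules in blue.
#'
#' @param meanImage numeric matrix in [0, 255].
#' @param vessels list of [VesselSegment-class].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
writeVesselOverlay <- function(meanImage, vessels, path) {
  g <- clampGray(meanImage) / GMAX
  rgb <- array(rep(g, 3L), dim = c(nrow(g), ncol(g), 3L))
  for (v in vessels) {
    idx <- round(v@centerline) + 1L
    keep <- idx[, 1L] >= 1 & idx[, 1L] <= nrow(g) &
      idx[, 2L] >= 1 & idx[, 2L] <= ncol(g)
    idx <- idx[keep, , drop = FALSE]
    col <- if (v@vesselType == "capillary") c(1, 0.1, 0.1) else c(0.2, 0.3, 1)
    for (ch in 1:3)
      rgb[cbind(idx, ch)] <- col[ch]
  }
  png::writePNG(rgb, path)
  invisible(path)
}

#' Render a space-time diagram with detected paths
#'
#' @param std a [SpaceTimeDiagram-class].
#' @param paths list of [RBCPath-class] for this vessel.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
writeDiagramOverlay <- function(std, paths, path) {
  g <- clampGray(std@matrix) / GMAX
  rgb <- array(rep(g, 3L), dim = c(nrow(g), ncol(g), 3L))
  for (p in paths) {
    idx <- round(p@points) + 1L  # (space, time) -> (row, col)
    keep <- idx[, 1L] >= 1 & idx[, 1L] <= nrow(g) &
      idx[, 2L] >= 1 & idx[, 2L] <= ncol(g)
    idx <- idx[keep, , drop = FALSE]
    col <- switch(p@pathType, artifact = c(1, 0.8, 0.1),
                  no_low_flow = c(0.2, 0.4, 1), c(0.1, 1, 0.2))
    for (ch in 1:3) rgb[cbind(idx, ch)] <- col[ch]
  }
  png::writePNG(rgb, path)
  invisible(path)
}
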