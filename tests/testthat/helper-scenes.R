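# Shared fixture builders. All scenes are generated in code at test time;
# seeds are fixed so the suite is reproducible.

SCENE_SEED <- 42L

# single gently curved capillary, archetype geometry
oneVesselScene <- function(velocity, pattern = NULL, spacing = 18,
                           cellLen = 7, nFrames = 120L, noiseSd = 2,
                           seed = SCENE_SEED) {
  cp <- hvmflow:::.curvedControl(30, 20, 130, 140, bow = 8)
  sceneSpec(160, 160, nFrames, frameRate = 60, pixelPitch = 1,
            vessels = list(sceneVessel(cp, diameterUm = 8,
                                       velocity = velocity,
                                       spacingUm = spacing, contrast = 75,
                                       cellLengthUm = cellLen,
                                       pattern = pattern)),
            noiseSd = noiseSd, seed = seed)
}

# static textured scene without vessels (stabilization fixtures)
staticScene <- function(nFrames = 8L, size = 128L, noiseSd = 0,
                        jitter = 0, seed = SCENE_SEED) {
  sceneSpec(size, size, nFrames, frameRate = 25, pixelPitch = 1,
            vessels = list(), noiseSd = noiseSd, flickerAmplitude = 0,
            jitterAmplitude = jitter, textureAmplitude = 10, seed = seed)
}

# run the velocimetry stages on the true centerline of vessel i
velocimetryOnTruth <- function(scene, params = hvmParams(), i = 1L) {
  v <- vesselFromTruth(scene$truth, i = i,
                       frameRate = frameRate(scene$sequence))
  enh <- enhanceFrames(scene$sequence, params$enhance_sigma)
  std <- buildSpaceTimeDiagram(enh, v)
  paths <- detectRBCPaths(std, params)
  paths <- classifyPaths(paths, v@vmax, params$min_path_length,
                         params$curvature_index_cutoff,
                         params$low_flow_cutoff)
  resolveSlowPaths(paths, params$low_flow_cutoff, params$perfusion_fraction)
}

# minimal hand-built vessel segment
makeVessel <- function(id, lengthUm, type = "capillary", rbcv = NA_real_,
                       perfusion = NA_character_, diameterUm = 8) {
  n <- max(2L, ceiling(lengthUm / 5))
  cl <- cbind(seq(0, lengthUm, length.out = n), rep(id * 10, n))
  new("VesselSegment", id = as.integer(id), centerline = cl,
      normalAngle = rep(0, n), widthPx = rep(diameterUm, n),
      lengthUm = lengthUm, meanDiameterUm = diameterUm,
      vesselType = type, rbcv = rbcv, vmax = NA_real_,
      perfusion = perfusion)
}

# minimal hand-built RBC path
makePath <- function(velocity, type = "raw", n = 20L, ci = 1) {
  pts <- cbind(seq(0, by = max(velocity, 1) / 60, length.out = n), 0:(n - 1L))
  p <- new("RBCPath", points = pts, velocity = velocity,
           curvatureIndex = ci, pathType = type, vesselId = 1L)
  p
}

# line-point table for linking tests
makeLinePoints <- function(row, col, angle, response = 1, strong = TRUE,
                           width = 4) {
  data.frame(row = row, col = col, angle = angle,
             response = rep_len(response, length(row)),
             strong = rep_len(strong, length(row)),
             width = rep_len(width, length(row)))
}

# independent global histogram-equalization oracle (definition: s' = G * cdf(s))
globalEqOracle <- function(img, gmax = 255) {
  s <- pmin(pmax(round(img), 0), gmax)
  h <- tabulate(s + 1L, nbins = gmax + 1L)
  cdf <- cumsum(h) / length(s)
  matrix((gmax * cdf)[s + 1L], nrow(img), ncol(img))
}
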