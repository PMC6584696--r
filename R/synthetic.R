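#' Describe one synthetic vessel
#'
#' A tube is defined by centerline control points (interpolated by a smooth
#' natural spline), a diameter (the full width at half maximum of the dark
#' cross-profile), a red blood cell velocity (0 for a stationary cell
#' column), the cell spacing (center-to-center, producing plasma gaps
#' between cells), the cell contrast in gray levels, and an optional
#' per-frame on/off intermittency pattern. Narrow vessels (capillaries) are
#' rendered as individual moving cells; vessels wider than 20 um are
#' rendered as a continuously filled dark column with sparse moving texture
#' cells, emulating the packed red cell column of a venule.
#'
#' @param controlPoints n x 2 matrix of (row, col) control points, px.
#' @param diameterUm tube diameter (cross-profile FWHM), um.
#' @param velocity cell velocity along the tube, um/s (>= 0).
#' @param spacingUm cell center-to-center spacing, um.
#' @param contrast cell darkening, gray levels.
#' @param cellLengthUm cell extent along the flow direction, um (red blood
#'   cell scale, about 7 um).
#' @param pattern optional numeric/logical vector of per-frame on/off flow
#'   states (recycled to the frame count); `NULL` means always on.
#' @return a list understood by [sceneSpec()].
#' @export
sceneVessel <- function(controlPoints, diameterUm, velocity, spacingUm = 15,
                        contrast = 70, cellLengthUm = 7, pattern = NULL) {
  stopifnot(ncol(controlPoints) == 2L, nrow(controlPoints) >= 2L,
            diameterUm > 0, velocity >= 0, spacingUm > 0, contrast > 0)
  if (spacingUm < cellLengthUm)
    stop("cell spacing must not be smaller than the cell size")
  list(controlPoints = controlPoints, diameterUm = diameterUm,
       velocity = velocity, spacingUm = spacingUm, contrast = contrast,
       cellLengthUm = cellLengthUm, pattern = pattern)
}

#' Construct a synthetic scene specification
#'
#' @param width,height raster size, px.
#' @param nFrames number of frames.
#' @param frameRate frames per second.
#' @param pixelPitch um per pixel.
#' @param backgroundLevel bright tissue background gray level.
#' @param vessels list of [sceneVessel()] descriptions.
#' @param noiseSd additive Gaussian sensor noise SD, gray levels.
#' @param flickerAmplitude global per-frame brightness flicker amplitude
#'   (offsets drawn uniformly in +/- amplitude), gray levels.
#' @param jitterAmplitude translational jitter amplitude (per-frame shifts
#'   drawn uniformly in +/- amplitude), px.
#' @param textureAmplitude static smooth tissue-texture amplitude, gray
#'   levels (gives the stabilizer trackable structure).
#' @param seed integer seed; rendering is deterministic given the seed.
#' @return a [SceneSpec-class].
#' @export
sceneSpec <- function(width, height, nFrames, frameRate = 25,
                      pixelPitch = 1.0, backgroundLevel = 190,
                      vessels = list(), noiseSd = 0, flickerAmplitude = 0,
                      jitterAmplitude = 0, textureAmplitude = 8,
                      seed = 1L) {
  new("SceneSpec", width = as.integer(width), height = as.integer(height),
      nFrames = as.integer(nFrames), frameRate = as.numeric(frameRate),
      pixelPitch = as.numeric(pixelPitch),
      backgroundLevel = as.numeric(backgroundLevel), vessels = vessels,
      noiseSd = as.numeric(noiseSd),
      flickerAmplitude = as.numeric(flickerAmplitude),
      jitterAmplitude = as.numeric(jitterAmplitude),
      textureAmplitude = as.numeric(textureAmplitude),
      seed = as.integer(seed))
}

# Dense arclength-parametrized centerline (0.5 px steps) from control
# points: natural splines over the chord-length parameter.
.denseCenterline <- function(cp) {
  d <- sqrt(diff(cp[, 1L])^2 + diff(cp[, 2L])^2)
  s <- c(0, cumsum(d))
  fr <- stats::splinefun(s, cp[, 1L], method = "natural")
  fc <- stats::splinefun(s, cp[, 2L], method = "natural")
  tfine <- seq(0, s[length(s)], by = 0.25)
  pr <- fr(tfine); pc <- fc(tfine)
  seg <- sqrt(diff(pr)^2 + diff(pc)^2)
  arc <- c(0, cumsum(seg))
  L <- arc[length(arc)]
  si <- seq(0, L, by = 0.5)
  r <- stats::approx(arc, pr, xout = si)$y
  c <- stats::approx(arc, pc, xout = si)$y
  tr <- c(diff(r), utils::tail(diff(r), 1L)) / 0.5
  tc <- c(diff(c), utils::tail(diff(c), 1L)) / 0.5
  nn <- sqrt(tr^2 + tc^2)
  list(s = si, row = r, col = c, tr = tr / nn, tc = tc / nn, length = L)
}

# subtract an anisotropic Gaussian cell footprint from `img` in place
.stampCell <- function(img, r0, c0, tr, tc, sa, sp, contrast) {
  h <- ceiling(3 * max(sa, sp))
  rs <- max(1L, floor(r0) - h):min(nrow(img), ceiling(r0) + h)
  cs <- max(1L, floor(c0) - h):min(ncol(img), ceiling(c0) + h)
  if (!length(rs) || !length(cs)) return(img)
  dr <- rs - 1 - r0; dc <- cs - 1 - c0
  U <- outer(dr, dc, function(a, b) a * tr + b * tc)
  W <- outer(dr, dc, function(a, b) -a * tc + b * tr)
  img[rs, cs] <- img[rs, cs] - contrast * exp(-(U^2 / (2 * sa^2) +
                                                W^2 / (2 * sp^2)))
  img
}

# Gaussian cross-profile tube membership over the minimum distance to the
# (subsampled) centerline; returns the affected window and the profile
.tubeProfile <- function(dims, cl, sp) {
  h <- ceiling(3 * sp)
  rs <- max(1L, floor(min(cl$row)) - h):min(dims[1L], ceiling(max(cl$row)) + h)
  cs <- max(1L, floor(min(cl$col)) - h):min(dims[2L], ceiling(max(cl$col)) + h)
  sub <- seq(1L, length(cl$row), by = 4L)  # 2 px steps along the centerline
  pr <- cl$row[sub]; pc <- cl$col[sub]
  dmin2 <- matrix(Inf, length(rs), length(cs))
  rg <- rs - 1; cg <- cs - 1
  for (k in seq_along(pr))
    dmin2 <- pmin(dmin2, outer((rg - pr[k])^2, (cg - pc[k])^2, `+`))
  list(rows = rs, cols = cs, profile = exp(-dmin2 / (2 * sp^2)))
}

#' Render a synthetic HVM scene
#'
#' Composites dark Gaussian-profile red blood cells advected along smooth
#' spline centerlines at the specified velocities (with plasma gaps set by
#' the cell spacing) onto a bright background with a static smooth tissue
#' texture; adds global per-frame brightness flicker, per-frame
#' translational jitter, and finally additive Gaussian sensor noise.
#' Output is identical for identical seeds.
#'
#' @param spec a [SceneSpec-class].
#' @return list with `sequence` (an [ImageSequence-class]) and `truth`
#'   (a [GroundTruth-class]).
#' @export
renderScene <- function(spec) {
  set.seed(spec@seed)
  H <- spec@height; W <- spec@width
  nF <- spec@nFrames; f <- spec@frameRate; pitch <- spec@pixelPitch
  pad <- ceiling(spec@jitterAmplitude) + 2L

  # static background: bright tissue + smooth texture (+ wide-vessel tubes),
  # rendered padded so jitter can sample shifted windows
  static <- matrix(spec@backgroundLevel, H + 2L * pad, W + 2L * pad)
  if (spec@textureAmplitude > 0) {
    tx <- matrix(stats::rnorm((H + 2L * pad) * (W + 2L * pad)),
                 H + 2L * pad, W + 2L * pad)
    tx <- gaussSmooth(tx, 2.5)
    static <- static + spec@textureAmplitude * tx / stats::sd(tx)
  }

  vinfo <- vector("list", length(spec@vessels))
  for (i in seq_along(spec@vessels)) {
    v <- spec@vessels[[i]]
    cl <- .denseCenterline(v$controlPoints)
    margin <- 3 * (v$diameterUm / pitch) / 2.355 + 1
    if (any(cl$row < margin | cl$row > H - 1 - margin |
            cl$col < margin | cl$col > W - 1 - margin))
      stop("vessel ", i, " outside frame")
    sp <- (v$diameterUm / pitch) / 2.355      # FWHM -> sigma, px
    sa <- (v$cellLengthUm / pitch) / 2.355
    lengthUm <- cl$length * pitch
    wide <- v$diameterUm > 20
    clPad <- list(row = cl$row + pad, col = cl$col + pad)
    tp <- .tubeProfile(dim(static), clPad, sp)
    # the plasma-filled lumen homogenizes the optical path: damp the
    # background texture under the tube
    win <- static[tp$rows, tp$cols]
    win <- spec@backgroundLevel + (win - spec@backgroundLevel) *
      (1 - 0.85 * tp$profile)
    if (wide) win <- win - v$contrast * tp$profile
    static[tp$rows, tp$cols] <- win
    mask <- if (is.null(v$pattern)) rep(1, nF)
      else rep(as.numeric(v$pattern), length.out = nF)
    # extend the centerline beyond both ends (cells slide smoothly in and
    # out of the segment instead of appearing abruptly at the wrap point);
    # the cell train lives on the extended loop, so the cell count uses the
    # extended length to honor the nominal spacing
    extPx <- ceiling(3 * sa)
    ne <- 2L * extPx  # 0.5 px steps
    t0 <- c(cl$tr[1L], cl$tc[1L]); t1 <- c(cl$tr[length(cl$tr)], cl$tc[length(cl$tc)])
    pre <- seq(ne, 1L)
    post <- seq_len(ne)
    clx <- list(
      row = c(cl$row[1L] - pre * 0.5 * t0[1L], cl$row,
              cl$row[length(cl$row)] + post * 0.5 * t1[1L]),
      col = c(cl$col[1L] - pre * 0.5 * t0[2L], cl$col,
              cl$col[length(cl$col)] + post * 0.5 * t1[2L]),
      tr = c(rep(t0[1L], ne), cl$tr, rep(t1[1L], ne)),
      tc = c(rep(t0[2L], ne), cl$tc, rep(t1[2L], ne)))
    extUm <- extPx * pitch
    spacing <- if (wide) max(v$spacingUm, 20) else v$spacingUm
    loopUm <- lengthUm + 2 * extUm
    nCells <- max(1L, floor(loopUm / spacing))
    phase <- stats::runif(1, 0, spacing)
    # irregular plasma gaps (+/- 40% around the nominal spacing): perfectly
    # regular cell trains would alias stroboscopically at video frame rates
    gaps <- spacing * stats::runif(nCells, 0.6, 1.4)
    offsets <- (cumsum(gaps) - gaps[1L] + phase) %% loopUm
    dutyCum <- c(0, cumsum(mask))[seq_len(nF)]  # on-frames before frame t
    vinfo[[i]] <- list(cl = cl, clx = clx, extUm = extUm, sp = sp, sa = sa,
                       lengthUm = lengthUm, wide = wide, offsets = offsets,
                       dutyCum = dutyCum, mask = mask, v = v,
                       contrast = if (wide) 0.35 * v$contrast else v$contrast)
  }

  flicker <- if (spec@flickerAmplitude > 0)
    stats::runif(nF, -spec@flickerAmplitude, spec@flickerAmplitude)
  else rep(0, nF)
  jitter <- if (spec@jitterAmplitude > 0)
    cbind(stats::runif(nF, -spec@jitterAmplitude, spec@jitterAmplitude),
          stats::runif(nF, -spec@jitterAmplitude, spec@jitterAmplitude))
  else matrix(0, nF, 2L)
  jitter[1L, ] <- 0  # frame 1 is the reference

  fr <- vector("list", nF)
  rows <- seq_len(H) + pad; cols <- seq_len(W) + pad
  for (t in seq_len(nF)) {
    # content shifted by jitter[t,]: sample the static field at x - j
    if (any(jitter[t, ] != 0)) {
      rg <- rep(rows - 1 - jitter[t, 1L], times = W)
      cg <- rep(cols - 1 - jitter[t, 2L], each = H)
      img <- matrix(cpp_bilinear(static, rg, cg), H, W)
    } else {
      img <- static[rows, cols]
    }
    for (vi in vinfo) {
      # cell coordinate lives on the extended path [0, L + 2 ext)
      Lext <- vi$lengthUm + 2 * vi$extUm
      posUm <- (vi$offsets + vi$v$velocity * vi$dutyCum[t] / f) %% Lext
      posPx <- posUm / pitch
      idx <- pmin(length(vi$clx$row), pmax(1L, round(posPx / 0.5) + 1L))
      for (k in seq_along(idx)) {
        ii <- idx[k]
        img <- .stampCell(img, vi$clx$row[ii] + jitter[t, 1L],
                          vi$clx$col[ii] + jitter[t, 2L],
                          vi$clx$tr[ii], vi$clx$tc[ii],
                          vi$sa, vi$sp, vi$contrast)
      }
    }
    img <- img + flicker[t]
    if (spec@noiseSd > 0)
      img <- img + matrix(stats::rnorm(H * W, 0, spec@noiseSd), H, W)
    fr[[t]] <- clampGray(img)
  }

  seq <- imageSequence(fr, frameRate = f, pixelPitch = pitch)
  truthVessels <- lapply(seq_along(vinfo), function(i) {
    vi <- vinfo[[i]]
    duty <- mean(vi$mask)
    meanV <- vi$v$velocity * duty
    list(id = i, centerline = cbind(vi$cl$row, vi$cl$col),
         lengthUm = vi$lengthUm, diameterUm = vi$v$diameterUm,
         velocity = vi$v$velocity, meanVelocity = meanV, duty = duty,
         type = if (vi$wide) "venule" else "capillary",
         # a vessel counts perfused when it carries flowing cells at all;
         # only fully stalled (or sub-cutoff) vessels are non-perfused
         perfused = vi$v$velocity >= 25 && duty > 0.05)
  })
  area <- fovArea(seq)
  caps <- Filter(function(v) v$type == "capillary", truthVessels)
  capLen <- vapply(caps, `[[`, numeric(1), "lengthUm")
  perf <- vapply(caps, `[[`, logical(1), "perfused")
  vel <- vapply(caps, `[[`, numeric(1), "meanVelocity")
  tvd <- sum(capLen) / 1000 / area
  fcd <- sum(capLen[perf]) / 1000 / area
  truth <- new("GroundTruth", vessels = truthVessels, jitter = jitter,
               metrics = list(tvd = tvd, fcd = fcd,
                              ppv = if (tvd > 0) fcd / tvd else 0,
                              rbcv = if (length(capLen))
                                sum(capLen * vel) / sum(capLen) else NA_real_,
                              fovArea = area))
  list(sequence = seq, truth = truth)
}

# gently curved centerline between two endpoints with a sinusoidal bow
.curvedControl <- function(r0, c0, r1, c1, bow = 6, n = 7L) {
  tt <- seq(0, 1, length.out = n)
  r <- r0 + tt * (r1 - r0)
  c <- c0 + tt * (c1 - c0)
  len <- sqrt((r1 - r0)^2 + (c1 - c0)^2)
  nr <- -(c1 - c0) / len; ncl <- (r1 - r0) / len
  off <- bow * sin(pi * tt)
  cbind(r + off * nr, c + off * ncl)
}

#' Reference suite of synthetic scenes
#'
#' Six scenes with analytic expectations covering the canonical flow
#' archetypes seen in space-time diagrams — normal flow, "hyperdynamic"
#' fast flow near the measurable maximum, intermittent flow, and no flow
#' (the barcode sign) — plus a multi-vessel density scene (mixed
#' capillaries and one venule) and a stress scene combining flicker,
#' jitter and sensor noise.
#'
#' @param seed integer seed forwarded to every scene.
#' @return named list of entries, each with `spec` (a [SceneSpec-class])
#'   and `expect` (a list of analytic expectations, including the expected
#'   per-vessel perfusion labels for the archetypes).
#' @export
defaultSuite <- function(seed = 1L) {
  seed <- as.integer(seed)
  arche <- function(v, pattern = NULL, nm, expPerf, cellLen = 7,
                    spacing = 18, nFrames = 120L) {
    cp <- .curvedControl(30, 20, 130, 140, bow = 8)
    sp <- sceneSpec(160, 160, nFrames, frameRate = 60, pixelPitch = 1,
                    vessels = list(sceneVessel(cp, diameterUm = 8,
                                               velocity = v,
                                               spacingUm = spacing,
                                               contrast = 75,
                                               cellLengthUm = cellLen,
                                               pattern = pattern)),
                    noiseSd = 2, seed = seed)
    list(name = nm, spec = sp, expect = list(perfusion = expPerf))
  }
  # vessel arclength ~ 157 px -> vmax ~ 3140 um/s at 60 fps; the
  # hyperdynamic scene uses long cell trains with long plasma gaps, the
  # pattern actually observable at such speeds
  suite <- list(
    normal_flow = arche(300, NULL, "normal_flow", "perfused"),
    hyperdynamic = arche(800, NULL, "hyperdynamic", "perfused",
                         cellLen = 25, spacing = 60),
    # flow stalls for a full second at a time, as in septic intermittence;
    # flowing episodes dominate the resolved path population, so the
    # distribution rule reports the vessel perfused
    intermittent = arche(300, rep(c(1, 0), each = 60), "intermittent",
                         "perfused", nFrames = 240L),
    no_flow = arche(0, NULL, "no_flow", "non_perfused", spacing = 9)
  )

  caps <- list(
    sceneVessel(.curvedControl(60, 40, 90, 460, bow = 14), 8, 400,
                spacingUm = 16, contrast = 75),
    sceneVessel(.curvedControl(140, 30, 120, 430, bow = -10), 12, 250,
                spacingUm = 18, contrast = 70),
    sceneVessel(.curvedControl(240, 60, 200, 470, bow = 8), 6, 600,
                spacingUm = 15, contrast = 70),
    sceneVessel(.curvedControl(300, 40, 340, 450, bow = -12), 10, 150,
                spacingUm = 17, contrast = 75),
    sceneVessel(.curvedControl(420, 50, 380, 420, bow = 10), 8, 0,
                spacingUm = 10, contrast = 75, cellLengthUm = 7),
    sceneVessel(.curvedControl(470, 120, 440, 480, bow = -6), 14, 350,
                spacingUm = 20, contrast = 70)
  )
  ven <- sceneVessel(cbind(c(60, 160, 280, 380, 450), c(85, 110, 120, 110, 90)),
                     diameterUm = 55, velocity = 500, spacingUm = 30,
                     contrast = 80)
  density <- sceneSpec(512, 512, 100, frameRate = 60, pixelPitch = 1.3,
                       vessels = c(caps, list(ven)), noiseSd = 0,
                       seed = seed)
  suite$density <- list(name = "density", spec = density,
                        expect = list(nCapillaries = 6L, nVenules = 1L))
  noisy <- density
  noisy@noiseSd <- 6
  suite$density_noisy <- list(name = "density_noisy", spec = noisy,
                              expect = list(nCapillaries = 6L, nVenules = 1L))

  stress <- sceneSpec(256, 256, 50, frameRate = 60, pixelPitch = 1,
                      vessels = list(
                        sceneVessel(.curvedControl(60, 40, 200, 210, bow = 10),
                                    9, 350, spacingUm = 16, contrast = 75)),
                      noiseSd = 6, flickerAmplitude = 12,
                      jitterAmplitude = 2, seed = seed)
  suite$stress <- list(name = "stress", spec = stress,
                       expect = list(perfusion = "perfused"))
  suite
}

#' Build a vessel segment from ground truth
#'
#' Constructs a [VesselSegment-class] directly from a rendered scene's
#' ground truth, the synthetic analog of a manually drawn centerline. Used
#' to validate the velocimetry stages in isolation from vessel detection.
#'
#' @param truth a [GroundTruth-class].
#' @param i vessel index.
#' @param frameRate frame rate used for the v_max bound, 1/s.
#' @return a [VesselSegment-class].
#' @export
vesselFromTruth <- function(truth, i = 1L, frameRate = 60) {
  tv <- truth@vessels[[i]]
  cl <- tv$centerline
  new("VesselSegment", id = as.integer(i), centerline = cl,
      normalAngle = rep(0, nrow(cl)),
      widthPx = rep(tv$diameterUm, nrow(cl)), lengthUm = tv$lengthUm,
      meanDiameterUm = tv$diameterUm,
      vesselType = if (tv$type == "venule") "venule" else "capillary",
      rbcv = NA_real_, vmax = computeVmax(tv$lengthUm, frameRate),
      perfusion = NA_character_)
}

#' Velocity-sweep validation scene
#'
#' A short capillary (about 45 px) observed at 60 frames/s, carrying cells
#' at a chosen fraction of the vessel's maximum measurable velocity
#' v_max = l f / 3. Cell length and plasma-gap spacing grow with the
#' expected band slope so that the moving pattern remains resolvable at
#' the video sampling rate (per-frame displacement below the cell extent,
#' and inter-cell gaps that do not collapse under slope compression in the
#' space-time diagram).
#'
#' @param frac injected velocity as a fraction of v_max (may exceed 1 to
#'   probe the artifact rule).
#' @param seed scene seed.
#' @param nFrames number of frames.
#' @return a [SceneSpec-class].
#' @export
velocitySweepScene <- function(frac, seed = 1L, nFrames = 300L) {
  cp <- cbind(seq(55, 87, length.out = 4), seq(60, 92, length.out = 4))
  lenPx <- 32 * sqrt(2)                      # ~45.25 px straight vessel
  slope <- frac * lenPx / 3                  # expected band slope, px/frame
  spacing <- max(18, 7 * slope)
  cellLen <- max(7, 1.2 * slope)
  sceneSpec(160, 160, nFrames, frameRate = 60, pixelPitch = 1,
            vessels = list(sceneVessel(cp, 8, frac * lenPx * 60 / 3,
                                       spacingUm = spacing, contrast = 75,
                                       cellLengthUm = cellLen)),
            noiseSd = 2, seed = seed)
}
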