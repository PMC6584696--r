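# drawn space-time diagram with a dark band of known slope (px per frame)
drawDiagram <- function(S = 80, T = 60, slope = 4, bandHalf = 1.5,
                        spacing = 20, bg = 200, contrast = 80) {
  m <- matrix(bg, S, T)
  period <- S + 10
  for (t in seq_len(T)) {
    centers <- unique((slope * (t - 1) + seq(0, period - 1, by = spacing)) %%
                        period)
    for (c0 in centers) {
      # bandHalf is the thickness perpendicular to the sloped band
      d <- (seq_len(S) - 1 - c0) / sqrt(1 + slope^2)
      m[, t] <- m[, t] - contrast * exp(-d^2 / (2 * bandHalf^2))
    }
  }
  pmax(m, 0)
}

test_that("per-frame equalization suppresses global flicker", {
  sc <- renderScene(oneVesselScene(300, nFrames = 20L))
  fr <- frames(sc$sequence)
  flick <- lapply(seq_along(fr), function(i)
    pmin(pmax(fr[[i]] + c(-20, 20)[(i %% 2) + 1], 0), 255))
  seqF <- imageSequence(flick, 60, 1)
  enh <- enhanceFrames(seqF, smoothSigma = 1)
  means <- vapply(frames(enh), mean, numeric(1))
  expect_lt(max(abs(diff(means))), 2)
})

test_that("Gaussian smoothing reduces noise variance by the analytic factor", {
  set.seed(9)
  noise <- matrix(rnorm(300 * 300, 0, 10), 300, 300)
  s <- 3
  sm <- gaussSmooth(noise, s)
  inner <- sm[30:270, 30:270]
  ratio <- stats::var(as.vector(inner)) / 100
  expect_equal(ratio, 1 / (4 * pi * s^2), tolerance = 0.1)
})

test_that("static scenes give horizontally banded diagrams", {
  sc <- renderScene(oneVesselScene(0, spacing = 9, nFrames = 30L, noiseSd = 0))
  v <- vesselFromTruth(sc$truth, frameRate = 60)
  std <- buildSpaceTimeDiagram(enhanceFrames(sc$sequence, 1), v)
  rowSd <- apply(std@matrix, 1, stats::sd)
  expect_lt(median(rowSd), 6)  # rows nearly constant along time
})

test_that("diagram dimensions are centerline arclength by frame count", {
  cl <- cbind(seq(10, 130, length.out = 241), rep(64, 241))  # arclength 120
  v <- new("VesselSegment", id = 1L, centerline = cl,
           normalAngle = rep(0, nrow(cl)), widthPx = rep(6, nrow(cl)),
           lengthUm = 120, meanDiameterUm = 6, vesselType = "capillary",
           rbcv = NA_real_, vmax = NA_real_, perfusion = NA_character_)
  fr <- replicate(100, matrix(128, 160, 160), simplify = FALSE)
  fr <- lapply(fr, function(f) { f[, ] <- runif(length(f), 0, 255); f })
  std <- buildSpaceTimeDiagram(imageSequence(fr, 25, 1), v)
  expect_equal(dim(std@matrix), c(120L, 100L))
})

test_that("a drawn band of known slope is recovered as one velocity", {
  # slope 5 px/frame at 1 um/px and 100 fps = 500 um/s
  m <- drawDiagram(S = 80, T = 60, slope = 5, spacing = 40)
  std <- new("SpaceTimeDiagram", matrix = m, pixelPitch = 1,
             frameRate = 100, vesselId = 1L)
  paths <- detectRBCPaths(std, hvmParams())
  paths <- classifyPaths(paths, vmax = 5000, minPathLength = 10,
                         ciCutoff = 0.8, lowFlowCutoff = 25)
  kept <- Filter(function(p) p@pathType != "artifact", paths)
  expect_gt(length(kept), 0L)
  v <- mean(vapply(kept, function(p) p@velocity, numeric(1)))
  expect_lt(abs(v - 500) / 500, 0.1)
})

test_that("barcode diagrams yield near-zero slopes", {
  m <- drawDiagram(S = 80, T = 60, slope = 0, spacing = 15)
  std <- new("SpaceTimeDiagram", matrix = m, pixelPitch = 1,
             frameRate = 25, vesselId = 1L)
  paths <- detectRBCPaths(std, hvmParams())
  expect_gt(length(paths), 0L)
  vs <- vapply(paths, function(p) p@velocity, numeric(1))
  expect_lt(median(vs, na.rm = TRUE), 5)
})

test_that("path velocity follows the mean first derivative definition", {
  p <- cbind(seq(0, 40, by = 4), 0:10)
  expect_equal(pathVelocity(p, pitch = 1, f = 25), 100)
  # piecewise path: equal halves at 200 and 400 um/s average to 300
  half1 <- cbind(seq(0, 40, by = 8), 0:5)
  half2 <- cbind(seq(40 + 16, 40 + 16 * 5, by = 16), 6:10)
  pw <- rbind(half1, half2)
  expect_equal(pathVelocity(pw, pitch = 1, f = 25), 300)
  # direction does not matter, only the magnitude
  rev <- cbind(seq(40, 0, by = -4), 0:10)
  expect_equal(pathVelocity(rev, 1, 25), 100)
})

test_that("path velocity agrees with a least-squares slope on straight tracks", {
  set.seed(11)
  for (slope in c(0.5, 2, 6)) {
    t <- seq(0, 30, by = 0.5)
    p <- cbind(slope * t + rnorm(length(t), 0, 0.15), t)
    v <- pathVelocity(p, 1, 25)
    ls <- abs(stats::coef(stats::lm(p[, 1] ~ p[, 2]))[2]) * 25
    expect_lt(abs(v - ls) / ls, 0.05)
  }
})

test_that("curvature index matches chord-over-length geometry", {
  straight <- cbind(seq(0, 10), seq(0, 10))
  expect_equal(curvatureIndex(straight), 1)
  th <- seq(0, pi, length.out = 500)
  semi <- cbind(5 * cos(th), 5 * sin(th))
  expect_equal(curvatureIndex(semi), 2 / pi, tolerance = 1e-4)
  loop <- cbind(5 * cos(seq(0, 2 * pi, length.out = 500)),
                5 * sin(seq(0, 2 * pi, length.out = 500)))
  expect_equal(curvatureIndex(loop), 0, tolerance = 1e-6)
  expect_error(curvatureIndex(cbind(c(1, 1), c(2, 2))), "degenerate")
})

test_that("maximum measurable velocity is l*f/3", {
  expect_equal(computeVmax(300, 25), 2500)
  expect_equal(computeVmax(60, 60), 1200)
  expect_equal(computeVmax(0, 25), 0)
  expect_error(computeVmax(-1, 25))
})

test_that("path discard rules fire on length, curvature, vmax and time span", {
  short <- makePath(200, n = 3L)
  expect_equal(classifyPaths(list(short), vmax = 1000)[[1]]@pathType,
               "artifact")
  fast <- makePath(1200, n = 20L)
  expect_equal(classifyPaths(list(fast), vmax = 1000)[[1]]@pathType,
               "artifact")
  bent <- makePath(200, n = 20L, ci = 0.5)
  expect_equal(classifyPaths(list(bent), vmax = 1000)[[1]]@pathType,
               "artifact")
  slow <- makePath(10, n = 20L)
  expect_equal(classifyPaths(list(slow), vmax = 1000,
                             lowFlowCutoff = 25)[[1]]@pathType, "no_low_flow")
  ok <- makePath(200, n = 20L)
  expect_equal(classifyPaths(list(ok), vmax = 1000)[[1]]@pathType,
               "normal_flow")
})

test_that("vessel RBCv is the mean over non-artifact paths", {
  ps <- list(makePath(100, "normal_flow"), makePath(200, "normal_flow"),
             makePath(300, "normal_flow"))
  expect_equal(vesselRBCV(ps), 200)
  expect_equal(vesselRBCV(list(makePath(250, "normal_flow"))), 250)
  arts <- list(makePath(100, "artifact"), makePath(900, "artifact"))
  expect_true(is.na(vesselRBCV(arts)))
  mixed <- c(ps, arts)
  expect_equal(vesselRBCV(mixed), 200)
})

test_that("perfusion classification follows the strict >95% rules", {
  mk <- function(nNormal, nSlow, vFast = 300, vSlow = 5) {
    c(replicate(nNormal, makePath(vFast, "normal_flow"), simplify = FALSE),
      replicate(nSlow, makePath(vSlow, "no_low_flow"), simplify = FALSE))
  }
  expect_equal(classifyPerfusion(mk(100, 0)), "perfused")
  expect_equal(classifyPerfusion(mk(96, 4)), "perfused")
  expect_equal(classifyPerfusion(mk(95, 5)), "non_perfused")
  # barcode rule: a slow majority wins regardless of a fast minority
  expect_equal(classifyPerfusion(mk(4, 96)), "non_perfused")
  expect_equal(classifyPerfusion(list()), "non_perfused")
  expect_equal(classifyPerfusion(list(makePath(1, "artifact"))),
               "non_perfused")
})

test_that("perfusion is monotone in the normal-flow fraction", {
  mk <- function(nNormal, nSlow) {
    c(replicate(nNormal, makePath(300, "normal_flow"), simplify = FALSE),
      replicate(nSlow, makePath(5, "no_low_flow"), simplify = FALSE))
  }
  states <- vapply(0:100, function(k)
    classifyPerfusion(mk(k, 100 - k)), character(1))
  flips <- diff(states == "perfused")
  expect_true(all(flips >= 0))  # never flips back to non_perfused
})

test_that("no reported non-artifact path exceeds its vessel's vmax", {
  for (frac in c(0.5, 1.3)) {
    sc <- renderScene(velocitySweepScene(frac, seed = SCENE_SEED,
                                         nFrames = 150L))
    paths <- velocimetryOnTruth(sc)
    kept <- Filter(function(p) p@pathType != "artifact", paths)
    vmax <- vesselFromTruth(sc$truth, frameRate = 60)@vmax
    if (length(kept))
      expect_true(all(vapply(kept, function(p) p@velocity, numeric(1)) <=
                        vmax))
  }
})

test_that("minority slow paths resolve to artifacts, majority stays barcode", {
  mostlyFast <- c(replicate(18, makePath(300, "normal_flow"), simplify = FALSE),
                  replicate(2, makePath(5, "no_low_flow"), simplify = FALSE))
  r <- resolveSlowPaths(mostlyFast, 25)
  types <- vapply(r, function(p) p@pathType, character(1))
  expect_equal(sum(types == "artifact"), 2L)
  expect_equal(vesselRBCV(r), 300)
  mostlySlow <- c(replicate(1, makePath(300, "normal_flow"), simplify = FALSE),
                  replicate(30, makePath(5, "no_low_flow"), simplify = FALSE))
  r2 <- resolveSlowPaths(mostlySlow, 25)
  expect_equal(sum(vapply(r2, function(p) p@pathType, character(1)) ==
                     "no_low_flow"), 30L)
  expect_equal(classifyPerfusion(r2), "non_perfused")
})
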