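test_that("rendering is deterministic given the seed", {
  spec <- oneVesselScene(300, nFrames = 6L, noiseSd = 3)
  a <- renderScene(spec)
  b <- renderScene(spec)
  expect_identical(frames(a$sequence), frames(b$sequence))
  expect_identical(a$truth@jitter, b$truth@jitter)
  spec2 <- oneVesselScene(300, nFrames = 6L, noiseSd = 3, seed = 43L)
  c <- renderScene(spec2)
  expect_false(identical(frames(a$sequence), frames(c$sequence)))
})

test_that("invalid vessel geometry and cell packing are rejected", {
  out <- sceneVessel(cbind(c(5, 100), c(5, 100)), 8, 100)
  expect_error(renderScene(sceneSpec(60, 60, 2, vessels = list(out))),
               "outside frame")
  expect_error(sceneVessel(cbind(c(10, 50), c(10, 50)), 8, 100,
                           spacingUm = 4, cellLengthUm = 7),
               "spacing")
})

test_that("a static tube's mean-image cross profile has the specified FWHM", {
  cp <- cbind(c(20, 64, 108), c(64, 64, 64))  # vertical straight tube
  spec <- sceneSpec(128, 128, 10, pixelPitch = 1, vessels = list(
    sceneVessel(cp, diameterUm = 4, velocity = 0, spacingUm = 2.6,
                contrast = 80, cellLengthUm = 2.5)),
    noiseSd = 0, textureAmplitude = 0, seed = SCENE_SEED)
  sc <- renderScene(spec)
  mi <- computeMeanImage(sc$sequence)
  prof <- mi[64, ]
  bg <- max(prof)
  depth <- bg - min(prof)
  fine <- stats::approx(seq_along(prof), prof, xout = seq(50, 80, by = 0.01))
  below <- fine$x[fine$y <= bg - depth / 2]
  expect_lt(abs((max(below) - min(below)) - 4), 0.5)
})

test_that("the default suite covers the archetypes with expected labels", {
  suite <- defaultSuite(seed = SCENE_SEED)
  expect_gte(length(suite), 6L)
  expect_true(all(c("normal_flow", "hyperdynamic", "intermittent", "no_flow",
                    "density", "stress") %in% names(suite)))
  expect_equal(suite$normal_flow$expect$perfusion, "perfused")
  expect_equal(suite$hyperdynamic$expect$perfusion, "perfused")
  expect_equal(suite$no_flow$expect$perfusion, "non_perfused")
  expect_equal(suite$intermittent$expect$perfusion, "perfused")
})

test_that("analytic ground-truth metrics equal the metrics-module formulas", {
  sc <- renderScene(defaultSuite(seed = SCENE_SEED)$density$spec)
  tr <- sc$truth
  vs <- lapply(tr@vessels, function(tv)
    makeVessel(tv$id, tv$lengthUm, type = tv$type,
               rbcv = tv$meanVelocity,
               perfusion = if (tv$perfused) "perfused" else "non_perfused",
               diameterUm = tv$diameterUm))
  area <- tr@metrics$fovArea
  expect_equal(totalVesselDensity(vs, area), tr@metrics$tvd)
  r <- functionalCapillaryDensity(vs, area)
  expect_equal(r$fcd, tr@metrics$fcd)
  expect_equal(r$ppv, tr@metrics$ppv)
})

test_that("rendered per-frame displacement matches velocity over pitch*f", {
  spec <- oneVesselScene(300, nFrames = 10L, noiseSd = 0)
  sc <- renderScene(spec)
  cl <- sc$truth@vessels[[1]]$centerline
  fr <- frames(sc$sequence)
  prof <- function(t) hvmflow:::cpp_bilinear(fr[[t]], cl[, 1], cl[, 2])
  # cross-correlate consecutive along-tube profiles over subpixel shifts
  bestShift <- function(a, b) {
    sh <- seq(2, 8, by = 0.1)
    s <- seq_along(a)
    score <- vapply(sh, function(d) {
      bb <- stats::approx(s, b, xout = s - d / 0.5)$y  # centerline step 0.5 px
      ok <- !is.na(bb)
      stats::cor(a[ok], bb[ok])
    }, numeric(1))
    sh[which.max(score)]
  }
  shifts <- vapply(1:5, function(t) bestShift(prof(t + 1), prof(t)), numeric(1))
  expect_lt(abs(median(shifts) - 300 / 60), 0.3)
})

test_that("a zero-velocity vessel ends up non-perfused with a barcode diagram", {
  sc <- renderScene(oneVesselScene(0, spacing = 9, nFrames = 60L))
  res <- analyzeSequence(sc$sequence, stabilize = FALSE)
  main <- res$vessels[[which.max(vapply(res$vessels, vesselLength,
                                        numeric(1)))]]
  expect_equal(perfusion(main), "non_perfused")
  expect_true(is.na(rbcv(main)) || rbcv(main) < 25)
})
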