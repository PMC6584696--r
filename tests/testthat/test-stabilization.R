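smallParams <- hvmParams(stab_max_features = 200L, stab_iterations = 20L,
                         smoothing_window = 5L)

test_that("identical frames give identity transforms", {
  sc <- renderScene(staticScene(nFrames = 4L))
  f <- frames(sc$sequence)[[1]]
  seq <- imageSequence(list(f, f, f, f), 25, 1)
  tr <- estimateTransforms(seq, smallParams)
  expect_lt(max(abs(tr[, 1:2])), 0.01)
  expect_lt(max(abs(tr[, 3])), 1e-3)
  expect_lt(max(abs(tr[, 4] - 1)), 1e-3)
})

test_that("injected translational jitter is recovered to subpixel accuracy", {
  sc <- renderScene(staticScene(nFrames = 12L, size = 160L, noiseSd = 2,
                                jitter = 3))
  tr <- estimateTransforms(sc$sequence, smallParams)
  err <- tr[, 1:2] + sc$truth@jitter  # transform translation = -displacement
  expect_lt(sqrt(mean(err^2)), 0.25)
})

test_that("a one-degree rotation about the frame center is recovered", {
  sc <- renderScene(staticScene(nFrames = 2L, size = 160L))
  f1 <- frames(sc$sequence)[[1]]
  th <- pi / 180
  ctr <- (dim(f1) - 1) / 2
  shift <- ctr - c(cos(th) * ctr[1] - sin(th) * ctr[2],
                   sin(th) * ctr[1] + cos(th) * ctr[2])
  M <- hvmflow:::transformMatrix(hvmflow:::invertTransform(c(shift, th, 1)))
  f2 <- hvmflow:::cpp_warp_similarity(f1, M)
  f2[is.na(f2)] <- mean(f1)
  tr <- estimateTransforms(imageSequence(list(f1, f2), 25, 1), smallParams)
  expect_lt(abs(abs(tr[2, 3]) - th), 0.1 * pi / 180)
})

test_that("trajectory smoothing preserves constant and linear trajectories", {
  n <- 30
  const <- cbind(rep(2, n), rep(-1, n), rep(0.01, n), rep(1, n))
  expect_equal(smoothTrajectory(const, 15L), const)
  lin <- cbind(seq(0, 29), seq(0, -29), seq(0, 0.029, along.with = 1:n),
               rep(1, n))
  sm <- smoothTrajectory(lin, 15L)
  # symmetric (shrinking) windows reproduce a linear ramp exactly
  expect_equal(sm[, 1], lin[, 1], tolerance = 1e-12)
  expect_equal(sm[, 2], lin[, 2], tolerance = 1e-12)
})

test_that("alternating jitter is suppressed below 0.2 px by smoothing", {
  n <- 40
  tr <- cbind(rep(c(1, -1), n / 2), rep(c(-1, 1), n / 2), rep(0, n), rep(1, n))
  sm <- smoothTrajectory(tr, 15L)
  interior <- 8:(n - 7)
  expect_lt(sqrt(mean(sm[interior, 1:2]^2)), 0.2)
})

test_that("windows larger than the sequence are clamped with a warning", {
  tr <- cbind(1:5, 1:5, rep(0, 5), rep(1, 5))
  expect_warning(sm <- smoothTrajectory(tr, 15L), "clamping")
  expect_equal(nrow(sm), 5L)
  expect_error(smoothTrajectory(tr, 4L))  # even window rejected
})

test_that("warping crops to the common valid region", {
  sc <- renderScene(staticScene(nFrames = 3L, size = 64L))
  seq <- sc$sequence
  id <- matrix(rep(c(0, 0, 0, 1), each = 3), 3, 4)
  out <- applyAndCrop(seq, id)
  expect_equal(dim(out), dim(seq))
  expect_equal(frames(out), frames(seq))
  # +/-2 px shifts shrink each dimension by at least 4 px
  corr <- rbind(c(0, 0, 0, 1), c(2, 2, 0, 1), c(-2, -2, 0, 1))
  out2 <- applyAndCrop(seq, corr)
  expect_lte(dim(out2)[1], 64 - 4)
  expect_lte(dim(out2)[2], 64 - 4)
  expect_equal(fovArea(out2), prod(dim(out2)) * 1e-6)
  # excessive motion empties the intersection
  far <- rbind(c(0, 0, 0, 1), c(40, 0, 0, 1), c(-40, 0, 0, 1))
  expect_error(applyAndCrop(seq, far), "excessive motion")
})

test_that("stabilizing an already stable sequence is a near no-op", {
  sc <- renderScene(staticScene(nFrames = 6L, size = 128L, noiseSd = 2))
  st <- stabilizeSequence(sc$sequence, smallParams)
  tr2 <- estimateTransforms(st$sequence, smallParams)
  expect_lt(max(abs(tr2[, 1:2])), 0.1)
})

test_that("stabilization reduces temporal variance of a jittered static scene", {
  clean <- renderScene(staticScene(nFrames = 10L, size = 128L, noiseSd = 3,
                                   jitter = 0))
  jit <- renderScene(staticScene(nFrames = 10L, size = 128L, noiseSd = 3,
                                 jitter = 2))
  st <- stabilizeSequence(jit$sequence, smallParams)
  tvar <- function(seq, crop = 10) {
    fr <- frames(seq)
    d <- dim(fr[[1]])
    a <- simplify2array(lapply(fr, function(f)
      f[crop:(d[1] - crop), crop:(d[2] - crop)]))
    mean(apply(a, c(1, 2), stats::var))
  }
  expect_lte(tvar(st$sequence), 1.1 * tvar(clean$sequence))
})
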