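# dark line with Gaussian cross-profile at subpixel row r0 (horizontal)
gaussLineImage <- function(nr = 64, nc = 200, r0 = 30.3, widthPx = 4,
                           contrast = 80, bg = 200) {
  sp <- widthPx / 2.355  # width is the profile FWHM
  d <- outer(seq_len(nr) - 1 - r0, rep(1, nc))
  bg - contrast * exp(-d^2 / (2 * sp^2))
}

test_that("uniform images contain no line points", {
  pts <- stegerDetect(matrix(128, 64, 64), sigma = 2, highThresh = 0.02,
                      lowThresh = 0.01)
  expect_equal(nrow(pts), 0L)
})

test_that("a dark Gaussian line is localized to subpixel accuracy", {
  img <- gaussLineImage(r0 = 30.3, widthPx = 4)
  sigma <- 4 / sqrt(3)  # matched scale for a 4 px line
  pts <- stegerDetect(img, sigma, highThresh = 0.05, lowThresh = 0.02)
  expect_gt(nrow(pts), 100)
  expect_lt(max(abs(pts$row - 30.3)), 0.3)
  # normal direction is vertical (angle 0 mod pi) for a horizontal line
  ang <- pmin(pts$angle, pi - pts$angle)
  expect_lt(max(ang), 0.05)
})

test_that("estimated line width is within 20% of the true width", {
  img <- gaussLineImage(r0 = 30.3, widthPx = 4)
  pts <- stegerDetect(img, 4 / sqrt(3), highThresh = 0.05, lowThresh = 0.02)
  expect_lt(abs(median(pts$width) - 4) / 4, 0.2)
  # and for a wider line at its matched scale
  img2 <- gaussLineImage(r0 = 30.3, widthPx = 8)
  pts2 <- stegerDetect(img2, 8 / sqrt(3), highThresh = 0.05, lowThresh = 0.02)
  expect_lt(abs(median(pts2$width) - 8) / 8, 0.2)
})

test_that("collinear points within link distance form a single polyline", {
  n <- 20
  pts <- makeLinePoints(row = rep(10, n), col = seq(0, by = 1.2, length.out = n),
                        angle = rep(0, n))  # normal along rows, tangent along cols
  lines <- linkLinePoints(pts, h = 0.5, l = 2.5, minLength = 5)
  expect_length(lines, 1L)
  expect_equal(nrow(lines[[1]]), n)
  # the polyline is ordered along the chain
  expect_true(all(diff(lines[[1]]$col) > 0) || all(diff(lines[[1]]$col) < 0))
})

test_that("parallel chains farther apart than the link distance stay separate", {
  n <- 15
  a <- makeLinePoints(rep(10, n), seq_len(n), rep(0, n))
  b <- makeLinePoints(rep(20, n), seq_len(n), rep(0, n))
  lines <- linkLinePoints(rbind(a, b), h = 0.5, l = 2.5, minLength = 5)
  expect_length(lines, 2L)
  rows <- sort(vapply(lines, function(l) l$row[1], numeric(1)))
  expect_equal(rows, c(10, 20))
})

test_that("an X-crossing resolves into two straight polylines", {
  # two straight lines through the origin at +/-20 degrees from horizontal
  t <- seq(-15, 15, by = 1)
  t <- t[abs(t) > 0.5]
  a1 <- 20 * pi / 180
  l1 <- cbind(40 + t * sin(a1), 40 + t * cos(a1))
  l2 <- cbind(40 - t * sin(a1), 40 + t * cos(a1))
  pts <- makeLinePoints(c(l1[, 1], l2[, 1]), c(l1[, 2], l2[, 2]),
                        angle = c(rep((pi - a1) %% pi, nrow(l1)),
                                  rep(a1, nrow(l2))))
  lines <- linkLinePoints(pts, h = 0.5, l = 2.5, minLength = 5)
  expect_length(lines, 2L)
  # oracle: each polyline must lie entirely on one generating line
  for (ln in lines) {
    d1 <- abs((ln$row - 40) * cos(a1) - (ln$col - 40) * sin(a1))
    d2 <- abs((ln$row - 40) * cos(a1) + (ln$col - 40) * sin(a1))
    expect_true(max(d1) < 0.1 || max(d2) < 0.1)
  }
  # and both lines are fully recovered
  expect_equal(sort(vapply(lines, nrow, integer(1))), rep(nrow(l1), 2))
})

test_that("polylines shorter than the minimum length are discarded", {
  pts <- makeLinePoints(rep(10, 4), 1:4, rep(0, 4))
  expect_length(linkLinePoints(pts, 0.5, 2.5, minLength = 10), 0L)
  expect_length(linkLinePoints(pts, 0.5, 2.5, minLength = 2), 1L)
})

test_that("detection is invariant to a global additive brightness offset", {
  sc <- renderScene(oneVesselScene(300, nFrames = 30L, noiseSd = 0))
  mi <- computeMeanImage(sc$sequence)
  p <- hvmParams()
  v1 <- detectVessels(mi, 1, p)
  v2 <- detectVessels(pmin(mi + 25, 255), 1, p)
  l1 <- sum(vapply(v1, vesselLength, numeric(1)))
  l2 <- sum(vapply(v2, vesselLength, numeric(1)))
  expect_lt(abs(l1 - l2) / l1, 0.05)
})
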