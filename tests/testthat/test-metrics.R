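test_that("total vessel density sums capillary lengths over the area", {
  vs <- list(makeVessel(1, 500), makeVessel(2, 300))
  expect_equal(totalVesselDensity(vs, 0.1), 8)
  expect_equal(totalVesselDensity(list(), 0.1), 0)
  # venules do not contribute
  vs2 <- c(vs, list(makeVessel(3, 1000, type = "venule", diameterUm = 60)))
  expect_equal(totalVesselDensity(vs2, 0.1), 8)
  expect_error(totalVesselDensity(vs, 0))
})

test_that("FCD and PPV follow length weighting of perfused capillaries", {
  allP <- list(makeVessel(1, 500, perfusion = "perfused"),
               makeVessel(2, 300, perfusion = "perfused"))
  r <- functionalCapillaryDensity(allP, 0.1)
  expect_equal(r$fcd, totalVesselDensity(allP, 0.1))
  expect_equal(r$ppv, 1)
  none <- list(makeVessel(1, 500, perfusion = "non_perfused"))
  r2 <- functionalCapillaryDensity(none, 0.1)
  expect_equal(r2$fcd, 0)
  expect_equal(r2$ppv, 0)
  mix <- list(makeVessel(1, 100, perfusion = "perfused"),
              makeVessel(2, 300, perfusion = "non_perfused"))
  expect_equal(functionalCapillaryDensity(mix, 0.1)$ppv, 0.25)
})

test_that("field RBCv is the length-weighted mean over defined capillaries", {
  vs <- list(makeVessel(1, 100, rbcv = 200), makeVessel(2, 300, rbcv = 400))
  expect_equal(fieldRBCV(vs), 350)
  eq <- list(makeVessel(1, 200, rbcv = 100), makeVessel(2, 200, rbcv = 300))
  expect_equal(fieldRBCV(eq), 200)
  expect_equal(fieldRBCV(list(makeVessel(1, 150, rbcv = 275))), 275)
  expect_true(is.na(fieldRBCV(list(makeVessel(1, 150)))))
  # vessels with undefined RBCv are excluded from both sides of the mean
  vs2 <- c(vs, list(makeVessel(3, 500)))
  expect_equal(fieldRBCV(vs2), 350)
})

test_that("metric identities hold over random vessel populations", {
  set.seed(SCENE_SEED)
  for (i in 1:1000) {
    n <- sample(1:8, 1)
    vs <- lapply(seq_len(n), function(j)
      makeVessel(j, runif(1, 50, 600),
                 type = sample(c("capillary", "venule"), 1, prob = c(0.8, 0.2)),
                 rbcv = if (runif(1) < 0.8) runif(1, 5, 1500) else NA_real_,
                 perfusion = sample(c("perfused", "non_perfused"), 1)))
    area <- runif(1, 0.05, 0.5)
    tvd <- totalVesselDensity(vs, area)
    r <- functionalCapillaryDensity(vs, area)
    expect_lte(r$fcd, tvd + 1e-12)
    if (tvd > 0) expect_equal(r$ppv, r$fcd / tvd)
    expect_gte(r$ppv, 0); expect_lte(r$ppv, 1)
    fv <- fieldRBCV(vs)
    caps <- Filter(function(v) v@vesselType == "capillary" && !is.na(v@rbcv), vs)
    if (length(caps)) {
      rng <- range(vapply(caps, function(v) v@rbcv, numeric(1)))
      expect_gte(fv, rng[1] - 1e-9); expect_lte(fv, rng[2] + 1e-9)
    } else expect_true(is.na(fv))
  }
})

test_that("splitting a capillary into abutting halves changes nothing", {
  whole <- list(makeVessel(1, 400, rbcv = 350, perfusion = "perfused"),
                makeVessel(2, 200, rbcv = 100, perfusion = "perfused"))
  split <- list(makeVessel(1, 250, rbcv = 350, perfusion = "perfused"),
                makeVessel(3, 150, rbcv = 350, perfusion = "perfused"),
                makeVessel(2, 200, rbcv = 100, perfusion = "perfused"))
  expect_equal(totalVesselDensity(whole, 0.2), totalVesselDensity(split, 0.2))
  expect_equal(fieldRBCV(whole), fieldRBCV(split))
  expect_equal(functionalCapillaryDensity(whole, 0.2)$fcd,
               functionalCapillaryDensity(split, 0.2)$fcd)
})

test_that("fieldMetrics aggregates counts and enforces its invariants", {
  vs <- list(makeVessel(1, 400, rbcv = 350, perfusion = "perfused"),
             makeVessel(2, 200, perfusion = "non_perfused"),
             makeVessel(3, 800, type = "venule", diameterUm = 60))
  m <- fieldMetrics(vs, 0.2, nPaths = 12L)
  expect_s4_class(m, "FieldMetrics")
  expect_equal(m@nCapillaries, 2L)
  expect_equal(m@nVenules, 1L)
  expect_equal(m@tvd, (400 + 200) / 1000 / 0.2)
  expect_equal(m@fcd, 400 / 1000 / 0.2)
  expect_equal(m@ppv, m@fcd / m@tvd)
  expect_equal(m@rbcv, 350)
})
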