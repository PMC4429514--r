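test_that("membership fields form an exact partition of unity", {
  z <- matrix(0, 5, 5)
  m <- membershipFields(z, z, 0.3)
  for (k in 1:4) expect_equal(m[[k]], matrix(0.25, 5, 5))
  big <- matrix(1e8, 5, 5)
  m2 <- membershipFields(big, big, 0.3)
  expect_gt(min(m2$m1), 1 - 1e-6)
  expect_lt(max(m2$m2 + m2$m3 + m2$m4), 1e-6)
  for (sd in 1:5) {
    p1 <- matrix(rnorm(49), 7, 7); p2 <- matrix(rnorm(49), 7, 7)
    m3 <- membershipFields(p1, p2, 0.3)
    expect_equal(m3$m1 + m3$m2 + m3$m3 + m3$m4, matrix(1, 7, 7),
                 tolerance = 1e-14)
    expect_true(all(sapply(m3, function(x) all(x > 0 & x < 1))))
  }
})

test_that("four-phase means match the explicit-loop oracle", {
  cimg <- matrix(0.6, 6, 6)
  m <- membershipFields(randomPhi(6, 1), randomPhi(6, 2), 0.3)
  expect_equal(unname(fourPhaseMeans(cimg, m)), rep(0.6, 4))
  # matched four-quadrant configuration
  q <- rbind(cbind(matrix(0.1, 4, 4), matrix(0.4, 4, 4)),
             cbind(matrix(0.7, 4, 4), matrix(1.0, 4, 4)))
  p1 <- rbind(matrix(1, 4, 8), matrix(-1, 4, 8))   # top pair positive
  p2 <- cbind(matrix(1, 8, 4), matrix(-1, 8, 4))   # left pair positive
  mm <- membershipFields(p1, p2, 0.3)
  got <- fourPhaseMeans(q, mm)
  expect_equal(unname(got), loopFourPhaseMeans(q, mm), tolerance = 1e-10)
  # phase 1 (both positive) is dominated by the top-left quadrant
  expect_lt(got[["c1"]], 0.35)
  expect_gt(got[["c4"]], 0.75)
  img <- randomImage(7, 31)
  mr <- membershipFields(randomPhi(7, 32), randomPhi(7, 33), 0.3)
  expect_equal(unname(fourPhaseMeans(img, mr)), loopFourPhaseMeans(img, mr),
               tolerance = 1e-10)
})

test_that("four-phase local fits match the naive oracle", {
  cimg <- matrix(0.3, 6, 6)
  m <- membershipFields(randomPhi(6, 3), randomPhi(6, 4), 0.3)
  f <- fourPhaseLocalFits(cimg, m, 2)
  for (k in 1:4) expect_equal(f[[k]], cimg)
  img <- randomImage(8, 5)
  m2 <- membershipFields(randomPhi(8, 6), randomPhi(8, 7), 0.3)
  got <- fourPhaseLocalFits(img, m2, 2)
  w <- gauss1d(2)
  for (k in 1:4) {
    want <- naiveConvolve(m2[[k]] * img, w) /
      pmax(naiveConvolve(m2[[k]], w), 1e-12)
    expect_equal(got[[k]], want, tolerance = 1e-8)
  }
  # deep inside a pure phase the fit tracks that phase's intensity
  img3 <- cbind(matrix(0.2, 10, 20), matrix(0.9, 10, 20))
  p1 <- cbind(matrix(1, 10, 20), matrix(-1, 10, 20))
  p2 <- matrix(1, 10, 40)
  m3 <- membershipFields(p1, p2, 0.3)
  f3 <- fourPhaseLocalFits(img3, m3, 2)
  expect_equal(f3$f1[, 1:10], matrix(0.2, 10, 10), tolerance = 1e-3)
  expect_equal(f3$f3[, 31:40], matrix(0.9, 10, 10), tolerance = 1e-3)
})

test_that("four-phase forces are bounded with a zero constant-image limit", {
  cimg <- matrix(0.5, 8, 8)
  m <- membershipFields(randomPhi(8, 8), randomPhi(8, 9), 0.3)
  cs <- fourPhaseMeans(cimg, m)
  s0 <- fourPhaseSPF(cimg, randomPhi(8, 8), randomPhi(8, 9), cs, omega = 1)
  expect_equal(s0$spf1, matrix(0, 8, 8))
  expect_equal(s0$spf2, matrix(0, 8, 8))
  for (sd in 1:10) {
    img <- randomImage(10, sd + 50)
    p1 <- randomPhi(10, sd + 60); p2 <- randomPhi(10, sd + 70)
    mm <- membershipFields(p1, p2, 0.3)
    cs <- fourPhaseMeans(img, mm)
    fs <- fourPhaseLocalFits(img, mm, 2)
    om <- adaptiveWeight(localContrast(img), 1)
    s <- fourPhaseSPF(img, p1, p2, cs, fs, om, 0.3, 2)
    expect_true(all(abs(s$spf1) <= 1) && all(abs(s$spf2) <= 1))
    # with omega = 1 the forces need no local fits at all
    sg <- fourPhaseSPF(img, p1, p2, cs, omega = 1)
    expect_true(all(abs(sg$spf1) <= 1) && all(abs(sg$spf2) <= 1))
  }
})

test_that("a noise-free four-quadrant scene is recovered almost exactly", {
  ph <- makePhantom(phantomSpec(c(64, 64), "four_quadrant", noiseSigma = 0))
  res <- segmentFourPhase(phantomImage(ph),
                          params = evolutionParams(alpha = 30,
                                                   maxIters = 60L))
  md <- multiLabelDice(phantomTruth(ph), labelMap(res))
  expect_true(all(md$perLabel >= 0.95))
  # reported means are membership-weighted (eps 0.3), hence mildly mixed
  expect_lt(max(abs(sort(unname(phaseMeans(res))) - c(0.1, 0.4, 0.7, 1.0))),
            0.15)
  expect_length(phaseLegend(res), 4L)
})

test_that("a two-value image leaves only two populated phases", {
  ph <- makePhantom(phantomSpec(c(64, 64), "disk", noiseSigma = 0.02,
                                seed = 5))
  res <- segmentFourPhase(phantomImage(ph),
                          params = evolutionParams(alpha = 30,
                                                   maxIters = 60L))
  share <- sort(tabulate(labelMap(res), 4L), decreasing = TRUE)
  expect_gte(sum(share[1:2]) / sum(share), 0.99)
})

test_that("label maps are a pure function of the final field signs", {
  ph <- makePhantom(phantomSpec(c(48, 48), "four_quadrant",
                                noiseSigma = 0.01, seed = 9))
  res <- segmentFourPhase(phantomImage(ph),
                          params = evolutionParams(alpha = 30,
                                                   maxIters = 30L))
  f <- levelSet(res)
  lab <- matrix(4L, 48, 48)
  lab[f$phi1 > 0 & f$phi2 > 0] <- 1L
  lab[f$phi1 > 0 & f$phi2 <= 0] <- 2L
  lab[f$phi1 <= 0 & f$phi2 > 0] <- 3L
  expect_identical(labelMap(res), lab)
})

test_that("freezing phi2 reduces the flow to the two-phase model", {
  ph <- makePhantom(phantomSpec(c(96, 96), "disk", noiseSigma = 0))
  img <- phantomImage(ph)
  p <- evolutionParams(alpha = 20, maxIters = 120L)
  twoP <- segmentTwoPhase(img, c(24, 72, 24, 72), p)
  frozen <- matrix(1000, 96, 96)
  fourP <- segmentFourPhase(img, c(24, 72, 24, 72), frozen, p,
                            freeze2 = TRUE)
  expect_equal(dice(segMask(twoP), labelMap(fourP) == 1L), 1)
})

test_that("identical initializations raise a collapse warning", {
  img <- randomImage(32, 77)
  expect_warning(
    segmentFourPhase(img, c(8, 24, 8, 24), c(8, 24, 8, 24),
                     evolutionParams(alpha = 30, maxIters = 2L)),
    "identical")
})
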