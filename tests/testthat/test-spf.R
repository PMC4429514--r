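test_that("global region means match the explicit-loop oracle", {
  cimg <- matrix(0.4, 5, 5)
  phi <- randomPhi(5, 1)
  expect_equal(globalRegionMeans(cimg, phi, 0.3),
               c(c1 = 0.4, c2 = 0.4))
  # left-dark/right-bright with a matched binarized field
  img <- cbind(matrix(0, 4, 2), matrix(1, 4, 2))
  phi2 <- cbind(matrix(-1, 4, 2), matrix(1, 4, 2))
  expect_equal(globalRegionMeans(img, phi2, 0.3),
               loopGlobalMeans(img, phi2, 0.3))
  # checkerboard with a single negative pixel
  cb <- matrix(rep(c(0, 1), length.out = 16), 4, 4)
  phi3 <- matrix(1, 4, 4); phi3[2, 3] <- -1
  expect_equal(globalRegionMeans(cb, phi3, 0.3),
               loopGlobalMeans(cb, phi3, 0.3))
  # randomized fixtures
  for (s in 1:5) {
    img <- randomImage(7, s); phi <- randomPhi(7, s + 100)
    expect_equal(globalRegionMeans(img, phi, 0.3),
                 loopGlobalMeans(img, phi, 0.3), tolerance = 1e-12)
  }
})

test_that("a degenerate side falls back to the global mean with a warning", {
  img <- matrix(runif(16), 4, 4)
  phi <- matrix(1e9, 4, 4)  # outside weight ~ 0 for tiny eps
  expect_warning(m <- globalRegionMeans(img, phi, 1e-6), "degenerate")
  expect_equal(unname(m["c2"]), mean(img))
})

test_that("local fitting functions match the naive windowed oracle", {
  cimg <- matrix(0.8, 6, 6)
  f <- localFittingFunctions(cimg, randomPhi(6, 2), 2, 0.3)
  expect_equal(f$f1, cimg)
  expect_equal(f$f2, cimg)
  img <- randomImage(8, 3); phi <- randomPhi(8, 4)
  got <- localFittingFunctions(img, phi, 2, 0.3)
  want <- naiveLocalFits(img, phi, 2, 0.3)
  expect_equal(got$f1, want$f1, tolerance = 1e-8)
  expect_equal(got$f2, want$f2, tolerance = 1e-8)
})

test_that("far from a straight boundary the fits recover the region values", {
  # two constant regions split vertically; kernel sigma 2 (radius 6)
  img <- cbind(matrix(0.2, 10, 20), matrix(0.9, 10, 20))
  phi <- cbind(matrix(1, 10, 20), matrix(-1, 10, 20))
  f <- localFittingFunctions(img, phi, 2, 0.3)
  expect_equal(f$f1[, 1:10], matrix(0.2, 10, 10), tolerance = 1e-6)
  expect_equal(f$f2[, 31:40], matrix(0.9, 10, 10), tolerance = 1e-6)
})

test_that("global SPF thresholds at the mean midpoint and normalizes to 1", {
  expect_equal(spfGlobal(matrix(0.3, 4, 4), c(c1 = 0.3, c2 = 0.3)),
               matrix(0, 4, 4))
  img <- matrix(c(0, 1, 1, 0, 1, 0), 2, 3)
  s <- spfGlobal(img, c(c1 = 1, c2 = 0))
  expect_equal(s, ifelse(img > 0.5, 1, -1))
  for (sd in 1:5) {
    img <- randomImage(6, sd)
    s <- spfGlobal(img, globalRegionMeans(img, randomPhi(6, sd), 0.3))
    expect_true(all(abs(s) <= 1))
    expect_equal(max(abs(s)), 1)
  }
})

test_that("local SPF follows the pointwise fit midpoint", {
  cimg <- matrix(0.5, 5, 5)
  expect_equal(spfLocal(cimg, list(f1 = cimg, f2 = cimg)), matrix(0, 5, 5))
  img <- randomImage(8, 9)
  fits <- localFittingFunctions(img, randomPhi(8, 10), 2, 0.3)
  s <- spfLocal(img, fits)
  raw <- img - (fits$f1 + fits$f2) / 2
  expect_equal(s, raw / max(abs(raw)))
  expect_equal(max(abs(s)), 1)
})

test_that("local contrast matches hand values and the loop oracle", {
  expect_equal(localContrast(matrix(0.7, 6, 6)), matrix(0, 6, 6))
  # binary step profile: windows straddling the step see 0.6/1.0
  img <- cbind(matrix(0.2, 5, 6), matrix(0.8, 5, 6))
  cr <- localContrast(img, 5)
  expect_equal(cr[3, 6], 0.6 / (1.0 + 1e-8))
  expect_equal(cr[3, 2], 0)   # deep inside the dark region
  expect_equal(cr[3, 11], 0)  # deep inside the bright region
  img2 <- randomImage(7, 12)
  expect_equal(localContrast(img2, 5), loopContrast(img2, 5))
  expect_equal(localContrast(img2, 3), loopContrast(img2, 3))
  expect_error(localContrast(img2, 4), "odd")
})

test_that("adaptive weight is a decreasing, scale-invariant exponential", {
  expect_equal(adaptiveWeight(matrix(0, 5, 5), 1), matrix(1, 5, 5))
  cr <- matrix(runif(36), 6, 6)
  w <- adaptiveWeight(cr, 1)
  expect_true(all(w > 0 & w <= 1))
  # a pixel at exactly the mean contrast maps to exp(-beta)
  cr2 <- cr
  target <- (sum(cr2) - cr2[3, 3]) / 35  # solves x = mean(cr2 with x at [3,3])
  cr2[3, 3] <- target  # now cr2[3,3] == mean(cr2)
  expect_equal(adaptiveWeight(cr2, 1)[3, 3], exp(-1))
  # monotone: larger contrast, smaller weight
  o <- order(cr)
  expect_true(all(diff(w[o]) <= 0))
  # scale invariance through the contrast ratio
  img <- randomImage(8, 5) + 0.1
  expect_equal(adaptiveWeight(localContrast(img), 1),
               adaptiveWeight(localContrast(3.7 * img), 1),
               tolerance = 1e-6)
})

test_that("combined SPF is the stated convex combination", {
  sg <- randomImage(6, 21) * 2 - 1
  sl <- randomImage(6, 22) * 2 - 1
  expect_equal(combinedSPF(sg, sl, matrix(1, 6, 6)), sg)
  expect_equal(combinedSPF(sg, sl, matrix(0, 6, 6)), sl)
  half <- combinedSPF(matrix(1, 6, 6), matrix(-1, 6, 6), matrix(0.5, 6, 6))
  expect_equal(half, matrix(0, 6, 6))
  expect_error(combinedSPF(sg, sl[1:5, 1:5], matrix(1, 6, 6)), "shape")
})

test_that("SPF fields stay in [-1, 1] with unit max on random inputs", {
  for (sd in 1:20) {
    img <- randomImage(10, sd)
    phi <- randomPhi(10, sd + 500)
    sg <- spfGlobal(img, globalRegionMeans(img, phi, 0.3))
    sl <- spfLocal(img, localFittingFunctions(img, phi, 2, 0.3))
    om <- adaptiveWeight(localContrast(img), 1)
    sc <- combinedSPF(sg, sl, om)
    expect_true(all(abs(sg) <= 1) && all(abs(sl) <= 1) && all(abs(sc) <= 1))
    expect_equal(max(abs(sg)), 1)
    expect_equal(max(abs(sl)), 1)
  }
})

test_that("local and global SPF agree in sign on a clean two-level scene", {
  img <- cbind(matrix(0.2, 12, 12), matrix(0.8, 12, 12))
  phi <- cbind(matrix(-1, 12, 12), matrix(1, 12, 12))
  sg <- spfGlobal(img, globalRegionMeans(img, phi, 0.3))
  sl <- spfLocal(img, localFittingFunctions(img, phi, 2, 0.3))
  # far from the boundary the local force decays to rounding noise; signs
  # must agree wherever the local force is non-negligible
  act <- abs(sl) > 1e-6
  expect_true(any(act))
  expect_true(all(sign(sg[act]) == sign(sl[act])))
  expect_true(all(abs(sl[!act]) < 1e-6))
})
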