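test_that("contrast transform obeys the pointwise formula and clipping", {
  img <- GrayImage(matrix(c(128L, 0L, 200L, 64L), 2), 10)
  out15 <- pixels(adjustContrast(img, 1.5))
  expect_identical(out15[1, 1], 128L)     # fixed point of the transform
  expect_identical(out15[2, 1], 0L)       # f(0) = -64 clips to 0
  out20 <- pixels(adjustContrast(img, 2.0))
  expect_identical(out20[1, 2], 255L)     # f(200) = 272 clips to 255
  expect_identical(out20[2, 2], 0L)       # f(64) = 0
  # gain 1 is the identity on any image
  rnd <- smallRandomImage(16)
  expect_identical(pixels(adjustContrast(rnd, 1.0)), pixels(rnd))
  expect_error(adjustContrast(rnd, 0), "positive")
})

test_that("contrast transform is monotone and injective off the clip range", {
  ramp <- GrayImage(matrix(0:255, 16), 10)
  for (g in c(1.5, 2.0)) {
    out <- as.vector(pixels(adjustContrast(ramp, g)))
    expect_true(all(diff(out) >= 0))
    keep <- out > 0 & out < 255
    expect_true(all(diff(out[keep]) >= 1))   # strictly increasing -> injective
  }
})

test_that("histogram normalization anchors at the saturation percentiles", {
  # two-valued image, zero saturation: min -> 0, max -> 255
  tw <- GrayImage(matrix(c(rep(50L, 8), rep(100L, 8)), 4), 10)
  expect_setequal(unique(as.vector(pixels(normalizeHistogram(tw, 0)))),
                  c(0L, 255L))
  # full-range uniform image is unchanged away from the saturated tails
  u <- GrayImage(matrix(rep(0:255, 4), 32), 10)
  out <- pixels(normalizeHistogram(u, 0.3))
  expect_true(mean(out == pixels(u)) > 0.98)
  # 1000-px ramp, 0.3%: anchors from the explicit cumulative histogram
  v <- as.integer(round(seq(10, 240, length.out = 1000)))
  rampimg <- GrayImage(matrix(v, 25), 10)
  h <- tabulate(v + 1L, nbins = 256)
  budget <- 1000 * 0.3 / 100 / 2
  lo <- which(cumsum(h) > budget)[1] - 1L
  hi <- 256L - which(cumsum(rev(h)) > budget)[1]
  expected <- pmin(pmax(round(255 * (v - lo) / (hi - lo)), 0), 255)
  got <- as.vector(pixels(normalizeHistogram(rampimg, 0.3)))
  expect_true(max(abs(got - expected)) <= 1)   # rounding convention slack
  expect_warning(normalizeHistogram(GrayImage(matrix(9L, 4, 4), 10)),
                 "constant")
  expect_error(normalizeHistogram(tw, 100), "\\[0, 100\\)")
})

test_that("CLAHE respects range, constancy and the slope-1 identity", {
  const <- GrayImage(matrix(100L, 64, 64), 10)
  outc <- pixels(claheEqualize(const))
  expect_equal(length(unique(as.vector(outc))), 1L)
  ramp <- GrayImage(matrix(as.integer(seq(40, 215, length.out = 128 * 128)),
                           128), 10)
  ident <- pixels(claheEqualize(ramp, maxSlope = 1))
  expect_true(max(abs(ident - pixels(ramp))) <= 1)
  # equalization widens a low-contrast texture and stays 8-bit
  tex <- makeCCTemplate(subjectParams(intensityRange = c(100, 160),
                                      rngSeed = 6), 128L)$image
  out <- claheEqualize(tex)
  expect_gt(sd(pixels(out)), sd(pixels(tex)))
  expect_true(all(pixels(out) >= 0 & pixels(out) <= 255))
})

test_that("registration recovers known rigid jitter within tolerance", {
  tpl <- makeRetinalTemplate(subjectParams(rngSeed = 42), 160L)$image
  # pure translation (+3, -2) must be undone by (-3, +2)
  acq <- simulateAcquisition(tpl, acquisitionJitter(shiftPx = c(3, -2),
                                                    rngSeed = 7))
  reg <- registerRigid(acq, tpl)
  expect_lt(abs(reg$transform@translation[1] + 3), 0.5)
  expect_lt(abs(reg$transform@translation[2] - 2), 0.5)
  # pure 1 degree rotation must be undone by about -1 degree
  acq2 <- simulateAcquisition(tpl, acquisitionJitter(rotationDeg = 1,
                                                     rngSeed = 8))
  reg2 <- registerRigid(acq2, tpl)
  expect_lt(abs(reg2$transform@rotationDeg + 1), 0.25)
  # sub-pixel shift
  acq3 <- simulateAcquisition(tpl, acquisitionJitter(shiftPx = c(-1.4, 0.7),
                                                     rngSeed = 9))
  reg3 <- registerRigid(acq3, tpl)
  expect_lt(abs(reg3$transform@translation[1] - 1.4), 0.5)
  expect_lt(abs(reg3$transform@translation[2] + 0.7), 0.5)
})

test_that("registering an image onto itself is the identity", {
  tpl <- makeCCTemplate(subjectParams(rngSeed = 12), 96L)$image
  reg <- registerRigid(tpl, tpl)
  expect_lt(abs(reg$transform@translation[1]), 0.1)
  expect_lt(abs(reg$transform@translation[2]), 0.1)
  expect_lt(abs(reg$transform@rotationDeg), 0.1)
})

test_that("registration of a constant image degrades to identity + warning", {
  flat <- GrayImage(matrix(50L, 64, 64), 10)
  tex <- makeCCTemplate(subjectParams(rngSeed = 1), 64L)$image
  expect_warning(reg <- registerRigid(flat, tex), "identity")
  expect_equal(reg$transform@translation, c(0, 0))
})

test_that("re-registering a registered image yields a near-identity step", {
  tpl <- makeRetinalTemplate(subjectParams(rngSeed = 21), 128L)$image
  acq <- simulateAcquisition(tpl, acquisitionJitter(shiftPx = c(2, 1),
                                                    rotationDeg = 0.5,
                                                    rngSeed = 3))
  once <- registerRigid(acq, tpl)
  twice <- registerRigid(once$image, tpl)
  expect_lt(sqrt(sum(twice$transform@translation^2)), 0.5)
  expect_lt(abs(twice$transform@rotationDeg), 0.3)
})
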