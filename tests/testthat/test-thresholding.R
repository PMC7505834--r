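test_that("global Otsu equals exhaustive search on random histograms", {
  set.seed(101)
  for (i in 1:100) {
    h <- randomHistogram()
    if (sum(h > 0) < 2) next
    expect_identical(as.integer(globalThreshold(h, "global_otsu")),
                     as.integer(oracleOtsu(h)))
  }
})

test_that("global IsoData lands on an intermeans fixpoint", {
  set.seed(102)
  for (i in 1:100) {
    h <- randomHistogram()
    if (sum(h > 0) < 2) next
    t <- globalThreshold(h, "global_isodata")
    expect_true(oracleIsoDataFix(h, t))
  }
})

test_that("global Huang minimizes fuzzy entropy over all candidates", {
  set.seed(103)
  for (i in 1:40) {
    h <- randomHistogram()
    occ <- which(h > 0)
    if (length(occ) < 2) next
    t <- globalThreshold(h, "global_huang")
    Sgot <- oracleHuangEntropy(h, t)
    cand <- (occ[1] - 1):(occ[length(occ)] - 2)
    Sbest <- min(vapply(cand, function(tt) oracleHuangEntropy(h, tt),
                        numeric(1)))
    expect_lt(Sgot - Sbest, 1e-8)
  }
})

test_that("global mean floors the overall mean", {
  h <- rep(4L, 256)                        # uniform 0..255, mean 127.5
  expect_identical(globalThreshold(h, "global_mean"), 127L)
  set.seed(104)
  for (i in 1:20) {
    h <- randomHistogram()
    expect_identical(globalThreshold(h, "global_mean"),
                     as.integer(floor(sum((0:255) * h) / sum(h))))
  }
})

test_that("global Default ignores the extreme bins, unlike IsoData", {
  # spike at 0 dominates; Default zeroes it before iterating
  h <- integer(256); h[1] <- 10000L; h[101] <- 100L; h[201] <- 100L
  tDef <- globalThreshold(h, "global_default")
  tIso <- globalThreshold(h, "global_isodata")
  expect_identical(as.integer(tDef), 150L)  # intermeans of 100 and 200
  expect_lt(tIso, tDef)                     # dragged down by the 0 spike
})

test_that("degenerate single-bin histograms warn and return the bin", {
  h <- integer(256); h[43] <- 50L
  for (m in c("global_default", "global_huang", "global_isodata",
              "global_otsu")) {
    expect_warning(t <- globalThreshold(h, m), "single occupied bin")
    expect_identical(as.integer(t), 42L)
  }
})

test_that("binarization tie rule is white iff p > t", {
  # one bright pixel on a dark field: otsu keeps exactly that pixel white
  m <- matrix(0L, 8, 8); m[3, 4] <- 255L
  img <- GrayImage(m, 10)
  b <- binarizeGlobal(img, "global_otsu")
  expect_identical(sum(pixels(b)), 1L)
  expect_true(pixels(b)[3, 4])
  # forced t = 255 -> nothing exceeds it
  expect_false(any(pixels(binarizeGlobal(img, "global_otsu", t = 255))))
  # plateau exactly at t stays black under the p > t rule
  plateau <- GrayImage(matrix(c(rep(10L, 32), rep(200L, 32)), 8), 10)
  t <- globalThreshold(plateau, "global_otsu")
  bp <- binarizeGlobal(plateau, "global_otsu")
  expect_identical(vesselAreaDensity(bp),
                   100 * mean(pixels(plateau) > t))
  expect_false(any(pixels(bp)[pixels(plateau) == t]))
})

test_that("local methods match the direct per-pixel oracle on random images", {
  set.seed(105)
  img <- smallRandomImage(24)
  for (m in c("local_mean", "local_median", "local_niblack",
              "local_phansalkar", "local_bernsen", "local_otsu")) {
    got <- pixels(binarizeLocal(img, thresholdSpec(m, radiusPx = 5L)))
    want <- oracleLocalBinary(pixels(img), 5L, m)
    expect_identical(got, want)
  }
})

test_that("constant image under local mean is all black (tie rule)", {
  img <- GrayImage(matrix(77L, 40, 40), 10)
  expect_false(any(pixels(binarizeLocal(img, "local_mean"))))
})

test_that("a bright dot survives local median, background does not", {
  m <- matrix(10L, 40, 40); m[20, 20] <- 250L
  b <- pixels(binarizeLocal(GrayImage(m, 10), "local_median"))
  expect_true(b[20, 20])
  expect_identical(sum(b), 1L)
})

test_that("Niblack with k = 0 reduces to local mean", {
  img <- smallRandomImage(32)
  p0 <- thresholdParams(niblack_k = 0)
  expect_identical(
    pixels(binarizeLocal(img, thresholdSpec("local_niblack", 7L, p0))),
    pixels(binarizeLocal(img, thresholdSpec("local_mean", 7L, p0))))
})

test_that("huge radius makes local methods agree with their global twins", {
  # clip border mode: a disc covering the whole image IS the image, so the
  # local formula coincides with the global one
  img <- smallRandomImage(20)
  big <- 40L   # > image diagonal
  expect_identical(
    pixels(binarizeLocal(img, thresholdSpec("local_mean", big), border = "clip")),
    pixels(binarizeGlobal(img, "global_mean", t = mean(pixels(img)))))
  expect_identical(
    pixels(binarizeLocal(img, thresholdSpec("local_otsu", big), border = "clip")),
    pixels(binarizeGlobal(img, "global_otsu")))
  expect_identical(
    pixels(binarizeLocal(img, thresholdSpec("local_median", big), border = "clip")),
    matrix(pixels(img) > sort(pixels(img))[(length(pixels(img)) + 1) %/% 2],
           20, 20))
})

test_that("local thresholds error when the radius swallows the image", {
  img <- smallRandomImage(10)
  expect_error(binarizeLocal(img, thresholdSpec("local_mean", 10L)),
               "smaller than the image")
})

test_that("local median is invariant under monotone injective transforms", {
  sp <- subjectParams(intensityRange = c(65, 191), rngSeed = 3)
  for (tpl in list(makeCCTemplate(sp, 96L)$image,
                   makeRetinalTemplate(sp, 96L)$image)) {
    base <- pixels(binarizeLocal(tpl, "local_median"))
    for (gain in c(1.5, 2.0)) {
      tr <- adjustContrast(tpl, gain)
      # the no-clip range keeps the transform injective
      expect_true(min(pixels(tr)) > 0 && max(pixels(tr)) < 255)
      expect_identical(pixels(binarizeLocal(tr, "local_median")), base)
    }
  }
})

test_that("local otsu agrees with the EBImage global otsu in the big-radius limit", {
  skip_if_not_installed("EBImage")
  img <- smallRandomImage(20)
  big <- 40L
  got <- pixels(binarizeLocal(img, thresholdSpec("local_otsu", big),
                              border = "clip"))
  # EBImage otsu returns a [0,1] cut for the same criterion
  t_eb <- EBImage::otsu(EBImage::Image(t(pixels(img)) / 255), range = c(0, 1),
                        levels = 256)
  want <- pixels(img) / 255 > t_eb
  expect_true(mean(got == want) > 0.99)
})

test_that("precomputed fields give the same answer as the direct path", {
  img <- smallRandomImage(24)
  flds <- localFields(img, 5L)
  for (m in c("local_mean", "local_niblack", "local_bernsen")) {
    expect_identical(
      pixels(binarizeLocal(img, thresholdSpec(m, 5L), fields = flds)),
      pixels(binarizeLocal(img, thresholdSpec(m, 5L))))
  }
})
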