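test_that("vessel area density is the white-pixel percentage", {
  expect_equal(vesselAreaDensity(BinaryImage(matrix(TRUE, 4, 4), 10)), 100)
  chk <- outer(1:8, 1:8, function(i, j) (i + j) %% 2 == 1)
  expect_equal(vesselAreaDensity(BinaryImage(chk, 10)), 50)
  m <- matrix(FALSE, 3, 3); m[c(1, 5, 9)] <- TRUE
  expect_equal(vesselAreaDensity(BinaryImage(m, 10)), 100 / 3)
})

test_that("VAD of an image and its inverse always sum to 100", {
  set.seed(7)
  for (i in 1:10) {
    m <- matrix(runif(400) > runif(1, 0.1, 0.9), 20, 20)
    b <- BinaryImage(m, 10)
    inv <- BinaryImage(!m, 10)
    expect_identical(vesselAreaDensity(b) + vesselAreaDensity(inv), 100)
  }
})

test_that("skeletonization thins a bar to a one-pixel line", {
  bar <- matrix(FALSE, 7, 14)
  bar[3:5, 3:12] <- TRUE
  sk <- skeletonize(BinaryImage(bar, 10))
  px <- pixels(sk)
  expect_true(all(px[bar == FALSE] == FALSE))          # skeleton within source
  expect_true(all(colSums(px[, 3:12]) <= 1))           # 1 px wide
  n <- sum(px)
  # endpoint erosion trims a pixel or two off the ideal 10-px line
  expect_gte(n, 7); expect_lte(n, 10)
  # no 2x2 all-white block remains
  blocks <- px[-nrow(px), -ncol(px)] & px[-1, -ncol(px)] &
            px[-nrow(px), -1] & px[-1, -1]
  expect_false(any(blocks))
})

test_that("skeletonization is idempotent and preserves component count", {
  set.seed(11)
  sp <- subjectParams(rngSeed = 31)
  b <- binarizeImage(makeRetinalTemplate(sp, 96L)$image, "global_otsu")
  sk <- skeletonize(b)
  sk2 <- skeletonize(BinaryImage(pixels(sk), pitchUm(sk)))
  expect_identical(pixels(sk2), pixels(sk))
  expect_identical(max(labelComponents(pixels(sk))),
                   max(labelComponents(pixels(b))))
  # empty image -> empty skeleton
  empty <- BinaryImage(matrix(FALSE, 8, 8), 10)
  expect_false(any(pixels(skeletonize(empty))))
})

test_that("vessel length counts pixels by default, steps in euclidean mode", {
  line <- matrix(FALSE, 5, 12); line[3, 2:11] <- TRUE
  sk <- new("SkeletonImage", pixels = line, pitchUm = 7)
  vl <- vesselLength(sk)
  expect_equal(vl$length_px, 10)
  expect_equal(vl$length_um, 70)
  expect_equal(vesselLength(sk, mode = "euclidean")$length_px, 9)
  diag_ <- matrix(FALSE, 6, 6); diag(diag_) <- TRUE
  skd <- new("SkeletonImage", pixels = diag_, pitchUm = 1)
  expect_equal(vesselLength(skd, mode = "euclidean")$length_px, 5 * sqrt(2))
  emptysk <- new("SkeletonImage", pixels = matrix(FALSE, 4, 4), pitchUm = 1)
  expect_equal(vesselLength(emptysk)$length_px, 0)
})

test_that("flow deficits are 8-connected components of the inverted mask", {
  # all white -> no deficits, mean size NA (not zero)
  fd0 <- flowDeficits(BinaryImage(matrix(TRUE, 6, 6), 10))
  expect_identical(fd0$fd_count, 0L)
  expect_true(is.na(fd0$fd_mean_size_px2))
  # one 5-px blob
  m <- matrix(TRUE, 8, 8); m[3, 2:6] <- FALSE
  fd1 <- flowDeficits(BinaryImage(m, 10))
  expect_equal(fd1$fd_count, 1L)
  expect_equal(fd1$fd_mean_size_px2, 5)
  expect_equal(fd1$fd_mean_size_um2, 500)
  # blobs of 3 and 7 -> mean 5
  m2 <- matrix(TRUE, 10, 10)
  m2[2, 2:4] <- FALSE; m2[8, 2:8] <- FALSE
  fd2 <- flowDeficits(BinaryImage(m2, 10))
  expect_equal(fd2$fd_count, 2L)
  expect_equal(fd2$fd_mean_size_px2, 5)
  # diagonal touch merges under 8-connectivity
  m3 <- matrix(TRUE, 6, 6); m3[2, 2] <- FALSE; m3[3, 3] <- FALSE
  expect_equal(flowDeficits(BinaryImage(m3, 10))$fd_count, 1L)
  # ... but not under 4-connectivity
  expect_equal(max(labelComponents(!m3, connectivity = 4)), 2L)
})

test_that("count times mean size equals the total black area", {
  set.seed(13)
  for (i in 1:10) {
    m <- matrix(runif(900) > 0.3, 30, 30)
    fd <- flowDeficits(BinaryImage(m, 10))
    black <- sum(!m)
    if (fd$fd_count == 0) expect_identical(black, 0L)
    else expect_equal(fd$fd_count * fd$fd_mean_size_px2, black)
  }
})

test_that("edge exclusion and size filters work", {
  m <- matrix(TRUE, 8, 8)
  m[1, 1:2] <- FALSE          # edge-touching deficit, size 2
  m[4:5, 4:5] <- FALSE        # interior deficit, size 4
  fdAll <- flowDeficits(BinaryImage(m, 10))
  expect_equal(fdAll$fd_count, 2L)
  fdNoEdge <- flowDeficits(BinaryImage(m, 10), includeEdge = FALSE)
  expect_equal(fdNoEdge$fd_count, 1L)
  expect_equal(fdNoEdge$fd_mean_size_px2, 4)
  fdBig <- flowDeficits(BinaryImage(m, 10), minSizePx2 = 3)
  expect_equal(fdBig$fd_count, 1L)
})

test_that("planted CC deficits are recovered when binarizing with the truth", {
  counts <- numeric(20)
  for (s in 1:20) {
    tr <- makeCCTemplate(subjectParams(ccDeficitDensity = 8,
                                       ccDeficitRadiusUm = 25,
                                       rngSeed = 100 + s), 128L)$truth
    counts[s] <- flowDeficits(BinaryImage(!tr@deficitMask, 10))$fd_count
  }
  # within merge tolerance of the Poisson planting intensity over 20 seeds
  prof <- DeviceProfile("synthetic", 128L)
  lambda <- 8 * (128 * pitchUm(prof) / 1000)^2
  expect_lt(abs(mean(counts) - lambda) / lambda, 0.1)
})

test_that("labelComponents agrees with EBImage bwlabel on component counts", {
  skip_if_not_installed("EBImage")
  set.seed(17)
  m <- matrix(runif(400) > 0.6, 20, 20)
  ours <- max(labelComponents(m, connectivity = 4))
  eb <- max(EBImage::bwlabel(EBImage::Image(t(m * 1))))
  expect_identical(as.integer(ours), as.integer(eb))
})

test_that("metricRecord fills the plexus-appropriate fields", {
  b <- binarizeImage(makeCCTemplate(subjectParams(rngSeed = 4), 96L)$image,
                     "global_otsu")
  rec <- metricRecord(b, "CC")
  expect_false(is.na(rec$fd_count))
  expect_true(is.na(rec$vl_px))
  rec2 <- metricRecord(b, "SCP")
  expect_false(is.na(rec2$vl_px))
  expect_true(is.na(rec2$fd_count))
})
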