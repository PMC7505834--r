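# Contrast adjustment and the image processing techniques applied before
# binarization: histogram normalization, CLAHE, rigid registration.

#' Pointwise contrast gain about mid-grey
#'
#' Maps every pixel by f(p) = gain * (p - 128) + 128, rounds half away from
#' zero, and clips to \[0, 255\].  Gain 1 is the identity; gains above 1
#' increase contrast and clip intensities far from mid-grey.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param gain positive contrast factor (the study's levels are 1.0, 1.5,
#'   2.0).
#' @return a \linkS4class{GrayImage}.
#' @examples
#' img <- GrayImage(matrix(c(0L, 128L, 200L, 255L), 2), 10)
#' pixels(adjustContrast(img, 2.0))  # 0, 128, 255, 255
#' @export
adjustContrast <- function(image, gain) {
  stopifnot(is(image, "GrayImage"))
  if (length(gain) != 1L || !is.finite(gain) || gain <= 0)
    stop("gain must be a single positive number")
  f <- roundHalfAway(gain * (pixels(image) - 128) + 128)
  px <- pmin(pmax(f, 0), 255)
  storage.mode(px) <- "integer"
  GrayImage(px, pitchUm(image))
}

#' Histogram normalization with tail saturation
#'
#' Stretches the histogram linearly so the minimum maps to 0 and the maximum
#' to 255, after saturating the darkest and brightest
#' \code{saturatedPercent/2} of pixels.  Anchors come from the cumulative
#' histogram: the low anchor is the smallest grey level whose cumulative
#' count exceeds half the saturation budget, the high anchor the largest
#' such level from above.  Constant images are returned unchanged with a
#' warning.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param saturatedPercent total percentage of pixels driven to 0/255
#'   (default 0.3, i.e. 0.15\% per tail).
#' @return a \linkS4class{GrayImage}.
#' @export
normalizeHistogram <- function(image, saturatedPercent = 0.3) {
  stopifnot(is(image, "GrayImage"))
  if (saturatedPercent < 0 || saturatedPercent >= 100)
    stop("saturatedPercent must be in [0, 100)")
  px <- pixels(image)
  if (min(px) == max(px)) {
    warning("constant image cannot be normalized; returned unchanged")
    return(image)
  }
  h <- tabulate(as.vector(px) + 1L, nbins = 256L)
  n <- length(px)
  budget <- n * saturatedPercent / 100 / 2
  lo <- which(cumsum(h) > budget)[1] - 1L
  hi <- 256L - which(cumsum(rev(h)) > budget)[1]
  if (hi <= lo) { lo <- min(px); hi <- max(px) }
  out <- roundHalfAway(255 * (px - lo) / (hi - lo))
  out <- pmin(pmax(out, 0), 255)
  storage.mode(out) <- "integer"
  GrayImage(out, pitchUm(image))
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-based equalization: the image is divided into a grid of tiles of at
#' most \code{blockSize} pixels per side, each tile's histogram is clipped
#' so the equalization mapping slope never exceeds \code{maxSlope} (clipped
#' mass is redistributed uniformly), and per-pixel output is bilinearly
#' interpolated between the mappings of the four nearest tile centres.  With
#' \code{maxSlope = 1} every tile mapping collapses to the identity (up to
#' rounding); constant images stay constant.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param blockSize tile side length in pixels (default 127).
#' @param bins histogram bins per tile (default 256).
#' @param maxSlope maximum slope of the equalization mapping (default 3).
#' @return a \linkS4class{GrayImage}.
#' @export
claheEqualize <- function(image, blockSize = 127L, bins = 256L, maxSlope = 3.0) {
  stopifnot(is(image, "GrayImage"))
  if (blockSize < 3) stop("blockSize must be >= 3")
  if (bins < 2) stop("bins must be >= 2")
  if (maxSlope < 1) stop("maxSlope must be >= 1")
  px <- pixels(image)
  nr <- nrow(px); nc <- ncol(px)
  ny <- max(1L, ceiling(nr / blockSize)); nx <- max(1L, ceiling(nc / blockSize))
  # tile boundaries (near-equal split) and centres
  yb <- round(seq(0, nr, length.out = ny + 1)); xb <- round(seq(0, nc, length.out = nx + 1))
  ycen <- (yb[-1] + yb[-(ny + 1)] + 1) / 2
  xcen <- (xb[-1] + xb[-(nx + 1)] + 1) / 2
  binOf <- (px * bins) %/% 256L                    # 0-based bin index
  binOf[binOf > bins - 1L] <- bins - 1L
  # per-tile clipped-CDF mappings, evaluated mid-bin -> [0, 255]
  M <- array(0, dim = c(bins, ny, nx))
  for (ty in seq_len(ny)) for (tx in seq_len(nx)) {
    blk <- binOf[(yb[ty] + 1):yb[ty + 1], (xb[tx] + 1):xb[tx + 1]]
    h <- tabulate(as.vector(blk) + 1L, nbins = bins)
    ntile <- sum(h)
    lim <- maxSlope * ntile / bins
    # iterative clip-and-redistribute: excess mass above the limit is
    # spread over the bins still below it until the slope bound holds
    for (it in seq_len(100)) {
      excess <- sum(pmax(h - lim, 0))
      if (excess <= ntile * 1e-9) break
      h <- pmin(h, lim)
      under <- h < lim
      if (!any(under)) { h[] <- lim; break }
      h[under] <- h[under] + excess / sum(under)
    }
    h <- pmin(h, lim)
    h <- h * (ntile / sum(h))
    cdf <- cumsum(h)
    M[, ty, tx] <- 255 * (cdf - h / 2) / ntile
  }
  # bilinear interpolation between tile mappings
  iy <- findInterval(seq_len(nr), ycen)           # lower tile index (0..ny)
  iy0 <- pmax(iy, 1L); iy1 <- pmin(iy + 1L, ny)
  fy <- ifelse(iy < 1L, 0, ifelse(iy >= ny, 1,
               (seq_len(nr) - ycen[iy0]) / (ycen[iy1] - ycen[iy0])))
  fy[!is.finite(fy)] <- 0
  ix <- findInterval(seq_len(nc), xcen)
  ix0 <- pmax(ix, 1L); ix1 <- pmin(ix + 1L, nx)
  fx <- ifelse(ix < 1L, 0, ifelse(ix >= nx, 1,
               (seq_len(nc) - xcen[ix0]) / (xcen[ix1] - xcen[ix0])))
  fx[!is.finite(fx)] <- 0
  b1 <- as.vector(binOf) + 1L
  rowi <- rep(seq_len(nr), times = nc)
  coli <- rep(seq_len(nc), each = nr)
  look <- function(tyv, txv) M[cbind(b1, tyv, txv)]
  v00 <- look(iy0[rowi], ix0[coli]); v01 <- look(iy0[rowi], ix1[coli])
  v10 <- look(iy1[rowi], ix0[coli]); v11 <- look(iy1[rowi], ix1[coli])
  wy <- fy[rowi]; wx <- fx[coli]
  out <- (1 - wy) * ((1 - wx) * v00 + wx * v01) + wy * ((1 - wx) * v10 + wx * v11)
  out <- matrix(roundHalfAway(pmin(pmax(out, 0), 255)), nr, nc)
  storage.mode(out) <- "integer"
  GrayImage(out, pitchUm(image))
}

#' Construct a RigidTransform
#'
#' @param dx,dy translation in pixels (+x rightwards, +y downwards).
#' @param rotationDeg rotation in degrees about the image centre.
#' @return a \linkS4class{RigidTransform}.
#' @export
RigidTransform <- function(dx = 0, dy = 0, rotationDeg = 0) {
  new("RigidTransform", translation = c(dx, dy),
      rotationDeg = as.numeric(rotationDeg))
}

#' Apply a rigid transform to an image
#'
#' Rotates about the image centre then translates, resampling bilinearly
#' with replicate padding; the result is rounded back to 8-bit.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param transform a \linkS4class{RigidTransform}.
#' @return a \linkS4class{GrayImage}.
#' @export
applyRigid <- function(image, transform) {
  stopifnot(is(image, "GrayImage"), is(transform, "RigidTransform"))
  m <- cpp_warp_rigid(pixels(image) + 0.0, transform@translation[1],
                      transform@translation[2], transform@rotationDeg)
  px <- roundHalfAway(pmin(pmax(m, 0), 255))
  storage.mode(px) <- "integer"
  GrayImage(px, pitchUm(image))
}

# Phase correlation between two equal-sized matrices (Hann-windowed).
# Returns the sub-pixel shift (dx, dy) that moves `mov` onto `ref`, and the
# correlation peak height.
phaseCorrelate <- function(ref, mov) {
  nr <- nrow(ref); nc <- ncol(ref)
  wy <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nr) - 1) / (nr - 1))
  wx <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nc) - 1) / (nc - 1))
  w <- outer(wy, wx)
  F1 <- fft((ref - mean(ref)) * w)
  F2 <- fft((mov - mean(mov)) * w)
  R <- F1 * Conj(F2)
  mag <- Mod(R)
  R <- R / pmax(mag, 1e-12)
  r <- Re(fft(R, inverse = TRUE)) / length(R)
  pk <- which(r == max(r), arr.ind = TRUE)[1, ]
  peak <- max(r)
  # wrap indices to signed offsets
  off <- function(i, n) { v <- i - 1L; if (v > n / 2) v - n else v }
  oy <- off(pk[1], nr); ox <- off(pk[2], nc)
  # 3-point parabolic sub-pixel refinement per axis
  at <- function(dyy, dxx) {
    r[((pk[1] - 1 + dyy) %% nr) + 1, ((pk[2] - 1 + dxx) %% nc) + 1]
  }
  sub <- function(m1, m0, p1) {
    den <- m1 - 2 * m0 + p1
    if (abs(den) < 1e-12) 0 else max(-0.5, min(0.5, 0.5 * (m1 - p1) / den))
  }
  dy <- oy + sub(at(-1, 0), at(0, 0), at(1, 0))
  dx <- ox + sub(at(0, -1), at(0, 0), at(0, 1))
  list(dx = dx, dy = dy, peak = peak)
}

#' Rigid registration of a moving image onto a reference
#'
#' Estimates the translation and small rotation aligning \code{moving} to
#' \code{reference} by phase correlation combined with a rotation search
#' (coarse grid then parabolic refinement), and returns the resampled image
#' with the estimated \linkS4class{RigidTransform}.  When no correlation
#' peak can be found (e.g. constant images) the identity transform is
#' returned with a warning rather than an error, so a pipeline run never
#' aborts mid-cohort.
#'
#' @param moving,reference \linkS4class{GrayImage}s of identical dimensions.
#' @param maxRotationDeg half-width of the rotation search interval
#'   (default 2).
#' @param rotationStepDeg coarse grid step (default 0.25).
#' @return list with elements \code{image} (the registered
#'   \linkS4class{GrayImage}) and \code{transform}
#'   (\linkS4class{RigidTransform}).
#' @export
registerRigid <- function(moving, reference, maxRotationDeg = 2,
                          rotationStepDeg = 0.25) {
  stopifnot(is(moving, "GrayImage"), is(reference, "GrayImage"))
  if (!identical(dim(pixels(moving)), dim(pixels(reference))))
    stop("moving and reference must have identical dimensions")
  ref <- pixels(reference) + 0.0
  mov <- pixels(moving) + 0.0
  if (stats::sd(ref) == 0 || stats::sd(mov) == 0) {
    warning("registration failed (constant image); identity transform used")
    return(list(image = moving, transform = RigidTransform()))
  }
  score <- function(theta) {
    m <- if (theta == 0) mov else cpp_warp_rigid(mov, 0, 0, theta)
    pc <- phaseCorrelate(ref, m)
    c(pc$peak, pc$dx, pc$dy)
  }
  thetas <- seq(-maxRotationDeg, maxRotationDeg, by = rotationStepDeg)
  peaks <- vapply(thetas, function(t) score(t)[1], numeric(1))
  if (!any(is.finite(peaks)) || max(peaks) <= 0) {
    warning("registration failed (no correlation peak); identity transform used")
    return(list(image = moving, transform = RigidTransform()))
  }
  i <- which.max(peaks)
  theta <- thetas[i]
  if (i > 1 && i < length(thetas)) {     # parabolic refinement of the angle
    den <- peaks[i - 1] - 2 * peaks[i] + peaks[i + 1]
    if (abs(den) > 1e-12)
      theta <- theta + rotationStepDeg *
        max(-0.5, min(0.5, 0.5 * (peaks[i - 1] - peaks[i + 1]) / den))
  }
  rot <- if (theta == 0) mov else cpp_warp_rigid(mov, 0, 0, theta)
  pc <- phaseCorrelate(ref, rot)
  tf <- RigidTransform(dx = pc$dx, dy = pc$dy, rotationDeg = theta)
  list(image = applyRigid(moving, tf), transform = tf)
}
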