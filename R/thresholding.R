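# The eleven binarization thresholding algorithms: five global methods
# computed from the 256-bin image histogram, six local methods computed
# over a circular pixel neighbourhood with replicate padding.
#
# One tie rule is used everywhere: a pixel is white (flow) iff p > t.

GLOBAL_METHODS <- c("global_default", "global_huang", "global_isodata",
                    "global_mean", "global_otsu")
LOCAL_METHODS <- c("local_bernsen", "local_mean", "local_median",
                   "local_niblack", "local_otsu", "local_phansalkar")

#' The eleven threshold method names
#'
#' @return character vector of the five global and six local method labels.
#' @export
thresholdMethods <- function() c(GLOBAL_METHODS, LOCAL_METHODS)

#' Per-method threshold constants
#'
#' Defaults follow the conventions of the widely used auto-threshold plugin
#' family: Bernsen contrast 15, Niblack k = 0.2 and c = 0, mean/median
#' offsets 0, Phansalkar k = 0.25, r = 0.5, p = 2, q = 10.  All are
#' overridable per call.
#'
#' @param bernsen_contrast local-contrast cutoff below which a Bernsen
#'   neighbourhood is treated as single-class.
#' @param niblack_k,niblack_c Niblack t = mean + k * sd - c.
#' @param mean_c local mean t = mean - c.
#' @param median_c local median t = median - c.
#' @param phansalkar_k,phansalkar_r,phansalkar_p,phansalkar_q Phansalkar
#'   t = mean * (1 + p * exp(-q * mean) + k * (sd / r - 1)) on intensities
#'   normalized to \[0, 1\].
#' @return a named list of constants.
#' @export
thresholdParams <- function(bernsen_contrast = 15, niblack_k = 0.2,
                            niblack_c = 0, mean_c = 0, median_c = 0,
                            phansalkar_k = 0.25, phansalkar_r = 0.5,
                            phansalkar_p = 2, phansalkar_q = 10) {
  as.list(environment())
}

#' Specify a binarization threshold
#'
#' @param method one of \code{\link{thresholdMethods}()}.
#' @param radiusPx circular neighbourhood radius for local methods
#'   (default 15 px, the radius used across the prior OCTA studies whose
#'   methods this package reproduces).
#' @param params method constants from \code{\link{thresholdParams}}.
#' @return a list of class "ThresholdSpec".
#' @export
thresholdSpec <- function(method, radiusPx = 15L, params = thresholdParams()) {
  method <- match.arg(method, thresholdMethods())
  if (method %in% LOCAL_METHODS && radiusPx < 1)
    stop("radiusPx must be >= 1 for local methods")
  stopifnot(all(vapply(params, is.finite, logical(1))))
  structure(list(method = method, radiusPx = as.integer(radiusPx),
                 params = params),
            class = "ThresholdSpec")
}

#' 256-bin histogram of an 8-bit image
#'
#' @param image a \linkS4class{GrayImage}.
#' @return integer vector of 256 counts (bin i = grey level i - 1).
#' @export
histogram256 <- function(image) {
  stopifnot(is(image, "GrayImage"))
  tabulate(as.vector(pixels(image)) + 1L, nbins = 256L)
}

# ---- global threshold algorithms (histogram in, threshold t out; white
# iff p > t) ------------------------------------------------------------

# Legacy "Default": iterative intermeans that ignores the extreme occupied
# bins (grey levels 0 and 255 are zeroed before iterating), kept distinct
# from IsoData.
thresholdDefault <- function(h) {
  h <- as.numeric(h)
  h[1] <- 0; h[256] <- 0
  occ <- which(h > 0)
  if (length(occ) == 0L) return(128L)   # only extremes were occupied
  if (length(occ) == 1L) {
    warning("degenerate histogram: single occupied bin")
    return(occ[1] - 1L)
  }
  mnG <- occ[1] - 1L; mxG <- occ[length(occ)] - 1L   # grey levels
  lev <- seq_len(256) - 1L
  movingIndex <- mnG
  repeat {
    below <- (mnG + 1L):(movingIndex + 1L)           # histogram indices
    above <- (movingIndex + 2L):(mxG + 1L)
    m1 <- sum(lev[below] * h[below]) / sum(h[below])
    m2 <- sum(lev[above] * h[above]) / sum(h[above])
    result <- (m1 + m2) / 2
    movingIndex <- movingIndex + 1L
    if (!((movingIndex + 1) <= result && movingIndex < mxG - 1)) break
  }
  as.integer(round(result))
}

# Ridler-Calvard iterative intermeans to a fixpoint.
thresholdIsoData <- function(h) {
  h <- as.numeric(h)
  occ <- which(h > 0)
  if (length(occ) == 1L) {
    warning("degenerate histogram: single occupied bin")
    return(occ[1] - 1L)
  }
  lev <- seq_len(256) - 1L
  t <- as.integer(floor(sum(lev * h) / sum(h)))
  repeat {
    if (t >= 255L) break
    lo <- h[1:(t + 1)]; hi <- h[(t + 2):256]
    if (sum(lo) == 0) { t <- t + 1L; next }
    if (sum(hi) == 0) break
    m0 <- sum(lev[1:(t + 1)] * lo) / sum(lo)
    m1 <- sum(lev[(t + 2):256] * hi) / sum(hi)
    tNew <- as.integer(round((m0 + m1) / 2))
    if (tNew == t) break
    t <- tNew
  }
  t
}

# Otsu: smallest t maximizing between-class variance of {<= t} vs {> t}.
thresholdOtsu <- function(h) {
  h <- as.numeric(h)
  occ <- which(h > 0)
  if (length(occ) == 1L) {
    warning("degenerate histogram: single occupied bin")
    return(occ[1] - 1L)
  }
  lev <- seq_len(256) - 1L
  total <- sum(h); mu <- sum(lev * h)
  w0 <- cumsum(h); s0 <- cumsum(lev * h)
  w1 <- total - w0
  valid <- w0 > 0 & w1 > 0
  bc <- rep(-Inf, 256)
  bc[valid] <- w0[valid] * w1[valid] *
    (s0[valid] / w0[valid] - (mu - s0[valid]) / w1[valid])^2
  which.max(bc) - 1L     # which.max returns the first (smallest) maximizer
}

# Huang: minimize fuzzy membership entropy over candidate thresholds.
thresholdHuang <- function(h) {
  h <- as.numeric(h)
  occ <- which(h > 0)
  if (length(occ) == 1L) {
    warning("degenerate histogram: single occupied bin")
    return(occ[1] - 1L)
  }
  lev <- seq_len(256) - 1L
  first <- occ[1] - 1L; last <- occ[length(occ)] - 1L
  C <- last - first
  w0 <- cumsum(h); s0 <- cumsum(lev * h)
  total <- sum(h); stot <- sum(lev * h)
  best <- Inf; bestT <- first
  for (t in first:(last - 1)) {
    i <- t + 1L
    mu0 <- s0[i] / w0[i]
    mu1 <- (stot - s0[i]) / (total - w0[i])
    mux <- ifelse(lev <= t, 1 / (1 + abs(lev - mu0) / C),
                  1 / (1 + abs(lev - mu1) / C))
    mf <- pmin(pmax(mux, 1e-12), 1 - 1e-12)
    S <- sum(h * (-mf * log(mf) - (1 - mf) * log(1 - mf)))
    if (S < best - 1e-12) { best <- S; bestT <- t }
  }
  as.integer(bestT)
}

thresholdMean <- function(h) {
  lev <- seq_len(256) - 1L
  as.integer(floor(sum(lev * as.numeric(h)) / sum(h)))
}

#' Compute a global threshold from a 256-bin histogram
#'
#' \describe{
#'   \item{global_default}{legacy iterative intermeans that zeroes the
#'     extreme bins (grey 0 and 255) before iterating from the lowest
#'     occupied bin.}
#'   \item{global_huang}{minimizes the fuzzy membership entropy.}
#'   \item{global_isodata}{iterates t <- (mean below + mean above)/2 to a
#'     fixpoint.}
#'   \item{global_mean}{floor of the overall mean grey level.}
#'   \item{global_otsu}{maximizes between-class variance; ties broken by
#'     the smallest t.}
#' }
#' A histogram with a single occupied bin returns that bin's value with a
#' warning.  Pixels are classified white iff p > t.
#'
#' @param hist integer vector of 256 counts (see \code{\link{histogram256}}),
#'   or a \linkS4class{GrayImage}.
#' @param method a global method name.
#' @return integer threshold t in \[0, 255\].
#' @export
globalThreshold <- function(hist, method) {
  if (is(hist, "GrayImage")) hist <- histogram256(hist)
  stopifnot(length(hist) == 256L, all(hist >= 0), sum(hist) > 0)
  method <- match.arg(method, GLOBAL_METHODS)
  switch(method,
    global_default = thresholdDefault(hist),
    global_huang = thresholdHuang(hist),
    global_isodata = thresholdIsoData(hist),
    global_mean = thresholdMean(hist),
    global_otsu = thresholdOtsu(hist))
}

#' Binarize with a global threshold
#'
#' @param image a \linkS4class{GrayImage}.
#' @param spec a \code{\link{thresholdSpec}} with a global method, or a
#'   global method name.
#' @param t optional forced threshold (overrides the method).
#' @return a \linkS4class{BinaryImage}; white iff p > t.
#' @export
binarizeGlobal <- function(image, spec, t = NULL) {
  stopifnot(is(image, "GrayImage"))
  if (is.character(spec)) spec <- thresholdSpec(spec)
  if (!spec$method %in% GLOBAL_METHODS) stop("spec.method must be global")
  if (is.null(t)) t <- globalThreshold(histogram256(image), spec$method)
  BinaryImage(pixels(image) > t, pitchUm(image))
}

#' Binarize with a local threshold
#'
#' The neighbourhood of a pixel is the circular disc dx^2 + dy^2 <=
#' radius^2 around it, with replicate padding at the image border.
#' Per-method threshold:
#' \describe{
#'   \item{local_bernsen}{midgray = (max + min)/2.  If local contrast
#'     (max - min) < \code{bernsen_contrast} the whole neighbourhood is
#'     single-class: white iff midgray >= 128.  Otherwise t = midgray.}
#'   \item{local_mean}{t = mean - mean_c.}
#'   \item{local_median}{t = median - median_c (lower median of the disc).}
#'   \item{local_niblack}{t = mean + niblack_k * sd - niblack_c
#'     (population sd).}
#'   \item{local_otsu}{Otsu's criterion on the neighbourhood histogram.}
#'   \item{local_phansalkar}{t = m * (1 + p * exp(-q * m) + k * (s/r - 1))
#'     with mean m and sd s computed on intensities normalized to \[0, 1\].}
#' }
#' Except for Bernsen's low-contrast branch, a pixel is white iff p > t.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param spec a \code{\link{thresholdSpec}} with a local method, or a local
#'   method name (radius 15, default constants).
#' @param fields optional precomputed neighbourhood statistics from
#'   \code{\link{localFields}} for this image, radius and border mode, so
#'   several local methods can share one neighbourhood pass.
#' @param border "replicate" (default; out-of-image neighbours take the
#'   nearest edge value, the plugin-family convention) or "clip" (the
#'   neighbourhood is intersected with the image, under which a radius
#'   covering the whole image makes each local method coincide with its
#'   global counterpart).
#' @return a \linkS4class{BinaryImage}.
#' @export
binarizeLocal <- function(image, spec, fields = NULL,
                          border = c("replicate", "clip")) {
  stopifnot(is(image, "GrayImage"))
  border <- match.arg(border)
  if (is.character(spec)) spec <- thresholdSpec(spec)
  if (!spec$method %in% LOCAL_METHODS) stop("spec.method must be local")
  px <- pixels(image)
  if (border == "replicate" && spec$radiusPx >= min(dim(px)))
    stop("radius must be smaller than the image")
  prm <- spec$params
  if (spec$method == "local_otsu") {
    t <- cpp_local_otsu(px, spec$radiusPx, border == "clip")
    return(BinaryImage(px > t, pitchUm(image)))
  }
  f <- if (is.null(fields)) cpp_local_fields(px, spec$radiusPx, border == "clip")
       else fields
  white <- switch(spec$method,
    local_mean = px > f$mean - prm$mean_c,
    local_median = px > f$median - prm$median_c,
    local_niblack = px > f$mean + prm$niblack_k * f$sd - prm$niblack_c,
    local_phansalkar = {
      m <- f$mean / 255; s <- f$sd / 255
      t <- m * (1 + prm$phansalkar_p * exp(-prm$phansalkar_q * m) +
                  prm$phansalkar_k * (s / prm$phansalkar_r - 1))
      px / 255 > t
    },
    local_bernsen = {
      midgray <- (f$max + f$min) / 2
      lowContrast <- (f$max - f$min) < prm$bernsen_contrast
      ifelse(lowContrast, midgray >= 128, px > midgray)
    })
  white <- matrix(as.logical(white), nrow(px), ncol(px))
  BinaryImage(white, pitchUm(image))
}

#' Circular-neighbourhood statistics of an image
#'
#' Per-pixel mean, population sd, min, max and lower median over the disc
#' dx^2 + dy^2 <= radius^2 with replicate padding.  These drive the local
#' threshold formulas; computing them once and passing the result to
#' \code{\link{binarizeLocal}} lets several methods share the pass.
#'
#' @param image a \linkS4class{GrayImage}.
#' @param radiusPx disc radius in pixels.
#' @param border "replicate" or "clip" (see \code{\link{binarizeLocal}}).
#' @return list with matrices mean, sd, min, max, median and the per-pixel
#'   neighbourhood count n.
#' @export
localFields <- function(image, radiusPx = 15L,
                        border = c("replicate", "clip")) {
  stopifnot(is(image, "GrayImage"))
  border <- match.arg(border)
  cpp_local_fields(pixels(image), as.integer(radiusPx), border == "clip")
}

#' Binarize with any of the eleven methods
#'
#' Dispatches to \code{\link{binarizeGlobal}} or \code{\link{binarizeLocal}}
#' according to the method name.
#'
#' @inheritParams binarizeLocal
#' @return a \linkS4class{BinaryImage}.
#' @export
binarizeImage <- function(image, spec, fields = NULL,
                          border = c("replicate", "clip")) {
  if (is.character(spec)) spec <- thresholdSpec(spec)
  if (spec$method %in% GLOBAL_METHODS) binarizeGlobal(image, spec)
  else binarizeLocal(image, spec, fields = fields, border = border)
}
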