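# Quantification of binarized angiograms: vessel area density, skeleton
# vessel length, choriocapillaris flow-deficit statistics.

#' Vessel area density
#'
#' The percentage of white (flow) pixels in a binarized angiogram.
#'
#' @param binary a \linkS4class{BinaryImage}.
#' @return percentage in \[0, 100\].
#' @examples
#' b <- BinaryImage(matrix(c(TRUE, FALSE), 2, 2), 10)
#' vesselAreaDensity(b)  # 50
#' @export
vesselAreaDensity <- function(binary) {
  stopifnot(is(binary, "BinaryImage"))
  100 * mean(pixels(binary))
}

#' Skeletonize a binary vessel mask
#'
#' Iterative binary thinning (Zhang-Suen) to 1-px-wide medial lines.  The
#' skeleton is a subset of the source foreground, preserves 8-connectivity
#' of its components, and thinning is idempotent.
#'
#' @param binary a \linkS4class{BinaryImage}.
#' @return a \linkS4class{SkeletonImage}.
#' @export
skeletonize <- function(binary) {
  stopifnot(is(binary, "BinaryImage"))
  px <- pixels(binary)
  sk <- cpp_thin(px)
  # simultaneous deletion can erase a tiny blob outright; its medial axis
  # is a single pixel, so retain one per vanished component
  lab <- cpp_label(px, 8L)
  if (max(lab) > 0L) {
    kept <- unique(lab[sk])
    lost <- setdiff(seq_len(max(lab)), kept[kept > 0])
    for (l in lost) {
      idx <- which(lab == l)
      sk[idx[ceiling(length(idx) / 2)]] <- TRUE
    }
  }
  new("SkeletonImage", pixels = sk, pitchUm = pitchUm(binary))
}

#' Vessel length from a skeleton
#'
#' The default counts skeleton pixels (the tag-and-count convention of
#' skeleton analysis plugins); mode "euclidean" instead sums per-step
#' distances between 8-adjacent skeleton pixels (1 for orthogonal, sqrt(2)
#' for diagonal neighbours, each adjacent pair counted once).  Calibrated
#' length in micrometres is pixel count (or step sum) times the pixel
#' pitch.
#'
#' @param skeleton a \linkS4class{SkeletonImage}.
#' @param mode "pixels" (default) or "euclidean".
#' @return list with \code{length_px} and \code{length_um}.
#' @export
vesselLength <- function(skeleton, mode = c("pixels", "euclidean")) {
  stopifnot(is(skeleton, "SkeletonImage"))
  mode <- match.arg(mode)
  m <- pixels(skeleton)
  if (mode == "pixels") {
    n <- sum(m)
    return(list(length_px = n, length_um = n * pitchUm(skeleton)))
  }
  nr <- nrow(m); nc <- ncol(m)
  # each unordered adjacent pair once: E, S, SE, SW offsets
  pair <- function(dy, dx, w) {
    a <- m[seq_len(nr - abs(dy)) + max(0, -dy), seq_len(nc - abs(dx)) + max(0, -dx)]
    b <- m[seq_len(nr - abs(dy)) + max(0, dy), seq_len(nc - abs(dx)) + max(0, dx)]
    w * sum(a & b)
  }
  len <- pair(0, 1, 1) + pair(1, 0, 1) + pair(1, 1, sqrt(2)) + pair(1, -1, sqrt(2))
  list(length_px = len, length_um = len * pitchUm(skeleton))
}

#' Label connected components
#'
#' @param mask logical matrix or \linkS4class{BinaryImage}.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of component labels (0 = background).
#' @export
labelComponents <- function(mask, connectivity = 8) {
  if (is(mask, "BinaryImage")) mask <- pixels(mask)
  stopifnot(is.logical(mask), connectivity %in% c(4, 8))
  cpp_label(mask, as.integer(connectivity))
}

#' Flow-deficit statistics of a binarized choriocapillaris image
#'
#' The binarized CC image is inverted (deficits = black pixels become the
#' foreground) and its 8-connected components are counted; no size filter
#' is applied and components touching the image edge are included (both
#' choices can be changed).  With zero deficits the mean size is undefined
#' and reported as NA, never as 0.
#'
#' @param binaryCC a \linkS4class{BinaryImage} from a CC angiogram.
#' @param minSizePx2 drop components smaller than this area (default 0 =
#'   keep all).
#' @param includeEdge keep components touching the image border
#'   (default TRUE).
#' @return list with \code{fd_count}, \code{fd_mean_size_px2},
#'   \code{fd_mean_size_um2}.
#' @export
flowDeficits <- function(binaryCC, minSizePx2 = 0, includeEdge = TRUE) {
  stopifnot(is(binaryCC, "BinaryImage"))
  lab <- cpp_label(!pixels(binaryCC), 8L)
  sizes <- tabulate(lab[lab > 0])
  if (!includeEdge && length(sizes)) {
    edge <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    edge <- edge[edge > 0]
    sizes <- sizes[setdiff(seq_along(sizes), edge)]
  }
  sizes <- sizes[sizes >= max(1, minSizePx2)]
  if (length(sizes) == 0L)
    return(list(fd_count = 0L, fd_mean_size_px2 = NA_real_,
                fd_mean_size_um2 = NA_real_))
  list(fd_count = length(sizes),
       fd_mean_size_px2 = mean(sizes),
       fd_mean_size_um2 = mean(sizes) * pitchUm(binaryCC)^2)
}

#' Quantify one binarized image
#'
#' Computes the metric set appropriate to the plexus: VAD for all slabs,
#' vessel length for retinal slabs (FRL/SCP/DCP), flow-deficit count and
#' mean size for CC.
#'
#' @param binary a \linkS4class{BinaryImage}.
#' @param plexus one of FRL/SCP/DCP/CC.
#' @return one-row data.frame with columns vad, vl_px, vl_um, fd_count,
#'   fd_mean_px2, fd_mean_um2 (NA where not applicable).
#' @export
metricRecord <- function(binary, plexus) {
  stopifnot(plexus %in% c("FRL", "SCP", "DCP", "CC"))
  vad <- vesselAreaDensity(binary)
  vl_px <- vl_um <- fd_count <- fd_mean_px2 <- fd_mean_um2 <- NA_real_
  if (plexus == "CC") {
    fd <- flowDeficits(binary)
    fd_count <- fd$fd_count
    fd_mean_px2 <- fd$fd_mean_size_px2
    fd_mean_um2 <- fd$fd_mean_size_um2
  } else {
    vl <- vesselLength(skeletonize(binary))
    vl_px <- vl$length_px
    vl_um <- vl$length_um
  }
  data.frame(vad = vad, vl_px = vl_px, vl_um = vl_um, fd_count = fd_count,
             fd_mean_px2 = fd_mean_px2, fd_mean_um2 = fd_mean_um2)
}
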