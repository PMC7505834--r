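# Canonical image types, device profiles and raster I/O.

#' Construct a GrayImage
#'
#' @param pixels numeric or integer matrix with values in \[0, 255\];
#'   non-integer values are rejected (convert first with
#'   \code{\link{asEightBit}}).
#' @param pitchUm physical pixel pitch in micrometres.
#' @return a \linkS4class{GrayImage}.
#' @export
GrayImage <- function(pixels, pitchUm) {
  storage.mode(pixels) <- "integer"
  new("GrayImage", pixels = pixels, pitchUm = as.numeric(pitchUm))
}

#' Construct a BinaryImage
#'
#' @param pixels logical matrix (TRUE = white = flow) or 0/1 matrix.
#' @param pitchUm physical pixel pitch in micrometres.
#' @return a \linkS4class{BinaryImage}.
#' @export
BinaryImage <- function(pixels, pitchUm) {
  if (!is.logical(pixels)) {
    if (!all(pixels %in% c(0, 1))) stop("binary pixels must be 0/1 or logical")
    pixels <- array(pixels != 0, dim = dim(pixels))
  }
  new("BinaryImage", pixels = pixels, pitchUm = as.numeric(pitchUm))
}

#' Construct a DeviceProfile
#'
#' Profiles for the three devices whose 3 x 3 mm exports the local threshold
#' radius was calibrated against are available via \code{standardProfiles()}.
#'
#' @param name device label.
#' @param imageSizePx side length of the square export in pixels.
#' @param scanSizeMm physical field width in millimetres (default 3).
#' @return a \linkS4class{DeviceProfile}.
#' @examples
#' pitchUm(DeviceProfile("PLEX", 1024))   # ~2.93 um
#' @export
DeviceProfile <- function(name, imageSizePx, scanSizeMm = 3.0) {
  new("DeviceProfile", name = as.character(name),
      imageSizePx = as.integer(imageSizePx), scanSizeMm = as.numeric(scanSizeMm))
}

#' The three 3 x 3 mm device export grids studied
#'
#' @return a named list of \linkS4class{DeviceProfile}: PLEX (1024 px),
#'   Cirrus (429 px), Avanti (304 px), each over a 3 mm field.
#' @export
standardProfiles <- function() {
  list(PLEX   = DeviceProfile("PLEX", 1024L),
       Cirrus = DeviceProfile("Cirrus", 429L),
       Avanti = DeviceProfile("Avanti", 304L))
}

#' Convert a local-threshold radius from pixels to micrometres
#'
#' A fixed pixel radius corresponds to different physical neighbourhood
#' sizes on devices with different export resolutions: 15 px is 43.9 um on a
#' 1024-px 3-mm grid but 148.0 um on a 304-px grid.
#'
#' @param radiusPx radius in pixels (positive).
#' @param profile a \linkS4class{DeviceProfile}.
#' @param digits decimals to report (default 1, the convention used when
#'   quoting neighbourhood sizes).
#' @return the radius in micrometres, rounded to \code{digits}.
#' @examples
#' pixelRadiusToUm(15, DeviceProfile("PLEX", 1024))   # 43.9
#' pixelRadiusToUm(15, DeviceProfile("Avanti", 304))  # 148.0
#' @export
pixelRadiusToUm <- function(radiusPx, profile, digits = 1) {
  if (length(radiusPx) != 1L || !is.finite(radiusPx) || radiusPx <= 0)
    stop("radiusPx must be a single positive number")
  round(radiusPx * pitchUm(profile), digits)
}

# Round half away from zero (8-bit image arithmetic convention; R's round()
# is half-to-even).
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Rescale an arbitrary numeric raster to 8-bit
#'
#' Linear rescale to \[0, 255\] by max-range division, then rounding half
#' away from zero.  Matrices already within \[0, 255\] integer range are
#' returned unchanged; 16-bit rasters are divided by 257 (65535/255);
#' \[0, 1\] float rasters are multiplied by 255.
#'
#' @param mat numeric matrix.
#' @return integer matrix in \[0, 255\].
#' @export
asEightBit <- function(mat) {
  if (anyNA(mat)) stop("raster contains NA")
  mx <- max(mat); mn <- min(mat)
  if (mn < 0) stop("raster contains negative values")
  if (mx <= 255 && all(mat == round(mat))) {
    storage.mode(mat) <- "integer"
    return(mat)
  }
  den <- if (mx <= 1) 1 else if (mx <= 255) 255 else if (mx <= 65535) 65535 else mx
  out <- roundHalfAway(mat / den * 255)
  storage.mode(out) <- "integer"
  out
}

#' Read an en-face angiogram from PNG or TIFF
#'
#' Multi-channel rasters are converted to luminance (0.2126 R + 0.7152 G +
#' 0.0722 B) with a warning; bit depths other than 8 are rescaled to
#' \[0, 255\] by max-range division.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @param profile a \linkS4class{DeviceProfile} supplying the physical pitch.
#' @return a \linkS4class{GrayImage}.
#' @export
loadImage <- function(path, profile) {
  if (!file.exists(path)) stop("cannot read '", path, "': file does not exist")
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: .", ext))
  if (length(dim(raw)) == 3L) {
    warning("multi-channel raster converted to luminance")
    nch <- dim(raw)[3]
    raw <- if (nch >= 3)
      0.2126 * raw[, , 1] + 0.7152 * raw[, , 2] + 0.0722 * raw[, , 3]
    else raw[, , 1]
  }
  # readPNG/readTIFF return [0, 1] doubles
  px <- roundHalfAway(raw * 255)
  storage.mode(px) <- "integer"
  GrayImage(px, pitchUm(profile))
}

#' Write a GrayImage or BinaryImage to PNG or TIFF
#'
#' Binary images are written as 0/255.  The round trip
#' \code{loadImage(saveImage(x))} is lossless for 8-bit content.
#'
#' @param image a \linkS4class{GrayImage} or \linkS4class{BinaryImage}.
#' @param path output path ending in .png, .tif or .tiff.
#' @return \code{path}, invisibly.
#' @export
saveImage <- function(image, path) {
  px <- pixels(image)
  if (is.logical(px)) px <- px * 255L
  arr <- px / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(arr, path),
    tif = ,
    tiff = tiff::writeTIFF(arr, path, bits.per.sample = 8L),
    stop("unsupported raster format: .", ext))
  invisible(path)
}

#' Write a cohort to disk as PNG files plus a manifest CSV
#'
#' The manifest has columns subject_id, repeat, plexus, device, processing,
#' path; truth masks (when present) are written alongside as
#' \code{truth_<subject>_<mask>.png}.
#'
#' @param cohort a \linkS4class{CohortDataset}.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
saveCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  info <- cohortInfo(cohort)
  paths <- character(nrow(info))
  for (i in seq_len(nrow(info))) {
    paths[i] <- file.path(dir, sprintf("%s_r%d_%s_%s.png",
      info$subject_id[i], info$repeat_index[i], info$plexus[i], info$device[i]))
    saveImage(cohortImages(cohort)[[i]], paths[i])
  }
  tr <- cohortTruths(cohort)
  pitch <- pitchUm(cohortImages(cohort)[[1]])
  for (s in names(tr)) {
    for (m in c("fazMask", "vesselMask", "deficitMask")) {
      msk <- slot(tr[[s]], m)
      if (any(msk))
        saveImage(BinaryImage(msk, pitch),
                  file.path(dir, sprintf("truth_%s_%s.png", s, m)))
    }
  }
  man <- cbind(info, path = paths)
  names(man)[names(man) == "repeat_index"] <- "repeat"
  mp <- file.path(dir, "manifest.csv")
  write.csv(man, mp, row.names = FALSE)
  invisible(mp)
}

#' Read a cohort back from a manifest CSV
#'
#' @param manifestPath path to a manifest written by \code{\link{saveCohort}}.
#' @param profile a \linkS4class{DeviceProfile} for the pixel pitch.
#' @return a \linkS4class{CohortDataset} (without truth masks).
#' @export
loadCohort <- function(manifestPath, profile) {
  man <- read.csv(manifestPath, stringsAsFactors = FALSE, check.names = FALSE)
  names(man)[names(man) == "repeat"] <- "repeat_index"
  imgs <- lapply(man$path, loadImage, profile = profile)
  new("CohortDataset",
      info = man[c("subject_id", "repeat_index", "plexus", "device", "processing")],
      images = imgs, truths = list())
}
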