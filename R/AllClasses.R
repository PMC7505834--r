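#' @useDynLib octarep, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif rpois quantile sd median fft nextn lm anova
#' @importFrom utils write.csv read.csv
NULL

#' GrayImage: an 8-bit en-face angiogram
#'
#' A 2-D raster of integer intensities in \[0, 255\] together with the
#' physical size of one pixel.  En-face OCTA scans are square
#' (e.g. 1024 x 1024 px covering a 3 x 3 mm field); non-square matrices are
#' permitted so that small crafted fixtures can be represented.
#'
#' @slot pixels integer matrix, values in \[0, 255\]; rows are y (downwards),
#'   columns are x (rightwards), origin at the top-left.
#' @slot pitchUm physical width of one pixel in micrometres.
#' @export
setClass("GrayImage",
  representation(pixels = "matrix", pitchUm = "numeric"),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p)) return("pixels must be a numeric/integer matrix")
    if (anyNA(p)) return("pixels must not contain NA")
    if (any(p < 0 | p > 255)) return("pixel values must lie in [0, 255]")
    if (any(p != round(p))) return("pixel values must be integers")
    if (length(object@pitchUm) != 1L || !is.finite(object@pitchUm) ||
        object@pitchUm <= 0) return("pitchUm must be a single positive number")
    TRUE
  })

#' BinaryImage: a flow mask
#'
#' White (TRUE) pixels denote flow; black (FALSE) pixels denote no flow.
#'
#' @slot pixels logical matrix, same dimensions as the source image.
#' @slot pitchUm physical width of one pixel in micrometres.
#' @export
setClass("BinaryImage",
  representation(pixels = "matrix", pitchUm = "numeric"),
  validity = function(object) {
    if (!is.logical(object@pixels)) return("pixels must be a logical matrix")
    if (anyNA(object@pixels)) return("pixels must not contain NA")
    if (length(object@pitchUm) != 1L || !is.finite(object@pitchUm) ||
        object@pitchUm <= 0) return("pitchUm must be a single positive number")
    TRUE
  })

#' SkeletonImage: a 1-px-wide thinned vessel mask
#'
#' @slot pixels logical matrix of medial-line pixels.
#' @slot pitchUm physical width of one pixel in micrometres.
#' @export
setClass("SkeletonImage", contains = "BinaryImage")

#' DeviceProfile: pixel grid and physical field of an OCTA device export
#'
#' @slot name device label (e.g. "PLEX").
#' @slot imageSizePx side length of the square en-face export in pixels.
#' @slot scanSizeMm physical field width in millimetres (3.0 for the 3 x 3 mm
#'   scans analysed here).
#' @export
setClass("DeviceProfile",
  representation(name = "character", imageSizePx = "integer",
                 scanSizeMm = "numeric"),
  validity = function(object) {
    if (length(object@imageSizePx) != 1L || object@imageSizePx < 1L)
      return("imageSizePx must be a single positive integer")
    if (length(object@scanSizeMm) != 1L || object@scanSizeMm <= 0)
      return("scanSizeMm must be a single positive number")
    TRUE
  })

#' RigidTransform: translation plus rotation
#'
#' @slot translation numeric length-2 vector (dx, dy) in pixels; +x moves
#'   content rightwards (columns), +y downwards (rows).
#' @slot rotationDeg rotation angle in degrees about the image centre.
#' @export
setClass("RigidTransform",
  representation(translation = "numeric", rotationDeg = "numeric"),
  validity = function(object) {
    if (length(object@translation) != 2L) return("translation must have length 2")
    if (length(object@rotationDeg) != 1L) return("rotationDeg must have length 1")
    TRUE
  })

#' PhantomTruth: ground-truth masks of a synthetic angiogram
#'
#' @slot fazMask logical matrix marking the foveal avascular zone (retinal
#'   phantoms; all-FALSE otherwise).
#' @slot vesselMask logical matrix of true vessel pixels.
#' @slot deficitMask logical matrix of true choriocapillaris flow deficits.
#' @export
setClass("PhantomTruth",
  representation(fazMask = "matrix", vesselMask = "matrix",
                 deficitMask = "matrix"),
  validity = function(object) {
    if (any(object@fazMask & object@vesselMask))
      return("fazMask and vesselMask must be disjoint")
    TRUE
  })

#' CohortDataset: subjects x repeats grid of images with provenance
#'
#' @slot info data.frame with one row per image: subject_id, repeat_index,
#'   plexus, device, processing.
#' @slot images list of \linkS4class{GrayImage}, parallel to \code{info}.
#' @slot truths named list of \linkS4class{PhantomTruth}, one per subject
#'   (synthetic cohorts only; may be empty).
#' @export
setClass("CohortDataset",
  representation(info = "data.frame", images = "list", truths = "list"),
  validity = function(object) {
    need <- c("subject_id", "repeat_index", "plexus", "device", "processing")
    if (!all(need %in% names(object@info)))
      return(paste("info must have columns:", paste(need, collapse = ", ")))
    if (nrow(object@info) != length(object@images))
      return("info rows and images must be parallel")
    key <- do.call(paste, c(object@info[need], sep = "\r"))
    if (anyDuplicated(key))
      return("(subject_id, repeat_index, plexus, device, processing) must be unique")
    reps <- table(object@info$subject_id)
    if (length(unique(reps)) > 1L)
      return("every subject must have the same number of repeats")
    TRUE
  })

#' ICCResult: an intraclass correlation estimate with its ANOVA
#'
#' @slot icc the ICC estimate (NA when the grid has zero total variance).
#' @slot model "oneway_random", "twoway_mixed" (consistency) or
#'   "twoway_agreement".
#' @slot anova data.frame of sums of squares, degrees of freedom and mean
#'   squares for the variance decomposition.
#' @slot classification "high" (> 0.80), "moderate" or "low" (< 0.50).
#' @slot n number of subjects (rows); @slot k measurements per subject.
#' @export
setClass("ICCResult",
  representation(icc = "numeric", model = "character", anova = "data.frame",
                 classification = "character", n = "integer", k = "integer"),
  validity = function(object) {
    if (!object@model %in% c("oneway_random", "twoway_mixed", "twoway_agreement"))
      return("unknown model")
    if (!is.na(object@icc) && object@icc > 1 + 1e-12)
      return("ICC cannot exceed 1")
    TRUE
  })

#' ExperimentConfig: one factorial repeatability run
#'
#' @slot nSubjects,nRepeats cohort size.
#' @slot plexuses subset of FRL/SCP/DCP/CC.
#' @slot profiles list of \linkS4class{DeviceProfile}.
#' @slot sizePx phantom side length in pixels (scaled-down grids are used so
#'   a full factorial stays tractable; the physical pitch follows the
#'   profile's scan size).
#' @slot population list of population-level parameter distributions for
#'   subject draws (see \code{\link{makeCohort}}).
#' @slot jitter list of acquisition-jitter scales (see
#'   \code{\link{cohortJitter}}).
#' @slot processing subset of none/contrast_1.5/contrast_2.0/normalize/
#'   clahe/register.
#' @slot methods threshold method names (see \code{\link{thresholdMethods}}).
#' @slot radiusPx local threshold radius in pixels.
#' @slot contrastGains gains for the contrast-repeatability grids.
#' @slot masterSeed integer seed governing the whole run.
#' @export
setClass("ExperimentConfig",
  representation(nSubjects = "integer", nRepeats = "integer",
                 plexuses = "character", profiles = "list",
                 sizePx = "integer", population = "list", jitter = "list",
                 processing = "character", methods = "character",
                 radiusPx = "integer", contrastGains = "numeric",
                 masterSeed = "integer"))

#' ResultsBundle: all tables from one experiment run
#'
#' @slot metrics per-image metric table (long format).
#' @slot repeatICC repeat-acquisition ICC table (one-way random model).
#' @slot deltaICC ICC(processed) - ICC(unprocessed) per processing step.
#' @slot contrastICC averaged two-way mixed ICC across contrast gains.
#' @slot manifest list of seeds, parameters and package version sufficient
#'   to reproduce the run bit-exactly.
#' @export
setClass("ResultsBundle",
  representation(metrics = "data.frame", repeatICC = "data.frame",
                 deltaICC = "data.frame", contrastICC = "data.frame",
                 manifest = "list"))
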