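#' @rdname pixels
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setGeneric("pitchUm", function(x) standardGeneric("pitchUm"))

#' Accessors for image objects
#'
#' \code{pixels} returns the raw pixel matrix (integer for
#' \linkS4class{GrayImage}, logical for \linkS4class{BinaryImage});
#' \code{pitchUm} the physical pixel pitch in micrometres.
#'
#' @param x a \linkS4class{GrayImage}, \linkS4class{BinaryImage} or
#'   \linkS4class{DeviceProfile}.
#' @return \code{pixels}: a matrix; \code{pitchUm}: a single number.
#' @name pixels
#' @aliases pitchUm
#' @examples
#' img <- GrayImage(matrix(0L, 8, 8), pitchUm = 9.87)
#' dim(pixels(img))
#' pitchUm(img)
NULL

setMethod("pixels", "GrayImage", function(x) x@pixels)
setMethod("pixels", "BinaryImage", function(x) x@pixels)
setMethod("pitchUm", "GrayImage", function(x) x@pitchUm)
setMethod("pitchUm", "BinaryImage", function(x) x@pitchUm)
setMethod("pitchUm", "DeviceProfile",
          function(x) x@scanSizeMm * 1000 / x@imageSizePx)

setMethod("show", "GrayImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("GrayImage %d x %d px, pitch %.2f um, intensity range [%d, %d]\n",
              d[2], d[1], object@pitchUm, min(object@pixels), max(object@pixels)))
})

setMethod("show", "BinaryImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("%s %d x %d px, pitch %.2f um, %.2f%% white\n",
              class(object), d[2], d[1], object@pitchUm,
              100 * mean(object@pixels)))
})

setMethod("show", "DeviceProfile", function(object) {
  cat(sprintf("DeviceProfile '%s': %d x %d px over %.1f x %.1f mm (pitch %.2f um)\n",
              object@name, object@imageSizePx, object@imageSizePx,
              object@scanSizeMm, object@scanSizeMm, pitchUm(object)))
})

setMethod("show", "ICCResult", function(object) {
  cat(sprintf("ICC (%s): %s  [%s]  n = %d subjects, k = %d\n",
              object@model,
              if (is.na(object@icc)) "undefined (zero variance)"
              else sprintf("%.4f", object@icc),
              object@classification, object@n, object@k))
})

setMethod("show", "CohortDataset", function(object) {
  cat(sprintf("CohortDataset: %d images, %d subjects x %d repeats (%s / %s / %s)\n",
              nrow(object@info), length(unique(object@info$subject_id)),
              max(object@info$repeat_index),
              paste(unique(object@info$plexus), collapse = ","),
              paste(unique(object@info$device), collapse = ","),
              paste(unique(object@info$processing), collapse = ",")))
})

setMethod("show", "ResultsBundle", function(object) {
  cat("ResultsBundle\n")
  cat(sprintf("  metrics:     %d rows\n", nrow(object@metrics)))
  cat(sprintf("  repeatICC:   %d rows\n", nrow(object@repeatICC)))
  cat(sprintf("  deltaICC:    %d rows\n", nrow(object@deltaICC)))
  cat(sprintf("  contrastICC: %d rows\n", nrow(object@contrastICC)))
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: dx = %+.3f px, dy = %+.3f px, theta = %+.3f deg\n",
              object@translation[1], object@translation[2], object@rotationDeg))
})

#' @rdname CohortDataset-access
#' @export
setGeneric("cohortInfo", function(x) standardGeneric("cohortInfo"))

#' @rdname CohortDataset-access
#' @export
setGeneric("cohortImages", function(x) standardGeneric("cohortImages"))

#' @rdname CohortDataset-access
#' @export
setGeneric("cohortTruths", function(x) standardGeneric("cohortTruths"))

#' Access the parts of a CohortDataset
#'
#' @param x a \linkS4class{CohortDataset}.
#' @return \code{cohortInfo}: the provenance data.frame; \code{cohortImages}:
#'   the list of \linkS4class{GrayImage}; \code{cohortTruths}: the per-subject
#'   \linkS4class{PhantomTruth} list.
#' @name CohortDataset-access
NULL

setMethod("cohortInfo", "CohortDataset", function(x) x@info)
setMethod("cohortImages", "CohortDataset", function(x) x@images)
setMethod("cohortTruths", "CohortDataset", function(x) x@truths)

#' @rdname ICCResult-access
#' @export
setGeneric("iccValue", function(x) standardGeneric("iccValue"))

#' @rdname ICCResult-access
#' @export
setGeneric("iccAnova", function(x) standardGeneric("iccAnova"))

#' Access the parts of an ICCResult
#'
#' @param x an \linkS4class{ICCResult}.
#' @return \code{iccValue}: the estimate (possibly NA); \code{iccAnova}: the
#'   mean-square decomposition as a data.frame.
#' @name ICCResult-access
NULL

setMethod("iccValue", "ICCResult", function(x) x@icc)
setMethod("iccAnova", "ICCResult", function(x) x@anova)
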