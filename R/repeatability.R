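# ICC estimation from ANOVA mean squares, repeatability classification,
# contrast-change repeatability, and delta-ICC reporting.

checkGrid <- function(grid) {
  grid <- as.matrix(grid)
  if (!is.numeric(grid)) stop("grid must be numeric")
  if (anyNA(grid)) stop("grid must have no missing cells (apply listwise deletion first)")
  if (nrow(grid) < 2) stop("need at least 2 subjects (rows)")
  if (ncol(grid) < 2) stop("need at least 2 measurements per subject (columns)")
  grid
}

classLabel <- function(icc) {
  if (is.na(icc)) return("undefined")
  if (icc > 0.80) "high" else if (icc < 0.50) "low" else "moderate"
}

#' One-way random effects ICC
#'
#' ICC(1) = (MSB - MSW) / (MSB + (k - 1) MSW) from the one-way ANOVA of a
#' subjects x repeats grid, where MSB is the between-subject and MSW the
#' within-subject mean square.  This is the model for repeatability across
#' multiple acquisitions of the same eye: it estimates the proportion of
#' total variation attributable to between-subject variation.  Negative
#' estimates (bounded below by -1/(k-1)) are retained, not truncated; they
#' indicate low repeatability.  A grid with zero total variance has an
#' undefined ICC, reported as NA with a warning.
#'
#' @param grid numeric matrix, subjects in rows, repeat acquisitions in
#'   columns, no missing cells.
#' @return an \linkS4class{ICCResult}.
#' @export
iccOneway <- function(grid) {
  grid <- checkGrid(grid)
  n <- nrow(grid); k <- ncol(grid)
  grand <- mean(grid)
  rm_ <- rowMeans(grid)
  ssb <- k * sum((rm_ - grand)^2)
  ssw <- sum((grid - rm_)^2)
  dfb <- n - 1L; dfw <- n * (k - 1L)
  msb <- ssb / dfb; msw <- ssw / dfw
  an <- data.frame(source = c("between_subjects", "within_subjects"),
                   ss = c(ssb, ssw), df = c(dfb, dfw), ms = c(msb, msw))
  if (ssb + ssw == 0) {
    warning("zero total variance: ICC undefined")
    icc <- NA_real_
  } else {
    icc <- (msb - msw) / (msb + (k - 1) * msw)
  }
  new("ICCResult", icc = icc, model = "oneway_random", anova = an,
      classification = classLabel(icc), n = as.integer(n), k = as.integer(k))
}

#' Two-way mixed effects ICC
#'
#' Single-rater ICC from the two-way ANOVA of a subjects x conditions grid
#' with fixed column (condition) effects.  The default, consistency
#' ICC(3,1) = (MSR - MSE) / (MSR + (k - 1) MSE), ignores systematic
#' per-condition shifts, which is the natural choice when the conditions
#' are fixed contrast levels applied to the same image; absolute-agreement
#' ICC(2,1) is available via \code{type = "agreement"}.  Zero-variance
#' grids give NA with a warning; negative estimates are retained.
#'
#' @param grid numeric matrix, subjects in rows, conditions (e.g. contrast
#'   gains) in columns.
#' @param type "consistency" (default) or "agreement".
#' @return an \linkS4class{ICCResult}.
#' @export
iccTwowayMixed <- function(grid, type = c("consistency", "agreement")) {
  type <- match.arg(type)
  grid <- checkGrid(grid)
  n <- nrow(grid); k <- ncol(grid)
  grand <- mean(grid)
  rm_ <- rowMeans(grid); cm_ <- colMeans(grid)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  sst <- sum((grid - grand)^2)
  sse <- sst - ssr - ssc
  dfr <- n - 1L; dfc <- k - 1L; dfe <- (n - 1L) * (k - 1L)
  msr <- ssr / dfr; msc <- ssc / dfc; mse <- sse / dfe
  an <- data.frame(source = c("rows", "columns", "error"),
                   ss = c(ssr, ssc, sse), df = c(dfr, dfc, dfe),
                   ms = c(msr, msc, mse))
  if (sst == 0) {
    warning("zero total variance: ICC undefined")
    icc <- NA_real_
    model <- if (type == "consistency") "twoway_mixed" else "twoway_agreement"
  } else if (type == "consistency") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    model <- "twoway_mixed"
    if (msr == 0 && mse == 0) { warning("zero subject and error variance: ICC undefined"); icc <- NA_real_ }
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
    model <- "twoway_agreement"
  }
  new("ICCResult", icc = icc, model = model, anova = an,
      classification = classLabel(icc), n = as.integer(n), k = as.integer(k))
}

#' Averaged contrast-change repeatability
#'
#' Repeatability across contrast gains is assessed per repeat image: each
#' grid holds one metric for subjects x contrast levels of the same repeat
#' acquisition; the two-way mixed (consistency) ICC is computed per grid
#' and the estimates are arithmetically averaged over the repeats.
#' Undefined per-image ICCs are excluded from the average with a warning.
#'
#' @param perImageGrids list of subjects x contrast-level matrices, one per
#'   repeat acquisition.
#' @param type passed to \code{\link{iccTwowayMixed}}.
#' @return list with \code{icc} (the average), \code{perImage} (the
#'   individual estimates) and \code{classification}.
#' @export
contrastRepeatability <- function(perImageGrids, type = "consistency") {
  stopifnot(is.list(perImageGrids), length(perImageGrids) >= 1)
  per <- vapply(perImageGrids,
                function(g) iccValue(iccTwowayMixed(g, type)), numeric(1))
  if (anyNA(per)) warning("undefined per-image ICC excluded from the average")
  avg <- if (all(is.na(per))) NA_real_ else mean(per, na.rm = TRUE)
  list(icc = avg, perImage = per, classification = classLabel(avg))
}

#' Classify an ICC value
#'
#' High repeatability is an ICC above 0.80 and low an ICC below 0.50
#' (strict inequalities; exactly 0.80 or 0.50 is "moderate").  Negative
#' values, which some estimators produce, classify as low.
#'
#' @param icc a numeric ICC value.
#' @return "high", "moderate" or "low" ("undefined" for NA).
#' @examples
#' classifyICC(0.85)   # "high"
#' classifyICC(-0.2)   # "low"
#' classifyICC(0.80)   # "moderate"
#' @export
classifyICC <- function(icc) {
  stopifnot(length(icc) == 1L)
  classLabel(icc)
}

#' ICC change due to an image processing step
#'
#' ICC on the processed image minus ICC on the unprocessed image; positive
#' differences represent improvement.
#'
#' @param iccProcessed,iccUnprocessed numeric ICC values.
#' @return the difference.
#' @examples
#' deltaICC(0.83, 0.39)  # +0.44
#' @export
deltaICC <- function(iccProcessed, iccUnprocessed) {
  stopifnot(is.finite(iccProcessed), is.finite(iccUnprocessed))
  iccProcessed - iccUnprocessed
}

#' Bin a delta-ICC for heat-map reporting
#'
#' Bins: "<=0" (no change or worsening), deciles of improvement
#' "(0,0.1]" ... "(0.4,0.5]", and ">0.5" (most improvement).
#'
#' @param delta a delta-ICC value.
#' @return the bin label.
#' @export
deltaICCBin <- function(delta) {
  stopifnot(length(delta) == 1L, is.finite(delta))
  if (delta <= 0) return("<=0")
  if (delta > 0.5) return(">0.5")
  hi <- ceiling(delta * 10) / 10
  sprintf("(%.1f,%.1f]", hi - 0.1, hi)
}
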