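# Orchestration of the full factorial repeatability experiment:
# cohort -> processing variants -> thresholds -> metrics -> ICC tables.

PROCESSING_SET <- c("none", "contrast_1.5", "contrast_2.0", "normalize",
                    "clahe", "register")

#' Configure a factorial repeatability experiment
#'
#' @param nSubjects,nRepeats cohort size (defaults 13 eyes x 3 repeats, the
#'   acquisition structure of a three-scans-per-eye repeatability study).
#' @param plexuses subset of FRL/SCP/DCP/CC.
#' @param profiles list of \linkS4class{DeviceProfile}s.
#' @param sizePx phantom side length in pixels; the default 160 keeps a
#'   full factorial run tractable while leaving room for the 15-px local
#'   threshold radius.
#' @param population \code{\link{cohortPopulation}} settings.
#' @param jitter \code{\link{cohortJitter}} settings.
#' @param processing subset of none/contrast_1.5/contrast_2.0/normalize/
#'   clahe/register; variants are applied to the original images
#'   independently, never chained.
#' @param methods threshold methods (default all eleven).
#' @param radiusPx local threshold radius (default 15).
#' @param contrastGains gains for the contrast-repeatability grids
#'   (default 1.0, 1.5, 2.0).
#' @param masterSeed integer seed governing the whole run.
#' @return an \linkS4class{ExperimentConfig}.
#' @export
experimentConfig <- function(nSubjects = 13L, nRepeats = 3L,
                             plexuses = c("SCP", "CC"),
                             profiles = list(DeviceProfile("synthetic", 160L)),
                             sizePx = 160L,
                             population = cohortPopulation(),
                             jitter = cohortJitter(),
                             processing = c("none", "contrast_1.5",
                                            "contrast_2.0"),
                             methods = thresholdMethods(),
                             radiusPx = 15L,
                             contrastGains = c(1.0, 1.5, 2.0),
                             masterSeed = 1L) {
  stopifnot(all(plexuses %in% c("FRL", "SCP", "DCP", "CC")),
            all(processing %in% PROCESSING_SET),
            all(methods %in% thresholdMethods()),
            length(profiles) >= 1)
  if (!"none" %in% processing) processing <- c("none", processing)
  new("ExperimentConfig", nSubjects = as.integer(nSubjects),
      nRepeats = as.integer(nRepeats), plexuses = plexuses,
      profiles = profiles, sizePx = as.integer(sizePx),
      population = population, jitter = jitter, processing = processing,
      methods = methods, radiusPx = as.integer(radiusPx),
      contrastGains = contrastGains, masterSeed = as.integer(masterSeed))
}

#' Apply one processing variant to a cohort
#'
#' Variants are applied to the original images independently.  For
#' "register" the first acquisition of each subject is the reference and
#' repeats 2..k are rigidly registered onto it.
#'
#' @param cohort a \linkS4class{CohortDataset} with processing "none".
#' @param processing one of the processing labels.
#' @return a \linkS4class{CohortDataset} with the processing tag updated.
#' @export
applyProcessing <- function(cohort, processing) {
  stopifnot(processing %in% PROCESSING_SET)
  if (processing == "none") return(cohort)
  info <- cohortInfo(cohort)
  imgs <- cohortImages(cohort)
  out <- imgs
  if (processing == "register") {
    for (sid in unique(info$subject_id)) {
      idx <- which(info$subject_id == sid)
      idx <- idx[order(info$repeat_index[idx])]
      ref <- imgs[[idx[1]]]
      for (i in idx[-1]) out[[i]] <- registerRigid(imgs[[i]], ref)$image
    }
  } else {
    f <- switch(processing,
      "contrast_1.5" = function(im) adjustContrast(im, 1.5),
      "contrast_2.0" = function(im) adjustContrast(im, 2.0),
      "normalize" = normalizeHistogram,
      "clahe" = claheEqualize)
    out <- lapply(imgs, f)
  }
  info$processing <- processing
  new("CohortDataset", info = info, images = out, truths = cohortTruths(cohort))
}

# Metrics relevant for a plexus.
metricsFor <- function(plexus) {
  if (plexus == "CC") c("vad", "fd_count", "fd_mean_px2") else c("vad", "vl_px")
}

quantifyCohort <- function(cohort, methods, radiusPx) {
  info <- cohortInfo(cohort)
  imgs <- cohortImages(cohort)
  rows <- vector("list", nrow(info) * length(methods))
  needFields <- any(methods %in% setdiff(LOCAL_METHODS, "local_otsu"))
  j <- 0L
  for (i in seq_len(nrow(info))) {
    flds <- if (needFields) localFields(imgs[[i]], radiusPx) else NULL
    for (m in methods) {
      bin <- binarizeImage(imgs[[i]], thresholdSpec(m, radiusPx), fields = flds)
      rec <- metricRecord(bin, info$plexus[i])
      j <- j + 1L
      rows[[j]] <- cbind(info[i, , drop = FALSE], method = m, rec,
                         row.names = NULL)
    }
  }
  do.call(rbind, rows)
}

# subjects x repeats grid of one metric from a long table slice.
metricGrid <- function(tab, metric) {
  wide <- tapply(tab[[metric]], list(tab$subject_id, tab$repeat_index),
                 identity)
  matrix(unlist(wide), nrow = nrow(wide), dimnames = dimnames(wide))
}

#' Run the full factorial repeatability experiment
#'
#' For every plexus x device profile a synthetic cohort is generated; every
#' processing variant is applied independently to the originals; every
#' image is binarized with every threshold method; metrics are quantified;
#' and three sets of ICC tables are assembled: repeat-acquisition ICCs
#' (one-way random model) per processing variant, delta-ICCs of each
#' processing variant against the unprocessed baseline, and averaged
#' contrast-change ICCs (two-way mixed model) across the configured gains
#' applied to the same (unregistered) images.  The run is deterministic
#' given the master seed; cells whose metric is undefined (e.g. mean
#' deficit size with zero deficits) are dropped listwise per grid, and
#' grids left with fewer than two subjects or zero variance yield NA ICCs.
#'
#' @param config an \linkS4class{ExperimentConfig}.
#' @return a \linkS4class{ResultsBundle}.
#' @export
runExperiment <- function(config) {
  stopifnot(is(config, "ExperimentConfig"))
  metricTabs <- list(); repeatRows <- list(); contrastRows <- list()
  cohortSeeds <- withSeed(config@masterSeed,
    replicate(length(config@plexuses) * length(config@profiles), drawSeed()))
  ci <- 0L
  for (prof in config@profiles) {
    for (plexus in config@plexuses) {
      ci <- ci + 1L
      cohort <- makeCohort(config@nSubjects, config@nRepeats, plexus, prof,
                           config@sizePx, config@population, config@jitter,
                           masterSeed = cohortSeeds[ci])
      # --- repeat-acquisition analysis under each processing variant
      for (proc in config@processing) {
        proc_cohort <- applyProcessing(cohort, proc)
        tab <- quantifyCohort(proc_cohort, config@methods, config@radiusPx)
        metricTabs[[length(metricTabs) + 1L]] <- tab
        for (m in config@methods) {
          for (metric in metricsFor(plexus)) {
            sl <- tab[tab$method == m, ]
            grid <- metricGrid(sl, metric)
            grid <- grid[stats::complete.cases(grid), , drop = FALSE]
            icc <- if (nrow(grid) < 2) NA_real_ else {
              r <- withCallingHandlers(iccOneway(grid),
                     warning = function(w) invokeRestart("muffleWarning"))
              iccValue(r)
            }
            repeatRows[[length(repeatRows) + 1L]] <- data.frame(
              plexus = plexus, device = prof@name, processing = proc,
              method = m, metric = metric, icc = icc,
              classification = classLabel(icc))
          }
        }
      }
      # --- contrast-change analysis on the original (unregistered) images
      gainTabs <- lapply(config@contrastGains, function(g) {
        gc <- cohort
        if (g != 1.0) {
          imgs <- lapply(cohortImages(cohort), adjustContrast, gain = g)
          inf <- cohortInfo(cohort); inf$processing <- sprintf("gain_%.1f", g)
          gc <- new("CohortDataset", info = inf, images = imgs,
                    truths = cohortTruths(cohort))
        }
        quantifyCohort(gc, config@methods, config@radiusPx)
      })
      for (m in config@methods) {
        for (metric in metricsFor(plexus)) {
          grids <- lapply(seq_len(config@nRepeats), function(r) {
            cols <- lapply(gainTabs, function(tb) {
              sl <- tb[tb$method == m & tb$repeat_index == r, ]
              sl[[metric]][order(sl$subject_id)]
            })
            g <- do.call(cbind, cols)
            g[stats::complete.cases(g), , drop = FALSE]
          })
          grids <- grids[vapply(grids, nrow, integer(1)) >= 2]
          cr <- if (length(grids) == 0) list(icc = NA_real_) else
            withCallingHandlers(contrastRepeatability(grids),
              warning = function(w) invokeRestart("muffleWarning"))
          contrastRows[[length(contrastRows) + 1L]] <- data.frame(
            plexus = plexus, device = prof@name, method = m, metric = metric,
            icc = cr$icc, classification = classLabel(cr$icc))
        }
      }
    }
  }
  repeatICC <- do.call(rbind, repeatRows)
  contrastICC <- do.call(rbind, contrastRows)
  # --- delta-ICC of each processing variant vs the unprocessed baseline
  base <- repeatICC[repeatICC$processing == "none", ]
  deltaRows <- list()
  for (proc in setdiff(config@processing, "none")) {
    pr <- repeatICC[repeatICC$processing == proc, ]
    mg <- merge(pr, base, by = c("plexus", "device", "method", "metric"),
                suffixes = c("_proc", "_base"))
    if (nrow(mg) == 0) next
    d <- mg$icc_proc - mg$icc_base
    deltaRows[[length(deltaRows) + 1L]] <- data.frame(
      plexus = mg$plexus, device = mg$device, processing = proc,
      method = mg$method, metric = mg$metric, delta_icc = d,
      bin = vapply(d, function(x) if (is.na(x)) NA_character_
                   else deltaICCBin(x), character(1)))
  }
  deltaICC <- if (length(deltaRows)) do.call(rbind, deltaRows)
    else data.frame(plexus = character(0), device = character(0),
                    processing = character(0), method = character(0),
                    metric = character(0), delta_icc = numeric(0),
                    bin = character(0))
  manifest <- list(masterSeed = config@masterSeed,
                   cohortSeeds = cohortSeeds,
                   nSubjects = config@nSubjects, nRepeats = config@nRepeats,
                   plexuses = config@plexuses,
                   profiles = lapply(config@profiles, function(p)
                     list(name = p@name, imageSizePx = p@imageSizePx,
                          scanSizeMm = p@scanSizeMm)),
                   sizePx = config@sizePx, population = config@population,
                   jitter = config@jitter, processing = config@processing,
                   methods = config@methods, radiusPx = config@radiusPx,
                   contrastGains = config@contrastGains,
                   package_version = as.character(utils::packageVersion("octarep")))
  new("ResultsBundle", metrics = do.call(rbind, metricTabs),
      repeatICC = repeatICC, deltaICC = deltaICC, contrastICC = contrastICC,
      manifest = manifest)
}

#' @rdname ResultsBundle-access
#' @export
resultsMetrics <- function(x) x@metrics
#' @rdname ResultsBundle-access
#' @export
resultsRepeatICC <- function(x) x@repeatICC
#' @rdname ResultsBundle-access
#' @export
resultsContrastICC <- function(x) x@contrastICC

#' Access the tables of a ResultsBundle
#'
#' @param x a \linkS4class{ResultsBundle}.
#' @return the requested data.frame.
#' @name ResultsBundle-access
#' @aliases resultsDeltaICC resultsManifest
#' @export
resultsDeltaICC <- function(x) x@deltaICC
#' @rdname ResultsBundle-access
#' @export
resultsManifest <- function(x) x@manifest

#' Save the tables of a ResultsBundle as CSV plus a JSON manifest
#'
#' @param bundle a \linkS4class{ResultsBundle}.
#' @param dir output directory.
#' @return \code{dir}, invisibly.
#' @export
saveResults <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(bundle@metrics, file.path(dir, "metrics.csv"), row.names = FALSE)
  write.csv(bundle@repeatICC, file.path(dir, "repeat_icc.csv"), row.names = FALSE)
  write.csv(bundle@deltaICC, file.path(dir, "delta_icc.csv"), row.names = FALSE)
  write.csv(bundle@contrastICC, file.path(dir, "contrast_icc.csv"),
            row.names = FALSE)
  jsonlite::write_json(bundle@manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' FAZ mis-binarization report
#'
#' Local thresholds tend to binarize the avascular FAZ as white because the
#' neighbourhood statistics inside a uniformly dark region put the
#' threshold below local noise.  For each method this reports the mean
#' fraction of true-FAZ pixels classified white across a retinal cohort,
#' sorted descending (worst offender first).
#'
#' @param cohort a retinal \linkS4class{CohortDataset} with truth masks.
#' @param methods threshold method names.
#' @param radiusPx local threshold radius.
#' @return data.frame with columns method, faz_white_fraction.
#' @export
fazAccuracyReport <- function(cohort, methods = thresholdMethods(),
                              radiusPx = 15L) {
  info <- cohortInfo(cohort)
  imgs <- cohortImages(cohort)
  truths <- cohortTruths(cohort)
  if (length(truths) == 0) stop("cohort has no truth masks")
  needFields <- any(methods %in% setdiff(LOCAL_METHODS, "local_otsu"))
  fieldList <- lapply(seq_len(nrow(info)), function(i)
    if (needFields) localFields(imgs[[i]], radiusPx) else NULL)
  fr <- vapply(methods, function(m) {
    vals <- vapply(seq_len(nrow(info)), function(i) {
      faz <- truths[[info$subject_id[i]]]@fazMask
      if (!any(faz)) return(NA_real_)
      bin <- binarizeImage(imgs[[i]], thresholdSpec(m, radiusPx),
                           fields = fieldList[[i]])
      mean(pixels(bin)[faz])
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  out <- data.frame(method = methods, faz_white_fraction = unname(fr))
  out[order(-out$faz_white_fraction), ]
}
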