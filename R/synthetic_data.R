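# Synthetic OCTA phantoms: retinal-plexus and choriocapillaris templates,
# repeat-acquisition jitter, and hierarchical cohort assembly.

# Evaluate expr under a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Separable Gaussian blur with replicate padding.
gaussBlur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  nr <- nrow(mat); nc <- ncol(mat)
  # rows (y)
  idx <- function(i, n) pmin(pmax(i, 1L), n)
  out <- matrix(0, nr, nc)
  for (o in -r:r) out <- out + k[o + r + 1] * mat[idx(seq_len(nr) + o, nr), , drop = FALSE]
  out2 <- matrix(0, nr, nc)
  for (o in -r:r) out2 <- out2 + k[o + r + 1] * out[, idx(seq_len(nc) + o, nc), drop = FALSE]
  out2
}

#' Subject-level phantom parameters
#'
#' One draw of these parameters defines a subject; repeat acquisitions of
#' that subject share the template it generates.  Between-subject variation
#' in a cohort comes from drawing these per subject.
#'
#' @param vesselDensityLevel dimensionless in (0, 1); scales the number of
#'   seeded vessel trunks and the capillary mesh coverage.
#' @param fazRadiusUm foveal avascular zone radius in micrometres (retinal
#'   phantoms; 0 disables the FAZ).
#' @param ccDeficitDensity expected flow-deficit count per mm^2 (CC phantoms).
#' @param ccDeficitRadiusUm mean deficit radius in micrometres.
#' @param baseGain subject-level intensity scale factor.
#' @param intensityRange 2-vector: output intensities are mapped into this
#'   range.  The default spans the full 0-255 scale so that contrast gains
#'   about mid-grey clip; \code{c(65, 191)} gives a "no-clip" phantom on
#'   which gains 1.5 and 2.0 stay within range.
#' @param rngSeed integer seed; identical parameters and seed give
#'   bit-identical phantoms.
#' @return a named list of class "SubjectParams".
#' @export
subjectParams <- function(vesselDensityLevel = 0.5, fazRadiusUm = 250,
                          ccDeficitDensity = 25, ccDeficitRadiusUm = 30,
                          baseGain = 1.0, intensityRange = c(0, 255),
                          rngSeed = 1L) {
  stopifnot(vesselDensityLevel > 0, vesselDensityLevel < 1,
            fazRadiusUm >= 0, ccDeficitDensity >= 0, ccDeficitRadiusUm > 0,
            baseGain > 0, length(intensityRange) == 2L,
            intensityRange[1] < intensityRange[2],
            intensityRange[1] >= 0, intensityRange[2] <= 255)
  structure(list(vesselDensityLevel = vesselDensityLevel,
                 fazRadiusUm = fazRadiusUm,
                 ccDeficitDensity = ccDeficitDensity,
                 ccDeficitRadiusUm = ccDeficitRadiusUm,
                 baseGain = baseGain,
                 intensityRange = intensityRange,
                 rngSeed = as.integer(rngSeed)),
            class = "SubjectParams")
}

#' Per-acquisition jitter of a repeat scan
#'
#' Models the within-subject variation between successive scans of the same
#' eye: a small rigid misalignment, a per-acquisition intensity gain/offset,
#' an independent speckle-noise realisation, and a local elastic perturbation
#' of vessel appearance (shape/caliber/continuity differences between
#' repeats).  With every scale zero and zero shift/rotation the acquisition
#' reproduces the template exactly.
#'
#' @param shiftPx length-2 sub-pixel rigid translation (dx, dy) in pixels.
#' @param rotationDeg small rotation angle in degrees.
#' @param gainSd sd of the multiplicative intensity gain about 1.
#' @param offsetSd sd of the additive intensity offset (grey levels).
#' @param noiseSd sd of additive speckle noise (grey levels).
#' @param vesselPerturbationSd sd (pixels) of the smooth random displacement
#'   field perturbing local vessel appearance.
#' @param rngSeed integer seed for the acquisition draws.
#' @return a named list of class "AcquisitionJitter".
#' @export
acquisitionJitter <- function(shiftPx = c(0, 0), rotationDeg = 0,
                              gainSd = 0, offsetSd = 0, noiseSd = 0,
                              vesselPerturbationSd = 0, rngSeed = 1L) {
  stopifnot(length(shiftPx) == 2L, gainSd >= 0, offsetSd >= 0, noiseSd >= 0,
            vesselPerturbationSd >= 0)
  structure(list(shiftPx = as.numeric(shiftPx),
                 rotationDeg = as.numeric(rotationDeg),
                 gainSd = gainSd, offsetSd = offsetSd, noiseSd = noiseSd,
                 vesselPerturbationSd = vesselPerturbationSd,
                 rngSeed = as.integer(rngSeed)),
            class = "AcquisitionJitter")
}

# Clamp to [0, 1] preserving matrix dims (pmin/pmax with a scalar first
# argument drop them).
clamp01 <- function(x) { d <- dim(x); x <- pmin(pmax(x, 0), 1); dim(x) <- d; x }

# Map a [0, 1] composite to the subject's intensity range, as integers.
composeIntensity <- function(field, range) {
  v <- range[1] + field * (range[2] - range[1])
  px <- matrix(roundHalfAway(pmin(pmax(v, 0), 255)),
               nrow(field), ncol(field))
  storage.mode(px) <- "integer"
  px
}

# Per-subject spatial signal field: OCTA signal strength falls off
# unevenly across the field (pupil vignetting, media opacities, focus).
# Smooth, so locally adaptive thresholds absorb it at baseline, but
# contrast-gain clipping crosses different regions in different eyes.
signalField <- function(nr, nc) {
  a <- runif(1, 0.10, 0.35)                       # falloff depth
  cy <- runif(1, 0.3, 0.7) * nr; cx <- runif(1, 0.3, 0.7) * nc
  sy <- runif(1, 0.8, 1.3); sx <- runif(1, 0.8, 1.3)
  d2 <- outer(((seq_len(nr) - cy) / (sy * nr))^2,
              ((seq_len(nc) - cx) / (sx * nc))^2, "+")
  1 - a * d2 / max(d2)
}

# Stamp a filled disc into a logical mask / numeric field.
stampDisc <- function(nr, nc, cy, cx, rad) {
  r0 <- max(1L, floor(cy - rad)); r1 <- min(nr, ceiling(cy + rad))
  c0 <- max(1L, floor(cx - rad)); c1 <- min(nc, ceiling(cx + rad))
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  d2 <- outer((rows - cy)^2, (cols - cx)^2, "+")
  list(rows = rows, cols = cols, inside = d2 <= rad^2)
}

#' Generate a retinal-plexus phantom template
#'
#' Bright branching vessels are grown from the image border inwards by a
#' stochastic branching random walk with caliber decay, over a capillary
#' mesh built from band-pass-filtered noise; intensities inside the central
#' foveal avascular zone disc are suppressed towards background.  Ground
#' truth (vessel and FAZ masks) is returned alongside.
#'
#' @param params a \code{\link{subjectParams}} object.
#' @param sizePx image side length in pixels (>= 64).
#' @param profile optional \linkS4class{DeviceProfile}; defaults to a 3-mm
#'   field at \code{sizePx} resolution.
#' @return list with elements \code{image} (\linkS4class{GrayImage}) and
#'   \code{truth} (\linkS4class{PhantomTruth}).
#' @export
makeRetinalTemplate <- function(params, sizePx = 256L,
                                profile = DeviceProfile("synthetic", sizePx)) {
  stopifnot(inherits(params, "SubjectParams"), sizePx >= 64)
  pitch <- pitchUm(profile)
  fazPx <- params$fazRadiusUm / pitch
  if (fazPx > sizePx / 2)
    stop("fazRadiusUm larger than half the field")
  withSeed(params$rngSeed, {
    nr <- nc <- as.integer(sizePx)
    vessel <- matrix(0, nr, nc)        # vessel intensity field, [0, 1]
    vmask <- matrix(FALSE, nr, nc)
    # trunks are grown until their area fraction reaches the density
    # target: healthy maculae carry near-identical vascular area, so the
    # structural component of VAD is pinned and between-subject contrast
    # response is driven by intensity traits, not by layout luck
    trunkTarget <- 0.06 + 0.08 * params$vesselDensityLevel
    maxSeeds <- 60L
    ctr <- (nr + 1) / 2
    # subject-level appearance: where the capillary band, background and
    # vessel intensities sit is an independent trait of each eye/scan, so
    # contrast clipping crosses different components in different subjects
    # fixed appearance constants: the capillary band is dimmer than the
    # trunks (contrast gains clip it towards 0); between-subject intensity
    # variation enters through baseGain and the spatial signal field, the
    # way device signal strength and vignetting differ between eyes
    bgLev <- 0.10
    capHi <- 0.36
    vBright <- 0.87
    for (s in seq_len(maxSeeds)) {
      if (mean(vmask) >= trunkTarget) break
      side <- sample.int(4L, 1L)
      pos <- switch(side,
        c(1, runif(1, 1, nc)), c(nr, runif(1, 1, nc)),
        c(runif(1, 1, nr), 1), c(runif(1, 1, nr), nc))
      dir <- atan2(ctr - pos[1], ctr - pos[2]) + runif(1, -0.4, 0.4)
      stack <- list(list(pos = pos, dir = dir, cal = runif(1, 1.8, 2.4)))
      depth <- 0L
      while (length(stack) > 0 && depth < 4000L) {
        w <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        repeat {
          depth <- depth + 1L
          if (w$cal < 0.55) break
          if (w$pos[1] < -4 || w$pos[1] > nr + 4 ||
              w$pos[2] < -4 || w$pos[2] > nc + 4) break
          st <- stampDisc(nr, nc, w$pos[1], w$pos[2], w$cal)
          if (!is.null(st)) {
            bright <- vBright * (0.75 + 0.25 * runif(1))
            blk <- vessel[st$rows, st$cols]
            blk[st$inside] <- pmax(blk[st$inside], bright)
            vessel[st$rows, st$cols] <- blk
            mb <- vmask[st$rows, st$cols]
            mb[st$inside] <- TRUE
            vmask[st$rows, st$cols] <- mb
          }
          w$dir <- w$dir + rnorm(1, 0, 0.18)
          w$pos <- w$pos + 1.6 * c(sin(w$dir), cos(w$dir))
          w$cal <- w$cal * 0.995
          if (runif(1) < 0.025 && w$cal > 0.9) {
            child <- w
            child$dir <- w$dir + sample(c(-1, 1), 1) * runif(1, 0.4, 1.0)
            child$cal <- w$cal * 0.72
            w$cal <- w$cal * 0.88
            stack[[length(stack) + 1L]] <- child
          }
        }
      }
    }
    # capillary mesh: band-pass filtered noise, soft-thresholded
    noise <- matrix(rnorm(nr * nc), nr, nc)
    band <- gaussBlur(noise, 1.0) - gaussBlur(noise, 3.0)
    band <- band / stats::sd(band)
    # density sets the capillary area fraction directly: the sigmoid cut is
    # the band quantile at the target coverage, so the covered area tracks
    # the density trait instead of drifting with the band realization
    coverage <- 0.2 + 0.5 * params$vesselDensityLevel
    capCut <- as.numeric(stats::quantile(band, 1 - coverage))
    caps <- capHi / (1 + exp(-3 * (band - capCut)))
    bg <- bgLev + 0.04 * gaussBlur(matrix(rnorm(nr * nc), nr, nc), 6)
    field <- clamp01(bg + caps)
    field <- pmax(field, vessel)
    # per-eye focus quality: defocus blurs the capillary band into the
    # background, reshaping how the histogram crosses the contrast-gain
    # clip points without much moving the adaptively thresholded baseline
    field <- gaussBlur(field, runif(1, 0.30, 1.10))
    # FAZ suppression towards background
    faz <- matrix(FALSE, nr, nc)
    if (fazPx > 0) {
      st <- stampDisc(nr, nc, ctr, ctr, fazPx)
      faz[st$rows, st$cols][st$inside] <- TRUE
      d2 <- outer((seq_len(nr) - ctr)^2, (seq_len(nc) - ctr)^2, "+")
      soft <- 1 / (1 + exp(-(sqrt(d2) - fazPx) / max(1, fazPx * 0.08)))
      field <- field * (0.12 + 0.88 * soft)
      vmask[faz] <- FALSE
    }
    field <- clamp01(field * signalField(nr, nc) * params$baseGain)
    img <- GrayImage(composeIntensity(field, params$intensityRange), pitch)
    truth <- new("PhantomTruth", fazMask = faz, vesselMask = vmask,
                 deficitMask = matrix(FALSE, nr, nc))
    list(image = img, truth = truth)
  })
}

#' Generate a choriocapillaris phantom template
#'
#' A stationary granular flow texture (smoothed noise) with Poisson-placed
#' dark elliptical flow deficits; deficits are recorded in the truth mask.
#' The texture is homogeneous across the field (no FAZ), mirroring the
#' relative homogeneity of healthy CC angiograms.
#'
#' @inheritParams makeRetinalTemplate
#' @return list with elements \code{image} and \code{truth}.
#' @export
makeCCTemplate <- function(params, sizePx = 256L,
                           profile = DeviceProfile("synthetic", sizePx)) {
  stopifnot(inherits(params, "SubjectParams"), sizePx >= 64)
  pitch <- pitchUm(profile)
  withSeed(params$rngSeed, {
    nr <- nc <- as.integer(sizePx)
    tex <- gaussBlur(matrix(rnorm(nr * nc), nr, nc), 1.2)
    tex <- tex / stats::sd(tex)
    field <- clamp01(0.50 + 0.12 * tex)
    dmask <- matrix(FALSE, nr, nc)
    areaMm2 <- (nr * pitch / 1000) * (nc * pitch / 1000)
    nDef <- rpois(1, params$ccDeficitDensity * areaMm2)
    radPx <- params$ccDeficitRadiusUm / pitch
    if (nDef > 0) {
      for (i in seq_len(nDef)) {
        cy <- runif(1, 1, nr); cx <- runif(1, 1, nc)
        a <- max(0.8, rnorm(1, radPx, 0.2 * radPx))
        b <- max(0.8, a * runif(1, 0.6, 1))
        phi <- runif(1, 0, pi)
        r0 <- max(1L, floor(cy - a)); r1 <- min(nr, ceiling(cy + a))
        c0 <- max(1L, floor(cx - a)); c1 <- min(nc, ceiling(cx + a))
        if (r0 > r1 || c0 > c1) next
        rows <- r0:r1; cols <- c0:c1
        dy <- outer(rows - cy, rep(1, length(cols)))
        dx <- outer(rep(1, length(rows)), cols - cx)
        u <- cos(phi) * dx + sin(phi) * dy
        v <- -sin(phi) * dx + cos(phi) * dy
        inside <- (u / a)^2 + (v / b)^2 <= 1
        if (!any(inside)) {   # sub-pixel deficit: keep its nearest pixel
          nearest <- which.min(dy^2 + dx^2)
          inside[nearest] <- TRUE
        }
        blk <- field[rows, cols]
        blk[inside] <- blk[inside] * 0.25
        field[rows, cols] <- blk
        mb <- dmask[rows, cols]; mb[inside] <- TRUE
        dmask[rows, cols] <- mb
      }
    }
    field <- clamp01(field * signalField(nr, nc) * params$baseGain)
    img <- GrayImage(composeIntensity(field, params$intensityRange), pitch)
    truth <- new("PhantomTruth", fazMask = matrix(FALSE, nr, nc),
                 vesselMask = matrix(FALSE, nr, nc), deficitMask = dmask)
    list(image = img, truth = truth)
  })
}

#' Simulate one repeat acquisition of a subject template
#'
#' Applies, in order: a smooth elastic perturbation of local vessel
#' appearance, a rigid sub-pixel shift and small rotation (bilinear
#' resampling), a multiplicative gain and additive offset drawn once per
#' acquisition, and additive speckle noise; the result is clipped and
#' rounded back to 8-bit.  All-zero jitter reproduces the template exactly.
#'
#' @param template a \linkS4class{GrayImage} subject template.
#' @param jitter an \code{\link{acquisitionJitter}} object.
#' @param range intensity clamp for the acquired image (default the full
#'   8-bit range; a no-clip cohort passes its restricted template range so
#'   acquisition gain/noise cannot push pixels into the contrast-gain
#'   clipping zone).
#' @return a \linkS4class{GrayImage}.
#' @export
simulateAcquisition <- function(template, jitter, range = c(0, 255)) {
  stopifnot(is(template, "GrayImage"), inherits(jitter, "AcquisitionJitter"))
  withSeed(jitter$rngSeed, {
    m <- pixels(template) + 0.0
    nr <- nrow(m); nc <- ncol(m)
    if (jitter$vesselPerturbationSd > 0) {
      dyf <- gaussBlur(matrix(rnorm(nr * nc), nr, nc), 4)
      dxf <- gaussBlur(matrix(rnorm(nr * nc), nr, nc), 4)
      sc <- jitter$vesselPerturbationSd / max(stats::sd(dyf), 1e-12)
      m <- cpp_warp_field(m, dyf * sc, dxf * sc)
    }
    if (any(jitter$shiftPx != 0) || jitter$rotationDeg != 0)
      m <- cpp_warp_rigid(m, jitter$shiftPx[1], jitter$shiftPx[2],
                          jitter$rotationDeg)
    gain <- if (jitter$gainSd > 0) rnorm(1, 1, jitter$gainSd) else 1
    offset <- if (jitter$offsetSd > 0) rnorm(1, 0, jitter$offsetSd) else 0
    m <- m * gain + offset
    if (jitter$noiseSd > 0) m <- m + rnorm(nr * nc, 0, jitter$noiseSd)
    px <- roundHalfAway(pmin(pmax(m, range[1]), range[2]))
    storage.mode(px) <- "integer"
    GrayImage(px, pitchUm(template))
  })
}

#' Population- and jitter-level cohort settings
#'
#' \code{cohortPopulation} describes the between-subject distributions from
#' which \code{\link{subjectParams}} are drawn; \code{cohortJitter} the
#' within-subject acquisition-jitter scales.  Rigid misalignment is drawn
#' uniformly within \code{maxShiftPx} / \code{maxRotationDeg} per
#' acquisition (defaults 3 px and 1 degree, enough for registration to have
#' something to correct).
#'
#' @param vesselDensityMean,vesselDensitySd mean and sd of the subject
#'   vessel-density level (draws clamped to (0.05, 0.95)).  Healthy eyes
#'   have similar vascular density, so the between-subject sd is small;
#'   subjects differ more in overall signal strength (\code{baseGainSd}),
#'   which moves each subject's intensity distribution relative to the
#'   clipping points of contrast gains.
#' @param fazRadiusMeanUm,fazRadiusSdUm FAZ radius distribution (um).
#' @param ccDeficitDensityMean,ccDeficitDensitySd deficits per mm^2.
#' @param ccDeficitRadiusMeanUm mean deficit radius (um).
#' @param baseGainSd sd of the subject-level intensity gain about 1.
#' @param intensityRange passed through to \code{\link{subjectParams}}.
#' @return a named list.
#' @export
cohortPopulation <- function(vesselDensityMean = 0.5, vesselDensitySd = 0.02,
                             fazRadiusMeanUm = 250, fazRadiusSdUm = 50,
                             ccDeficitDensityMean = 25, ccDeficitDensitySd = 6,
                             ccDeficitRadiusMeanUm = 30, baseGainSd = 0.18,
                             intensityRange = c(0, 255)) {
  as.list(environment())
}

#' @param maxShiftPx,maxRotationDeg uniform bounds for the per-acquisition
#'   rigid misalignment.
#' @param gainSd,offsetSd,noiseSd,vesselPerturbationSd per-acquisition
#'   intensity and deformation scales (see \code{\link{acquisitionJitter}}).
#' @rdname cohortPopulation
#' @export
cohortJitter <- function(maxShiftPx = 3, maxRotationDeg = 1,
                         gainSd = 0.05, offsetSd = 3, noiseSd = 6,
                         vesselPerturbationSd = 0.8) {
  as.list(environment())
}

drawSeed <- function() sample.int(.Machine$integer.max - 1L, 1L)

#' Build a synthetic cohort of repeat acquisitions
#'
#' Hierarchical seeding (master seed, then one seed per subject, then one per
#' acquisition) makes the cohort bit-reproducible.  Each subject's repeats
#' derive from a single template, so downstream between/within variance has
#' the nested structure the ICC decomposes.
#'
#' @param nSubjects number of subjects (>= 2; the ICC is undefined for one).
#' @param nRepeats repeat acquisitions per subject (>= 2).
#' @param plexus one of "FRL", "SCP", "DCP" (retinal phantom) or "CC".
#' @param profile a \linkS4class{DeviceProfile}.
#' @param sizePx phantom side length in pixels (the physical pitch still
#'   follows the profile's scan size, so a scaled-down grid keeps realistic
#'   micron geometry).
#' @param population a \code{\link{cohortPopulation}} list.
#' @param jitter a \code{\link{cohortJitter}} list.
#' @param masterSeed integer master seed.
#' @return a \linkS4class{CohortDataset} with per-subject truth masks.
#' @export
makeCohort <- function(nSubjects, nRepeats, plexus = "SCP",
                       profile = DeviceProfile("synthetic", 256L),
                       sizePx = profile@imageSizePx,
                       population = cohortPopulation(),
                       jitter = cohortJitter(), masterSeed = 1L) {
  if (nSubjects < 2) stop("nSubjects must be >= 2 (ICC undefined otherwise)")
  if (nRepeats < 2) stop("nRepeats must be >= 2")
  stopifnot(plexus %in% c("FRL", "SCP", "DCP", "CC"))
  prof <- DeviceProfile(profile@name, sizePx, profile@scanSizeMm)
  subjSeeds <- withSeed(masterSeed, replicate(nSubjects, drawSeed()))
  images <- vector("list", nSubjects * nRepeats)
  truths <- list()
  info <- data.frame(subject_id = character(0), repeat_index = integer(0),
                     plexus = character(0), device = character(0),
                     processing = character(0))
  row <- 0L
  for (s in seq_len(nSubjects)) {
    sid <- sprintf("S%02d", s)
    sub <- withSeed(subjSeeds[s], {
      dens <- min(0.95, max(0.05, rnorm(1, population$vesselDensityMean,
                                        population$vesselDensitySd)))
      fazR <- max(0, rnorm(1, population$fazRadiusMeanUm,
                           population$fazRadiusSdUm))
      ccD <- max(0, rnorm(1, population$ccDeficitDensityMean,
                          population$ccDeficitDensitySd))
      gain <- max(0.5, rnorm(1, 1, population$baseGainSd))
      sp <- subjectParams(vesselDensityLevel = dens, fazRadiusUm = fazR,
                          ccDeficitDensity = ccD,
                          ccDeficitRadiusUm = population$ccDeficitRadiusMeanUm,
                          baseGain = gain,
                          intensityRange = population$intensityRange,
                          rngSeed = drawSeed())
      acqSeeds <- replicate(nRepeats, drawSeed())
      draws <- lapply(seq_len(nRepeats), function(r) {
        list(shift = runif(2, -jitter$maxShiftPx, jitter$maxShiftPx),
             rot = runif(1, -jitter$maxRotationDeg, jitter$maxRotationDeg),
             seed = acqSeeds[r])
      })
      list(sp = sp, draws = draws)
    })
    tpl <- if (plexus == "CC") makeCCTemplate(sub$sp, sizePx, prof)
           else makeRetinalTemplate(sub$sp, sizePx, prof)
    truths[[sid]] <- tpl$truth
    for (r in seq_len(nRepeats)) {
      d <- sub$draws[[r]]
      jit <- acquisitionJitter(shiftPx = d$shift, rotationDeg = d$rot,
                               gainSd = jitter$gainSd, offsetSd = jitter$offsetSd,
                               noiseSd = jitter$noiseSd,
                               vesselPerturbationSd = jitter$vesselPerturbationSd,
                               rngSeed = d$seed)
      row <- row + 1L
      images[[row]] <- simulateAcquisition(tpl$image, jit,
                                           range = population$intensityRange)
      info <- rbind(info, data.frame(subject_id = sid, repeat_index = r,
                                     plexus = plexus, device = prof@name,
                                     processing = "none"))
    }
  }
  new("CohortDataset", info = info, images = images, truths = truths)
}
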