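#' @include datablock-io.R
NULL

#' Synthetic cohort configuration
#'
#' Study-condition parameters for the synthetic data-block generator. The
#' defaults emulate the acquisition the analysis assumes: two patient groups
#' at the reported cohort scale (41 and 84 cells), 2--4 cells per field,
#' Poisson shot noise on a linear fluorophore mixing model, smooth
#' multiplicative vignetting, a dark offset with Gaussian read noise, and
#' rare hot/dead pixels. The group difference is placed entirely on the
#' NAD(P)H : flavins abundance ratio (the cellular redox ratio), the one
#' biologically anchored group-difference mechanism in this assay; nuisance
#' fluorophores and illumination are group-independent.
#'
#' @param nPatientsPerGroup patients per group (default 5).
#' @param cellsPerGroup total cells per group, \code{c(group0, group1)};
#'   default \code{c(41, 84)}, the reported cohort scale.
#' @param cellsPerField nominal cells per imaged field (default 3, from the
#'   documented 2--4 cells per field; the last field of a group may hold
#'   fewer to hit the group total exactly).
#' @param imageShape image size in pixels (default \code{c(256, 256)};
#'   desk-scale stand-in for the camera's 1200 x 1200 sensor, full size
#'   available by overriding).
#' @param effect group shift of the mean log NAD(P)H : flavins abundance
#'   ratio (group 0 higher). The default gives a designed Bayes AUC of 0.90
#'   on the true log-ratio given the variance components below; see
#'   [designedAUC()].
#' @param withinPatientSd,betweenPatientSd standard deviations of cell-level
#'   and patient-level log-abundances (per fluorophore, log units).
#' @param baseLogAbundance named log mean abundances for \code{"NAD(P)H"}
#'   and \code{"flavins"} (arbitrary abundance units; one unit of abundance
#'   yields the endmember response in counts/s at the channel peak).
#' @param nuisanceLogAbundance log mean abundance of each nuisance
#'   fluorophore.
#' @param vignettingStrength,vignettingTilt parameters of the smooth
#'   multiplicative illumination field \eqn{(1 - s\,\rho^2)(1 + t\,x)}; the
#'   default gives a raw coefficient of variation just over 10\% on a
#'   uniform target.
#' @param darkOffset,readNoise camera offset and Gaussian read noise
#'   (counts).
#' @param waterBackground constant buffer/stray background above dark
#'   (counts), present in sample and water reference images alike.
#' @param calibrationLevel calibration-fluid signal at unit illumination and
#'   1 s exposure (counts).
#' @param hotPixelRate,deadPixelRate per-pixel probabilities of
#'   saturated/dead pixels in the sample channel images.
#' @param textureSd log-sd of the smooth lognormal intra-cell texture.
#' @param cellRadiusRange semi-axis range of the elliptical cells (pixels).
#' @param noise logical; \code{FALSE} produces noise-free blocks (exact
#'   linear mixing, no Poisson/read noise, no bad pixels) for calibration
#'   oracles.
#' @param seed master seed; a fixed seed makes every generated file
#'   byte-identical across runs.
#' @return a validated list of class \code{"cohortConfig"}.
#' @export
cohortConfig <- function(nPatientsPerGroup = 5L,
                         cellsPerGroup = c(41L, 84L),
                         cellsPerField = 3L,
                         imageShape = c(256L, 256L),
                         effect = 0.6903,
                         withinPatientSd = 0.25,
                         betweenPatientSd = 0.10,
                         baseLogAbundance = c("NAD(P)H" = log(600),
                                              "flavins" = log(600)),
                         nuisanceLogAbundance = log(120),
                         vignettingStrength = 0.45,
                         vignettingTilt = 0.05,
                         darkOffset = 100,
                         readNoise = 5,
                         waterBackground = 30,
                         calibrationLevel = 1000,
                         hotPixelRate = 1e-3,
                         deadPixelRate = 1e-3,
                         textureSd = 0.3,
                         cellRadiusRange = c(10, 16),
                         noise = TRUE,
                         seed = 1L) {
  cfg <- list(nPatientsPerGroup = as.integer(nPatientsPerGroup),
              cellsPerGroup = as.integer(cellsPerGroup),
              cellsPerField = as.integer(cellsPerField),
              imageShape = as.integer(imageShape),
              effect = effect,
              withinPatientSd = withinPatientSd,
              betweenPatientSd = betweenPatientSd,
              baseLogAbundance = baseLogAbundance,
              nuisanceLogAbundance = nuisanceLogAbundance,
              vignettingStrength = vignettingStrength,
              vignettingTilt = vignettingTilt,
              darkOffset = darkOffset, readNoise = readNoise,
              waterBackground = waterBackground,
              calibrationLevel = calibrationLevel,
              hotPixelRate = hotPixelRate, deadPixelRate = deadPixelRate,
              textureSd = textureSd,
              cellRadiusRange = cellRadiusRange,
              noise = isTRUE(noise), seed = as.integer(seed))
  with(cfg, {
    stopifnot(length(cellsPerGroup) == 2L, all(cellsPerGroup >= 2L),
              cellsPerField >= 1L, nPatientsPerGroup >= 1L,
              length(imageShape) == 2L, all(imageShape >= 32L),
              withinPatientSd >= 0, betweenPatientSd >= 0,
              hotPixelRate >= 0, hotPixelRate <= 1,
              deadPixelRate >= 0, deadPixelRate <= 1,
              readNoise >= 0, darkOffset >= 0, waterBackground > 0,
              calibrationLevel > 0, textureSd >= 0,
              length(cellRadiusRange) == 2L, cellRadiusRange[1] >= 2)
  })
  structure(cfg, class = "cohortConfig")
}

#' Designed Bayes-optimal separability of a cohort configuration
#'
#' The per-cell true log NAD(P)H : flavins ratio is Gaussian within each
#' group with common variance \eqn{\sigma^2 = 2(\sigma_b^2 + \sigma_w^2)}
#' (both fluorophore log-abundances vary at the patient and cell level) and
#' group means separated by \code{effect}, so the best attainable AUC of any
#' classifier using the true log-ratio is
#' \eqn{\Phi(\mathrm{effect}/\sqrt{2\sigma^2})}. \code{effectForAUC} inverts
#' this to design a cohort with a target Bayes AUC.
#'
#' @param cfg a [cohortConfig()].
#' @param auc target Bayes-optimal AUC in (0.5, 1).
#' @return \code{designedAUC}: the AUC implied by \code{cfg};
#'   \code{effectForAUC}: the \code{effect} value achieving \code{auc}.
#' @examples
#' cfg <- cohortConfig()
#' designedAUC(cfg)                     # 0.90 by default
#' effectForAUC(0.75, cfg)
#' @export
designedAUC <- function(cfg) {
  s2 <- 2 * (cfg$betweenPatientSd^2 + cfg$withinPatientSd^2)
  pnorm(cfg$effect / sqrt(2 * s2))
}

#' @rdname designedAUC
#' @export
effectForAUC <- function(auc, cfg) {
  stopifnot(auc > 0.5, auc < 1)
  s2 <- 2 * (cfg$betweenPatientSd^2 + cfg$withinPatientSd^2)
  qnorm(auc) * sqrt(2 * s2)
}

#' Generate fluorophore endmember spectra
#'
#' Builds a per-channel emission response matrix whose structure matches the
#' known fluorophore-channel anchors of this acquisition geometry: the
#' NAD(P)H response peaks in channel 2 and the flavin response is largest in
#' channels 15 and 32 (its two emission lobes). Optional broad low-amplitude
#' nuisance fluorophores model unassigned cellular autofluorescence. A small
#' seeded multiplicative jitter (3\%) individualizes the spectra without
#' ever violating the anchor invariants; the same seed always returns the
#' identical matrix.
#'
#' @param channels a [ChannelSet-class] with at least 32 channels.
#' @param seed integer seed.
#' @param nNuisance number of nuisance fluorophores (default 1).
#' @return a validated [EndmemberSpectra-class].
#' @export
makeEndmembers <- function(channels, seed = 1L, nNuisance = 1L) {
  n <- nChannels(channels)
  if (n < 32) stopf("endmember anchors need at least 32 channels, got %d", n)
  i <- seq_len(n)
  withSeed(seed, {
    jit <- function(v) v * (1 + 0.03 * runif(length(v), -1, 1))
    nadph <- jit(0.01 + exp(-((i - 2) / 3)^2))
    flav <- jit(0.01 + 0.90 * exp(-((i - 15) / 2)^2) +
                  1.00 * exp(-((i - 32) / 2)^2))
    R <- cbind("NAD(P)H" = nadph / max(nadph), "flavins" = flav / max(flav))
    if (nNuisance > 0) {
      for (k in seq_len(nNuisance)) {
        ctr <- runif(1, 8, 28)
        nx <- jit(0.005 + 0.25 * exp(-((i - ctr) / 8)^2))
        R <- cbind(R, nx / max(nx) * 0.25)
        colnames(R)[ncol(R)] <- sprintf("nuisance%d", k)
      }
    }
    new("EndmemberSpectra", response = R)
  })
}

# smooth multiplicative illumination field on [-1,1]^2 coordinates
illuminationField <- function(shape, strength, tilt) {
  x <- seq(-1, 1, length.out = shape[2])
  y <- seq(-1, 1, length.out = shape[1])
  rho2 <- outer(y^2, x^2, `+`) / 2
  (1 - strength * rho2) * (1 + tilt * matrix(x, shape[1], shape[2], byrow = TRUE))
}

# smooth unit-variance Gaussian field (separable 5x5 box blur applied twice)
smoothField <- function(shape) {
  z <- matrix(rnorm(prod(shape)), shape[1], shape[2])
  blur1 <- function(m) {
    k <- rep(1 / 5, 5)
    m <- apply(m, 2, function(v) as.numeric(stats::filter(v, k, circular = TRUE)))
    t(apply(t(m), 2, function(v) as.numeric(stats::filter(v, k, circular = TRUE))))
  }
  z <- blur1(blur1(z))
  z / sd(z)
}

# rasterize an ellipse; returns linear pixel indices
ellipsePixels <- function(shape, cy, cx, a, b, theta) {
  ct <- cos(theta); st <- sin(theta)
  r0 <- max(1, floor(cy - max(a, b))); r1 <- min(shape[1], ceiling(cy + max(a, b)))
  c0 <- max(1, floor(cx - max(a, b))); c1 <- min(shape[2], ceiling(cx + max(a, b)))
  rr <- r0:r1; cc <- c0:c1
  dy <- matrix(rr - cy, length(rr), length(cc))
  dx <- matrix(cc - cx, length(rr), length(cc), byrow = TRUE)
  u <- (dx * ct + dy * st) / a
  v <- (-dx * st + dy * ct) / b
  inside <- u^2 + v^2 <= 1
  idx <- which(inside)
  (rep(cc, each = length(rr))[idx] - 1L) * shape[1] + rep(rr, length(cc))[idx]
}

# reference images for one acquisition session (shared across a patient's fields)
makeReferences <- function(cfg, channels, illum) {
  n <- nChannels(channels)
  shape <- cfg$imageShape
  npx <- prod(shape)
  navg <- channelTable(channels)$n_averages
  refNoise <- function(c) {
    if (!cfg$noise || cfg$readNoise == 0) 0
    else rnorm(npx, 0, cfg$readNoise / sqrt(navg[c]))
  }
  dark <- array(0, c(shape, n)); water <- dark; calib <- dark
  expo <- exposures(channels)
  for (c in seq_len(n)) {
    dark[, , c] <- round(pmax(cfg$darkOffset + refNoise(c), 0))
    water[, , c] <- round(pmax(cfg$darkOffset + cfg$waterBackground + refNoise(c), 0))
    calib[, , c] <- round(pmax(cfg$darkOffset +
                                 illum * cfg$calibrationLevel * expo[c] +
                                 refNoise(c), 1))
  }
  if (!cfg$noise) {              # exact references for calibration oracles
    for (c in seq_len(n)) {
      dark[, , c] <- cfg$darkOffset
      water[, , c] <- cfg$darkOffset + cfg$waterBackground
      calib[, , c] <- cfg$darkOffset + illum * cfg$calibrationLevel * expo[c]
    }
  }
  list(dark = dark, water = water, calibration = calib)
}

#' Generate one synthetic data block with ground truth
#'
#' Renders one field: elliptical cells with smooth lognormal intra-cell
#' texture, clean per-pixel signal
#' \eqn{\mathrm{illum}(x,y)\sum_f a_f R_{c,f} t_c} (abundance times
#' endmember response times exposure), then -- when \code{noise} is on --
#' Poisson shot noise, the constant water background, dark offset, Gaussian
#' read noise, quantization, and hot/dead pixel injection. Reference images
#' are generated consistently: dark = offset + noise, water = dark + constant
#' background, calibration = dark + illumination x constant.
#'
#' Draws from the current RNG stream; wrap in [withr::with_seed()] (or call
#' through [generateCohort()]) for reproducibility.
#'
#' @param cfg a [cohortConfig()].
#' @param spectra an [EndmemberSpectra-class].
#' @param patientId,groupLabel,fieldId identifiers for the block.
#' @param channels a [ChannelSet-class] (default [defaultChannelSet()]).
#' @param nCells number of cells to place (default \code{cfg$cellsPerField}).
#' @param patientEffects optional named per-fluorophore patient-level mean
#'   log-abundances (as sampled by [generateCohort()]); when \code{NULL}
#'   they are drawn from the group-level distribution.
#' @param refs optional precomputed reference list (dark/water/calibration)
#'   for the acquisition session; generated when \code{NULL}.
#' @return list with elements \code{block} ([DataBlock-class]), \code{mask}
#'   ([CellMask-class]) and \code{truth} (per-cell log-abundances, the clean
#'   signal array, the illumination field and the injected bad-pixel map:
#'   0 clean, 1 hot, 2 dead).
#' @export
generateDataBlock <- function(cfg, spectra, patientId, groupLabel, fieldId,
                              channels = defaultChannelSet(),
                              nCells = cfg$cellsPerField,
                              patientEffects = NULL, refs = NULL) {
  stopifnot(inherits(cfg, "cohortConfig"), is(spectra, "EndmemberSpectra"))
  R <- endmemberResponse(spectra)
  if (nrow(R) != nChannels(channels))
    stopf("endmember spectra have %d channels, channel set has %d",
          nrow(R), nChannels(channels))
  shape <- cfg$imageShape
  npx <- prod(shape)
  fl <- colnames(R)
  groupLabel <- as.integer(groupLabel)

  if (is.null(patientEffects))
    patientEffects <- samplePatientEffects(cfg, fl, groupLabel)

  # --- cell placement (non-overlapping ellipses, bounded retries) -------
  li <- matrix(0L, shape[1], shape[2])
  rr <- cfg$cellRadiusRange
  margin <- rr[2] + 2
  if (2 * margin >= min(shape))
    stopf("image shape %s too small for cell radius range", paste(shape, collapse = "x"))
  for (k in seq_len(nCells)) {
    placed <- FALSE
    for (try in 1:200) {
      cy <- runif(1, margin, shape[1] - margin)
      cx <- runif(1, margin, shape[2] - margin)
      a <- runif(1, rr[1], rr[2]); b <- runif(1, rr[1], rr[2])
      th <- runif(1, 0, pi)
      px <- ellipsePixels(shape, cy, cx, a, b, th)
      if (length(px) && all(li[px] == 0L)) {
        li[px] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stopf("could not place cell %d of %d without overlap in field %s",
            k, nCells, fieldId)
  }

  # --- per-cell abundances and clean signal ----------------------------
  logA <- matrix(0, nCells, length(fl), dimnames = list(NULL, fl))
  for (f in fl)
    logA[, f] <- rnorm(nCells, patientEffects[[f]], cfg$withinPatientSd)
  texture <- if (cfg$textureSd > 0)
    exp(cfg$textureSd * smoothField(shape) - cfg$textureSd^2 / 2)
  else matrix(1, shape[1], shape[2])
  M <- matrix(0, npx, length(fl))           # per-pixel abundance maps
  for (k in seq_len(nCells)) {
    px <- which(li == k)
    for (j in seq_along(fl))
      M[px, j] <- exp(logA[k, j]) * texture[px]
  }
  illum <- illuminationField(shape, cfg$vignettingStrength, cfg$vignettingTilt)
  P <- M %*% t(R)                           # pixels x channels, counts/s
  expo <- exposures(channels)
  clean <- array(0, c(shape, nChannels(channels)))
  for (c in seq_len(nChannels(channels)))
    clean[, , c] <- illum * matrix(P[, c], shape[1], shape[2]) * expo[c]

  # --- observation model ------------------------------------------------
  sat <- 2^16 - 1
  bad <- array(0L, dim(clean))
  imgs <- array(0, dim(clean))
  for (c in seq_len(nChannels(channels))) {
    lam <- clean[, , c] + cfg$waterBackground
    if (cfg$noise) {
      obs <- rpois(npx, as.vector(lam)) + cfg$darkOffset +
        rnorm(npx, 0, cfg$readNoise)
      obs <- round(pmin(pmax(obs, 0), sat))
      hot <- runif(npx) < cfg$hotPixelRate
      dead <- !hot & runif(npx) < cfg$deadPixelRate
      obs[hot] <- sat
      obs[dead] <- 0
      b <- integer(npx); b[hot] <- 1L; b[dead] <- 2L
      bad[, , c] <- b
      imgs[, , c] <- obs
    } else {
      imgs[, , c] <- lam + cfg$darkOffset
    }
  }
  if (is.null(refs)) refs <- makeReferences(cfg, channels, illum)
  bf <- 3000 * (1 - 0.3 * (li > 0)) +
    if (cfg$noise) rnorm(npx, 0, cfg$readNoise) else 0
  bf <- round(pmin(pmax(bf, 0), sat))

  block <- DataBlock(channels, imgs, matrix(bf, shape[1], shape[2]),
                     dark = refs$dark, water = refs$water,
                     calibration = refs$calibration,
                     fieldId = fieldId, patientId = patientId,
                     groupLabel = groupLabel, bitDepth = 16L,
                     saturationLevel = sat)
  mask <- CellMask(li, fieldId = fieldId)
  truth <- list(
    abundances = data.frame(patient_id = patientId, field_id = fieldId,
                            cell_id = seq_len(nCells),
                            group_label = groupLabel,
                            setNames(as.data.frame(logA),
                                     paste0("log_", gsub("[^A-Za-z0-9]", "",
                                                         tolower(fl)))),
                            log_ratio = logA[, "NAD(P)H"] - logA[, "flavins"]),
    clean = clean, illumination = illum, badPixels = bad,
    patientEffects = patientEffects)
  list(block = block, mask = mask, truth = truth)
}

# The group effect is split symmetrically over the two anchor fluorophores
# (+effect/4 on NAD(P)H, -effect/4 on flavins for group 0; reversed for
# group 1), so the group difference of the mean log redox ratio is exactly
# `effect`. With independent equal-variance log-abundances the symmetric
# split makes the log-ratio the Bayes-sufficient statistic: no feature of
# the true abundances can beat designedAUC(cfg), whereas a one-sided shift
# would let absolute NAD(P)H intensity exceed it.
samplePatientEffects <- function(cfg, fluorophores, groupLabel) {
  sgn <- 1 - 2 * groupLabel                # +1 for group 0, -1 for group 1
  out <- list()
  for (f in fluorophores) {
    base <- if (f %in% names(cfg$baseLogAbundance)) cfg$baseLogAbundance[[f]]
            else cfg$nuisanceLogAbundance
    shift <- switch(f, "NAD(P)H" = sgn * cfg$effect / 4,
                    "flavins" = -sgn * cfg$effect / 4, 0)
    out[[f]] <- rnorm(1, base + shift, cfg$betweenPatientSd)
  }
  out
}

#' Generate a synthetic patient cohort
#'
#' Hierarchical sampling at the study's scale: patient-level mean
#' log-abundances are Normal(group mean, between-patient sd), cell-level
#' log-abundances Normal(patient mean, within-patient sd); the group shift
#' is split symmetrically over NAD(P)H and flavins so the group difference
#' of the true log redox ratio is exactly \code{effect} and the log-ratio is
#' the Bayes-sufficient statistic. Fields are filled with \code{cellsPerField} cells
#' (the last field of a group may hold fewer so group totals are hit
#' exactly) and dealt to patients round-robin; each patient shares one
#' reference-image session.
#'
#' With \code{outDir} set, every block and mask is written through
#' [writeDataBlock()] / [writeCellMask()] so downstream stages consume
#' files; a fixed seed makes the output directory byte-identical across
#' runs. With \code{outDir = NULL} blocks are kept in memory (intended for
#' small image shapes).
#'
#' @param cfg a [cohortConfig()].
#' @param spectra optional [EndmemberSpectra-class]; generated from the
#'   master seed when \code{NULL}.
#' @param channels a [ChannelSet-class].
#' @param outDir optional cohort directory.
#' @return list with \code{truth} (per-cell data.frame of true
#'   log-abundances and labels), \code{channels}, \code{spectra},
#'   \code{config}, and either \code{blocks}/\code{masks} (in-memory mode)
#'   or \code{blockDirs}/\code{maskFiles} (file mode).
#' @export
generateCohort <- function(cfg, spectra = NULL, channels = defaultChannelSet(),
                           outDir = NULL) {
  stopifnot(inherits(cfg, "cohortConfig"))
  if (is.null(spectra))
    spectra <- makeEndmembers(channels, seed = childSeed(cfg$seed, 1L))
  keep <- is.null(outDir)
  if (!keep && !dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stopf("cannot create cohort directory %s", outDir)

  withSeed(childSeed(cfg$seed, 2L), {
    blocks <- list(); masks <- list(); blockDirs <- character()
    truthRows <- list()
    for (g in 0:1) {
      target <- cfg$cellsPerGroup[g + 1]
      nFields <- ceiling(target / cfg$cellsPerField)
      counts <- rep(cfg$cellsPerField, nFields)
      counts[nFields] <- target - (nFields - 1L) * cfg$cellsPerField
      pids <- sprintf("G%dP%02d", g + 1L, seq_len(cfg$nPatientsPerGroup))
      fieldPatient <- rep(pids, length.out = nFields)
      fl <- colnames(endmemberResponse(spectra))
      effects <- lapply(pids, function(p) samplePatientEffects(cfg, fl, g))
      names(effects) <- pids
      refsByPatient <- list()
      for (fi in seq_len(nFields)) {
        pid <- fieldPatient[fi]
        if (is.null(refsByPatient[[pid]]))
          refsByPatient[[pid]] <- makeReferences(
            cfg, channels,
            illuminationField(cfg$imageShape, cfg$vignettingStrength,
                              cfg$vignettingTilt))
        fid <- sprintf("G%dF%02d", g + 1L, fi)
        gb <- generateDataBlock(cfg, spectra, patientId = pid,
                                groupLabel = g, fieldId = fid,
                                channels = channels, nCells = counts[fi],
                                patientEffects = effects[[pid]],
                                refs = refsByPatient[[pid]])
        truthRows[[length(truthRows) + 1L]] <- gb$truth$abundances
        key <- paste(pid, fid, sep = "_")
        if (keep) {
          blocks[[key]] <- gb$block
          masks[[key]] <- gb$mask
        } else {
          bd <- file.path(outDir, "blocks", key)
          writeDataBlock(gb$block, bd)
          writeCellMask(gb$mask, file.path(bd, "mask.tif"))
          blockDirs[key] <- bd
        }
      }
    }
    truth <- do.call(rbind, truthRows)
    rownames(truth) <- NULL
    out <- list(truth = truth, channels = channels, spectra = spectra,
                config = cfg)
    if (keep) {
      out$blocks <- blocks
      out$masks <- masks
    } else {
      writeChannelSet(channels, file.path(outDir, "channels.csv"))
      em <- as.data.frame(endmemberResponse(spectra))
      write.csv(cbind(channel = seq_len(nrow(em)), em),
                file.path(outDir, "endmembers.csv"), row.names = FALSE)
      tw <- truth
      for (j in which(vapply(tw, is.numeric, logical(1)) &
                        colnames(tw) != "group_label"))
        tw[[j]] <- sprintf("%.15g", tw[[j]])
      write.csv(tw, file.path(outDir, "ground_truth.csv"),
                row.names = FALSE, quote = FALSE)
      writeCanonicalJSON(c(unclass(cfg)["seed"],
                           list(designed_auc = designedAUC(cfg),
                                n_blocks = length(blockDirs))),
                         file.path(outDir, "cohort.json"))
      out$blockDirs <- blockDirs
      out$dir <- outDir
    }
    out
  })
}
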