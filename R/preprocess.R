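#' @include datablock-io.R
NULL

#' Pixel-repair settings
#'
#' Controls the primary denoising step: removal of undetectable pixels and
#' outliers (spikes or dips) plus dead/saturated pixel repair.
#'
#' Outliers are pixels deviating from the local median by more than
#' \code{outlierK} sigma-consistent local MADs (MAD x 1.4826), measured in a
#' \code{detectWindow} x \code{detectWindow} neighborhood excluding the
#' center; flagged pixels are replaced by the median of the non-flagged
#' pixels in the \code{repairWindow} neighborhood. "Undetectable" is
#' operationalized as intensity below the channel's dark mean plus
#' \code{undetectableSd} dark standard deviations.
#'
#' @param outlierK MAD multiples for spike/dip detection (default 5).
#' @param repairWindow odd window for median repair (default 3).
#' @param detectWindow odd window for the median/MAD statistics (default 5;
#'   the larger detection window stabilizes the MAD so that clean Poisson
#'   pixels are almost never flagged).
#' @param clipNegative clip negatives to zero after background subtraction.
#' @param undetectableSd dark-sd multiples defining the undetectable floor.
#' @return a list of class \code{"correctionSettings"}.
#' @export
correctionSettings <- function(outlierK = 5, repairWindow = 3L,
                               detectWindow = 5L, clipNegative = TRUE,
                               undetectableSd = 2) {
  stopifnot(outlierK > 0,
            repairWindow >= 3, repairWindow %% 2 == 1,
            detectWindow >= 3, detectWindow %% 2 == 1)
  structure(list(outlierK = outlierK, repairWindow = as.integer(repairWindow),
                 detectWindow = as.integer(detectWindow),
                 clipNegative = isTRUE(clipNegative),
                 undetectableSd = undetectableSd),
            class = "correctionSettings")
}

#' Flag and repair bad pixels
#'
#' Per channel, flags pixels that are (i) at the saturation level, (ii) at
#' zero where the calibration image indicates a dead sensor element, (iii)
#' below the undetectable floor (dark mean + k dark sd), or (iv) spike/dip
#' outliers against the local median (see [correctionSettings()]). Flagged
#' pixels are replaced by the median of the non-flagged pixels in the repair
#' window; the flag map is returned for audit. Runs before reference
#' subtraction so that bad pixels cannot poison the corrections; the
#' detection thresholds are calibrated for raw images, so a block whose
#' processing log already records a repair passes through unchanged (this
#' makes the composed preprocessing chain idempotent).
#'
#' @param block a [DataBlock-class].
#' @param settings a [correctionSettings()].
#' @return list with \code{block} (repaired) and \code{badPixelMap}
#'   (integer array, 0 = clean, 1 = flagged).
#' @export
repairBadPixels <- function(block, settings = correctionSettings()) {
  stopifnot(is(block, "DataBlock"), inherits(settings, "correctionSettings"))
  if ("repair" %in% block@processing)      # already repaired: no-op, so the
    return(list(block = block,             # composed chain is idempotent
                badPixelMap = array(0L, dim(block@images))))
  imgs <- block@images
  n <- nChannels(block)
  badMap <- array(0L, dim(imgs))
  for (c in seq_len(n)) {
    img <- imgs[, , c]
    darkc <- block@dark[, , c]
    floorc <- mean(darkc) + settings$undetectableSd * sd(as.vector(darkc))
    calmd <- block@calibration[, , c] - darkc
    stat <- .localMedianMad(img, settings$detectWindow)
    dev <- abs(img - stat$median)
    flags <- img == block@saturationLevel |
      (img == 0 & calmd <= 0) |
      img < floorc |
      (dev > settings$outlierK * 1.4826 * stat$mad &
         dev > 1e-8 * (abs(stat$median) + 1))
    frac <- mean(flags)
    if (frac > 0.20)
      stopf("channel %d unusable: %.1f%% of pixels flagged", c, 100 * frac)
    if (any(flags)) {
      fallback <- median(img[!flags])
      imgs[, , c] <- .medianRepair(img, flags, settings$repairWindow, fallback)
      badMap[, , c] <- flags * 1L
    }
  }
  block@images <- imgs
  block@processing <- unique(c(block@processing, "repair"))
  list(block = block, badPixelMap = badMap)
}

#' Subtract reference images
#'
#' Per channel, subtracts the water reference from the sample image. The
#' water image is acquired with the dark offset included, so this removes
#' the camera offset and the buffer/stray background in one step; negatives
#' are clipped to zero by default. The block's references are updated
#' consistently (water and dark become zero, calibration becomes
#' calibration - dark), which makes the step idempotent.
#'
#' @param block a [DataBlock-class].
#' @param clipNegative clip negative results to 0 (default TRUE).
#' @return the corrected [DataBlock-class].
#' @export
subtractReferences <- function(block, clipNegative = TRUE) {
  stopifnot(is(block, "DataBlock"))
  imgs <- block@images - block@water
  if (clipNegative) imgs[imgs < 0] <- 0
  block@images <- imgs
  block@calibration <- block@calibration - block@dark
  block@dark <- array(0, dim(block@dark))
  block@water <- array(0, dim(block@water))
  block@processing <- unique(c(block@processing, "subtract"))
  validObject(block)
  block
}

#' Flatten uneven illumination using the calibration fluid
#'
#' Per channel, multiplies the image pixel-wise by
#' \code{mean(calibration - dark) / (calibration - dark)}: the calibration
#' fluid is spatially uniform, so its dark-subtracted image maps the
#' illumination/response field, and the mean normalization preserves the
#' spatial mean of a uniform target. After correction the stored calibration
#' image is replaced by its uniform mean so that reapplication is the
#' identity.
#'
#' @param block a [DataBlock-class].
#' @return the flat-fielded [DataBlock-class].
#' @export
flatfieldCorrect <- function(block) {
  stopifnot(is(block, "DataBlock"))
  imgs <- block@images
  calib <- block@calibration
  for (c in seq_len(nChannels(block))) {
    calmd <- calib[, , c] - block@dark[, , c]
    if (any(calmd <= 0))
      stopf("calibration not positive after dark subtraction in channel %d; repair references first", c)
    m <- mean(calmd)
    imgs[, , c] <- imgs[, , c] * (m / calmd)
    calib[, , c] <- block@dark[, , c] + m
  }
  block@images <- imgs
  block@calibration <- calib
  block@processing <- unique(c(block@processing, "flatfield"))
  block
}

#' Equalize channel exposures
#'
#' Divides each channel by its exposure time so intensities become counts
#' per second, making channels acquired with different exposures (up to 5 s)
#' directly comparable. Exposures are set to 1 afterwards, so the step is
#' idempotent.
#'
#' @param block a [DataBlock-class].
#' @return the equalized [DataBlock-class].
#' @export
equalizeExposure <- function(block) {
  stopifnot(is(block, "DataBlock"))
  expo <- exposures(block)
  if (any(expo <= 0)) stopf("non-positive exposure in channel %d",
                            which(expo <= 0)[1])
  imgs <- block@images
  for (c in seq_len(nChannels(block)))
    imgs[, , c] <- imgs[, , c] / expo[c]
  block@images <- imgs
  tb <- block@channels@table
  tb$exposure <- 1
  block@channels <- ChannelSet(tb)
  block@processing <- unique(c(block@processing, "equalize"))
  block
}

#' Full preprocessing chain
#'
#' Applies the fixed order repair -> reference subtraction -> flat-field ->
#' exposure equalization. Each step updates the block's references and
#' metadata so the composed map is idempotent on its own output.
#'
#' @param block a raw [DataBlock-class].
#' @param settings a [correctionSettings()].
#' @return list with \code{block} (preprocessed) and \code{badPixelMap}.
#' @examples
#' cs <- defaultChannelSet(34)
#' em <- makeEndmembers(cs, seed = 1)
#' cfg <- cohortConfig(imageShape = c(48, 48), cellRadiusRange = c(5, 7))
#' g <- withr::with_seed(1, generateDataBlock(cfg, em, "P1", 0L, "F1"))
#' pp <- preprocessBlock(g$block)
#' pp$block
#' @export
preprocessBlock <- function(block, settings = correctionSettings()) {
  rep1 <- repairBadPixels(block, settings)
  b <- subtractReferences(rep1$block, settings$clipNegative)
  b <- flatfieldCorrect(b)
  b <- equalizeExposure(b)
  list(block = b, badPixelMap = rep1$badPixelMap)
}
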