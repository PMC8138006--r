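#' @include datablock-io.R
NULL

FEATURE_KINDS <- c("mean", "top_decile_mean", "sd", "skewness", "kurtosis",
                   "ratio")

#' Feature-set policy
#'
#' The conservative model admits only features whose biological reading is
#' direct -- channel intensity means, top-decile means and channel intensity
#' ratios; the extended model additionally admits mathematically abstract
#' per-channel features (standard deviation, skewness, excess kurtosis).
#'
#' @param mode \code{"conservative"} or \code{"extended"}.
#' @param ratioChannels channels whose ordered pairs form the ratio feature
#'   list; default \code{c(2, 15, 32)}, the NAD(P)H- and flavin-dominated
#'   channels (channel 2 / channel 32 is the cellular redox ratio).
#' @param topDecile include top-10\%-pixel mean features (default TRUE;
#'   switch off to drop the thresholded variant).
#' @param exhaustiveRatios use all ordered channel pairs instead of
#'   \code{ratioChannels} (expensive: 34 x 33 features).
#' @return a list of class \code{"featurePolicy"}.
#' @export
featurePolicy <- function(mode = c("conservative", "extended"),
                          ratioChannels = c(2L, 15L, 32L),
                          topDecile = TRUE, exhaustiveRatios = FALSE) {
  mode <- match.arg(mode)
  structure(list(mode = mode, ratioChannels = as.integer(ratioChannels),
                 topDecile = isTRUE(topDecile),
                 exhaustiveRatios = isTRUE(exhaustiveRatios)),
            class = "featurePolicy")
}

#' Admissible feature descriptors under a policy
#'
#' Deterministic canonical ordering: channel means, top-decile means, ratios
#' (ordered pairs), then -- extended mode only -- per-channel sd, skewness
#' and kurtosis. Feature names are uniquely determined by kind and channels,
#' e.g. \code{"mean_ch02"}, \code{"ratio_ch02_ch32"}.
#'
#' @param policy a [featurePolicy()].
#' @param nChannels number of spectral channels.
#' @return \code{data.frame} with columns \code{name}, \code{kind},
#'   \code{channel_a}, \code{channel_b}.
#' @export
featureDescriptors <- function(policy, nChannels = 34L) {
  ch <- seq_len(nChannels)
  rows <- list(data.frame(name = paste0("mean_", chTag(ch)), kind = "mean",
                          channel_a = ch, channel_b = NA_integer_))
  if (policy$topDecile)
    rows <- c(rows, list(data.frame(name = paste0("top10_", chTag(ch)),
                                    kind = "top_decile_mean",
                                    channel_a = ch, channel_b = NA_integer_)))
  rc <- if (policy$exhaustiveRatios) ch else sort(policy$ratioChannels)
  if (any(rc > nChannels)) stopf("ratio channel outside the channel set")
  pairs <- expand.grid(channel_b = rc, channel_a = rc)[, 2:1]
  pairs <- pairs[pairs$channel_a != pairs$channel_b, , drop = FALSE]
  pairs <- pairs[order(pairs$channel_a, pairs$channel_b), , drop = FALSE]
  if (nrow(pairs))
    rows <- c(rows, list(data.frame(
      name = paste0("ratio_", chTag(pairs$channel_a), "_", chTag(pairs$channel_b)),
      kind = "ratio", channel_a = pairs$channel_a,
      channel_b = pairs$channel_b)))
  if (policy$mode == "extended") {
    for (k in c("sd", "skewness", "kurtosis")) {
      pre <- c(sd = "sd_", skewness = "skew_", kurtosis = "kurt_")[[k]]
      rows <- c(rows, list(data.frame(name = paste0(pre, chTag(ch)), kind = k,
                                      channel_a = ch,
                                      channel_b = NA_integer_)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract the pixel intensities of one cell
#'
#' Returns, per channel, the intensities of exactly the mask's pixels for
#' the requested cell, in registry order.
#'
#' @param block a preprocessed [DataBlock-class].
#' @param mask the field's [CellMask-class].
#' @param cellId a positive cell label present in the mask.
#' @return numeric matrix, pixels x channels.
#' @export
extractCellPixels <- function(block, mask, cellId) {
  rg <- cellRegistry(mask)
  rows <- rg[rg$cell == cellId, , drop = FALSE]
  if (nrow(rows) == 0L)
    stopf("cell id %s not present in mask for field %s", cellId, mask@fieldId)
  H <- dim(block@images)[1]
  lin <- rows$row + rows$col * H + 1L
  n <- nChannels(block)
  out <- matrix(0, nrow(rows), n,
                dimnames = list(NULL, chTag(seq_len(n))))
  npx <- prod(dim(block@images)[1:2])
  for (c in seq_len(n)) out[, c] <- block@images[lin + (c - 1L) * npx]
  out
}

#' Compute one spectral feature of a cell
#'
#' \code{mean}: arithmetic mean of the cell's pixels in a channel.
#' \code{top_decile_mean}: mean of the \eqn{\lceil 0.1 n \rceil} largest
#' pixels (at least one). \code{sd}: sample standard deviation (n-1).
#' \code{skewness}: adjusted Fisher--Pearson coefficient.
#' \code{kurtosis}: adjusted excess kurtosis. \code{ratio}: mean of channel
#' a over mean of channel b. Degenerate rules: moments of a constant (or
#' too-short) pixel vector are 0; a ratio with zero denominator yields 0
#' with a warning, so degenerate cells never abort a cohort run.
#'
#' @param pixels pixels x channels matrix from [extractCellPixels()].
#' @param kind one of \code{mean}, \code{top_decile_mean}, \code{sd},
#'   \code{skewness}, \code{kurtosis}, \code{ratio}.
#' @param channelA,channelB channel indices (\code{channelB} for ratios).
#' @return scalar feature value.
#' @export
computeFeature <- function(pixels, kind, channelA, channelB = NA) {
  kind <- match.arg(kind, FEATURE_KINDS)
  v <- pixels[, channelA]
  n <- length(v)
  if (n == 0L) stopf("empty pixel vector")
  switch(kind,
    mean = mean(v),
    top_decile_mean = {
      m <- max(1L, ceiling(0.1 * n))
      mean(sort(v, decreasing = TRUE)[seq_len(m)])
    },
    sd = if (n < 2L || all(v == v[1])) 0 else sd(v),
    skewness = {
      if (n < 3L || all(v == v[1])) 0
      else {
        s <- e1071::skewness(v, type = 2)
        if (is.finite(s)) s else 0
      }
    },
    kurtosis = {
      if (n < 4L || all(v == v[1])) 0
      else {
        k <- e1071::kurtosis(v, type = 2)
        if (is.finite(k)) k else 0
      }
    },
    ratio = {
      if (is.na(channelB)) stopf("ratio feature needs channelB")
      mb <- mean(pixels[, channelB])
      if (mb == 0) {
        warnf("zero denominator in ratio ch%02d/ch%02d; feature set to 0",
              channelA, channelB)
        0
      } else mean(v) / mb
    })
}

#' Build the per-cell feature table for a cohort
#'
#' One row per admissible feature, one column per cell, computed from
#' preprocessed blocks and their masks. Cells are ordered canonically by
#' (patient, field, cell id), so the result is invariant to the input block
#' order. Any non-finite feature aborts with the offending cell and feature
#' named.
#'
#' @param blocks list of preprocessed [DataBlock-class] objects, or a
#'   character vector of block directories (each holding a written block and
#'   a \code{mask.tif}).
#' @param masks list of [CellMask-class] objects parallel to \code{blocks};
#'   ignored when \code{blocks} is a directory vector.
#' @param policy a [featurePolicy()].
#' @return a validated [FeatureTable-class].
#' @export
buildFeatureTable <- function(blocks, masks = NULL,
                              policy = featurePolicy("conservative")) {
  fromDirs <- is.character(blocks)
  stopifnot(length(blocks) >= 1L,
            fromDirs || length(blocks) == length(masks))
  # blocks are loaded one at a time in directory mode, so cohort-scale
  # feature extraction never holds more than one image stack in memory
  loadPair <- function(i) {
    if (fromDirs) {
      b <- readDataBlock(blocks[[i]])
      list(b = b, m = readCellMask(file.path(blocks[[i]], "mask.tif"), b))
    } else list(b = blocks[[i]], m = masks[[i]])
  }
  first <- loadPair(1)
  nch <- nChannels(first$b)
  desc <- featureDescriptors(policy, nch)
  cols <- list(); info <- list()
  for (i in seq_along(blocks)) {
    pair <- if (i == 1L) first else loadPair(i)
    b <- pair$b; m <- pair$m
    for (cid in cellIds(m)) {
      px <- extractCellPixels(b, m, cid)
      vals <- vapply(seq_len(nrow(desc)), function(j)
        computeFeature(px, desc$kind[j], desc$channel_a[j], desc$channel_b[j]),
        numeric(1))
      bad <- which(!is.finite(vals))
      if (length(bad))
        stopf("non-finite feature '%s' for cell %s/%s/%s",
              desc$name[bad[1]], b@patientId, b@fieldId, cid)
      key <- paste(b@patientId, b@fieldId, cid, sep = "_")
      cols[[key]] <- vals
      info[[key]] <- data.frame(cell_id = cid, patient_id = b@patientId,
                                field_id = b@fieldId,
                                group_label = b@groupLabel)
    }
  }
  keys <- names(cols)
  cd <- do.call(rbind, info)
  ord <- order(cd$patient_id, cd$field_id, cd$cell_id)
  keys <- keys[ord]
  mat <- do.call(cbind, cols[keys])
  rownames(mat) <- desc$name
  colnames(mat) <- keys
  FeatureTable(mat, cd[ord, , drop = FALSE],
               featureData = desc,
               provenance = list(policy = policy$mode,
                                 ratio_channels = policy$ratioChannels))
}
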