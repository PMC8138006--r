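#' @include channels.R
NULL

FORMAT_VERSION <- "1"

#' Construct a data block
#'
#' @param channels a [ChannelSet-class].
#' @param images rows x cols x channels numeric array of autofluorescence
#'   intensities.
#' @param brightfield matrix with the same spatial shape.
#' @param dark,water,calibration per-channel reference image arrays.
#' @param fieldId,patientId identifiers.
#' @param groupLabel binary 0/1 patient status.
#' @param bitDepth camera bit depth.
#' @param saturationLevel maximum representable intensity (defaults to
#'   \code{2^bitDepth - 1}).
#' @param processing processing-step log (empty for raw blocks).
#' @return a validated [DataBlock-class].
#' @export
DataBlock <- function(channels, images, brightfield, dark, water, calibration,
                      fieldId, patientId, groupLabel, bitDepth = 16L,
                      saturationLevel = 2^bitDepth - 1,
                      processing = character()) {
  new("DataBlock", channels = channels, images = images,
      brightfield = brightfield, dark = dark, water = water,
      calibration = calibration, fieldId = as.character(fieldId),
      patientId = as.character(patientId), groupLabel = as.integer(groupLabel),
      bitDepth = as.integer(bitDepth),
      saturationLevel = as.numeric(saturationLevel), processing = processing)
}

# ---- low-level stack IO ------------------------------------------------
# Raw integer data are stored as 16-bit pages (lossless, verified exact);
# anything non-integral (preprocessed stacks) as 32-bit float scaled into
# [0, 1] with the scale recorded in the sidecar.

writeStack <- function(arr, path, saturationLevel) {
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  if (min(arr) < 0) stopf("negative intensities cannot be serialized: %s", path)
  pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
  integral <- all(vapply(pages, function(p)
    all(p == round(p)) && max(p) <= 65535, logical(1)))
  if (integral) {
    ok <- tiff::writeTIFF(lapply(pages, function(p) p / 65535), path,
                          bits.per.sample = 16L, compression = "none")
    scale <- NA_real_
  } else {
    scale <- max(max(arr), 1e-12)
    ok <- tiff::writeTIFF(lapply(pages, function(p) p / scale), path,
                          bits.per.sample = 32L, compression = "none")
    scale <- scale
  }
  if (!isTRUE(ok > 0)) stopf("failed to write %s", path)
  scale
}

readStack <- function(path, scale = NA_real_) {
  if (!file.exists(path)) stopf("image file not found: %s", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = is.na(scale))
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    arr[, , k] <- if (is.na(scale)) p else p * scale
  }
  arr
}

# ---- data block IO -----------------------------------------------------

#' Write and read a multispectral data block
#'
#' A block is laid out as one directory holding multi-page lossless TIFF
#' stacks (page order = channel index) for the channel images and each
#' reference set, a single-page brightfield TIFF, and a canonical JSON
#' sidecar (\code{metadata.json}) carrying identifiers, the full per-channel
#' table (excitation/emission bands, exposures, averaging), bit depth,
#' saturation level and the processing log. Raw integer intensities
#' round-trip bit-exactly; preprocessed float stacks round-trip to 32-bit
#' float precision with the scale factor recorded in the sidecar. Two writes
#' of one block produce byte-identical sidecars.
#'
#' @param block a [DataBlock-class].
#' @param dir output directory (created if needed).
#' @param channels optional [ChannelSet-class] the block must conform to; a
#'   channel-count mismatch between sidecar and this set is fatal.
#' @return \code{writeDataBlock}: \code{dir}, invisibly.
#'   \code{readDataBlock}: a validated [DataBlock-class].
#' @examples
#' cs <- defaultChannelSet(34)
#' em <- makeEndmembers(cs, seed = 1)
#' cfg <- cohortConfig(imageShape = c(48, 48), cellRadiusRange = c(5, 7))
#' g <- withr::with_seed(1,
#'   generateDataBlock(cfg, em, patientId = "P1", groupLabel = 0L,
#'                     fieldId = "F1"))
#' d <- file.path(tempdir(), "blk")
#' writeDataBlock(g$block, d)
#' b2 <- readDataBlock(d)
#' stopifnot(identical(channelImages(b2), channelImages(g$block)))
#' @export
writeDataBlock <- function(block, dir) {
  stopifnot(is(block, "DataBlock"))
  validObject(block)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stopf("cannot create output directory %s", dir)
  scales <- list(
    channels = writeStack(block@images, file.path(dir, "channels.tif"),
                          block@saturationLevel),
    brightfield = writeStack(block@brightfield,
                             file.path(dir, "brightfield.tif"),
                             block@saturationLevel),
    dark = writeStack(block@dark, file.path(dir, "dark.tif"),
                      block@saturationLevel),
    water = writeStack(block@water, file.path(dir, "water.tif"),
                       block@saturationLevel),
    calibration = writeStack(block@calibration,
                             file.path(dir, "calibration.tif"),
                             block@saturationLevel))
  meta <- list(
    format_version = FORMAT_VERSION,
    field_id = block@fieldId, patient_id = block@patientId,
    group_label = block@groupLabel, bit_depth = block@bitDepth,
    saturation_level = block@saturationLevel,
    processing = as.list(block@processing),
    n_channels = nChannels(block),
    channels = lapply(seq_len(nChannels(block)), function(i)
      as.list(channelTable(block)[i, , drop = FALSE])),
    float_scales = lapply(scales, function(s) if (is.na(s)) NULL else s))
  writeCanonicalJSON(meta, file.path(dir, "metadata.json"))
  invisible(dir)
}

#' @rdname writeDataBlock
#' @export
readDataBlock <- function(dir, channels = NULL) {
  metaPath <- file.path(dir, "metadata.json")
  if (!file.exists(metaPath)) stopf("metadata sidecar missing in %s", dir)
  meta <- readJSON(metaPath)
  chTab <- do.call(rbind, lapply(meta$channels, function(ch)
    as.data.frame(ch[REQUIRED_CHANNEL_COLS])))
  cs <- ChannelSet(chTab)
  if (!is.null(channels)) {
    if (nChannels(channels) != nChannels(cs))
      stopf("metadata lists %d channels but the channel set has %d",
            nChannels(cs), nChannels(channels))
    cs <- channels
  }
  sc <- function(nm) {
    s <- meta$float_scales[[nm]]
    if (is.null(s)) NA_real_ else as.numeric(s)
  }
  imgs <- readStack(file.path(dir, "channels.tif"), sc("channels"))
  if (dim(imgs)[3] != nChannels(cs)) {
    absent <- setdiff(seq_len(nChannels(cs)), seq_len(dim(imgs)[3]))
    stopf("channel stack holds %d pages for a %d-channel set; missing channel index %s",
          dim(imgs)[3], nChannels(cs),
          paste(absent, collapse = ","))
  }
  bf <- readStack(file.path(dir, "brightfield.tif"), sc("brightfield"))[, , 1]
  DataBlock(cs, imgs, bf,
            dark = readStack(file.path(dir, "dark.tif"), sc("dark")),
            water = readStack(file.path(dir, "water.tif"), sc("water")),
            calibration = readStack(file.path(dir, "calibration.tif"),
                                    sc("calibration")),
            fieldId = meta$field_id, patientId = meta$patient_id,
            groupLabel = meta$group_label, bitDepth = meta$bit_depth,
            saturationLevel = meta$saturation_level,
            processing = unlist(meta$processing) %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- masks -------------------------------------------------------------

#' Construct a cell mask from a label image
#'
#' Builds the per-cell pixel registry (0-based row/column coordinates, sorted
#' by cell then column-major pixel order) from an integer label image.
#' Labels need not be contiguous; 0 is background.
#'
#' @param labelImage integer matrix, 0 = background, k > 0 = cell k.
#' @param fieldId field identifier.
#' @return a validated [CellMask-class].
#' @export
CellMask <- function(labelImage, fieldId = "field") {
  stopifnot(is.matrix(labelImage))
  storage.mode(labelImage) <- "integer"
  pos <- which(labelImage > 0)
  if (length(pos) == 0L) stopf("no cells in field %s: mask has no positive labels",
                               fieldId)
  rows0 <- (pos - 1L) %% nrow(labelImage)
  cols0 <- (pos - 1L) %/% nrow(labelImage)
  rg <- data.frame(cell = labelImage[pos], row = rows0, col = cols0)
  rg <- rg[order(rg$cell, rg$col, rg$row), , drop = FALSE]
  rownames(rg) <- NULL
  new("CellMask", labelImage = labelImage, registry = rg,
      fieldId = as.character(fieldId))
}

#' Read / write a segmentation mask
#'
#' Masks are single-page 16-bit TIFF label images. On read, the mask must
#' match the block's spatial shape and contain at least one cell.
#'
#' @param path TIFF file path.
#' @param block the [DataBlock-class] the mask belongs to (shape check and
#'   field id).
#' @param mask a [CellMask-class].
#' @return \code{readCellMask}: a validated [CellMask-class];
#'   \code{writeCellMask}: the path, invisibly.
#' @export
readCellMask <- function(path, block) {
  li <- readStack(path)[, , 1]
  sp <- dim(block@images)[1:2]
  if (!identical(dim(li), sp))
    stopf("mask shape %s differs from block shape %s",
          paste(dim(li), collapse = "x"), paste(sp, collapse = "x"))
  CellMask(li, fieldId = block@fieldId)
}

#' @rdname readCellMask
#' @export
writeCellMask <- function(mask, path) {
  stopifnot(is(mask, "CellMask"))
  writeStack(mask@labelImage, path, 65535)
  invisible(path)
}

# ---- feature tables ----------------------------------------------------

#' Construct a feature table
#'
#' @param features features x cells numeric matrix with feature row names.
#' @param cellData \code{data.frame} with one row per cell: \code{cell_id},
#'   \code{patient_id}, \code{field_id}, \code{group_label}.
#' @param featureData optional per-feature annotation (kind, channels).
#' @param provenance optional list stored in \code{metadata()}.
#' @return a validated [FeatureTable-class].
#' @export
FeatureTable <- function(features, cellData, featureData = NULL,
                         provenance = list()) {
  cd <- DataFrame(cellData)
  cd$group_label <- as.integer(cd$group_label)
  rd <- if (is.null(featureData)) DataFrame(row.names = rownames(features))
        else DataFrame(featureData)
  se <- SummarizedExperiment(assays = list(features = features),
                             colData = cd, rowData = rd)
  metadata(se) <- c(list(package_version = as.character(packageVersion("specell"))),
                    provenance)
  new("FeatureTable", se)
}

featureTableFrame <- function(ft) {
  m <- t(featureMatrix(ft))
  cd <- as.data.frame(colData(ft))
  df <- cbind(cd[, c("patient_id", "field_id", "cell_id", "group_label")],
              as.data.frame(m))
  ord <- order(df$patient_id, df$field_id, df$cell_id)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write / read a feature table as CSV
#'
#' One row per cell, one header row, comma delimiter and '.' decimal. Rows
#' are written in canonical order (patient, then field, then cell id) and
#' numeric values with 15 significant digits, so the file round-trips
#' losslessly at 12+ significant digits and two writes of one table are
#' byte-identical regardless of input row order.
#'
#' @param ft a [FeatureTable-class].
#' @param path CSV path.
#' @return \code{writeFeatureTable}: the path invisibly;
#'   \code{readFeatureTable}: a validated [FeatureTable-class].
#' @export
writeFeatureTable <- function(ft, path) {
  stopifnot(is(ft, "FeatureTable"))
  validObject(ft)
  df <- featureTableFrame(ft)
  num <- vapply(df, is.numeric, logical(1)) &
    !colnames(df) %in% c("group_label")
  for (j in which(num)) df[[j]] <- sprintf("%.15g", df[[j]])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stopf("feature table not found: %s", path)
  df <- read.csv(path, check.names = FALSE)
  idCols <- c("patient_id", "field_id", "cell_id", "group_label")
  miss <- setdiff(idCols, colnames(df))
  if (length(miss))
    stopf("feature table missing required column(s): %s",
          paste(miss, collapse = ", "))
  featCols <- setdiff(colnames(df), idCols)
  m <- t(as.matrix(df[, featCols, drop = FALSE]))
  colnames(m) <- paste(df$patient_id, df$field_id, df$cell_id, sep = "_")
  FeatureTable(m, df[, idCols, drop = FALSE])
}
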