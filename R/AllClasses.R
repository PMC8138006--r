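#' @include specell-package.R
NULL

REQUIRED_CHANNEL_COLS <- c("index", "excitation_center", "excitation_halfwidth",
                           "emission_low", "emission_high", "exposure",
                           "n_averages")

#' Spectral channel set
#'
#' An ordered table of spectral channels, one row per (excitation band,
#' emission band) pair. The default acquisition geometry uses 34 channels
#' spanning excitation 340--510 nm and emission 420--650 nm, exposures up to
#' 5 s and 3-frame averaging.
#'
#' @slot table a \code{data.frame} with columns \code{index},
#'   \code{excitation_center}, \code{excitation_halfwidth},
#'   \code{emission_low}, \code{emission_high}, \code{exposure} (seconds) and
#'   \code{n_averages}.
#' @seealso [defaultChannelSet()], [readChannelSet()]
#' @exportClass ChannelSet
setClass("ChannelSet", representation(table = "data.frame"))

setValidity("ChannelSet", function(object) {
  tb <- object@table
  miss <- setdiff(REQUIRED_CHANNEL_COLS, colnames(tb))
  if (length(miss))
    return(paste("missing channel columns:", paste(miss, collapse = ", ")))
  if (nrow(tb) < 1L) return("channel set is empty")
  idx <- tb$index
  if (anyDuplicated(idx) || !identical(as.integer(idx), seq_len(nrow(tb))))
    return("channel indices must be unique and contiguous starting at 1")
  if (any(tb$excitation_center < 340 | tb$excitation_center > 510))
    return("excitation_center outside [340, 510] nm")
  if (any(tb$emission_low < 420 | tb$emission_high > 650))
    return("emission band outside [420, 650] nm")
  if (any(tb$emission_low >= tb$emission_high))
    return("emission_low must be < emission_high")
  if (any(tb$emission_low <= tb$excitation_center))
    return("emission_low must exceed excitation_center")
  if (any(tb$exposure <= 0 | tb$exposure > 5))
    return("exposure must satisfy 0 < exposure <= 5 s")
  if (any(tb$n_averages < 1))
    return("n_averages must be >= 1")
  TRUE
})

#' Multispectral data block
#'
#' The per-field acquisition bundle: one autofluorescence image per spectral
#' channel of the same sample area, a brightfield image, and per-channel
#' reference images (dark, water, calibration fluid of 30 uM NADH + 18 uM
#' FAD) used by the preprocessing stages.
#'
#' @slot channels a [ChannelSet-class].
#' @slot images numeric array, rows x cols x channels.
#' @slot brightfield numeric matrix with the same spatial shape.
#' @slot dark,water,calibration reference image arrays, rows x cols x
#'   channels each.
#' @slot fieldId,patientId identifiers.
#' @slot groupLabel integer 0/1 binary patient status.
#' @slot bitDepth camera bit depth (16 by default).
#' @slot saturationLevel largest representable intensity.
#' @slot processing character log of preprocessing steps already applied.
#' @exportClass DataBlock
setClass("DataBlock", representation(
  channels = "ChannelSet", images = "array", brightfield = "matrix",
  dark = "array", water = "array", calibration = "array",
  fieldId = "character", patientId = "character", groupLabel = "integer",
  bitDepth = "integer", saturationLevel = "numeric",
  processing = "character"))

setValidity("DataBlock", function(object) {
  d <- dim(object@images)
  if (length(d) != 3L) return("images must be a rows x cols x channels array")
  nc <- nrow(object@channels@table)
  if (d[3] != nc)
    return(sprintf("found %d channel images for a %d-channel set", d[3], nc))
  sp <- d[1:2]
  for (nm in c("dark", "water", "calibration")) {
    dr <- dim(slot(object, nm))
    if (!identical(dr, d))
      return(sprintf("%s reference shape (%s) differs from images (%s)",
                     nm, paste(dr, collapse = "x"), paste(d, collapse = "x")))
  }
  if (!identical(dim(object@brightfield), sp))
    return("brightfield shape differs from channel images")
  if (!object@groupLabel %in% c(0L, 1L)) return("groupLabel must be 0 or 1")
  if (object@saturationLevel <= 0) return("saturationLevel must be positive")
  calmd <- object@calibration - object@dark
  for (c in seq_len(nc)) {
    if (any(calmd[, , c] <= 0))
      return(sprintf(
        "calibration not strictly positive after dark subtraction in channel %d", c))
  }
  TRUE
})

#' Labelled cell segmentation mask
#'
#' A label image (0 = background, k > 0 = cell k) for one field, with a
#' registry tying every cell to its pixel coordinates. Coordinates are
#' 0-based (row, column).
#'
#' @slot labelImage integer matrix.
#' @slot registry \code{data.frame} with columns \code{cell}, \code{row},
#'   \code{col} (0-based pixel coordinates).
#' @slot fieldId the field the mask belongs to.
#' @exportClass CellMask
setClass("CellMask", representation(
  labelImage = "matrix", registry = "data.frame", fieldId = "character"))

setValidity("CellMask", function(object) {
  li <- object@labelImage
  if (any(li < 0)) return("negative labels in mask")
  labs <- sort(unique(li[li > 0]))
  if (length(labs) == 0L) return("no cells in field: mask has no positive labels")
  rg <- object@registry
  if (!all(c("cell", "row", "col") %in% colnames(rg)))
    return("registry must have columns cell, row, col")
  if (!setequal(unique(rg$cell), labs))
    return("registry cells do not match label image labels")
  if (any(rg$row < 0 | rg$row >= nrow(li) | rg$col < 0 | rg$col >= ncol(li)))
    return("registry pixel coordinates outside image bounds")
  TRUE
})

#' Per-cell spectral feature table
#'
#' A \linkS4class{SummarizedExperiment} holding the features x cells matrix
#' in assay \code{"features"}. \code{colData} carries \code{cell_id},
#' \code{patient_id}, \code{field_id} and the binary \code{group_label};
#' \code{rowData} records each feature's kind and channel(s). Provenance
#' (package version, feature policy) lives in \code{metadata()}.
#'
#' @exportClass FeatureTable
setClass("FeatureTable", contains = "SummarizedExperiment")

setValidity("FeatureTable", function(object) {
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    return("assay 'features' is required")
  cd <- colData(object)
  need <- c("cell_id", "patient_id", "field_id", "group_label")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    return(paste("colData missing:", paste(miss, collapse = ", ")))
  if (!all(cd$group_label %in% c(0L, 1L)))
    return("group_label must be binary 0/1")
  m <- assay(object, "features")
  if (any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    return(sprintf("non-finite feature value: feature '%s', cell '%s'",
                   rownames(m)[bad[1]], colnames(m)[bad[2]]))
  }
  key <- paste(cd$patient_id, cd$field_id, cd$cell_id)
  if (anyDuplicated(key)) return("duplicate (patient, field, cell) rows")
  TRUE
})

#' Fluorophore endmember spectra
#'
#' Per-channel emission response of each fluorophore per unit abundance.
#' In this acquisition geometry channel 2 is dominated by NAD(P)H and
#' channels 15 and 32 by flavins, which the validity method enforces.
#'
#' @slot response non-negative matrix, channels x fluorophores, with
#'   fluorophore column names including \code{"NAD(P)H"} and
#'   \code{"flavins"}.
#' @exportClass EndmemberSpectra
setClass("EndmemberSpectra", representation(response = "matrix"))

setValidity("EndmemberSpectra", function(object) {
  R <- object@response
  if (is.null(colnames(R))) return("response needs fluorophore column names")
  if (!all(c("NAD(P)H", "flavins") %in% colnames(R)))
    return("fluorophores must include NAD(P)H and flavins")
  if (any(R < 0)) return("response must be non-negative")
  if (nrow(R) < 32) return("response needs at least 32 channel rows")
  if (any(colSums(R) == 0)) return("every fluorophore needs a non-zero channel")
  if (which.max(R[, "NAD(P)H"]) != 2L)
    return("NAD(P)H response must peak in channel 2")
  topf <- order(R[, "flavins"], decreasing = TRUE)[1:2]
  if (!setequal(topf, c(15L, 32L)))
    return("flavins response must be largest in channels 15 and 32")
  TRUE
})

#' Canonical discriminant projection
#'
#' Selected features plus unit weight vectors spanning the discriminative
#' space: \code{w1} is the Fisher direction, \code{w2} the Fisher direction
#' in the orthogonal complement of \code{w1} (empty when only one feature is
#' selected), and \code{w1d = w1} defines the optimal 1-D projection.
#' Standardization constants from the training data are stored so projection
#' of new cells is self-contained.
#'
#' @slot features ordered selected feature names.
#' @slot w1,w2,w1d unit weight vectors over \code{features}.
#' @slot center,scale training means and standard deviations.
#' @slot gamma shrinkage weight used on the within-class covariance.
#' @slot criterion Fisher criterion value attained by \code{w1}.
#' @exportClass CanonicalProjection
setClass("CanonicalProjection", representation(
  features = "character", w1 = "numeric", w2 = "numeric", w1d = "numeric",
  center = "numeric", scale = "numeric", gamma = "numeric",
  criterion = "numeric"))

setValidity("CanonicalProjection", function(object) {
  p <- length(object@features)
  if (length(object@w1) != p || length(object@w1d) != p)
    return("w1/w1d length must match features")
  if (!length(object@w2) %in% c(0L, p))
    return("w2 must be empty or match features")
  unit <- function(v) abs(sqrt(sum(v^2)) - 1) < 1e-6
  if (!unit(object@w1)) return("w1 must be unit length")
  if (!unit(object@w1d)) return("w1d must be unit length")
  if (length(object@w2)) {
    if (!unit(object@w2)) return("w2 must be unit length")
    if (abs(sum(object@w1 * object@w2)) > 1e-6) return("w1 and w2 must be orthogonal")
  }
  TRUE
})

#' Nested cross-validation report
#'
#' Fold structure, per-fold and pooled held-out performance, the features and
#' feature count chosen inside each outer fold, and the group test on pooled
#' held-out scores.
#'
#' @slot folds list: per outer fold, the held-out grouping units.
#' @slot scores data.frame of pooled held-out cells (cell, patient, field,
#'   label, score, fold).
#' @slot foldAUC numeric per-fold held-out AUC.
#' @slot pooledAUC AUC of all pooled held-out scores.
#' @slot roc pooled ROC curve (list with fpr, tpr, thresholds, auc).
#' @slot chosen list per fold: chosen feature count and names.
#' @slot groupTest Mann-Whitney result on pooled scores.
#' @slot config the [cvConfig()] used, seed included.
#' @exportClass ValidationReport
setClass("ValidationReport", representation(
  folds = "list", scores = "data.frame", foldAUC = "numeric",
  pooledAUC = "numeric", roc = "list", chosen = "list",
  groupTest = "list", config = "list"))

setValidity("ValidationReport", function(object) {
  units <- unlist(object@folds, use.names = FALSE)
  if (anyDuplicated(units))
    return("a grouping unit appears in more than one outer test fold")
  if (length(object@foldAUC) != length(object@folds))
    return("one AUC per outer fold required")
  TRUE
})
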