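#' @include AllGenerics.R
NULL

#' Accessors for the core classes
#'
#' Slot access for \linkS4class{ChannelSet}, \linkS4class{DataBlock},
#' \linkS4class{CellMask}, \linkS4class{FeatureTable} and
#' \linkS4class{EndmemberSpectra} objects.
#'
#' @param x the object.
#' @return \code{nChannels}: integer; \code{channelTable}: the channel
#'   \code{data.frame}; \code{channelImages}: rows x cols x channels array;
#'   \code{referenceImages}: named list of arrays (dark, water, calibration);
#'   \code{exposures}: per-channel seconds; \code{labelImage}: integer
#'   matrix; \code{cellRegistry}: 0-based coordinate \code{data.frame};
#'   \code{cellIds}: sorted positive labels; \code{featureMatrix}: features x
#'   cells matrix; \code{groupLabels}, \code{patientIds}: per-cell vectors;
#'   \code{endmemberResponse}: channels x fluorophores matrix.
#' @name accessors
#' @aliases nChannels channelTable channelImages brightfield referenceImages
#'   exposures saturationLevel labelImage cellRegistry cellIds featureMatrix
#'   groupLabels patientIds endmemberResponse
NULL

#' @rdname accessors
#' @export
setMethod("nChannels", "ChannelSet", function(x) nrow(x@table))
#' @rdname accessors
#' @export
setMethod("nChannels", "DataBlock", function(x) nrow(x@channels@table))
#' @rdname accessors
#' @export
setMethod("channelTable", "ChannelSet", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("channelTable", "DataBlock", function(x) x@channels@table)
#' @rdname accessors
#' @export
setMethod("channelImages", "DataBlock", function(x) x@images)
#' @rdname accessors
#' @export
setMethod("brightfield", "DataBlock", function(x) x@brightfield)
#' @rdname accessors
#' @export
setMethod("referenceImages", "DataBlock", function(x)
  list(dark = x@dark, water = x@water, calibration = x@calibration))
#' @rdname accessors
#' @export
setMethod("exposures", "ChannelSet", function(x) x@table$exposure)
#' @rdname accessors
#' @export
setMethod("exposures", "DataBlock", function(x) x@channels@table$exposure)
#' @rdname accessors
#' @export
setMethod("saturationLevel", "DataBlock", function(x) x@saturationLevel)
#' @rdname accessors
#' @export
setMethod("labelImage", "CellMask", function(x) x@labelImage)
#' @rdname accessors
#' @export
setMethod("cellRegistry", "CellMask", function(x) x@registry)
#' @rdname accessors
#' @export
setMethod("cellIds", "CellMask", function(x) sort(unique(x@registry$cell)))
#' @rdname accessors
#' @export
setMethod("featureMatrix", "FeatureTable", function(x) assay(x, "features"))
#' @rdname accessors
#' @export
setMethod("groupLabels", "FeatureTable", function(x)
  as.integer(colData(x)$group_label))
#' @rdname accessors
#' @export
setMethod("patientIds", "FeatureTable", function(x)
  as.character(colData(x)$patient_id))
#' @rdname accessors
#' @export
setMethod("endmemberResponse", "EndmemberSpectra", function(x) x@response)

setMethod("show", "ChannelSet", function(object) {
  tb <- object@table
  cat(sprintf("ChannelSet with %d channels\n", nrow(tb)))
  cat(sprintf("  excitation %g-%g nm, emission %g-%g nm\n",
              min(tb$excitation_center), max(tb$excitation_center),
              min(tb$emission_low), max(tb$emission_high)))
  cat(sprintf("  exposures %g-%g s, averaging x%d\n",
              min(tb$exposure), max(tb$exposure), max(tb$n_averages)))
})

setMethod("show", "DataBlock", function(object) {
  d <- dim(object@images)
  cat(sprintf("DataBlock %s / field %s (group %d)\n",
              object@patientId, object@fieldId, object@groupLabel))
  cat(sprintf("  %d channels of %d x %d px, %d-bit (saturation %g)\n",
              d[3], d[1], d[2], object@bitDepth, object@saturationLevel))
  steps <- if (length(object@processing)) paste(object@processing, collapse = " -> ")
           else "none"
  cat("  processing:", steps, "\n")
})

setMethod("show", "CellMask", function(object) {
  ids <- cellIds(object)
  cat(sprintf("CellMask for field %s: %d cells (labels %s), %d px total\n",
              object@fieldId, length(ids),
              paste(ids, collapse = ","), nrow(object@registry)))
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d features x %d cells\n",
              nrow(object), ncol(object)))
  gl <- groupLabels(object)
  cat(sprintf("  groups: %d cells (group 0) / %d cells (group 1), %d patients\n",
              sum(gl == 0L), sum(gl == 1L), length(unique(patientIds(object)))))
  callNextMethod()
})

setMethod("show", "EndmemberSpectra", function(object) {
  R <- object@response
  cat(sprintf("EndmemberSpectra: %d channels x %d fluorophores (%s)\n",
              nrow(R), ncol(R), paste(colnames(R), collapse = ", ")))
})

setMethod("show", "CanonicalProjection", function(object) {
  cat(sprintf("CanonicalProjection over %d features (gamma = %.3g)\n",
              length(object@features), object@gamma))
  cat("  features:", paste(object@features, collapse = ", "), "\n")
  cat(sprintf("  Fisher criterion: %.4g\n", object@criterion))
})

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport: %d outer folds (%s-grouped)\n",
              length(object@folds),
              if (is.null(object@config$grouping)) "?" else object@config$grouping))
  cat(sprintf("  pooled held-out AUC %.3f (fold AUCs %s)\n", object@pooledAUC,
              paste(sprintf("%.3f", object@foldAUC), collapse = ", ")))
  gt <- object@groupTest
  if (length(gt)) {
    pTxt <- if (gt$p < 2.2e-16) "p < 2.2e-16" else sprintf("p = %.3g", gt$p)
    cat(sprintf("  Mann-Whitney U = %g, %s (%s)\n", gt$U, pTxt, gt$tier))
  }
})
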