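#' @include AllClasses.R
NULL

#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @export
setGeneric("channelTable", function(x) standardGeneric("channelTable"))
#' @export
setGeneric("channelImages", function(x) standardGeneric("channelImages"))
#' @export
setGeneric("brightfield", function(x) standardGeneric("brightfield"))
#' @export
setGeneric("referenceImages", function(x) standardGeneric("referenceImages"))
#' @export
setGeneric("exposures", function(x) standardGeneric("exposures"))
#' @export
setGeneric("saturationLevel", function(x) standardGeneric("saturationLevel"))
#' @export
setGeneric("labelImage", function(x) standardGeneric("labelImage"))
#' @export
setGeneric("cellRegistry", function(x) standardGeneric("cellRegistry"))
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))
#' @export
setGeneric("endmemberResponse", function(x) standardGeneric("endmemberResponse"))
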