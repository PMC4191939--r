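#' Accessor generics
#'
#' Small accessor layer over the package's S4 classes so user code never
#' touches slots directly.
#'
#' @param x An object of the documented class.
#' @param ... Passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname accessors
#' @export
setGeneric("genomeBins", function(x) standardGeneric("genomeBins"))

#' @rdname accessors
#' @export
setGeneric("pericentromere", function(x) standardGeneric("pericentromere"))

#' @rdname accessors
#' @export
setGeneric("mappability", function(x) standardGeneric("mappability"))

#' @rdname accessors
#' @export
setGeneric("retainedBins", function(x) standardGeneric("retainedBins"))

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname accessors
#' @export
setGeneric("permCounts", function(x) standardGeneric("permCounts"))

#' @rdname accessors
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' @rdname accessors
#' @export
setGeneric("nClassified", function(x) standardGeneric("nClassified"))

#' @rdname accessors
#' @export
setGeneric("nUnclassified", function(x) standardGeneric("nUnclassified"))

#' @rdname accessors
#' @export
setGeneric("profileBins", function(x) standardGeneric("profileBins"))

#' @rdname accessors
#' @export
setGeneric("baseWindows", function(x) standardGeneric("baseWindows"))

#' @rdname accessors
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))

#' @rdname accessors
#' @export
setGeneric("channelCounts", function(x) standardGeneric("channelCounts"))

#' Average replicate measurements
#'
#' @param x A [BinTable] (per-bin mean of sample counts) or a list of
#'   [PermutationProfile] objects (see [aggregateReplicates()]).
#' @param ... Method-specific arguments.
#' @export
setGeneric("averageReplicates", function(x, ...)
  standardGeneric("averageReplicates"))
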