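#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand reduce
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths seqlevels Seqinfo
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames rowData rowData<- rowRanges colData
NULL

#' Toy genome model for read-depth simulations
#'
#' A lightweight genome description used by the synthetic-data generators and
#' by the re-replication pipeline: chromosome lengths, a per-chromosome
#' pericentromeric interval carrying an elevated relative copy number, and a
#' binned mappability mask. It stands in for a real genome plus a read-length
#' mappability track in simulations where only bin-level structure matters.
#'
#' @slot seqlengths Named integer vector of chromosome lengths (bp).
#' @slot binSize Width (bp) of the bins on which mappability is defined.
#' @slot bins [GenomicRanges::GRanges] tiling of the genome at `binSize`,
#'   with metadata columns `mappability` (in \[0, 1\]) and `copy`
#'   (relative copy number, >= 0).
#' @slot pericentromere [GenomicRanges::GRanges] of the elevated-copy
#'   regions, metadata column `copyMultiplier`.
#'
#' @seealso [buildToyGenome()]
#' @export
setClass("GenomeModel",
  slots = c(
    seqlengths = "numeric",
    binSize = "integer",
    bins = "GRanges",
    pericentromere = "GRanges"
  )
)

setValidity("GenomeModel", function(object) {
  msg <- character()
  sl <- object@seqlengths
  if (is.null(names(sl)) || anyDuplicated(names(sl)))
    msg <- c(msg, "seqlengths must be uniquely named")
  if (any(sl <= 0)) msg <- c(msg, "chromosome lengths must be positive")
  mc <- mcols(object@bins)
  if (!all(c("mappability", "copy") %in% names(mc)))
    msg <- c(msg, "bins must carry 'mappability' and 'copy' columns")
  else {
    if (any(mc$mappability < 0 | mc$mappability > 1))
      msg <- c(msg, "mappability must lie in [0, 1]")
    if (any(mc$copy < 0)) msg <- c(msg, "copy multipliers must be >= 0")
  }
  peri <- object@pericentromere
  if (length(peri)) {
    within <- start(peri) >= 1 &
      end(peri) <= sl[as.character(seqnames(peri))]
    if (!all(within))
      msg <- c(msg, "pericentromeric intervals must lie within chromosomes")
  }
  if (length(msg)) msg else TRUE
})

#' Binned read counts with mappability and retention flags
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] whose rows are the
#' non-overlapping genome bins (default 10 kb) and whose `counts` assay holds
#' per-sample deduplicated read counts. Row metadata carries the bin
#' `mappability` and a logical `retained` flag maintained by [filterBins()];
#' bins are flagged rather than dropped so that sample grids stay aligned
#' across the whole pipeline.
#'
#' @seealso [binCounts()], [filterBins()], [averageReplicates()]
#' @export
setClass("BinTable", contains = "RangedSummarizedExperiment")

setValidity("BinTable", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "a 'counts' assay is required")
  else if (any(SummarizedExperiment::assay(object, "counts") < 0))
    msg <- c(msg, "counts must be non-negative")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("mappability", "retained") %in% names(rd)))
    msg <- c(msg, "rowData must carry 'mappability' and 'retained'")
  if (length(msg)) msg else TRUE
})

#' Per-bin log2 mutant/wild-type read-depth ratios
#'
#' @slot bins [GenomicRanges::GRanges] of the usable bins with metadata
#'   column `ratio` (log2 mutant / wild type).
#' @slot samples Character vector of length 2, `c(mutant, wildtype)` labels.
#' @slot nDropped Number of retained bins dropped because either sample had a
#'   zero count there.
#'
#' @seealso [log2Ratio()], [baseWindowScale()]
#' @export
setClass("RatioProfile",
  slots = c(bins = "GRanges", samples = "character", nDropped = "integer")
)

setValidity("RatioProfile", function(object) {
  if (!"ratio" %in% names(mcols(object@bins)))
    return("bins must carry a 'ratio' column")
  TRUE
})

#' Base-window scaled re-replication profile
#'
#' Per-bin scaled values `z = (ratio - mu_b) / sigma_b`, where `mu_b` and
#' `sigma_b` are the mean and SD of the log2 ratios over each chromosome's
#' base window (the sliding window of minimum mean ratio). The base window
#' therefore has mean scaled value 0, and values elsewhere are expressed in
#' units of the sample's own variability.
#'
#' @slot bins [GenomicRanges::GRanges] with metadata columns `ratio`, `z`
#'   and, after [smoothProfile()], `zSmooth`.
#' @slot baseWindows data.frame with one row per chromosome: `chrom`,
#'   `start`, `end` (1-based, inclusive), `mean`, `sd`, `nBins`.
#' @slot smoothK Running-mean width used for `zSmooth` (0 if unsmoothed).
#'
#' @seealso [baseWindowScale()], [smoothProfile()], [exportProfile()]
#' @export
setClass("ScaledProfile",
  slots = c(bins = "GRanges", baseWindows = "data.frame", smoothK = "integer")
)

setValidity("ScaledProfile", function(object) {
  if (!all(c("ratio", "z") %in% names(mcols(object@bins))))
    return("bins must carry 'ratio' and 'z' columns")
  TRUE
})

#' Terminal-permutation profile of one amplicon sample
#'
#' Counts and frequencies of the seven cyclic permutations of the plant
#' telomeric repeat TTTAGGG observed at the hairpin-ligation junction, i.e.
#' at the extreme 3' end of blunt-ended telomeres. Frequencies are computed
#' over classified reads only; reads without a locatable junction, without
#' sufficient upstream repeat context, or whose terminal 7-mer is not an
#' exact rotation are tallied as unclassified.
#'
#' @slot sampleId Sample label.
#' @slot counts Named integer vector over the 7 permutations
#'   (see [telomericPermutations()]).
#' @slot nUnclassified Number of reads that could not be classified.
#'
#' @seealso [profileSample()], [frequencies()], [aggregateReplicates()]
#' @export
setClass("PermutationProfile",
  slots = c(sampleId = "character", counts = "integer",
            nUnclassified = "integer")
)

setValidity("PermutationProfile", function(object) {
  msg <- character()
  if (length(object@counts) != 7L ||
      !identical(names(object@counts), telomericPermutations()))
    msg <- c(msg, "counts must be named by the 7 telomeric permutations")
  if (any(object@counts < 0) || object@nUnclassified < 0)
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Fluorescence histogram of nuclei (cytogram)
#'
#' Linear-scale flow-cytometry histogram: equal-width channels and the
#' number of nuclei recorded in each.
#'
#' @slot channels Numeric vector of channel midpoints, strictly increasing,
#'   equal spacing.
#' @slot counts Numeric vector of per-channel nucleus counts (>= 0).
#'
#' @seealso [simulateCytogram()], [detectPloidyPeaks()], [fitGaussianPeak()]
#' @export
setClass("Cytogram", slots = c(channels = "numeric", counts = "numeric"))

setValidity("Cytogram", function(object) {
  msg <- character()
  if (length(object@channels) != length(object@counts))
    msg <- c(msg, "channels and counts must have equal length")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  d <- diff(object@channels)
  if (length(d) && (any(d <= 0) ||
      max(d) - min(d) > 1e-6 * stats::median(d)))
    msg <- c(msg, "channels must be strictly increasing and equal width")
  if (length(msg)) msg else TRUE
})

#' Gaussian fit of one ploidy peak
#'
#' Least-squares Gaussian description of a single endoreduplication peak
#' (e.g. the 8C class) within its gate, together with the chi-square
#' peak-normality statistic and the right-shoulder excess fraction once
#' computed.
#'
#' @slot ploidyClass Ploidy class label ("2C" ... "32C").
#' @slot gate Numeric length-2 fluorescence gate (low, high).
#' @slot mu,sigma,amplitude Fitted Gaussian parameters.
#' @slot nGate Number of nuclei inside the gate.
#' @slot x2 Chi-square normality statistic (NA until [chi2Normality()]).
#' @slot shoulder Right-tail excess fraction (NA until [shoulderFraction()]).
#' @slot reliable FALSE when the gate holds fewer than 10 channels or fewer
#'   than 100 nuclei, or the fit did not converge.
#' @slot message Diagnostic note.
#'
#' @export
setClass("PeakFit",
  slots = c(ploidyClass = "character", gate = "numeric", mu = "numeric",
            sigma = "numeric", amplitude = "numeric", nGate = "numeric",
            x2 = "numeric", shoulder = "numeric", reliable = "logical",
            message = "character")
)

setValidity("PeakFit", function(object) {
  msg <- character()
  if (length(object@gate) != 2L || object@gate[1] >= object@gate[2])
    msg <- c(msg, "gate must be (low, high) with low < high")
  if (!is.na(object@sigma) && object@sigma <= 0)
    msg <- c(msg, "sigma must be positive")
  if (!is.na(object@shoulder) &&
      (object@shoulder < 0 || object@shoulder > 1))
    msg <- c(msg, "shoulder fraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
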