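#' Build a toy genome with pericentromeric copy gain
#'
#' Constructs a [GenomeModel] with `nChrom` equally sized chromosomes. A
#' pericentromeric interval covering `pericentromereFraction` of each
#' chromosome, centered on it, carries relative copy number `copyMultiplier`
#' (1 elsewhere). A random `unmappableFraction` of the bins get mappability 0
#' and all others mappability 1, emulating a read-length uniqueness
#' mappability track at bin resolution.
#'
#' @param nChrom Number of chromosomes.
#' @param chromLength Chromosome length in bp (>= 1e6).
#' @param pericentromereFraction Fraction of each chromosome covered by the
#'   elevated-copy pericentromere, in \[0, 1\].
#' @param copyMultiplier Relative copy number of the pericentromere (>= 0).
#' @param unmappableFraction Fraction of bins masked to mappability 0.
#' @param binSize Bin width in bp for the mappability grid (default 10 kb).
#' @param seed Integer seed; the mask is reproducible given the seed.
#'
#' @details A matched control genome (no copy gain, e.g. for simulating the
#' wild-type sample of a mutant/wild-type contrast) is obtained by calling
#' this function with `copyMultiplier = 1` and the same `seed`: the
#' mappability mask is then identical, only the sampling weights differ.
#' @return A [GenomeModel].
#' @examples
#' g <- buildToyGenome(2, 30e6, 0.2, 1.6, 0.02, seed = 7)
#' pericentromere(g)
#' @export
buildToyGenome <- function(nChrom = 2, chromLength = 30e6,
                           pericentromereFraction = 0.2,
                           copyMultiplier = 1.6,
                           unmappableFraction = 0.02,
                           binSize = 10000L, seed) {
  if (nChrom < 1 || chromLength < 1e6)
    stop("genome must have >= 1 chromosome of >= 1 Mb", call. = FALSE)
  .assertScalarNumber(pericentromereFraction, "pericentromereFraction", 0, 1)
  .assertScalarNumber(unmappableFraction, "unmappableFraction", 0, 1)
  .assertScalarNumber(copyMultiplier, "copyMultiplier", 0)
  seed <- .assertSeed(seed)

  sl <- stats::setNames(rep(as.numeric(chromLength), nChrom),
                        paste0("chr", seq_len(nChrom)))
  bins <- .binGrid(sl, binSize)

  if (pericentromereFraction > 0) {
    halfspan <- pericentromereFraction * chromLength / 2
    mid <- chromLength / 2
    peri <- GenomicRanges::GRanges(
      names(sl),
      IRanges::IRanges(floor(mid - halfspan) + 1, floor(mid + halfspan))
    )
    S4Vectors::mcols(peri)$copyMultiplier <- copyMultiplier
  } else {
    peri <- GenomicRanges::GRanges()
    S4Vectors::mcols(peri)$copyMultiplier <- numeric()
  }

  copy <- rep(1, length(bins))
  if (length(peri)) {
    ov <- GenomicRanges::findOverlaps(bins, peri, type = "within")
    copy[S4Vectors::queryHits(ov)] <-
      S4Vectors::mcols(peri)$copyMultiplier[S4Vectors::subjectHits(ov)]
  }
  mapp <- rep(1, length(bins))
  nMask <- round(unmappableFraction * length(bins))
  if (nMask > 0) {
    masked <- .withSeed(seed, sample.int(length(bins), nMask))
    mapp[masked] <- 0
  }
  S4Vectors::mcols(bins)$mappability <- mapp
  S4Vectors::mcols(bins)$copy <- copy

  methods::new("GenomeModel", seqlengths = sl, binSize = as.integer(binSize),
               bins = bins, pericentromere = peri)
}

#' @rdname accessors
#' @export
setMethod("binSize", "GenomeModel", function(x) x@binSize)

#' @rdname accessors
#' @export
setMethod("genomeBins", "GenomeModel", function(x) x@bins)

#' @rdname accessors
#' @export
setMethod("pericentromere", "GenomeModel", function(x) x@pericentromere)

#' @rdname accessors
#' @export
setMethod("mappability", "GenomeModel",
          function(x) S4Vectors::mcols(x@bins)$mappability)

#' @importFrom GenomeInfoDb seqlengths
#' @export
setMethod("seqlengths", "GenomeModel", function(x) x@seqlengths)

setMethod("show", "GenomeModel", function(object) {
  cat("GenomeModel:", length(object@seqlengths), "chromosome(s),",
      format(sum(object@seqlengths), big.mark = ","), "bp total\n")
  cat("  bin size:", object@binSize, "bp;",
      sum(mappability(object) == 0), "of", length(object@bins),
      "bins unmappable\n")
  if (length(object@pericentromere))
    cat("  pericentromere copy multiplier:",
        unique(S4Vectors::mcols(object@pericentromere)$copyMultiplier), "\n")
})

#' Write a chromosome-sizes table
#'
#' Two-column tab-separated `chrom<TAB>length` file, the conventional
#' `chrom.sizes` format.
#'
#' @param genome A [GenomeModel].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeChromSizes <- function(genome, path) {
  sl <- seqlengths(genome)
  utils::write.table(
    data.frame(chrom = names(sl), length = format(sl, scientific = FALSE,
                                                  trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export the mappability mask as bedGraph
#'
#' @param genome A [GenomeModel].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
exportMappability <- function(genome, path) {
  gr <- genomeBins(genome)
  S4Vectors::mcols(gr) <-
    S4Vectors::DataFrame(score = mappability(genome))
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}

#' Reconstruct a genome description from chrom.sizes and mappability files
#'
#' Used by the command-line pipeline when the analysis starts from files on
#' disk rather than from a simulated [GenomeModel]. The mappability bedGraph
#' must be defined on the same bin grid as `binSize`.
#'
#' @param chromSizes Path to a `chrom.sizes` table.
#' @param mappability Optional path to a bedGraph mappability track; when
#'   omitted all bins get mappability 1.
#' @param binSize Bin width in bp.
#' @return A [GenomeModel] (with no pericentromere annotation).
#' @export
genomeFromFiles <- function(chromSizes, mappability = NULL,
                            binSize = 10000L) {
  tab <- utils::read.table(chromSizes, header = FALSE,
                           col.names = c("chrom", "length"),
                           colClasses = c("character", "numeric"))
  sl <- stats::setNames(tab$length, tab$chrom)
  bins <- .binGrid(sl, binSize)
  mapp <- rep(1, length(bins))
  if (!is.null(mappability)) {
    track <- rtracklayer::import(mappability, format = "bedGraph")
    ov <- GenomicRanges::findOverlaps(bins, track, type = "equal")
    if (length(ov) != length(bins))
      stop("mappability track does not match the ", binSize,
           " bp bin grid", call. = FALSE)
    mapp[S4Vectors::queryHits(ov)] <-
      S4Vectors::mcols(track)$score[S4Vectors::subjectHits(ov)]
  }
  S4Vectors::mcols(bins)$mappability <- mapp
  S4Vectors::mcols(bins)$copy <- rep(1, length(bins))
  peri <- GenomicRanges::GRanges()
  S4Vectors::mcols(peri)$copyMultiplier <- numeric()
  methods::new("GenomeModel", seqlengths = sl, binSize = as.integer(binSize),
               bins = bins, pericentromere = peri)
}
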