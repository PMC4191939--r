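#' Simulate aligned read positions over a toy genome
#'
#' Draws read start positions with probability proportional to the local
#' relative copy number of the genome model, emulating deduplicated
#' alignments from sorted-nuclei sequencing. A `duplicateRate` fraction of
#' the emitted reads are exact copies (same chromosome, start and strand) of
#' previously emitted reads, emulating PCR/optical duplicates.
#'
#' @param genome A [GenomeModel].
#' @param nReads Number of reads to emit (> 0).
#' @param duplicateRate Fraction of emitted reads that duplicate an earlier
#'   read, in \[0, 1).
#' @param readLength Read length in bp (intervals are clipped at chromosome
#'   ends; binning and duplicate collapse use only the leftmost coordinate).
#' @param seed Integer seed.
#' @return A [GenomicRanges::GRanges] of read placements with strand.
#' @examples
#' g <- buildToyGenome(1, 1e6, 0, 1, 0, seed = 1)
#' reads <- simulateReadPositions(g, 1000, seed = 1)
#' @export
simulateReadPositions <- function(genome, nReads, duplicateRate = 0,
                                  readLength = 100L, seed) {
  if (!methods::is(genome, "GenomeModel") || length(genomeBins(genome)) == 0)
    stop("a non-empty GenomeModel is required", call. = FALSE)
  if (nReads < 1) stop("nReads must be > 0", call. = FALSE)
  .assertScalarNumber(duplicateRate, "duplicateRate", 0, 1 - 1e-12)
  seed <- .assertSeed(seed)

  bins <- genomeBins(genome)
  w <- S4Vectors::mcols(bins)$copy * GenomicRanges::width(bins)
  nUnique <- max(1L, round((1 - duplicateRate) * nReads))

  .withSeed(seed, {
    binIdx <- sample.int(length(bins), nUnique, replace = TRUE,
                         prob = w / sum(w))
    offset <- floor(stats::runif(nUnique) *
                      GenomicRanges::width(bins)[binIdx])
    starts <- GenomicRanges::start(bins)[binIdx] + offset
    strands <- sample(c("+", "-"), nUnique, replace = TRUE)
    nDup <- nReads - nUnique
    if (nDup > 0) {
      src <- sample.int(nUnique, nDup, replace = TRUE)
      binIdx <- c(binIdx, binIdx[src])
      starts <- c(starts, starts[src])
      strands <- c(strands, strands[src])
    }
    ord <- sample.int(nReads)
    chroms <- as.character(GenomicRanges::seqnames(bins))[binIdx][ord]
    starts <- starts[ord]
    strands <- strands[ord]
    sl <- seqlengths(genome)
    gr <- GenomicRanges::GRanges(
      chroms,
      IRanges::IRanges(starts, pmin(starts + readLength - 1,
                                    sl[chroms])),
      strand = strands)
    GenomeInfoDb::seqlevels(gr) <- names(sl)
    GenomeInfoDb::seqlengths(gr) <- sl
    gr
  })
}

#' Write / read read positions as BED6
#'
#' Thin wrappers over [rtracklayer::export()]/[rtracklayer::import()] pinning
#' the BED6 convention (0-based half-open on disk, 1-based in R).
#'
#' @param positions A [GenomicRanges::GRanges] of read placements.
#' @param path File path.
#' @return `writePositionsBed` returns `path` invisibly; `readPositionsBed`
#'   returns a [GenomicRanges::GRanges].
#' @export
writePositionsBed <- function(positions, path) {
  gr <- positions
  S4Vectors::mcols(gr) <- NULL
  names(gr) <- NULL
  S4Vectors::mcols(gr)$name <- paste0("read", seq_along(gr))
  S4Vectors::mcols(gr)$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname writePositionsBed
#' @export
readPositionsBed <- function(path) {
  rtracklayer::import(path, format = "BED")
}
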