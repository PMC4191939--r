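#' Collapse duplicate read placements
#'
#' Keeps at most one read per (chromosome, start, strand) key; order of the
#' input does not affect the retained set. Idempotent.
#'
#' @param positions A [GenomicRanges::GRanges] of read placements.
#' @return The deduplicated [GenomicRanges::GRanges].
#' @export
collapseDuplicates <- function(positions) {
  if (!length(positions)) return(positions)
  chromIdx <- as.integer(GenomicRanges::seqnames(positions))
  strandIdx <- as.integer(GenomicRanges::strand(positions))
  maxLen <- max(GenomicRanges::end(positions))
  key <- .positionKey(chromIdx, GenomicRanges::start(positions), strandIdx,
                      maxLen, max(chromIdx))
  positions[!duplicated(key)]
}

#' Sum reads into genome bins
#'
#' Tiles the genome into `binSize` bins (trailing partial bins kept and
#' flagged) and assigns each read to the bin containing its leftmost aligned
#' coordinate. Reads outside the chromosome bounds are discarded with a
#' warning and recorded in the result's metadata.
#'
#' @param positions A [GenomicRanges::GRanges] of deduplicated read
#'   placements.
#' @param genome A [GenomeModel] (supplies chromosome lengths and the
#'   mappability of each bin; its bin grid must match `binSize`).
#' @param binSize Bin width in bp (default 10 kb).
#' @param sampleId Column label for this sample.
#' @return A [BinTable] with a single `counts` column.
#' @export
binCounts <- function(positions, genome, binSize = 10000L,
                      sampleId = "sample") {
  binSize <- as.integer(binSize)
  if (binSize != binSize(genome))
    stop("binSize must match the genome model's mappability grid (",
         binSize(genome), " bp)", call. = FALSE)
  sl <- seqlengths(genome)
  bins <- genomeBins(genome)
  chrom <- as.character(GenomicRanges::seqnames(positions))
  starts <- GenomicRanges::start(positions)
  known <- chrom %in% names(sl)
  inb <- known & starts >= 1 & starts <= sl[chrom]
  nOut <- sum(!inb)
  if (nOut > 0) {
    warning(nOut, " read(s) outside genome bounds discarded")
    chrom <- chrom[inb]
    starts <- starts[inb]
  }
  binsPerChrom <- ceiling(sl / binSize)
  offset <- stats::setNames(c(0, cumsum(binsPerChrom))[seq_along(sl)],
                            names(sl))
  idx <- offset[chrom] + (starts - 1) %/% binSize + 1
  counts <- tabulate(idx, nbins = length(bins))

  rowdat <- S4Vectors::DataFrame(
    mappability = S4Vectors::mcols(bins)$mappability,
    retained = rep(TRUE, length(bins)),
    partial = S4Vectors::mcols(bins)$partial)
  rr <- GenomicRanges::granges(bins)
  S4Vectors::mcols(rr) <- rowdat
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = matrix(as.numeric(counts), ncol = 1,
                                  dimnames = list(NULL, sampleId))),
    rowRanges = rr)
  out <- methods::new("BinTable", se)
  S4Vectors::metadata(out)$discarded <- nOut
  out
}

#' Combine per-sample bin tables on a common grid
#'
#' @param ... [BinTable] objects on identical bin grids.
#' @return A multi-sample [BinTable]; retained flags are combined by AND.
#' @export
combineSamples <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1]])) tabs <- tabs[[1]]
  ref <- GenomicRanges::granges(SummarizedExperiment::rowRanges(tabs[[1]]))
  for (t in tabs[-1])
    if (!identical(ref,
                   GenomicRanges::granges(SummarizedExperiment::rowRanges(t))))
      stop("bin grids differ between samples", call. = FALSE)
  counts <- do.call(cbind, lapply(tabs, function(t)
    SummarizedExperiment::assay(t, "counts")))
  retained <- Reduce(`&`, lapply(tabs, retainedBins))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowRanges = SummarizedExperiment::rowRanges(tabs[[1]]))
  out <- methods::new("BinTable", se)
  SummarizedExperiment::rowData(out)$retained <- retained
  out
}

setMethod("show", "BinTable", function(object) {
  cat("BinTable:", nrow(object), "bins x", ncol(object), "sample(s);",
      sum(retainedBins(object)), "retained\n")
  methods::callNextMethod()
})

#' @rdname accessors
#' @export
setMethod("retainedBins", "BinTable",
          function(x) SummarizedExperiment::rowData(x)$retained)

#' @rdname accessors
#' @export
setMethod("mappability", "BinTable",
          function(x) SummarizedExperiment::rowData(x)$mappability)

#' Remove unmappable and over-covered bins
#'
#' Flags as removed (i) bins with mappability 0 and (ii), per sample, bins
#' whose count exceeds `T = Q(counts, 1 - topQuantile) + median(counts)`
#' computed over the mappability-passing bins (linearly interpolated type-7
#' quantile). A bin removed for any sample is removed for all samples, so
#' ratio grids stay aligned. Thresholds are recorded in the metadata.
#'
#' @param table A [BinTable] (single- or multi-sample).
#' @param topQuantile Upper tail fraction defining the count threshold
#'   (default 0.01, i.e. the 99th percentile).
#' @return The [BinTable] with updated `retained` flags.
#' @export
filterBins <- function(table, topQuantile = 0.01) {
  counts <- SummarizedExperiment::assay(table, "counts")
  mapp <- mappability(table)
  keep <- retainedBins(table) & mapp > 0
  if (!any(keep)) stop("all bins removed by the mappability filter",
                       call. = FALSE)
  thresholds <- vapply(seq_len(ncol(counts)), function(s) {
    v <- counts[keep, s]
    stats::quantile(v, 1 - topQuantile, type = 7, names = FALSE) +
      stats::median(v)
  }, numeric(1))
  high <- rep(FALSE, nrow(counts))
  for (s in seq_len(ncol(counts)))
    high <- high | (keep & counts[, s] > thresholds[s])
  retained <- keep & !high
  if (!any(retained)) stop("all bins removed by the count filter",
                           call. = FALSE)
  SummarizedExperiment::rowData(table)$retained <- retained
  S4Vectors::metadata(table)$filter <- list(
    topQuantile = topQuantile, thresholds = thresholds,
    removedMappability = sum(mapp == 0),
    removedHighCount = sum(high))
  table
}

#' @rdname averageReplicates
#' @param sampleId Label for the averaged column.
#' @export
setMethod("averageReplicates", "BinTable", function(x, sampleId = "mean") {
  counts <- SummarizedExperiment::assay(x, "counts")
  m <- matrix(rowMeans(counts), ncol = 1, dimnames = list(NULL, sampleId))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    rowRanges = SummarizedExperiment::rowRanges(x))
  out <- methods::new("BinTable", se)
  S4Vectors::metadata(out) <- S4Vectors::metadata(x)
  out
})

#' Per-bin log2 mutant / wild-type ratio
#'
#' Over the common retained bins where both samples have a non-zero count,
#' computes `log2(mutant / wildtype)`. Zero-count bins are dropped (no
#' pseudocount) and reported via the result's `nDropped`; a warning is
#' raised when fewer than half the retained bins are usable.
#'
#' @param mutant,wildtype Single-sample [BinTable] objects (e.g. replicate
#'   averages) on identical grids with identical retained flags.
#' @return A [RatioProfile].
#' @export
log2Ratio <- function(mutant, wildtype) {
  rrM <- SummarizedExperiment::rowRanges(mutant)
  rrW <- SummarizedExperiment::rowRanges(wildtype)
  if (!identical(GenomicRanges::granges(rrM), GenomicRanges::granges(rrW)) ||
      !identical(retainedBins(mutant), retainedBins(wildtype)))
    stop("mutant and wildtype must share grid and retained set",
         call. = FALSE)
  m <- SummarizedExperiment::assay(mutant, "counts")[, 1]
  w <- SummarizedExperiment::assay(wildtype, "counts")[, 1]
  retained <- retainedBins(mutant)
  use <- retained & m > 0 & w > 0
  nDropped <- sum(retained) - sum(use)
  if (sum(use) < 0.5 * sum(retained))
    warning("fewer than 50% of retained bins have non-zero counts in both ",
            "samples")
  bins <- GenomicRanges::granges(rrM)[use]
  S4Vectors::mcols(bins)$ratio <- log2(m[use] / w[use])
  methods::new("RatioProfile", bins = bins,
               samples = c(mutant = colnames(mutant)[1],
                           wildtype = colnames(wildtype)[1]),
               nDropped = as.integer(nDropped))
}

#' @rdname accessors
#' @export
setMethod("profileBins", "RatioProfile", function(x) x@bins)

setMethod("show", "RatioProfile", function(object) {
  cat("RatioProfile:", length(object@bins), "bins (",
      object@nDropped, "dropped );",
      paste(object@samples, collapse = " / "), "\n")
})

#' Scale log2 ratios to the base replication level
#'
#' For each chromosome, slides a `windowSpan` genomic window one bin at a
#' time, finds the window of minimum mean log2 ratio (the base window,
#' representing the unreplicated copy-number level), then transforms every
#' bin to `z = (ratio - mu_b) / sigma_b` with `mu_b`/`sigma_b` the mean and
#' sample SD of the ratios inside the base window. The base window's mean
#' scaled value is 0 by construction, and any constant shift of the input
#' ratios (e.g. a library-size factor) is absorbed. Chromosomes shorter than
#' `windowSpan` use the whole chromosome as the only candidate window.
#'
#' @param profile A [RatioProfile].
#' @param windowSpan Sliding-window span in bp (default 5 Mb).
#' @param minBins Minimum retained bins a candidate window must contain;
#'   default half the window's nominal bin capacity.
#' @param sigma `"window"` (default) scales by the SD within the base
#'   window; `"chromosome"` by the chromosome-wide SD.
#' @param strict When the scaling SD falls below 1e-9, `TRUE` raises an
#'   error; `FALSE` substitutes divisor 1 with a warning.
#' @return A [ScaledProfile].
#' @export
baseWindowScale <- function(profile, windowSpan = 5e6, minBins = NULL,
                            sigma = c("window", "chromosome"),
                            strict = TRUE) {
  sigma <- match.arg(sigma)
  bins <- profileBins(profile)
  if (!length(bins)) stop("empty ratio profile", call. = FALSE)
  binWidth <- stats::median(GenomicRanges::width(bins))
  if (is.null(minBins))
    minBins <- max(2L, floor(windowSpan / (2 * binWidth)))
  sl <- GenomeInfoDb::seqlengths(bins)
  chromOf <- as.character(GenomicRanges::seqnames(bins))
  z <- rep(NA_real_, length(bins))
  bw <- list()
  for (chrom in unique(chromOf)) {
    ii <- which(chromOf == chrom)
    r <- S4Vectors::mcols(bins)$ratio[ii]
    starts <- GenomicRanges::start(bins)[ii]
    ends <- GenomicRanges::end(bins)[ii]
    chromLen <- sl[chrom]
    if (is.na(chromLen)) chromLen <- max(ends)
    cs <- cumsum(c(0, r))
    if (chromLen <= windowSpan) {
      lo <- 1L
      hi <- length(ii)
      winStart <- 1
      winEnd <- chromLen
    } else {
      anchors <- which(starts + windowSpan - 1 <= chromLen)
      if (!length(anchors))
        stop("no eligible base window on ", chrom, call. = FALSE)
      hiAll <- findInterval(starts[anchors] + windowSpan - 1, ends)
      nwin <- hiAll - anchors + 1L
      ok <- nwin >= minBins
      if (!any(ok))
        stop("no window on ", chrom, " holds >= ", minBins,
             " retained bins", call. = FALSE)
      anchors <- anchors[ok]
      hiAll <- hiAll[ok]
      nwin <- nwin[ok]
      means <- (cs[hiAll + 1L] - cs[anchors]) / nwin
      pick <- which.min(means)
      lo <- anchors[pick]
      hi <- hiAll[pick]
      winStart <- starts[lo]
      winEnd <- winStart + windowSpan - 1
    }
    rWin <- r[lo:hi]
    muB <- mean(rWin)
    sdB <- if (sigma == "window") stats::sd(rWin) else stats::sd(r)
    if (is.na(sdB) || sdB < 1e-9) {
      if (strict)
        stop("base-window SD below 1e-9 on ", chrom,
             " (constant profile?); use strict = FALSE to scale by 1",
             call. = FALSE)
      warning("base-window SD below 1e-9 on ", chrom, "; divisor set to 1")
      sdB <- 1
    }
    z[ii] <- (r - muB) / sdB
    bw[[chrom]] <- data.frame(chrom = chrom, start = winStart, end = winEnd,
                              mean = muB, sd = sdB, nBins = hi - lo + 1L)
  }
  out <- bins
  S4Vectors::mcols(out)$z <- z
  methods::new("ScaledProfile", bins = out,
               baseWindows = do.call(rbind, c(bw, make.row.names = FALSE)),
               smoothK = 0L)
}

#' @rdname accessors
#' @export
setMethod("profileBins", "ScaledProfile", function(x) x@bins)

#' @rdname accessors
#' @export
setMethod("baseWindows", "ScaledProfile", function(x) x@baseWindows)

setMethod("show", "ScaledProfile", function(object) {
  cat("ScaledProfile:", length(object@bins), "bins;",
      nrow(object@baseWindows), "base window(s)")
  if (object@smoothK > 0)
    cat("; smoothed (k =", object@smoothK, ")")
  cat("\n")
  print(object@baseWindows)
})

#' Running-mean smoothing of a scaled profile
#'
#' Centered running mean over `k` consecutive retained bins within each
#' chromosome; edge bins use the available partial window. Stored in the
#' `zSmooth` column; `k = 1` copies `z` unchanged.
#'
#' @param scaled A [ScaledProfile].
#' @param k Window width in bins (default 10).
#' @return The [ScaledProfile] with a `zSmooth` column.
#' @export
smoothProfile <- function(scaled, k = 10L) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  bins <- scaled@bins
  chromOf <- as.character(GenomicRanges::seqnames(bins))
  zs <- rep(NA_real_, length(bins))
  for (chrom in unique(chromOf)) {
    ii <- which(chromOf == chrom)
    zs[ii] <- .runningMeanPartial(S4Vectors::mcols(bins)$z[ii], k)
  }
  S4Vectors::mcols(bins)$zSmooth <- zs
  methods::initialize(scaled, bins = bins, smoothK = k)
}

#' Bins exceeding a scaled threshold, merged into regions
#'
#' @param scaled A [ScaledProfile].
#' @param threshold Scaled-value cutoff (default 1).
#' @param smoothed Use the smoothed values when available.
#' @return A reduced [GenomicRanges::GRanges] of enriched regions.
#' @export
enrichedRegions <- function(scaled, threshold = 1, smoothed = TRUE) {
  bins <- profileBins(scaled)
  v <- if (smoothed && !is.null(S4Vectors::mcols(bins)$zSmooth))
    S4Vectors::mcols(bins)$zSmooth else S4Vectors::mcols(bins)$z
  GenomicRanges::reduce(GenomicRanges::granges(bins[v > threshold]))
}

#' Jaccard overlap between two region sets
#'
#' Ratio of the total width of the intersection to that of the union.
#'
#' @param a,b [GenomicRanges::GRanges] objects.
#' @return Jaccard index in \[0, 1\].
#' @export
regionJaccard <- function(a, b) {
  a <- GenomicRanges::reduce(GenomicRanges::granges(a))
  b <- GenomicRanges::reduce(GenomicRanges::granges(b))
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  GenomeInfoDb::seqlengths(a) <- rep(NA_integer_, length(lv))
  GenomeInfoDb::seqlengths(b) <- rep(NA_integer_, length(lv))
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(a, b,
                                                ignore.strand = TRUE)))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(a, b,
                                                ignore.strand = TRUE)))
  if (uni == 0) return(0)
  inter / uni
}

#' Export a scaled profile as bedGraph
#'
#' One record per bin, 0-based half-open on disk; the value is the smoothed
#' scaled value when present (and `smoothed = TRUE`), else the raw scaled
#' value. Round-trips through [readBedGraphProfile()] to 1e-6.
#'
#' @param scaled A [ScaledProfile].
#' @param path Output path.
#' @param smoothed Write `zSmooth` when available.
#' @return Invisibly, `path`.
#' @export
exportProfile <- function(scaled, path, smoothed = TRUE) {
  bins <- profileBins(scaled)
  v <- if (smoothed && !is.null(S4Vectors::mcols(bins)$zSmooth))
    S4Vectors::mcols(bins)$zSmooth else S4Vectors::mcols(bins)$z
  gr <- GenomicRanges::granges(bins)
  S4Vectors::mcols(gr)$score <- round(v, 6)
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}

#' @rdname exportProfile
#' @return `readBedGraphProfile` returns a [GenomicRanges::GRanges] with a
#'   `score` column.
#' @export
readBedGraphProfile <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}
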