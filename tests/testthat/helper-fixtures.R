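# shared fixtures and independent (naive) reference implementations used as
# oracles against the vectorized pipeline

ADAPTOR <- telorepAdaptor()
PERMS <- telomericPermutations()

tinyGenome <- function(seed = 1, nChrom = 1, len = 1e6, periFrac = 0,
                       mult = 1, unmap = 0) {
  buildToyGenome(nChrom, len, periFrac, mult, unmap, seed = seed)
}

# positions GRanges from bare vectors, for hand-built cases
grPositions <- function(chrom, start, strand = "+", len = 1e6,
                        chroms = unique(chrom), width = 1L) {
  gr <- GenomicRanges::GRanges(
    factor(chrom, levels = chroms),
    IRanges::IRanges(start, start + width - 1L), strand = strand)
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(rep(len, length(chroms)),
                                                  chroms)
  gr
}

# ---- naive reference implementations (loops, no shared code paths) --------

naiveDedup <- function(chrom, start, strand) {
  !duplicated(paste(chrom, start, strand, sep = "|"))
}

naiveBinCounts <- function(start, len, binSize) {
  nBins <- ceiling(len / binSize)
  counts <- integer(nBins)
  for (s in start) {
    b <- (s - 1) %/% binSize + 1
    counts[b] <- counts[b] + 1L
  }
  counts
}

# type-7 quantile written out from its definition
naiveQuantile7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

naiveMedian <- function(x) naiveQuantile7(x, 0.5)

naiveFilter <- function(counts, mapp, topQuantile = 0.01) {
  keep <- mapp > 0
  thr <- naiveQuantile7(counts[keep], 1 - topQuantile) +
    naiveMedian(counts[keep])
  keep & counts <= thr
}

# base-window scaling on one chromosome by exhaustive window search
naiveBaseWindowScale <- function(starts, ends, ratio, chromLen, span,
                                 minBins) {
  n <- length(ratio)
  if (chromLen <= span) {
    win <- seq_len(n)
  } else {
    bestMean <- Inf
    win <- NULL
    for (i in seq_len(n)) {
      if (starts[i] + span - 1 > chromLen) next
      members <- which(starts >= starts[i] & ends <= starts[i] + span - 1)
      if (length(members) < minBins) next
      m <- mean(ratio[members])
      if (m < bestMean - 1e-15) {
        bestMean <- m
        win <- members
      }
    }
  }
  mu <- mean(ratio[win])
  sd <- stats::sd(ratio[win])
  list(z = (ratio - mu) / sd, window = win, mu = mu, sd = sd)
}

naiveRunningMean <- function(x, k) {
  n <- length(x)
  lo <- floor((k - 1) / 2)
  hi <- k - 1 - lo
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- max(1, i - lo):min(n, i + hi)
    out[i] <- mean(x[w])
  }
  out
}

# build a PermutationProfile directly from counts (for statistics tests that
# do not need the read-level pipeline)
profileFromCounts <- function(counts, sampleId = "synthetic") {
  methods::new("PermutationProfile", sampleId = sampleId,
               counts = stats::setNames(as.integer(counts), PERMS),
               nUnclassified = 0L)
}

# mode channel of a single-peak cytogram
modeChannel <- function(cg) channels(cg)[which.max(channelCounts(cg))]
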