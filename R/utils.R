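# internal helpers shared across modules

.assertScalarNumber <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lo, hi),
         call. = FALSE)
  invisible(x)
}

.assertSeed <- function(seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("an explicit integer 'seed' is required", call. = FALSE)
  invisible(as.integer(seed))
}

# run an expression under a local RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  seed <- .assertSeed(seed)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# non-overlapping bin grid over named chromosome lengths; the trailing
# partial bin of each chromosome is kept and flagged
.binGrid <- function(seqlengths, binSize) {
  binSize <- as.integer(binSize)
  if (binSize < 1L) stop("binSize must be >= 1", call. = FALSE)
  startsByChrom <- lapply(seqlengths, function(len) seq(1, len, by = binSize))
  chroms <- rep(names(seqlengths), lengths(startsByChrom))
  starts <- unlist(startsByChrom, use.names = FALSE)
  ends <- pmin(starts + binSize - 1, seqlengths[chroms])
  gr <- GenomicRanges::GRanges(factor(chroms, levels = names(seqlengths)),
                               IRanges::IRanges(starts, ends))
  GenomeInfoDb::seqlengths(gr) <- seqlengths[GenomeInfoDb::seqlevels(gr)]
  S4Vectors::mcols(gr)$partial <- GenomicRanges::width(gr) < binSize
  gr
}

# centered running mean with partial windows at the edges; for even k the
# window extends one element further to the right
.runningMeanPartial <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n == 0L) return(x)
  lo <- floor((k - 1) / 2)
  hi <- k - 1L - lo
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  a <- pmax(i - lo, 1L)
  b <- pmin(i + hi, n)
  (cs[b + 1L] - cs[a]) / (b - a + 1L)
}

# encode (chrom index, start, strand index) into one numeric key; exact while
# the product stays below 2^53, otherwise fall back to string keys
.positionKey <- function(chromIdx, start, strandIdx, maxLen, nChrom) {
  span <- (maxLen + 1) * nChrom * 4
  if (span < 2^52) {
    ((chromIdx - 1) * (maxLen + 1) + start) * 4 + strandIdx
  } else {
    paste(chromIdx, start, strandIdx, sep = ":")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
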