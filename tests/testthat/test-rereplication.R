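test_that("duplicate collapse keys on (chrom, start, strand)", {
  gr <- grPositions(rep("chr1", 3), rep(100, 3), rep("+", 3))
  expect_length(collapseDuplicates(gr), 1)
  # same start, opposite strands: both kept
  gr2 <- grPositions(c("chr1", "chr1"), c(100, 100), c("+", "-"))
  expect_length(collapseDuplicates(gr2), 2)
  # idempotence and order independence
  gr3 <- grPositions(rep("chr1", 6), c(5, 1, 5, 2, 1, 5),
                     c("+", "+", "+", "-", "+", "+"))
  once <- collapseDuplicates(gr3)
  expect_identical(collapseDuplicates(once), once)
  perm <- collapseDuplicates(gr3[sample(length(gr3))])
  expect_identical(sort(perm), sort(once))
  # against the naive oracle on random data
  set.seed(7)
  chrom <- sample(c("chr1", "chr2"), 5000, TRUE)
  start <- sample(1000L, 5000, TRUE)
  strand <- sample(c("+", "-"), 5000, TRUE)
  gr4 <- grPositions(chrom, start, strand, chroms = c("chr1", "chr2"))
  expect_length(collapseDuplicates(gr4),
                sum(naiveDedup(chrom, start, strand)))
})

test_that("bin counting respects half-open bin boundaries and conserves reads", {
  g <- tinyGenome(seed = 1, len = 1e6)
  gr <- grPositions("chr1", c(1, 10000, 10001), len = 1e6)
  bt <- binCounts(gr, g)
  counts <- SummarizedExperiment::assay(bt, "counts")[, 1]
  expect_equal(counts[1], 2)  # bp 1..10000
  expect_equal(counts[2], 1)  # bp 10001..20000
  expect_equal(sum(counts), 3)

  gBig <- tinyGenome(seed = 1, len = 1e7)  # 1000 bins
  reads <- simulateReadPositions(gBig, 1e5, seed = 2)
  bt2 <- binCounts(reads, gBig)
  expect_equal(sum(SummarizedExperiment::assay(bt2, "counts")), 1e5)
  expect_identical(
    as.integer(SummarizedExperiment::assay(bt2, "counts")[, 1]),
    naiveBinCounts(GenomicRanges::start(reads), 1e7, 1e4))
  # uniform multinomial across many bins is Poisson-like
  v <- SummarizedExperiment::assay(bt2, "counts")[, 1]
  expect_lt(abs(var(v) / mean(v) - 1), 0.15)

  # out-of-bounds reads: warned, discarded, recorded
  oob <- grPositions("chr1", c(50, 2e6), len = 3e6)
  GenomeInfoDb::seqlengths(oob) <- c(chr1 = 3e6)
  expect_warning(bt3 <- binCounts(oob, g), "outside")
  expect_equal(S4Vectors::metadata(bt3)$discarded, 1)
  expect_equal(sum(SummarizedExperiment::assay(bt3, "counts")), 1)
})

test_that("bin filter removes unmappable bins then count outliers", {
  g <- tinyGenome(seed = 3, len = 1e7)  # 1000 bins
  mapp <- mappability(g)
  # force a known set of unmappable bins
  kZero <- c(5L, 17L, 400L)
  mapp[] <- 1
  mapp[kZero] <- 0
  # hand-built counts: 10 everywhere, one spike
  counts <- rep(10, 1000)
  counts[300] <- 10000
  rr <- genomeBins(g)
  S4Vectors::mcols(rr) <- S4Vectors::DataFrame(
    mappability = mapp, retained = TRUE,
    partial = S4Vectors::mcols(genomeBins(g))$partial)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = matrix(counts, ncol = 1,
                                  dimnames = list(NULL, "s"))),
    rowRanges = rr)
  bt <- methods::new("BinTable", se)
  filtered <- filterBins(bt)
  ret <- retainedBins(filtered)
  # threshold = q99(counts) + median(counts) = 10 + 10 = 20 over mappable bins
  expect_false(any(ret[kZero]))
  expect_false(ret[300])
  expect_equal(sum(!ret), 4)
  expect_equal(S4Vectors::metadata(filtered)$filter$thresholds, 20,
               ignore_attr = TRUE)
  # monotonicity: retained set is a subset of the input's retained set
  expect_true(all(which(ret) %in% which(retainedBins(bt))))
  # idempotence on already-filtered data (spike now gone)
  expect_identical(retainedBins(filterBins(filtered)), ret)
  # agreement with the naive implementation
  expect_identical(ret, naiveFilter(counts, mapp))
})

test_that("a bin removed for any sample is removed for all (consensus)", {
  g <- tinyGenome(seed = 4, len = 1e6)
  mk <- function(counts, id) {
    rr <- genomeBins(g)
    S4Vectors::mcols(rr) <- S4Vectors::DataFrame(
      mappability = rep(1, 100), retained = TRUE,
      partial = rep(FALSE, 100))
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = matrix(counts, ncol = 1,
                                    dimnames = list(NULL, id))),
      rowRanges = rr)
    methods::new("BinTable", se)
  }
  a <- rep(10, 100); a[7] <- 1000
  b <- rep(10, 100); b[93] <- 1000
  combined <- filterBins(combineSamples(mk(a, "a"), mk(b, "b")))
  ret <- retainedBins(combined)
  expect_false(ret[7])
  expect_false(ret[93])
  expect_equal(sum(!ret), 2)
})

test_that("replicate averaging is a per-bin arithmetic mean", {
  g <- tinyGenome(seed = 5, len = 1e6)
  r1 <- binCounts(simulateReadPositions(g, 1000, seed = 1), g,
                  sampleId = "r1")
  r2 <- binCounts(simulateReadPositions(g, 1000, seed = 2), g,
                  sampleId = "r2")
  avg12 <- averageReplicates(combineSamples(r1, r2))
  avg21 <- averageReplicates(combineSamples(r2, r1))
  c1 <- SummarizedExperiment::assay(r1, "counts")[, 1]
  c2 <- SummarizedExperiment::assay(r2, "counts")[, 1]
  expect_equal(SummarizedExperiment::assay(avg12, "counts")[, 1],
               (c1 + c2) / 2, ignore_attr = TRUE)
  # commutative; single table is identity
  expect_equal(SummarizedExperiment::assay(avg21, "counts"),
               SummarizedExperiment::assay(avg12, "counts"),
               ignore_attr = TRUE)
  expect_equal(SummarizedExperiment::assay(averageReplicates(r1), "counts")[, 1],
               c1, ignore_attr = TRUE)
  # mismatched grids rejected
  g2 <- tinyGenome(seed = 5, len = 2e6)
  r3 <- binCounts(simulateReadPositions(g2, 100, seed = 3), g2)
  expect_error(combineSamples(r1, r3), "grids differ")
})

test_that("log2 ratios drop zero-count bins and obey the log identity", {
  g <- tinyGenome(seed = 6, len = 1e6)
  mk <- function(counts, id) {
    rr <- genomeBins(g)
    S4Vectors::mcols(rr) <- S4Vectors::DataFrame(
      mappability = rep(1, 100), retained = TRUE, partial = rep(FALSE, 100))
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = matrix(counts, ncol = 1,
                                    dimnames = list(NULL, id))),
      rowRanges = rr)
    methods::new("BinTable", se)
  }
  mut <- mk(c(40, 10, 0, rep(10, 97)), "mut")
  wt <- mk(c(10, 10, 5, rep(10, 97)), "wt")
  rp <- log2Ratio(mut, wt)
  r <- S4Vectors::mcols(profileBins(rp))$ratio
  expect_equal(r[1], 2)
  expect_equal(r[2], 0)
  expect_equal(length(r), 99)  # one zero-count bin dropped
  expect_equal(rp@nDropped, 1L)
  # scaling mutant counts by c shifts all ratios by log2(c)
  mutC <- mk(8 * c(40, 10, 0, rep(10, 97)), "mut")
  rC <- S4Vectors::mcols(profileBins(log2Ratio(mutC, wt)))$ratio
  expect_equal(rC, r + 3)
})

test_that("base-window scaling centers the minimum-mean window at zero", {
  g <- tinyGenome(seed = 8, len = 1e6)
  reads <- function(s) simulateReadPositions(g, 3e4, seed = s)
  bt <- filterBins(combineSamples(
    binCounts(reads(1), g, sampleId = "m"),
    binCounts(reads(2), g, sampleId = "w")))
  rp <- log2Ratio(averageReplicates(bt[, 1, drop = FALSE], "m"),
                  averageReplicates(bt[, 2, drop = FALSE], "w"))
  sp <- baseWindowScale(rp, windowSpan = 3e5, minBins = 10)
  bw <- baseWindows(sp)
  bins <- profileBins(sp)
  sel <- GenomicRanges::start(bins) >= bw$start[1] &
    GenomicRanges::end(bins) <= bw$end[1]
  expect_lt(abs(mean(S4Vectors::mcols(bins)$z[sel])), 1e-9)
  expect_gt(bw$sd[1], 0)

  # shift invariance: adding a constant to all ratios changes nothing
  rpShift <- rp
  S4Vectors::mcols(rpShift@bins)$ratio <-
    S4Vectors::mcols(rp@bins)$ratio + 3.7
  spShift <- baseWindowScale(rpShift, windowSpan = 3e5, minBins = 10)
  expect_equal(S4Vectors::mcols(profileBins(spShift))$z,
               S4Vectors::mcols(bins)$z, tolerance = 1e-9)

  # constant profile: strict mode errors, permissive mode returns all zeros
  rpConst <- rp
  S4Vectors::mcols(rpConst@bins)$ratio <-
    rep(0.5, length(profileBins(rp)))
  expect_error(baseWindowScale(rpConst, windowSpan = 3e5, minBins = 10),
               "SD below")
  expect_warning(
    spConst <- baseWindowScale(rpConst, windowSpan = 3e5, minBins = 10,
                               strict = FALSE), "divisor")
  expect_true(all(S4Vectors::mcols(profileBins(spConst))$z == 0))
})

test_that("full chain matches the naive oracle on a 100-bin chromosome", {
  g <- tinyGenome(seed = 9, len = 1e6, periFrac = 0.2, mult = 1.8,
                  unmap = 0.03)
  gw <- tinyGenome(seed = 9, len = 1e6, periFrac = 0.2, mult = 1.0,
                   unmap = 0.03)
  rawM <- simulateReadPositions(g, 4e4, duplicateRate = 0.2, seed = 10)
  rawW <- simulateReadPositions(gw, 4e4, duplicateRate = 0.2, seed = 11)

  ## pipeline
  bt <- filterBins(combineSamples(
    binCounts(collapseDuplicates(rawM), g, sampleId = "m"),
    binCounts(collapseDuplicates(rawW), gw, sampleId = "w")))
  rp <- log2Ratio(averageReplicates(bt[, 1, drop = FALSE], "m"),
                  averageReplicates(bt[, 2, drop = FALSE], "w"))
  sp <- smoothProfile(baseWindowScale(rp, windowSpan = 3e5, minBins = 10),
                      k = 10)

  ## naive reference, plain loops throughout
  dedupCounts <- function(raw) {
    keep <- naiveDedup(as.character(GenomicRanges::seqnames(raw)),
                       GenomicRanges::start(raw),
                       as.character(GenomicRanges::strand(raw)))
    naiveBinCounts(GenomicRanges::start(raw)[keep], 1e6, 1e4)
  }
  cm <- dedupCounts(rawM)
  cw <- dedupCounts(rawW)
  mapp <- mappability(g)
  keep <- naiveFilter(cm, mapp) & naiveFilter(cw, mapp)
  use <- keep & cm > 0 & cw > 0
  ratio <- log2(cm[use] / cw[use])
  starts <- GenomicRanges::start(genomeBins(g))[use]
  ends <- GenomicRanges::end(genomeBins(g))[use]
  ref <- naiveBaseWindowScale(starts, ends, ratio, 1e6, 3e5, 10)
  refSmooth <- naiveRunningMean(ref$z, 10)

  bins <- profileBins(sp)
  expect_equal(GenomicRanges::start(bins), starts)
  expect_equal(S4Vectors::mcols(bins)$ratio, ratio, tolerance = 1e-12)
  expect_equal(S4Vectors::mcols(bins)$z, ref$z, tolerance = 1e-12)
  expect_equal(S4Vectors::mcols(bins)$zSmooth, refSmooth,
               tolerance = 1e-12)
  expect_equal(baseWindows(sp)$mean, ref$mu, tolerance = 1e-12)
  expect_equal(baseWindows(sp)$sd, ref$sd, tolerance = 1e-12)
})

test_that("scaled profiles are invariant to library size", {
  g <- tinyGenome(seed = 12, len = 1e6)
  btM <- binCounts(simulateReadPositions(g, 2e4, seed = 13), g,
                   sampleId = "m")
  btW <- binCounts(simulateReadPositions(g, 2e4, seed = 14), g,
                   sampleId = "w")
  chain <- function(m, w) {
    bt <- filterBins(combineSamples(m, w))
    rp <- log2Ratio(averageReplicates(bt[, 1, drop = FALSE], "m"),
                    averageReplicates(bt[, 2, drop = FALSE], "w"))
    baseWindowScale(rp, windowSpan = 3e5, minBins = 10)
  }
  base <- chain(btM, btW)
  scaledUp <- btM
  SummarizedExperiment::assay(scaledUp, "counts") <-
    SummarizedExperiment::assay(btM, "counts") * 7.3
  up <- chain(scaledUp, btW)
  expect_equal(S4Vectors::mcols(profileBins(up))$z,
               S4Vectors::mcols(profileBins(base))$z, tolerance = 1e-9)
  expect_identical(GenomicRanges::start(profileBins(up)),
                   GenomicRanges::start(profileBins(base)))
})

test_that("running-mean smoothing has the expected edge and variance behavior", {
  x <- rnorm(500)
  gr <- grPositions("chr1", seq(1, by = 1e4, length.out = 500), len = 5e6)
  S4Vectors::mcols(gr)$ratio <- x
  S4Vectors::mcols(gr)$z <- x
  sp <- methods::new("ScaledProfile", bins = gr,
                     baseWindows = data.frame(), smoothK = 0L)
  # k = 1 is the identity
  expect_equal(S4Vectors::mcols(profileBins(smoothProfile(sp, 1)))$zSmooth, x)
  # constant profile unchanged
  spc <- sp
  S4Vectors::mcols(spc@bins)$z <- rep(2, 500)
  expect_equal(
    S4Vectors::mcols(profileBins(smoothProfile(spc, 10)))$zSmooth,
    rep(2, 500))
  # white noise of SD s smooths to ~ s / sqrt(10) away from the edges
  set.seed(1)
  big <- rnorm(5000, sd = 2)
  smoothed <- telorep:::.runningMeanPartial(big, 10)
  inner <- smoothed[100:4900]
  expect_lt(abs(sd(inner) / (2 / sqrt(10)) - 1), 0.15)
})

test_that("bedGraph export round-trips and omits removed bins", {
  g <- tinyGenome(seed = 15, len = 1e6)
  bt <- filterBins(combineSamples(
    binCounts(simulateReadPositions(g, 2e4, seed = 16), g, sampleId = "m"),
    binCounts(simulateReadPositions(g, 2e4, seed = 17), g, sampleId = "w")))
  rp <- log2Ratio(averageReplicates(bt[, 1, drop = FALSE], "m"),
                  averageReplicates(bt[, 2, drop = FALSE], "w"))
  sp <- smoothProfile(baseWindowScale(rp, windowSpan = 3e5, minBins = 10),
                      10)
  path <- tempfile(fileext = ".bedGraph")
  exportProfile(sp, path)
  back <- readBedGraphProfile(path)
  bins <- profileBins(sp)
  expect_length(back, length(bins))
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(bins))
  expect_equal(S4Vectors::mcols(back)$score,
               S4Vectors::mcols(bins)$zSmooth, tolerance = 1e-6)
  # 0-based half-open on disk
  raw <- read.table(path)
  expect_equal(raw$V2[1], GenomicRanges::start(bins)[1] - 1)
})
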