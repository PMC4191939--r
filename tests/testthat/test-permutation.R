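test_that("demultiplexing assigns by unique <=1-mismatch barcode prefix", {
  barcodes <- c(s1 = "ACGTCA", s2 = "TGCAGT", s3 = "CATGAC")
  body <- paste0(strrep("TTTAGGG", 3), ADAPTOR)
  reads <- c(
    paste0("ACGTCA", body),  # exact s1
    paste0("ACGTCC", body),  # 1 mismatch from s1, >=2 from others
    paste0("GGGGGG", body))  # matches nothing
  dm <- demultiplexReads(reads, barcodes)
  expect_length(dm$s1, 2)
  expect_length(dm$s2, 0)
  expect_length(dm$undetermined, 1)
  # barcode stripped: junction sits at 21 in assigned reads
  expect_true(all(as.character(dm$s1) == body))
  # partition is exhaustive and disjoint
  expect_equal(sum(lengths(dm)), length(reads))

  # ambiguous prefix (1 mismatch from two barcodes) goes to undetermined
  amb <- c(a = "AAAAAA", b = "AAAATT")
  r <- paste0("AAAAAT", body)  # 1 from a, 1 from b
  dma <- demultiplexReads(r, amb)
  expect_length(dma$undetermined, 1)

  expect_error(demultiplexReads(reads, c(x = "AAAAAA", y = "AAAAAA")),
               "duplicate")
  expect_error(demultiplexReads(reads, c(x = "AAAAAA", y = "AAAAAT")),
               "2 mismatches")
  expect_error(demultiplexReads(reads, c(x = "AAAA", y = "AAAAGG")),
               "equal length")
})

test_that("junction location finds the smallest tolerant adaptor match", {
  read <- paste0(strrep("TTTAGGG", 3), ADAPTOR)
  expect_equal(locateJunction(read, ADAPTOR, 0)$offset, 21)

  mutated <- read
  substr(mutated, 25, 25) <- "A"  # substitution inside the adaptor prefix
  expect_null(locateJunction(mutated, ADAPTOR, 0))
  expect_equal(locateJunction(mutated, ADAPTOR, 1)$offset, 21)

  # reverse-complement input is located in G-strand coordinates
  rcRead <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(read)))
  loc <- locateJunction(rcRead, ADAPTOR, 1)
  expect_equal(loc$offset, 21)
  expect_equal(loc$orientation, "reverse")
})

test_that("random sequence almost never yields a junction", {
  set.seed(42)
  n <- 1e4
  rand <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
          collapse = ""), "")
  cls <- classifyReads(rand, ADAPTOR, maxMismatch = 1)
  # chance of a <=1-mismatch 10-mer match is ~1e-3 per read
  expect_lt(mean(!is.na(cls$junction)), 0.01)
  expect_true(all(cls$permutation == "UNCLASSIFIED"))
})

test_that("terminus classification is exact at the 7-mer and needs context", {
  expect_equal(classifyTerminus(paste0(strrep("TTTAGGG", 2), ADAPTOR), 14),
               "TTTAGGG")
  # terminal 7-mer GTTTAGG, phase-consistent upstream context
  readG <- paste0("TAGGGTTTAGGGTTTAGG", ADAPTOR)
  expect_equal(classifyTerminus(readG, 18), "GTTTAGG")
  # non-telomeric upstream: unclassified despite a perfect terminal 7-mer
  readBad <- paste0("AAAAAAATTTAGGG", ADAPTOR)
  expect_equal(classifyTerminus(readBad, 14), "UNCLASSIFIED")
  # junction too close to the read start for the required context
  expect_equal(classifyTerminus(paste0("TTTAGGG", ADAPTOR), 7),
               "UNCLASSIFIED")
  # a single substitution in the terminal 7-mer voids classification
  readMut <- paste0(strrep("TTTAGGG", 3), ADAPTOR)
  substr(readMut, 21, 21) <- "C"
  expect_equal(classifyTerminus(readMut, 21), "UNCLASSIFIED")
  # ...but one mismatch in the upstream (non-terminal) repeat is tolerated
  readUp <- paste0(strrep("TTTAGGG", 3), ADAPTOR)
  substr(readUp, 10, 10) <- "C"
  expect_equal(classifyTerminus(readUp, 21), "TTTAGGG")
})

test_that("error-free profiles equal the embedded true-label counts", {
  reads <- simulateAmpliconReads("stn1", 20000, errorRate = 0, seed = 21)
  prof <- profileSample(reads, sampleId = "stn1")
  oracle <- table(factor(trueLabels(reads), levels = PERMS))
  expect_identical(unname(permCounts(prof)), as.integer(oracle))
  expect_identical(nUnclassified(prof), 0L)
  expect_equal(sum(frequencies(prof)), 1, tolerance = 1e-12)

  # read-for-read agreement of the assigned labels
  cls <- classifyReads(reads)
  expect_identical(as.character(cls$permutation), unname(trueLabels(reads)))
})

test_that("classification is invariant to reverse complement and order", {
  reads <- simulateAmpliconReads("c24", 3000, errorRate = 0.01, seed = 22)
  prof <- profileSample(reads)
  rc <- Biostrings::reverseComplement(reads)
  expect_identical(permCounts(profileSample(rc)), permCounts(prof))
  shuffled <- reads[sample(length(reads))]
  expect_identical(permCounts(profileSample(shuffled)), permCounts(prof))
})

test_that("substitution errors only unclassify or untouch, never relabel", {
  reads <- simulateAmpliconReads("colzero", 30000, errorRate = 0.01,
                                 seed = 23)
  cls <- classifyReads(reads)
  truth <- trueLabels(reads)
  assigned <- as.character(cls$permutation)
  classified <- assigned != "UNCLASSIFIED"
  # rotations are >= 3 substitutions apart, so single errors cannot relabel
  expect_gt(mean(assigned[classified] == truth[classified]), 0.9995)
  # junction still locatable in >= 95% of reads at 1% error
  expect_gte(mean(!is.na(cls$junction)), 0.95)
})

test_that("all-adaptorless input yields an invalid empty profile", {
  reads <- Biostrings::DNAStringSet(rep(strrep("TTTAGGG", 7), 5))
  expect_warning(prof <- profileSample(reads), "no classifiable")
  expect_false(profileValid(prof))
  expect_true(all(is.na(frequencies(prof))))
  expect_error(profileSample(Biostrings::DNAStringSet()), "empty")
})

test_that("replicate aggregation gives unweighted means and sample SDs", {
  p1 <- profileFromCounts(c(40, 10, 10, 10, 10, 10, 10) * 10)
  p2 <- profileFromCounts(c(60, 10, 10, 10, 10, 0, 0) * 10)
  agg <- aggregateReplicates(list(p1, p2))
  expect_equal(agg$mean[1], 0.5)
  expect_equal(agg$sd[1], sd(c(0.4, 0.6)))  # ~0.1414
  expect_equal(sum(agg$mean), 1)

  aggSame <- aggregateReplicates(list(p1, p1, p1))
  expect_true(all(aggSame$sd == 0))
  expect_warning(one <- aggregateReplicates(list(p1)), "single replicate")
  expect_true(all(is.na(one$sd)))
})

test_that("profile contrasts report percentage-point deltas and t-tests", {
  pa <- lapply(c(400, 410, 395), function(k)
    profileFromCounts(c(k, rep(100, 6))))
  contrastNull <- compareProfiles(pa, pa)
  expect_true(all(contrastNull$delta == 0))

  pb <- lapply(c(250, 260, 255), function(k)
    profileFromCounts(c(k, rep(100, 6))))
  ct <- compareProfiles(pa, pb)
  expect_gt(ct$delta[ct$permutation == "TTTAGGG"], 0)
  expect_lt(ct$p[ct$permutation == "TTTAGGG"], 0.01)
  # degenerate zero-variance pair: delta reported, test undefined
  pz <- list(profileFromCounts(rep(100, 7)), profileFromCounts(rep(100, 7)))
  cz <- compareProfiles(pz, pz)
  expect_true(all(is.na(cz$p)))
  expect_true(all(cz$delta == 0))
  expect_error(compareProfiles(pa, pb[1]), "2 replicates")
})

test_that("contrast t-test holds its nominal type-I error under the null", {
  set.seed(99)
  preset <- permutationPresets()$c24
  nTrials <- 200
  rejections <- vapply(seq_len(nTrials), function(i) {
    mk <- function() lapply(seq_len(3), function(j)
      profileFromCounts(stats::rmultinom(1, 20000, preset)))
    ct <- compareProfiles(mk(), mk())
    ct$p[ct$permutation == "TTTAGGG"] < 0.05
  }, logical(1))
  # binomial(200, 0.05): mean 10, sd ~3.1; allow a generous 4-sigma band
  expect_gte(sum(rejections), 1)
  expect_lte(sum(rejections), 23)
})

test_that("profiles serialize to the documented CSV layout", {
  prof <- profileSample(simulateAmpliconReads("c24", 500, seed = 31))
  path <- tempfile(fileext = ".csv")
  writeProfile(prof, path)
  tab <- read.csv(path)
  expect_identical(names(tab), c("permutation", "count", "frequency"))
  expect_identical(tab$permutation, PERMS)
  expect_equal(sum(tab$count), nClassified(prof))
})
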