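#' Demultiplex barcoded amplicon reads
#'
#' Assigns each read to the unique barcode matching its prefix with at most
#' one mismatch. Reads matching no barcode, or more than one, go to the
#' `undetermined` bucket; the partition is exhaustive and disjoint. Assigned
#' reads are returned with the barcode prefix removed.
#'
#' @param reads A [Biostrings::DNAStringSet] (or character vector).
#' @param barcodes Named character vector (names = sample labels) of
#'   equal-length barcode sequences, mutually >= 2 mismatches apart.
#' @return List with one [Biostrings::DNAStringSet] per sample plus
#'   `undetermined`.
#' @export
demultiplexReads <- function(reads, barcodes) {
  if (is.null(names(barcodes)) || anyDuplicated(names(barcodes)))
    stop("barcodes must be uniquely named by sample", call. = FALSE)
  if (anyDuplicated(barcodes))
    stop("duplicate barcode sequences", call. = FALSE)
  bl <- unique(nchar(barcodes))
  if (length(bl) != 1L)
    stop("barcodes must have equal length", call. = FALSE)
  bmat <- vapply(strsplit(barcodes, ""), identity,
                 character(bl))  # bl x nBarcodes
  pair <- utils::combn(length(barcodes), 2)
  dists <- apply(pair, 2, function(ij) sum(bmat[, ij[1]] != bmat[, ij[2]]))
  if (any(dists < 2))
    stop("barcodes must be mutually >= 2 mismatches apart", call. = FALSE)

  seqs <- if (is.character(reads)) reads else as.character(reads)
  nm <- names(reads) %||% sprintf("read%07d", seq_along(seqs))
  prefix <- substr(seqs, 1, bl)
  mism <- matrix(0L, length(seqs), length(barcodes))
  for (j in seq_len(bl)) {
    pj <- substr(prefix, j, j)
    mism <- mism + outer(pj, bmat[j, ], "!=")
  }
  hits <- mism <= 1L
  nHits <- rowSums(hits)
  assign <- ifelse(nHits == 1L, max.col(hits, ties.method = "first"),
                   NA_integer_)
  out <- lapply(seq_along(barcodes), function(b) {
    sel <- which(!is.na(assign) & assign == b)
    x <- Biostrings::DNAStringSet(substr(seqs[sel], bl + 1, nchar(seqs[sel])))
    names(x) <- nm[sel]
    x
  })
  names(out) <- names(barcodes)
  und <- which(is.na(assign))
  u <- Biostrings::DNAStringSet(seqs[und])
  names(u) <- nm[und]
  out$undetermined <- u
  out
}

#' Read a barcode map from a two-column CSV
#'
#' @param path CSV with columns `sample` and `barcode`.
#' @return Named character vector suitable for [demultiplexReads()].
#' @export
readBarcodes <- function(path) {
  tab <- utils::read.csv(path, colClasses = "character")
  if (!all(c("sample", "barcode") %in% names(tab)))
    stop("barcode CSV must have columns 'sample' and 'barcode'",
         call. = FALSE)
  stats::setNames(toupper(tab$barcode), tab$sample)
}

# ---- junction location ----------------------------------------------------

# vectorized scan: smallest 1-based adaptor start with <= maxMismatch
# substitutions against the first 10 nt of the adaptor; NA when absent
.scanAdaptor <- function(seqs, adaptor, maxMismatch, chunk = 250000L) {
  k <- min(10L, nchar(adaptor))
  pat <- utf8ToInt(substr(adaptor, 1, k))
  n <- length(seqs)
  widths <- nchar(seqs)
  W <- if (n) max(widths) else 0L
  best <- rep(NA_integer_, n)
  if (W < k) return(best)
  for (cs in seq(1, n, by = chunk)) {
    ce <- min(cs + chunk - 1L, n)
    idx <- cs:ce
    x <- seqs[idx]
    wpad <- W - nchar(x)
    if (any(wpad > 0)) x <- paste0(x, strrep(" ", wpad))
    M <- matrix(utf8ToInt(paste(x, collapse = "")), nrow = W)
    b <- rep(NA_integer_, length(idx))
    wI <- widths[idx]
    for (o in seq_len(W - k + 1L)) {
      mism <- colSums(M[o:(o + k - 1L), , drop = FALSE] != pat)
      hit <- is.na(b) & mism <= maxMismatch & (o + k - 1L) <= wI
      b[hit] <- o
      if (!anyNA(b)) break
    }
    best[idx] <- b
  }
  best
}

# mismatches of the terminal (7 * minRepeats)-mer against the periodic
# consensus of each read's terminal rotation; returns list(perm, ctxMism,
# nRepeats) with NA perm where unclassifiable
.classifyAt <- function(seqs, prefixLen, minRepeats) {
  n <- length(seqs)
  perms <- telomericPermutations()
  span <- 7L * minRepeats
  allow <- floor(0.1 * span)
  perm <- rep(NA_integer_, n)
  nrep <- rep(NA_integer_, n)
  ok <- !is.na(prefixLen) & prefixLen >= span
  term <- rep(NA_character_, n)
  term[ok] <- substr(seqs[ok], prefixLen[ok] - 6L, prefixLen[ok])
  cand <- match(term, perms)
  for (p in seq_len(7L)) {
    ii <- which(ok & !is.na(cand) & cand == p)
    if (!length(ii)) next
    cons <- strrep(perms[p], minRepeats)
    ctx <- substr(seqs[ii], prefixLen[ii] - span + 1L, prefixLen[ii])
    mism <- integer(length(ii))
    for (j in seq_len(span))
      mism <- mism + (substr(ctx, j, j) != substr(cons, j, j))
    pass <- mism <= allow
    perm[ii[pass]] <- p
    # count consecutive exact repeat blocks upstream of the junction
    jj <- ii[pass]
    if (length(jj)) {
      cnt <- rep(0L, length(jj))
      active <- rep(TRUE, length(jj))
      blk <- 1L
      while (any(active)) {
        lo <- prefixLen[jj] - 7L * blk + 1L
        fits <- active & lo >= 1L
        eq <- rep(FALSE, length(jj))
        if (any(fits))
          eq[fits] <- substr(seqs[jj[fits]], lo[fits],
                             lo[fits] + 6L) == perms[p]
        cnt[eq] <- blk
        active <- eq
        blk <- blk + 1L
      }
      nrep[jj] <- cnt
    }
  }
  list(perm = perm, nRepeats = nrep)
}

.revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

#' Locate the ligation junction in a single read
#'
#' Finds the smallest offset at which the adaptor's first 10 nt match the
#' read with at most `maxMismatch` substitutions, searching the read as given
#' and its reverse complement. The junction is reported in G-strand
#' orientation: when both orientations contain an adaptor match, the one
#' whose upstream sequence better matches the phased telomeric-repeat
#' consensus wins (ties go to the forward orientation).
#'
#' @param read A single sequence (character or [Biostrings::DNAString]).
#' @param adaptor Adaptor sequence (>= 10 nt).
#' @param maxMismatch Allowed substitutions in the 10-nt adaptor prefix.
#' @return A list with `offset` (number of bases 5' of the adaptor in
#'   G-strand orientation) and `orientation` ("forward" or "reverse"), or
#'   `NULL` when no junction is found.
#' @examples
#' locateJunction(paste0(strrep("TTTAGGG", 3), telorepAdaptor()),
#'                telorepAdaptor(), 0)$offset  # 21
#' @export
locateJunction <- function(read, adaptor, maxMismatch = 1L) {
  if (nchar(adaptor) < 10) stop("adaptor must be >= 10 nt", call. = FALSE)
  seq <- toupper(as.character(read))
  stopifnot(length(seq) == 1L)
  rc <- .revcomp(seq)
  oF <- .scanAdaptor(seq, adaptor, maxMismatch)
  oR <- .scanAdaptor(rc, adaptor, maxMismatch)
  score <- function(s, o) {
    if (is.na(o) || o - 1L < 14L) return(Inf)
    pl <- o - 1L
    min(vapply(telomericPermutations(), function(p) {
      cons <- strrep(p, 2)
      ctx <- substr(s, pl - 13L, pl)
      sum(utf8ToInt(ctx) != utf8ToInt(cons))
    }, numeric(1)))
  }
  sF <- score(seq, oF)
  sR <- score(rc, oR)
  if (is.na(oF) && is.na(oR)) return(NULL)
  if (!is.na(oF) && (is.na(oR) || sF <= sR))
    list(offset = oF - 1L, orientation = "forward")
  else
    list(offset = oR - 1L, orientation = "reverse")
}

#' Classify the terminal permutation of a read with a located junction
#'
#' The 7-mer immediately 5' of the junction (G-strand orientation) must be
#' exactly one of the seven rotations of TTTAGGG; no mismatch is tolerated at
#' the terminus itself, because a substitution there would silently rename
#' the permutation being measured. In addition, at least `minRepeats`
#' complete repeats ending at the junction (the terminal 7-mer plus its
#' upstream continuation) must match the phase-consistent consensus with
#' >= 90% identity.
#'
#' @param read A single sequence, already in G-strand orientation.
#' @param junction Number of bases 5' of the adaptor (as returned by
#'   [locateJunction()]).
#' @param minRepeats Required complete telomeric repeats ending at the
#'   junction (default 2, i.e. 14 nt of context).
#' @return One of [telomericPermutations()] or `"UNCLASSIFIED"`.
#' @export
classifyTerminus <- function(read, junction, minRepeats = 2L) {
  seq <- toupper(as.character(read))
  stopifnot(length(seq) == 1L)
  res <- .classifyAt(seq, as.integer(junction), as.integer(minRepeats))
  if (is.na(res$perm[1])) "UNCLASSIFIED"
  else telomericPermutations()[res$perm[1]]
}

#' Classify every read of a sample
#'
#' Vectorized junction location and terminus classification. Reads whose
#' forward orientation yields no classifiable junction are retried as
#' reverse complements, making the result invariant to the sequencing
#' orientation of the library.
#'
#' @param reads A [Biostrings::DNAStringSet] or character vector.
#' @param adaptor Adaptor sequence (>= 10 nt).
#' @param minRepeats Required complete repeats of upstream context.
#' @param maxMismatch Allowed substitutions in the 10-nt adaptor prefix.
#' @return A [S4Vectors::DataFrame] with one row per read: `id`, `junction`
#'   (bases 5' of the adaptor, NA if not found), `orientation`,
#'   `permutation` (factor including `"UNCLASSIFIED"`), `nRepeats`.
#' @export
classifyReads <- function(reads, adaptor = telorepAdaptor(),
                          minRepeats = 2L, maxMismatch = 1L) {
  if (nchar(adaptor) < 10) stop("adaptor must be >= 10 nt", call. = FALSE)
  # XStringSet sequences are already uppercase; only raw character input
  # needs normalizing
  seqs <- if (is.character(reads)) toupper(reads) else as.character(reads)
  nm <- names(reads) %||% paste0("read", seq_along(seqs))
  n <- length(seqs)
  off <- .scanAdaptor(seqs, adaptor, maxMismatch)
  prefixLen <- off - 1L
  cls <- .classifyAt(seqs, prefixLen, as.integer(minRepeats))
  orientation <- rep("forward", n)
  retry <- which(is.na(cls$perm))
  if (length(retry)) {
    rc <- .revcomp(seqs[retry])
    off2 <- .scanAdaptor(rc, adaptor, maxMismatch)
    cls2 <- .classifyAt(rc, off2 - 1L, as.integer(minRepeats))
    take <- !is.na(cls2$perm)
    if (any(take)) {
      ii <- retry[take]
      prefixLen[ii] <- off2[take] - 1L
      cls$perm[ii] <- cls2$perm[take]
      cls$nRepeats[ii] <- cls2$nRepeats[take]
      orientation[ii] <- "reverse"
    }
    # keep a located-but-unclassified reverse junction for reporting
    miss <- retry[!take & is.na(prefixLen[retry]) & !is.na(off2)]
    if (length(miss)) {
      prefixLen[miss] <- off2[match(miss, retry)] - 1L
      orientation[miss] <- "reverse"
    }
  }
  perms <- telomericPermutations()
  lab <- factor(ifelse(is.na(cls$perm), "UNCLASSIFIED", perms[cls$perm]),
                levels = c(perms, "UNCLASSIFIED"))
  S4Vectors::DataFrame(id = nm, junction = prefixLen,
                       orientation = orientation, permutation = lab,
                       nRepeats = cls$nRepeats)
}

#' Terminal-permutation profile of a read sample
#'
#' Runs [classifyReads()] and tallies classified reads per permutation;
#' frequencies are computed over classified reads only.
#'
#' @inheritParams classifyReads
#' @param sampleId Sample label stored in the profile.
#' @return A [PermutationProfile]. When no read is classifiable, the profile
#'   is returned with all counts 0 and flagged by [profileValid()] returning
#'   `FALSE`, with a warning.
#' @examples
#' reads <- simulateAmpliconReads("c24", 2000, errorRate = 0, seed = 1)
#' frequencies(profileSample(reads))
#' @export
profileSample <- function(reads, adaptor = telorepAdaptor(),
                          minRepeats = 2L, maxMismatch = 1L,
                          sampleId = "sample") {
  if (length(reads) == 0) stop("empty read set", call. = FALSE)
  cls <- classifyReads(reads, adaptor, minRepeats, maxMismatch)
  perms <- telomericPermutations()
  tab <- table(cls$permutation)
  counts <- stats::setNames(as.integer(tab[perms]), perms)
  nUncl <- as.integer(tab[["UNCLASSIFIED"]])
  if (sum(counts) == 0L)
    warning("no classifiable reads: empty profile for '", sampleId, "'")
  methods::new("PermutationProfile", sampleId = sampleId, counts = counts,
               nUnclassified = nUncl)
}

#' @rdname accessors
#' @export
setMethod("sampleId", "PermutationProfile", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("permCounts", "PermutationProfile", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("nClassified", "PermutationProfile", function(x) sum(x@counts))

#' @rdname accessors
#' @export
setMethod("nUnclassified", "PermutationProfile", function(x) x@nUnclassified)

#' @rdname accessors
#' @export
setMethod("frequencies", "PermutationProfile", function(x) {
  n <- sum(x@counts)
  if (n == 0L) return(stats::setNames(rep(NA_real_, 7),
                                      telomericPermutations()))
  x@counts / n
})

#' Is a permutation profile non-empty?
#'
#' @param x A [PermutationProfile].
#' @return `TRUE` when at least one read was classified.
#' @export
profileValid <- function(x) nClassified(x) > 0L

setMethod("show", "PermutationProfile", function(object) {
  cat("PermutationProfile '", object@sampleId, "': ",
      nClassified(object), " classified, ", object@nUnclassified,
      " unclassified\n", sep = "")
  if (profileValid(object))
    print(round(frequencies(object), 4))
})

#' Write a permutation profile as CSV
#'
#' Columns `permutation,count,frequency`.
#'
#' @param profile A [PermutationProfile].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeProfile <- function(profile, path) {
  utils::write.csv(
    data.frame(permutation = telomericPermutations(),
               count = permCounts(profile),
               frequency = frequencies(profile)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mean and SD of permutation frequencies across replicates
#'
#' @param profiles List of [PermutationProfile] replicates. With a single
#'   replicate the mean is returned and the SD flagged unavailable (NA, with
#'   a warning).
#' @return data.frame with `permutation`, `mean`, `sd` and `n` (replicates).
#' @export
aggregateReplicates <- function(profiles) {
  if (!length(profiles)) stop("no profiles supplied", call. = FALSE)
  f <- vapply(profiles, frequencies, numeric(7))  # 7 x nrep
  if (length(profiles) == 1L) {
    warning("single replicate: SD unavailable")
    sds <- rep(NA_real_, 7)
  } else {
    sds <- apply(f, 1, stats::sd)
  }
  data.frame(permutation = telomericPermutations(),
             mean = rowMeans(f), sd = sds, n = length(profiles))
}

#' Contrast permutation profiles between two genotype groups
#'
#' Per permutation: difference of group mean frequencies in percentage
#' points (`(meanA - meanB) * 100`) and an equal-variance two-tailed
#' two-sample t-test on the replicate frequencies. When both groups have
#' zero variance for a permutation the test is undefined (NA) but the
#' difference is still reported.
#'
#' @param groupA,groupB Lists of [PermutationProfile] replicates (>= 2
#'   each).
#' @return data.frame with `permutation`, `delta` (percentage points),
#'   `meanA`, `meanB`, `sdA`, `sdB`, `t`, `p`.
#' @export
compareProfiles <- function(groupA, groupB) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("at least 2 replicates per group are required", call. = FALSE)
  fa <- vapply(groupA, frequencies, numeric(7))
  fb <- vapply(groupB, frequencies, numeric(7))
  res <- lapply(seq_len(7), function(p) {
    a <- fa[p, ]; b <- fb[p, ]
    d <- (mean(a) - mean(b)) * 100
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      c(delta = d, meanA = mean(a), meanB = mean(b), sdA = stats::sd(a),
        sdB = stats::sd(b), t = NA_real_, p = NA_real_)
    } else {
      tt <- stats::t.test(a, b, var.equal = TRUE)
      c(delta = d, meanA = mean(a), meanB = mean(b), sdA = stats::sd(a),
        sdB = stats::sd(b), t = unname(tt$statistic), p = tt$p.value)
    }
  })
  out <- as.data.frame(do.call(rbind, res))
  out <- cbind(permutation = telomericPermutations(), out)
  rownames(out) <- NULL
  out
}
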