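#' The seven terminal permutations of the plant telomeric repeat
#'
#' Cyclic rotations of TTTAGGG, read 5'->3' on the G-rich strand; the
#' rotation found immediately 5' of the hairpin-ligation junction names the
#' terminal permutation of a blunt-ended telomere.
#'
#' @return Character vector of the 7 rotations, starting with TTTAGGG and
#'   proceeding by successive left shifts.
#' @examples
#' telomericPermutations()
#' @export
telomericPermutations <- function() {
  s <- "TTTAGGG"
  vapply(0:6, function(k) paste0(substr(s, k + 1, 7), substr(s, 1, k)), "")
}

#' Default non-telomeric ligation adaptor used in simulations
#'
#' A fixed 20-nt sequence standing in for the hairpin adaptor; terminal
#' classification depends only on locating the ligation junction, not on the
#' adaptor's exact sequence, so any non-telomeric sequence of length >= 10
#' may be substituted.
#'
#' @return A 20-character adaptor sequence.
#' @export
telorepAdaptor <- function() "GATCGGAAGAGCACACGTCT"

#' Ground-truth terminal-permutation presets
#'
#' Frequency vectors over the 7 permutations used by
#' [simulateAmpliconReads()]. The TTTAGGG-3' components are anchored to
#' published figures for the two wild-type accessions (C24 0.58, Col-0 0.42)
#' and to the reported reductions in the mutants (pol alpha: 14 percentage
#' points below C24, in favour of GTTTAGG-3' and GGTTTAG-3'; stn1: 16 points
#' below Col-0, with the preference shifted to GTTTAGG-3'; exo1 stn1:
#' restored to a near wild-type profile). The remaining components follow the
#' qualitative rank order GTTTAGG > GGTTTAG > other rotations and are fixed
#' fixture constants of this package, not measured values.
#'
#' @return Named list of 7-vectors summing to 1, in the order of
#'   [telomericPermutations()]. Presets: `colzero`, `c24`, `stn1`,
#'   `exo1_stn1`, `polalpha`.
#' @examples
#' permutationPresets()$c24
#' @export
permutationPresets <- function() {
  perms <- telomericPermutations()
  mk <- function(tttaggg, gtttagg, ggtttag, rest) {
    v <- stats::setNames(rep(rest, 7), perms)
    v["TTTAGGG"] <- tttaggg
    v["GTTTAGG"] <- gtttagg
    v["GGTTTAG"] <- ggtttag
    stopifnot(abs(sum(v) - 1) < 1e-9)
    v
  }
  list(
    colzero   = mk(0.42, 0.22, 0.14, 0.055),
    c24       = mk(0.58, 0.16, 0.10, 0.040),
    stn1      = mk(0.26, 0.34, 0.18, 0.055),
    exo1_stn1 = mk(0.40, 0.23, 0.15, 0.055),
    polalpha  = mk(0.44, 0.24, 0.16, 0.040)
  )
}

.resolvePreset <- function(preset) {
  if (is.character(preset) && length(preset) == 1L) {
    presets <- permutationPresets()
    if (!preset %in% names(presets))
      stop("unknown preset '", preset, "'; available: ",
           paste(names(presets), collapse = ", "), call. = FALSE)
    return(presets[[preset]])
  }
  perms <- telomericPermutations()
  v <- as.numeric(preset)
  if (length(v) != 7L || any(v < 0) || abs(sum(v) - 1) > 1e-9)
    stop("preset frequencies must be a non-negative 7-vector summing to 1",
         call. = FALSE)
  stats::setNames(v, perms)
}

#' Simulate hairpin-ligation amplicon reads
#'
#' Each read is `barcode` + a G-strand telomeric repeat array + `adaptor`,
#' truncated to `readLength`. The repeat array is a suffix of the periodic
#' sequence (TTTAGGG)n chosen so that its terminal 7-mer, immediately 5' of
#' the ligation junction, is drawn from the preset's permutation
#' frequencies. Substitution errors are injected independently per base at
#' `errorRate`; the true permutation is recorded in each read identifier
#' (`label=<permutation>`) so classifier accuracy is computable exactly.
#'
#' @param preset A preset name (see [permutationPresets()]) or a 7-vector of
#'   frequencies summing to 1.
#' @param nReads Number of reads.
#' @param readLength Read length in nt (default 50, single-end).
#' @param errorRate Per-base substitution probability.
#' @param adaptor Adaptor sequence (>= 10 nt).
#' @param barcode Sample barcode prefixed to every read ("" for none).
#' @param seed Integer seed; output is reproducible given the seed.
#' @return A [Biostrings::DNAStringSet]; names carry the read id and the
#'   embedded true label.
#' @examples
#' reads <- simulateAmpliconReads("c24", 100, errorRate = 0, seed = 1)
#' head(names(reads))
#' @export
simulateAmpliconReads <- function(preset, nReads, readLength = 50L,
                                  errorRate = 0, adaptor = telorepAdaptor(),
                                  barcode = "", seed) {
  freqs <- .resolvePreset(preset)
  if (nchar(adaptor) < 10)
    stop("adaptor must be at least 10 nt", call. = FALSE)
  .assertScalarNumber(errorRate, "errorRate", 0, 1)
  seed <- .assertSeed(seed)
  teloLen <- readLength - nchar(barcode) - nchar(adaptor)
  if (teloLen < 21)
    stop("readLength leaves <21 nt of telomeric context ",
         "(need the terminal 7-mer plus two upstream repeats)",
         call. = FALSE)

  perms <- telomericPermutations()
  full <- strrep("TTTAGGG", ceiling((teloLen + 7) / 7) + 2)
  suffixes <- vapply(0:6, function(k) {
    end <- k + 7
    while (end < teloLen + 7) end <- end + 7
    substr(full, end - teloLen + 1, end)
  }, "")
  stopifnot(substr(suffixes, teloLen - 6, teloLen) == perms)

  .withSeed(seed, {
    lab <- sample.int(7, nReads, replace = TRUE, prob = freqs)
    reads <- paste0(barcode, suffixes[lab], adaptor)
    reads <- substr(reads, 1, readLength)
    if (errorRate > 0) {
      nerr <- stats::rbinom(nReads, readLength, errorRate)
      bases <- c("A", "C", "G", "T")
      one <- which(nerr == 1L)
      if (length(one)) {
        pos <- sample.int(readLength, length(one), replace = TRUE)
        old <- substr(reads[one], pos, pos)
        new <- bases[(match(old, bases) +
                        sample.int(3, length(one), replace = TRUE) - 1) %%
                       4 + 1]
        substr(reads[one], pos, pos) <- new
      }
      for (i in which(nerr >= 2L)) {
        pos <- sample.int(readLength, nerr[i])
        for (p in pos) {
          old <- substr(reads[i], p, p)
          new <- bases[(match(old, bases) + sample.int(3, 1) - 1) %% 4 + 1]
          substr(reads[i], p, p) <- new
        }
      }
    }
    out <- Biostrings::DNAStringSet(reads)
    names(out) <- paste0("read", seq_len(nReads), " label=", perms[lab])
    out
  })
}

#' Extract the embedded true labels from simulated read names
#'
#' @param reads A [Biostrings::DNAStringSet] produced by
#'   [simulateAmpliconReads()], or its names.
#' @return Character vector of true permutation labels.
#' @export
trueLabels <- function(reads) {
  nm <- if (is.character(reads)) reads else names(reads)
  sub(".*label=", "", nm)
}

#' Write / read amplicon reads as FASTQ
#'
#' Sanger-quality (Phred+33) FASTQ via Biostrings. Simulated reads carry no
#' meaningful qualities, so a constant quality character is written.
#'
#' @param reads A named [Biostrings::DNAStringSet].
#' @param path File path (a `.gz` suffix enables compression on read).
#' @param qualityChar Constant quality character (default "I", Q40).
#' @return `writeFastqReads` returns `path` invisibly; `readFastqReads`
#'   returns a named [Biostrings::DNAStringSet].
#' @export
writeFastqReads <- function(reads, path, qualityChar = "I") {
  quals <- Biostrings::BStringSet(strrep(qualityChar,
                                         Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = quals)
  invisible(path)
}

#' @rdname writeFastqReads
#' @export
readFastqReads <- function(path) {
  Biostrings::readDNAStringSet(path, format = "fastq")
}
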