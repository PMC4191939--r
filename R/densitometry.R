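#' Simulate a densitometry table with known fold change
#'
#' Emits lane-level densitometry rows for a wild-type ("wt") and a mutant
#' ("mut") genotype such that the G-overhang normalization chain
#' ([overhangSignal()] then [foldChange()]) recovers `trueFold` in
#' expectation. Every sample contributes a native lane and a matched
#' T4-polymerase-pretreated lane (overhangs removed, so only background
#' signal remains). Loadings vary across lanes even in the noise-free table
#' so that the loading-normalization step is genuinely exercised.
#' Measurement noise is multiplicative log-normal with coefficient of
#' variation `noiseCv`, applied independently to every lane signal and
#' scaled to unit mean so expectations are preserved; the loadings are the
#' design values of the table (densitometric noise on the loading channel is
#' subsumed in the signal noise).
#'
#' @param trueFold Mutant / wild-type overhang fold change (> 0).
#' @param nLanesPerGenotype Samples per genotype.
#' @param noiseCv Log-normal noise CV (0 gives an exact, deterministic
#'   table).
#' @param seed Integer seed (ignored when `noiseCv == 0`).
#' @param background T4-resistant background signal per unit loading.
#' @return data.frame with columns `sample`, `genotype`, `signal`,
#'   `loading`, `t4_treated` (two rows per sample).
#' @examples
#' tab <- makeDensitometryFixture(6, 4, 0, seed = 0)
#' foldChange(overhangSignal(tab), "mut", "wt")$fold
#' @export
makeDensitometryFixture <- function(trueFold, nLanesPerGenotype = 4,
                                    noiseCv = 0, seed = 0,
                                    background = 0.25) {
  .assertScalarNumber(trueFold, "trueFold", 1e-12)
  .assertScalarNumber(noiseCv, "noiseCv", 0, 1)
  n <- as.integer(nLanesPerGenotype)
  if (n < 1) stop("nLanesPerGenotype must be >= 1", call. = FALSE)

  genotype <- rep(c("wt", "mut"), each = n)
  overhang <- rep(c(1, trueFold), each = n)
  # deterministic loading spread, recycled across genotypes
  loading <- rep(seq(0.8, 1.2, length.out = n), times = 2)
  sample <- paste0(genotype, "_", rep(seq_len(n), times = 2))

  native <- (overhang + background) * loading
  t4 <- background * loading

  tab <- data.frame(
    sample = rep(sample, each = 2),
    genotype = rep(genotype, each = 2),
    signal = as.vector(rbind(native, t4)),
    loading = rep(loading, each = 2),
    t4_treated = rep(c(FALSE, TRUE), times = 2 * n)
  )
  if (noiseCv > 0) {
    sdlog <- sqrt(log(1 + noiseCv^2))
    noise <- function(k) exp(stats::rnorm(k, -sdlog^2 / 2, sdlog))
    tab <- .withSeed(seed, {
      tab$signal <- tab$signal * noise(nrow(tab))
      tab
    })
  }
  tab
}

#' Normalized G-overhang signal per sample
#'
#' Implements the in-gel hybridization normalization chain: each lane's
#' signal is first divided by its loading control (ethidium-bromide
#' staining), the loading-normalized signal of the matched T4-pretreated
#' lane is subtracted (removing the T4-resistant background), and the result
#' is divided by the mean over the reference (wild-type) samples so that the
#' wild-type mean is exactly 1. Negative background-subtracted signals are
#' floored at 0 with a warning.
#'
#' @param table data.frame with columns `sample`, `genotype`, `signal`,
#'   `loading`, `t4_treated`; each sample must have exactly one native and
#'   one T4-treated row.
#' @param reference Genotype label of the reference group (default "wt").
#' @return data.frame with one row per sample: `sample`, `genotype`,
#'   `value` (dimensionless, reference mean = 1).
#' @export
overhangSignal <- function(table, reference = "wt") {
  need <- c("sample", "genotype", "signal", "loading", "t4_treated")
  if (!all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(table$signal <= 0) || any(table$loading <= 0))
    stop("signal and loading must be positive", call. = FALSE)
  nat <- table[!table$t4_treated, ]
  t4 <- table[table$t4_treated, ]
  if (!setequal(nat$sample, t4$sample) ||
      anyDuplicated(nat$sample) || anyDuplicated(t4$sample))
    stop("each sample needs exactly one native and one T4-treated lane",
         call. = FALSE)
  t4 <- t4[match(nat$sample, t4$sample), ]
  graw <- nat$signal / nat$loading - t4$signal / t4$loading
  if (any(graw < 0)) {
    warning(sum(graw < 0),
            " negative background-subtracted signal(s) floored at 0")
    graw <- pmax(graw, 0)
  }
  ref <- nat$genotype == reference
  if (!any(ref))
    stop("no samples with reference genotype '", reference, "'",
         call. = FALSE)
  refMean <- mean(graw[ref])
  if (refMean <= 0)
    stop("reference group has zero overhang signal", call. = FALSE)
  data.frame(sample = nat$sample, genotype = nat$genotype,
             value = graw / refMean)
}

#' Normalized dot-blot telomere content per sample
#'
#' Telomeric hybridization signal divided by the repeat loading control
#' (CEN180 signal), then normalized so the reference genotype's mean is
#' exactly 1.
#'
#' @param table data.frame with columns `sample`, `genotype`, `signal`
#'   (telomere probe) and `loading` (CEN180 probe), one row per sample.
#' @param reference Reference genotype label (default "wt").
#' @return data.frame with `sample`, `genotype`, `value`.
#' @export
dotblotContent <- function(table, reference = "wt") {
  need <- c("sample", "genotype", "signal", "loading")
  if (!all(need %in% names(table)))
    stop("table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(table$loading <= 0))
    stop("zero or negative loading", call. = FALSE)
  content <- table$signal / table$loading
  ref <- table$genotype == reference
  if (!any(ref))
    stop("no samples with reference genotype '", reference, "'",
         call. = FALSE)
  data.frame(sample = table$sample, genotype = table$genotype,
             value = content / mean(content[ref]))
}

#' Fold change between genotype groups of normalized signals
#'
#' Ratio of group means with a first-order propagated SD:
#' `sd = fold * sqrt((sdA/meanA)^2 + (sdB/meanB)^2)` from the replicate SDs
#' of the two groups (NA when either group has a single replicate).
#'
#' @param values data.frame from [overhangSignal()] or [dotblotContent()].
#' @param groupA,groupB Genotype labels (fold = mean A / mean B).
#' @return list with `fold`, `sd`, `nA`, `nB`.
#' @export
foldChange <- function(values, groupA, groupB) {
  a <- values$value[values$genotype == groupA]
  b <- values$value[values$genotype == groupB]
  if (!length(a) || !length(b))
    stop("both groups need at least one sample", call. = FALSE)
  if (mean(b) == 0) stop("zero denominator group mean", call. = FALSE)
  fold <- mean(a) / mean(b)
  sd <- if (length(a) > 1 && length(b) > 1) {
    fold * sqrt((stats::sd(a) / mean(a))^2 + (stats::sd(b) / mean(b))^2)
  } else NA_real_
  list(fold = fold, sd = sd, nA = length(a), nB = length(b))
}

#' Read / write densitometry tables as CSV
#'
#' @param table Lane-level densitometry data.frame.
#' @param path File path.
#' @return `writeDensitometry` returns `path` invisibly; `readDensitometry`
#'   a data.frame.
#' @export
writeDensitometry <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDensitometry
#' @export
readDensitometry <- function(path) {
  utils::read.csv(path)
}
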