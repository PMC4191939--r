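#' Re-replication shoulder specification
#'
#' Generative model of the high-DNA-content shoulder seen on endoreplicated
#' peaks when heterochromatin re-replicates: each nucleus of an
#' endoreplicated class (8C and above) carries, with probability
#' `rerepProbability`, extra DNA drawn uniformly between 0 and
#' `extraFractionMax` times the class's C-value position.
#'
#' @param rerepProbability Fraction of endoreplicated nuclei carrying extra
#'   DNA, in \[0, 1\].
#' @param extraFractionMax Maximum extra DNA as a fraction of the class mean,
#'   in \[0, 1\].
#' @return A list of class `shoulderSpec`.
#' @export
shoulderSpec <- function(rerepProbability = 0, extraFractionMax = 0) {
  .assertScalarNumber(rerepProbability, "rerepProbability", 0, 1)
  .assertScalarNumber(extraFractionMax, "extraFractionMax", 0, 1)
  structure(list(rerepProbability = rerepProbability,
                 extraFractionMax = extraFractionMax),
            class = "shoulderSpec")
}

#' Simulate per-nucleus fluorescence values
#'
#' Each nucleus draws a ploidy class (2C, 4C, 8C, 16C, 32C) from
#' `classWeights`; its fluorescence is Gaussian with mean at the class
#' position `peak2C * {1, 2, 4, 8, 16}` and coefficient of variation `cv`.
#' Nuclei of classes 8C and above additionally receive the shoulder's extra
#' DNA (see [shoulderSpec()]).
#'
#' @param peak2C Fluorescence position of the 2C peak (arbitrary linear
#'   units).
#' @param cv Coefficient of variation of each peak (sd / mean).
#' @param classWeights 5-vector of class probabilities summing to 1,
#'   ordered 2C..32C.
#' @param shoulder A [shoulderSpec()].
#' @param nNuclei Number of nuclei.
#' @param seed Integer seed.
#' @return data.frame with one row per nucleus: `class` (label), `mean`
#'   (class position), `extra` (shoulder DNA added) and `value` (final
#'   fluorescence).
#' @export
simulateNuclei <- function(peak2C = 50, cv = 0.05,
                           classWeights = c(0.35, 0.30, 0.20, 0.10, 0.05),
                           shoulder = shoulderSpec(), nNuclei = 3000,
                           seed) {
  if (length(classWeights) != 5L || any(classWeights < 0) ||
      abs(sum(classWeights) - 1) > 1e-9)
    stop("classWeights must be a non-negative 5-vector summing to 1",
         call. = FALSE)
  .assertScalarNumber(cv, "cv", 0, 1)
  seed <- .assertSeed(seed)
  labels <- c("2C", "4C", "8C", "16C", "32C")
  mu <- peak2C * c(1, 2, 4, 8, 16)

  .withSeed(seed, {
    cls <- sample.int(5, nNuclei, replace = TRUE, prob = classWeights)
    value <- stats::rnorm(nNuclei, mean = mu[cls], sd = cv * mu[cls])
    extra <- numeric(nNuclei)
    endo <- cls >= 3L
    hit <- endo & stats::runif(nNuclei) < shoulder$rerepProbability
    if (any(hit))
      extra[hit] <- stats::runif(sum(hit)) *
        shoulder$extraFractionMax * mu[cls[hit]]
    data.frame(class = labels[cls], mean = mu[cls], extra = extra,
               value = value + extra)
  })
}

#' Bin fluorescence values into a cytogram
#'
#' @param values Numeric per-nucleus fluorescence values.
#' @param nChannels Number of equal-width channels (default 512).
#' @param fullScale Upper end of the fluorescence axis; values outside
#'   \[0, fullScale\] are dropped with a warning.
#' @return A [Cytogram].
#' @export
cytogramFromValues <- function(values, nChannels = 512L, fullScale) {
  .assertScalarNumber(fullScale, "fullScale", 1e-12)
  drop <- values < 0 | values > fullScale
  if (any(drop)) {
    warning(sum(drop), " value(s) outside [0, fullScale] dropped")
    values <- values[!drop]
  }
  widthC <- fullScale / nChannels
  idx <- pmin(nChannels, floor(values / widthC) + 1L)
  counts <- tabulate(idx, nbins = nChannels)
  methods::new("Cytogram",
               channels = (seq_len(nChannels) - 0.5) * widthC,
               counts = as.numeric(counts))
}

#' Simulate a flow-cytometry cytogram of endoreplicated nuclei
#'
#' Convenience wrapper: [simulateNuclei()] followed by
#' [cytogramFromValues()]. The default full scale is `24 * peak2C`, placing
#' the 2C..32C doubling series well inside the axis and giving roughly 60
#' channels across an 8C gate at the default 512-channel resolution.
#'
#' @inheritParams simulateNuclei
#' @inheritParams cytogramFromValues
#' @return A [Cytogram].
#' @examples
#' cg <- simulateCytogram(nNuclei = 3000, seed = 1)
#' cg
#' @export
simulateCytogram <- function(peak2C = 50, cv = 0.05,
                             classWeights = c(0.35, 0.30, 0.20, 0.10, 0.05),
                             shoulder = shoulderSpec(), nNuclei = 3000,
                             nChannels = 512L, fullScale = 24 * peak2C,
                             seed) {
  if (peak2C * 16 >= fullScale)
    stop("peaks at peak2C * {1,2,4,8,16} must fit within fullScale",
         call. = FALSE)
  nuc <- simulateNuclei(peak2C, cv, classWeights, shoulder, nNuclei, seed)
  cytogramFromValues(nuc$value, nChannels, fullScale)
}

#' @rdname accessors
#' @export
setMethod("channels", "Cytogram", function(x) x@channels)

#' @rdname accessors
#' @export
setMethod("channelCounts", "Cytogram", function(x) x@counts)

setMethod("show", "Cytogram", function(object) {
  cat("Cytogram:", length(object@channels), "channels,",
      sum(object@counts), "nuclei, full scale ~",
      round(max(object@channels) + diff(object@channels[1:2]) / 2, 2), "\n")
})

#' Read / write a cytogram as two-column CSV
#'
#' CSV with header `channel,count`; channels are midpoints on a linear axis.
#'
#' @param cytogram A [Cytogram].
#' @param path File path.
#' @return `writeCytogram` returns `path` invisibly; `readCytogram` a
#'   [Cytogram].
#' @export
writeCytogram <- function(cytogram, path) {
  utils::write.csv(data.frame(channel = channels(cytogram),
                              count = channelCounts(cytogram)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeCytogram
#' @export
readCytogram <- function(path) {
  tab <- utils::read.csv(path)
  if (!all(c("channel", "count") %in% names(tab)))
    stop("cytogram CSV must have columns 'channel' and 'count'",
         call. = FALSE)
  methods::new("Cytogram", channels = tab$channel,
               counts = as.numeric(tab$count))
}
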