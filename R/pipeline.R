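#' Run one pipeline stage from a configuration list
#'
#' Single programmatic entry point behind the `telorep` command-line script
#' (`system.file("scripts", "telorep.R", package = "telorep")`). The
#' configuration is a named list with a `subcommand` element plus that
#' stage's parameters; every stochastic stage requires an explicit `seed`.
#' Outputs are written next to a machine-readable JSON run report (the exact
#' configuration, package version, per-stage record counts), so an output
#' directory always contains what is needed to regenerate it; identical
#' configuration and seed give identical outputs.
#'
#' Subcommands and their parameters:
#' \describe{
#'   \item{`simulate-amplicons`}{`preset`, `n`, `readLength`, `errorRate`,
#'     `adaptor`, `barcode`, `seed`, `out` (FASTQ path).}
#'   \item{`simulate-positions`}{toy-genome parameters (`nChrom`,
#'     `chromLength`, `pericentromereFraction`, `copyMultiplier`,
#'     `unmappableFraction`, `binSize`, `genomeSeed`), `n`, `duplicateRate`,
#'     `seed`, `outDir` (writes `reads.bed`, `chrom.sizes`,
#'     `mappability.bedGraph`).}
#'   \item{`simulate-cytogram`}{`peak2C`, `cv`, `classWeights`,
#'     `rerepProbability`, `extraFractionMax`, `n`, `nChannels`, `seed`,
#'     `out` (CSV).}
#'   \item{`simulate-densitometry`}{`trueFold`, `lanes`, `noiseCv`, `seed`,
#'     `out` (CSV).}
#'   \item{`permute`}{`fastq`, optional `barcodes` CSV, `adaptor`,
#'     `minRepeats`, `maxMismatch`, `outPrefix` (writes
#'     `<prefix>.<sample>.csv` per sample and a JSON summary).}
#'   \item{`rerep`}{`mutant` and `wildtype` (character vectors of BED
#'     paths), `chromSizes`, optional `mappability` bedGraph, `binSize`,
#'     `windowSpan`, `topQuantile`, `smoothK`, `outPrefix` (writes a
#'     bedGraph profile and a JSON report).}
#'   \item{`ploidy`}{`cytogram` CSV, `class`, optional `mode`, `out`
#'     (JSON).}
#'   \item{`densito`}{`table` CSV, `assay` ("overhang" or "dotblot"),
#'     `reference`, `groupA`, `groupB`, `out` (JSON).}
#' }
#'
#' @param config Named list as described above.
#' @return Invisibly, a list of the stage's key results (also serialized in
#'   the run report).
#' @export
runPipeline <- function(config) {
  if (is.null(config$subcommand))
    stop("config$subcommand is required", call. = FALSE)
  need <- function(field) {
    if (is.null(config[[field]]))
      stop("missing required parameter '", field, "' for subcommand '",
           config$subcommand, "'", call. = FALSE)
    config[[field]]
  }
  opt <- function(field, default) config[[field]] %||% default

  result <- switch(config$subcommand,
    "simulate-amplicons" = {
      out <- need("out")
      reads <- simulateAmpliconReads(
        need("preset"), need("n"),
        readLength = opt("readLength", 50L),
        errorRate = opt("errorRate", 0),
        adaptor = opt("adaptor", telorepAdaptor()),
        barcode = opt("barcode", ""), seed = need("seed"))
      writeFastqReads(reads, out)
      list(outputs = out, nReads = length(reads))
    },
    "simulate-positions" = {
      outDir <- need("outDir")
      dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
      genome <- buildToyGenome(
        nChrom = opt("nChrom", 2), chromLength = opt("chromLength", 30e6),
        pericentromereFraction = opt("pericentromereFraction", 0.2),
        copyMultiplier = opt("copyMultiplier", 1.6),
        unmappableFraction = opt("unmappableFraction", 0.02),
        binSize = opt("binSize", 10000L),
        seed = opt("genomeSeed", need("seed")))
      reads <- simulateReadPositions(genome, need("n"),
                                     duplicateRate = opt("duplicateRate", 0),
                                     seed = need("seed"))
      bed <- file.path(outDir, "reads.bed")
      writePositionsBed(reads, bed)
      cs <- writeChromSizes(genome, file.path(outDir, "chrom.sizes"))
      mp <- exportMappability(genome,
                              file.path(outDir, "mappability.bedGraph"))
      list(outputs = c(bed, cs, mp), nReads = length(reads))
    },
    "simulate-cytogram" = {
      out <- need("out")
      cg <- simulateCytogram(
        peak2C = opt("peak2C", 50), cv = opt("cv", 0.05),
        classWeights = opt("classWeights", c(0.35, 0.30, 0.20, 0.10, 0.05)),
        shoulder = shoulderSpec(opt("rerepProbability", 0),
                                opt("extraFractionMax", 0)),
        nNuclei = opt("n", 3000), nChannels = opt("nChannels", 512L),
        seed = need("seed"))
      writeCytogram(cg, out)
      list(outputs = out, nNuclei = sum(channelCounts(cg)))
    },
    "simulate-densitometry" = {
      out <- need("out")
      tab <- makeDensitometryFixture(need("trueFold"),
                                     nLanesPerGenotype = opt("lanes", 4),
                                     noiseCv = opt("noiseCv", 0),
                                     seed = opt("seed", 0))
      writeDensitometry(tab, out)
      list(outputs = out, nLanes = nrow(tab))
    },
    "permute" = {
      prefix <- need("outPrefix")
      reads <- readFastqReads(need("fastq"))
      groups <- if (!is.null(config$barcodes)) {
        dm <- demultiplexReads(reads, readBarcodes(config$barcodes))
        dm[names(dm) != "undetermined"]
      } else list(sample = reads)
      profs <- lapply(names(groups), function(s) {
        if (!length(groups[[s]])) return(NULL)
        p <- profileSample(groups[[s]],
                           adaptor = opt("adaptor", telorepAdaptor()),
                           minRepeats = opt("minRepeats", 2L),
                           maxMismatch = opt("maxMismatch", 1L),
                           sampleId = s)
        writeProfile(p, paste0(prefix, ".", s, ".csv"))
        p
      })
      profs <- Filter(Negate(is.null), profs)
      summary <- lapply(profs, function(p) list(
        sample = sampleId(p), nClassified = nClassified(p),
        nUnclassified = nUnclassified(p),
        frequencies = as.list(frequencies(p))))
      jsonlite::write_json(summary, paste0(prefix, ".summary.json"),
                           auto_unbox = TRUE, digits = NA)
      list(outputs = paste0(prefix, ".summary.json"),
           nSamples = length(profs))
    },
    "rerep" = {
      prefix <- need("outPrefix")
      binSize <- opt("binSize", 10000L)
      genome <- genomeFromFiles(need("chromSizes"),
                                mappability = config$mappability,
                                binSize = binSize)
      loadSide <- function(paths, label) {
        tabs <- lapply(seq_along(paths), function(i) {
          reads <- collapseDuplicates(readPositionsBed(paths[i]))
          binCounts(reads, genome, binSize,
                    sampleId = paste0(label, i))
        })
        tabs
      }
      mut <- loadSide(need("mutant"), "mut")
      wt <- loadSide(need("wildtype"), "wt")
      combined <- filterBins(combineSamples(c(mut, wt)),
                             topQuantile = opt("topQuantile", 0.01))
      nm <- length(mut)
      mutAvg <- averageReplicates(combined[, seq_len(nm)], "mutant")
      wtAvg <- averageReplicates(combined[, nm + seq_along(wt)], "wildtype")
      scaled <- smoothProfile(
        baseWindowScale(log2Ratio(mutAvg, wtAvg),
                        windowSpan = opt("windowSpan", 5e6)),
        k = opt("smoothK", 10L))
      bg <- paste0(prefix, ".bedGraph")
      exportProfile(scaled, bg)
      report <- list(
        filter = S4Vectors::metadata(combined)$filter,
        baseWindows = baseWindows(scaled),
        nBins = length(profileBins(scaled)))
      jsonlite::write_json(report, paste0(prefix, ".report.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      list(outputs = c(bg, paste0(prefix, ".report.json")),
           nBins = report$nBins)
    },
    "ploidy" = {
      out <- need("out")
      cg <- readCytogram(need("cytogram"))
      fit <- analyzePeak(cg, class = opt("class", "8C"),
                         mode = config$mode)
      res <- list(class = fit@ploidyClass, gate = fit@gate, mu = fit@mu,
                  sigma = fit@sigma, nGate = fit@nGate, x2 = fit@x2,
                  shoulder = fit@shoulder, reliable = fit@reliable)
      jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA)
      list(outputs = out, x2 = fit@x2)
    },
    "densito" = {
      out <- need("out")
      tab <- readDensitometry(need("table"))
      assay <- opt("assay", "overhang")
      values <- if (assay == "overhang")
        overhangSignal(tab, reference = opt("reference", "wt"))
      else if (assay == "dotblot")
        dotblotContent(tab, reference = opt("reference", "wt"))
      else stop("unknown assay '", assay, "'", call. = FALSE)
      fc <- foldChange(values, opt("groupA", "mut"), opt("groupB", "wt"))
      res <- list(assay = assay, values = values, foldChange = fc)
      jsonlite::write_json(res, out, auto_unbox = TRUE, digits = NA)
      list(outputs = out, fold = fc$fold)
    },
    stop("unknown subcommand '", config$subcommand, "'", call. = FALSE)
  )

  # sidecar run report next to the first output
  first <- result$outputs[1]
  sidecar <- file.path(dirname(first),
                       paste0(sub("\\.[A-Za-z0-9.]*$", "", basename(first)),
                              ".runconfig.json"))
  jsonlite::write_json(
    list(package = "telorep",
         version = as.character(utils::packageVersion("telorep")),
         config = config,
         result = result[setdiff(names(result), "outputs")]),
    sidecar, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(result)
}
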