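#' @importFrom tools md5sum
#' @importFrom utils packageVersion write.table
NULL

# High-level wrappers behind the command-line entry point
# (inst/scripts/en2splice-cli.R). Each run writes a JSON manifest next to
# its outputs: subcommand, input paths and md5 hashes, config echo, package
# version, seed, timestamp.

#' Write a run manifest
#'
#' @param path output JSON path.
#' @param subcommand name of the pipeline stage.
#' @param inputs character vector of input file paths (hashed with md5).
#' @param seed integer seed or \code{NULL}.
#' @param config optional list echoed verbatim.
#' @return Invisibly, the manifest list.
#' @export
writeRunManifest <- function(path, subcommand, inputs = character(),
                             seed = NULL, config = NULL) {
  manifest <- list(
    subcommand = subcommand,
    tool = "en2splice",
    version = as.character(utils::packageVersion("en2splice")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    config = config)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

#' Classify an allele-design table end to end
#'
#' Parses the exon and design tables, predicts an outcome per design, and
#' writes \code{predictions.csv}, \code{summary.json} and a run manifest
#' into \code{outputDir}.
#'
#' @param exonFile exon table path (see [parseExonTable()]).
#' @param designFile design table path (see [parseDesignTable()]).
#' @param outputDir output directory (created if needed).
#' @param dialect,columnMap passed to [parseExonTable()].
#' @param mode,bothModes,collapseStop passed to [predictAll()].
#' @return Invisibly, the predictions data.frame.
#' @export
runClassify <- function(exonFile, designFile, outputDir,
                        dialect = "canonical", columnMap = NULL, mode = NULL,
                        bothModes = FALSE, collapseStop = FALSE) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  exons <- parseExonTable(exonFile, dialect = dialect, columnMap = columnMap)
  designs <- parseDesignTable(designFile)
  pred <- predictAll(designs, exons, mode = mode, bothModes = bothModes,
                     collapseStop = collapseStop)
  writePredictions(pred, file.path(outputDir, "predictions.csv"),
                   file.path(outputDir, "summary.json"))
  writeRunManifest(file.path(outputDir, "manifest.json"), "classify",
                   inputs = c(exonFile, designFile),
                   config = list(mode = mode, bothModes = bothModes,
                                 collapseStop = collapseStop,
                                 dialect = dialect))
  invisible(pred)
}

#' Summarise phenotype and lacZ tables by predicted category
#'
#' Reads a predictions CSV (as written by [runClassify()]) together with a
#' phenotype-hit CSV and, optionally, a lacZ-expression CSV; writes the
#' per-category summary (\code{category_summary.csv}), its long format
#' (\code{category_summary_long.csv}), the lacZ-silent gene list
#' (\code{lacz_silent_genes.txt}) and a manifest into \code{outputDir}.
#'
#' @param predictionsFile predictions CSV path.
#' @param phenotypeFile phenotype CSV path.
#' @param outputDir output directory.
#' @param laczFile optional lacZ CSV path; skipped with a warning if
#'   missing.
#' @param minTissues threshold for [laczSilentGenes()].
#' @param columnMap passed to [parsePhenotypeCsv()].
#' @return Invisibly, the summary data.frame.
#' @export
runSummarize <- function(predictionsFile, phenotypeFile, outputDir,
                         laczFile = NULL, minTissues = 27L,
                         columnMap = NULL) {
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  pred <- .readTable(predictionsFile)
  pred$category <- .asOutcome(pred$category)
  phen <- parsePhenotypeCsv(phenotypeFile, columnMap = columnMap)
  summary <- summarizeCategories(pred, phen)
  out <- summary
  utils::write.csv(out, file.path(outputDir, "category_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(summaryLong(summary),
                   file.path(outputDir, "category_summary_long.csv"),
                   row.names = FALSE)
  inputs <- c(predictionsFile, phenotypeFile)
  if (!is.null(laczFile)) {
    if (file.exists(laczFile)) {
      silent <- laczSilentGenes(parseLaczCsv(laczFile),
                                minTissues = minTissues)
      writeLines(silent, file.path(outputDir, "lacz_silent_genes.txt"))
      inputs <- c(inputs, laczFile)
    } else {
      warning("lacZ file not found, silent-gene list skipped: ", laczFile)
    }
  }
  writeRunManifest(file.path(outputDir, "manifest.json"), "summarize",
                   inputs = inputs,
                   config = list(minTissues = minTissues))
  invisible(summary)
}

#' Generate a synthetic bundle from a config file
#'
#' @param configFile flat key:value config (see [readSimulationConfig()]),
#'   or \code{NULL} for the defaults.
#' @param outputDir output directory.
#' @param seed optional seed overriding the config's.
#' @return Invisibly, the list of written file paths.
#' @export
runSimulate <- function(configFile = NULL, outputDir, seed = NULL) {
  config <- if (is.null(configFile)) simulationConfig()
            else readSimulationConfig(configFile)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  writeSimulatedBundle(config, outputDir)
}

#' Report the cassette and its three-frame translations
#'
#' Prints the bundled 158 bp acceptor and 115 bp retained insert in FASTA
#' form, followed by the insert's translation in each start phase with any
#' in-frame stop coordinates — the quick reference for interpreting a
#' phase-pair classification.
#'
#' @param cassette an [En2Cassette-class].
#' @return Invisibly, the list of the three \code{TranslationResult}s.
#' @export
cassetteReport <- function(cassette = en2Cassette()) {
  wrap <- function(s) gsub("(.{60})", "\\1\n", s)
  cat(">En2_splice_acceptor_full length=158\n",
      wrap(as.character(fullSequence(cassette))), "\n", sep = "")
  cat(">En2_retained_insert length=115\n",
      wrap(as.character(insertSequence(cassette))), "\n", sep = "")
  res <- lapply(0:2, function(p) translateInsert(cassette, p))
  for (r in res) print(r)
  invisible(res)
}
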