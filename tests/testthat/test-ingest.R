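test_that("exon tables parse identically across dialects and separators", {
  exons <- toyExons()
  tsv <- writeExonFile(exons)
  parsedTsv <- parseExonTable(tsv)
  expect_identical(nrow(parsedTsv), nrow(exons))
  expect_identical(parsedTsv$start_phase, exons$start_phase)
  expect_identical(parsedTsv$rank, exons$rank)

  # comma twin with BioMart headers
  bm <- exons
  names(bm) <- c("Gene stable ID", "Transcript stable ID", "Exon stable ID",
                 "Exon rank in transcript", "Start phase", "End phase",
                 "Exon length")
  csv <- writeExonFile(bm, tempfile(fileext = ".csv"), sep = ",")
  parsedCsv <- parseExonTable(csv, dialect = "biomart")
  expect_identical(parsedCsv[.mandatoryCols <- c("gene_id", "exon_id", "rank",
                                                 "start_phase", "end_phase")],
                   parsedTsv[.mandatoryCols])

  # custom headers via a column map
  odd <- exons
  names(odd)[names(odd) == "start_phase"] <- "phase at 5' end"
  csv2 <- writeExonFile(odd, tempfile(fileext = ".csv"), sep = ",")
  parsed2 <- parseExonTable(csv2,
                            columnMap = c(start_phase = "phase at 5' end"))
  expect_identical(parsed2$start_phase, parsedTsv$start_phase)
})

test_that("invalid rows are rejected with bookkeeping, bad tables error", {
  exons <- toyExons()
  exons$start_phase[4L] <- 3L  # out of the phase domain
  path <- writeExonFile(exons)
  # dropping G2's rank-1 exon also (correctly) warns about contiguity
  expect_message(suppressWarnings(parsed <- parseExonTable(path)),
                 "rejected 1 row")
  expect_identical(attr(parsed, "rejected"), 4L)
  expect_identical(nrow(parsed), nrow(exons) - 1L)

  dup <- toyExons()
  dup$rank[2L] <- 1L
  expect_error(suppressWarnings(parseExonTable(writeExonFile(dup))),
               "duplicate")

  noCol <- toyExons()
  noCol$end_phase <- NULL
  expect_error(parseExonTable(writeExonFile(noCol)), "end_phase")
})

test_that("column maps load from key:value files", {
  mapFile <- tempfile()
  writeLines(c("# comment", "start_phase: phase at 5' end",
               "end_phase: phase at 3' end"), mapFile)
  map <- readColumnMap(mapFile)
  expect_identical(unname(map["start_phase"]), "phase at 5' end")
  expect_identical(length(map), 2L)
})

test_that("critical phase resolution uses first-start/last-end over the block", {
  exons <- toyExons()
  one <- resolveCriticalPhases("G1.E2", exons)
  expect_identical(c(one$start_phase, one$end_phase), c(0L, 1L))
  # consecutive two-exon block: start of first, end of last
  two <- resolveCriticalPhases(c("G2.E2", "G2.E3"), exons)
  expect_identical(c(two$start_phase, two$end_phase), c(1L, 2L))
  # unknown exon id: no phase information, design must be skipped
  expect_null(resolveCriticalPhases("G9.E1", exons))
  # non-consecutive ranks are a design error, not a skip
  expect_error(resolveCriticalPhases(c("G2.E2", "G2.E4"), exons),
               "consecutive")
})

test_that("duplicated exon ids across transcripts break ties lexicographically", {
  exons <- toyExons()
  dupTx <- exons[exons$gene_id == "G1", ]
  dupTx$transcript_id <- "G1.T0"
  exons2 <- rbind(exons, dupTx)
  expect_warning(res <- resolveCriticalPhases("G1.E2", exons2),
                 "several transcripts")
  expect_identical(res$transcript_id, "G1.T0")
  # the design's named transcript wins without a warning
  expect_silent(res2 <- resolveCriticalPhases("G1.E2", exons2,
                                              transcriptId = "G1.T1"))
  expect_identical(res2$transcript_id, "G1.T1")
})

test_that("bulk prediction partitions designs and honours allele modes", {
  exons <- toyExons()
  designs <- toyDesigns()
  pred <- predictAll(designs, exons)
  expect_identical(nrow(pred), 3L)
  # tm1b -> REPLACES, tm1a -> BEFORE
  expect_identical(pred$mode[pred$design_id == "D1"], "REPLACES")
  expect_identical(pred$mode[pred$design_id == "D2"], "BEFORE")
  # G1.E2 (0,1) replaced: readthrough; G2 block (1,2) before: frameshift;
  # G3.E2 (2,0) replaced: stop in insert
  expect_identical(as.character(pred$category[order(pred$design_id)]),
                   c("READTHROUGH", "FRAMESHIFT", "STOP_IN_INSERT"))
  expect_identical(sum(categoryTotals(pred)), nrow(pred))

  # forced REPLACES mode overrides the class mapping
  predR <- predictAll(designs, exons, mode = "REPLACES")
  expect_identical(as.character(predR$category[predR$design_id == "D2"]),
                   "READTHROUGH")  # (1,2) matches the insert's end phase

  # both modes emit two predictions per design
  predB <- predictAll(designs, exons, bothModes = TRUE)
  expect_identical(nrow(predB), 6L)
  expect_identical(sort(unique(predB$mode)), c("BEFORE", "REPLACES"))
})

test_that("unresolvable designs are tallied, not silently dropped", {
  exons <- toyExons()
  designs <- toyDesigns()
  designs$critical_exon_ids[[2L]] <- "MISSING.E1"
  pred <- predictAll(designs, exons)
  expect_identical(nrow(pred), 2L)
  skipped <- attr(pred, "skipped")
  expect_identical(skipped$design_id, "D2")
  expect_identical(skipped$reason, "no phase information")

  empty <- designs[0L, ]
  predE <- predictAll(empty, exons)
  expect_identical(nrow(predE), 0L)
  expect_identical(unname(c(categoryTotals(predE))), rep(0L, 4L))
})

test_that("design tables round-trip through CSV including exon lists", {
  path <- writeDesignFile(toyDesigns())
  parsed <- parseDesignTable(path)
  expect_identical(parsed$allele_class,
                   c("LACZ_DELETION", "KNOCKOUT_FIRST", "LACZ_DELETION"))
  expect_identical(parsed$critical_exon_ids[[2L]], c("G2.E2", "G2.E3"))
  # tm-codes embedded in full allele symbols normalise too
  d <- toyDesigns()
  d$allele_class <- c("Abc<tm2b(KOMP)Wtsi>", "TARGETED_NONCOND", "tm1e")
  parsed2 <- parseDesignTable(writeDesignFile(d))
  expect_identical(parsed2$allele_class,
                   c("LACZ_DELETION", "TARGETED_NONCOND", "TARGETED_NONCOND"))
})

test_that("genes spanning several categories are flagged once", {
  pred <- makePredictions(
    gene_id = c("GA", "GA", "GB", "GB", "GC", "GC", "GC"),
    category = c("READTHROUGH", "FRAMESHIFT",
                 "FRAMESHIFT", "FRAMESHIFT",
                 "READTHROUGH", "FRAMESHIFT", "STOP_IN_INSERT"))
  expect_identical(sort(multiCategoryGenes(pred)), c("GA", "GC"))
})

test_that("prediction outputs serialise with category totals", {
  exons <- toyExons()
  pred <- predictAll(toyDesigns(), exons)
  csv <- tempfile(fileext = ".csv")
  json <- tempfile(fileext = ".json")
  s <- writePredictions(pred, csv, json)
  back <- read.csv(csv)
  expect_identical(nrow(back), nrow(pred))
  expect_identical(sort(names(s)),
                   sort(c("n_designs", "category_totals",
                          "multi_category_genes", "genes_per_category",
                          "n_skipped")))
  parsed <- jsonlite::read_json(json)
  expect_equal(parsed$n_designs, 3L)
})
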