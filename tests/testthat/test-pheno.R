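writePhenoCsv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

test_that("phenotype rows group per line with term-set union", {
  df <- data.frame(
    gene_id = c("G1", "G1", "G2"),
    line_id = c("L1", "L1", "L2"),
    allele_symbol = c("G1<tm1a(EUCOMM)Wtsi>", "G1<tm1a(EUCOMM)Wtsi>",
                      "G2<tm1b(KOMP)Wtsi>"),
    mp_term_id = c("MP:1", "MP:2", ""),
    mp_term_name = c("abnormal gait", "decreased body weight", ""),
    stringsAsFactors = FALSE)
  ph <- parsePhenotypeCsv(writePhenoCsv(df))
  expect_identical(nrow(ph), 2L)
  l1 <- ph[ph$line_id == "L1", ]
  expect_identical(l1$n_terms, 2L)
  expect_setequal(l1$mp_term_names[[1L]],
                  c("abnormal gait", "decreased body weight"))
  # empty hit field: a tested line with zero significant phenotypes
  expect_identical(ph$n_terms[ph$line_id == "L2"], 0L)

  # the same line split across rows with a repeated term keeps it once
  df2 <- rbind(df, df[1L, ])
  ph2 <- parsePhenotypeCsv(writePhenoCsv(df2))
  expect_identical(ph2$n_terms[ph2$line_id == "L1"], 2L)

  # delimited layout is equivalent to the long layout
  df3 <- data.frame(
    gene_id = "G1", line_id = "L1",
    allele_symbol = "G1<tm1a(EUCOMM)Wtsi>",
    mp_term_name = "abnormal gait; decreased body weight",
    stringsAsFactors = FALSE)
  ph3 <- parsePhenotypeCsv(writePhenoCsv(df3))
  expect_identical(ph3$n_terms, 2L)

  # IMPC-style headers are recognised without a map
  df4 <- df
  names(df4) <- c("Gene Accession Id", "Colony Id", "Allele Symbol",
                  "MP Term Id", "MP Term Name")
  ph4 <- parsePhenotypeCsv(writePhenoCsv(df4))
  expect_identical(ph4$n_terms, ph$n_terms)
})

test_that("allele symbols map to the two aggregation groups", {
  expect_identical(alleleGroupOf("Xyz<tm1a(EUCOMM)Wtsi>"),
                   "KO_FIRST_AND_NONCOND")
  expect_identical(alleleGroupOf("Xyz<tm2a(KOMP)Mbp>"), "KO_FIRST_AND_NONCOND")
  expect_identical(alleleGroupOf("Xyz<tm1e(EUCOMM)Wtsi>"),
                   "KO_FIRST_AND_NONCOND")
  expect_identical(alleleGroupOf("Xyz<tm2b(KOMP)>"), "LACZ_DELETION")
  # conditional alleles rescue gene function: excluded from the audit
  expect_identical(alleleGroupOf("Xyz<tm1c>"), NA_character_)
  expect_identical(alleleGroupOf("no-code-here"), NA_character_)
  expect_identical(alleleGroupOf(c("a<tm1a>", "b<tm1b>", "c<tm1c>")),
                   c("KO_FIRST_AND_NONCOND", "LACZ_DELETION", NA))
})

test_that("lethality terms match by case-insensitive substring or id list", {
  expect_true(isLethal("preweaning lethality, complete penetrance"))
  expect_true(isLethal("embryonic lethality prior to organogenesis"))
  expect_true(isLethal("Postnatal LETHALITY"))
  expect_false(isLethal("increased circulating glucose level"))
  expect_identical(isLethal(c("x lethal y", "z")), c(TRUE, FALSE))
  expect_identical(
    isLethal(c("anything", "else"), mpTermId = c("MP:1", "MP:2"),
             idAllowlist = "MP:2"),
    c(FALSE, TRUE))
})

test_that("category summaries compute the per-line metrics", {
  pred <- makePredictions(gene_id = c("G1", "G2", "G3"),
                          category = c("READTHROUGH", "READTHROUGH",
                                       "FRAMESHIFT"))
  ph <- makePhenotypeLines(
    gene_id = c("G1", "G2"),
    line_id = c("L1", "L2"),
    allele_symbol = c("G1<tm1b(KOMP)>", "G2<tm1b(KOMP)>"),
    n_terms = c(4L, 2L))
  s <- summarizeCategories(pred, ph)
  row <- s[s$category == "READTHROUGH" & s$allele_group == "LACZ_DELETION", ]
  expect_identical(row$lines_tested, 2L)
  expect_identical(row$phenotypes_per_line, 3.0)
  expect_identical(row$lines_lethal, 0L)
  expect_identical(row$lines_no_phenotype, 0L)
  expect_identical(row$genes_total, 2L)
  expect_identical(row$genes_untested, 0L)
  # the frameshift gene has no phenotype rows at all
  fs <- s[s$category == "FRAMESHIFT" & s$allele_group == "LACZ_DELETION", ]
  expect_identical(fs$genes_untested, 1L)
  expect_identical(fs$lines_tested, 0L)
  expect_true(is.nan(fs$phenotypes_per_line))
})

test_that("no-phenotype and phenotyped lines partition the tested lines", {
  set.seed(7)
  genes <- sprintf("G%02d", 1:30)
  pred <- makePredictions(genes,
                          sample(c("READTHROUGH", "FRAMESHIFT",
                                   "STOP_IN_INSERT"), 30L, replace = TRUE))
  nT <- rpois(30L, 3L)
  ph <- makePhenotypeLines(
    gene_id = genes, line_id = sprintf("L%02d", 1:30),
    allele_symbol = sprintf("%s<tm1%s(EUCOMM)>", genes,
                            sample(c("a", "b", "e"), 30L, replace = TRUE)),
    n_terms = nT, n_lethal_terms = as.integer(nT > 0L & runif(30L) < 0.3))
  s <- summarizeCategories(pred, ph)
  withLines <- s[s$lines_tested > 0L, ]
  linesWithHits <- vapply(seq_len(nrow(withLines)), function(i) {
    r <- withLines[i, ]
    sub <- ph[ph$gene_id %in% pred$gene_id[as.character(pred$category) ==
                                             r$category] &
                ph$allele_group == r$allele_group, ]
    sum(sub$n_terms > 0L)
  }, integer(1L))
  expect_identical(withLines$lines_tested - withLines$lines_no_phenotype,
                   linesWithHits)
  expect_true(all(withLines$lines_lethal <= withLines$lines_tested))
  long <- summaryLong(s)
  pct <- long$value[grepl("_pct$", long$metric) & !is.nan(long$value)]
  expect_true(all(pct >= 0 & pct <= 100))
})

test_that("multi-category genes vanish from every summary row", {
  pred <- makePredictions(gene_id = c("G1", "G2", "G3"),
                          category = c("READTHROUGH", "FRAMESHIFT",
                                       "FRAMESHIFT"))
  ph <- makePhenotypeLines(
    gene_id = c("G1", "G2", "G3"),
    line_id = c("L1", "L2", "L3"),
    allele_symbol = c("G1<tm1b>", "G2<tm1b>", "G3<tm1b>"),
    n_terms = c(1L, 5L, 2L))
  before <- summarizeCategories(pred, ph)
  # a second G2 design in a new category makes G2 multi-category
  pred2 <- rbind(pred, makePredictions("G2", "READTHROUGH", "D9"))
  after <- summarizeCategories(pred2, ph)
  expect_identical(multiCategoryGenes(pred2), "G2")
  # G2's line is gone from every row
  fsRow <- after[after$category == "FRAMESHIFT" &
                   after$allele_group == "LACZ_DELETION", ]
  expect_identical(fsRow$lines_tested, 1L)
  expect_identical(fsRow$phenotypes_per_line, 2.0)
  # G1 and G3 numbers are untouched
  rtBefore <- before[before$category == "READTHROUGH" &
                       before$allele_group == "LACZ_DELETION", ]
  rtAfter <- after[after$category == "READTHROUGH" &
                     after$allele_group == "LACZ_DELETION", ]
  expect_identical(rtAfter$lines_tested, rtBefore$lines_tested)
  expect_identical(rtAfter$phenotypes_per_line, rtBefore$phenotypes_per_line)
})

test_that("lacZ silence needs full negativity over enough tissues", {
  mk <- function(gene, n, expressed) {
    data.frame(gene_id = gene, tissue = sprintf("tissue %02d", seq_len(n)),
               expressed = expressed, stringsAsFactors = FALSE)
  }
  lacz <- rbind(
    mk("G.allneg30", 30L, FALSE),
    mk("G.allneg27", 27L, FALSE),
    mk("G.allneg10", 10L, FALSE),                      # too few tissues
    mk("G.onepos", 30L, c(rep(FALSE, 29L), TRUE)))     # one positive call
  expect_setequal(laczSilentGenes(lacz), c("G.allneg30", "G.allneg27"))
  expect_identical(laczSilentGenes(lacz, minTissues = 5L),
                   c("G.allneg10", "G.allneg27", "G.allneg30"))
  expect_identical(laczSilentGenes(lacz[0L, ]), character())
})

test_that("lacZ parsing collapses duplicates and normalises calls", {
  df <- data.frame(
    gene_id = c("G1", "G1", "G1", "G2"),
    tissue = c("Brain", " brain", "liver", "brain"),
    expressed = c("no expression", "expression", "FALSE", "0"),
    stringsAsFactors = FALSE)
  lz <- parseLaczCsv(writePhenoCsv(df))
  expect_identical(nrow(lz), 3L)  # Brain/" brain" collapse, OR -> TRUE
  expect_true(lz$expressed[lz$gene_id == "G1" & lz$tissue == "brain"])
  expect_false(lz$expressed[lz$gene_id == "G2" & lz$tissue == "brain"])
})
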