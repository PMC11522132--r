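# Small in-code fixtures shared across test files.

# three-gene exon table covering negative UTR phases and a two-exon block
toyExons <- function() {
  data.frame(
    gene_id = c(rep("G1", 3L), rep("G2", 4L), rep("G3", 3L)),
    transcript_id = c(rep("G1.T1", 3L), rep("G2.T1", 4L), rep("G3.T1", 3L)),
    exon_id = c("G1.E1", "G1.E2", "G1.E3",
                "G2.E1", "G2.E2", "G2.E3", "G2.E4",
                "G3.E1", "G3.E2", "G3.E3"),
    rank = c(1:3, 1:4, 1:3),
    start_phase = c(-1L, 0L, 1L, -1L, 1L, 0L, 2L, -1L, 2L, 0L),
    end_phase = c(0L, 1L, -1L, 1L, 0L, 2L, -1L, 2L, 0L, -1L),
    length_bp = c(120L, 100L, 80L, 90L, 101L, 110L, 75L, 60L, 103L, 50L),
    stringsAsFactors = FALSE)
}

writeExonFile <- function(exons, path = tempfile(fileext = ".tsv"),
                          sep = "\t") {
  write.table(exons, path, sep = sep, row.names = FALSE, quote = TRUE)
  path
}

toyDesigns <- function() {
  d <- data.frame(
    design_id = c("D1", "D2", "D3"),
    gene_id = c("G1", "G2", "G3"),
    allele_class = c("tm1b", "tm1a", "tm1b"),
    transcript_id = c("G1.T1", "G2.T1", "G3.T1"),
    stringsAsFactors = FALSE)
  d$critical_exon_ids <- list("G1.E2", c("G2.E2", "G2.E3"), "G3.E2")
  d
}

writeDesignFile <- function(designs, path = tempfile(fileext = ".csv")) {
  d <- designs
  d$critical_exon_ids <- vapply(d$critical_exon_ids, paste, character(1L),
                                collapse = ";")
  write.csv(d, path, row.names = FALSE)
  path
}

# minimal per-line phenotype table in the shape parsePhenotypeCsv() returns
makePhenotypeLines <- function(gene_id, line_id, allele_symbol, n_terms,
                               n_lethal_terms = 0L) {
  data.frame(gene_id = gene_id, line_id = line_id,
             allele_symbol = allele_symbol,
             allele_group = alleleGroupOf(allele_symbol),
             n_terms = as.integer(n_terms),
             n_lethal_terms = as.integer(n_lethal_terms),
             stringsAsFactors = FALSE)
}

# minimal predictions table in the shape predictAll() returns
makePredictions <- function(gene_id, category,
                            design_id = paste0("D", seq_along(gene_id))) {
  data.frame(design_id = design_id, gene_id = gene_id,
             allele_class = "LACZ_DELETION", mode = "REPLACES",
             start_phase = 0L, end_phase = 0L,
             category = factor(category, levels = outcomeCategories()),
             stringsAsFactors = FALSE)
}
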