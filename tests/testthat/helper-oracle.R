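# Independent brute-force oracles, deliberately not sharing code with the
# package: a hand-built standard codon table and a character-by-character
# translation scan.

oracleCodonTable <- local({
  b <- c("T", "C", "A", "G")
  codons <- paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L), rep(b, 16L))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1L]]
  stats::setNames(aa, codons)
})

# translate `dna` starting after `consumed` skipped bases, halting at the
# first stop codon; returns peptide, remainder and the stop's base range
oracleTranslate <- function(dna, consumed) {
  dna <- toupper(dna)
  pep <- character()
  i <- consumed + 1L
  stopStart <- NA_integer_
  while (i + 2L <= nchar(dna)) {
    codon <- substr(dna, i, i + 2L)
    aa <- oracleCodonTable[[codon]]
    pep <- c(pep, aa)
    if (aa == "*") {
      stopStart <- i
      break
    }
    i <- i + 3L
  }
  remainder <- if (is.na(stopStart)) substr(dna, i, nchar(dna)) else ""
  list(peptide = paste(pep, collapse = ""),
       remainder = tolower(remainder),
       stopStart = stopStart)
}

# all stop-codon start positions in the frame beginning at `first`
oracleStops <- function(dna, first) {
  dna <- toupper(dna)
  hits <- integer()
  for (i in seq.int(first, nchar(dna) - 2L, by = 3L)) {
    if (oracleCodonTable[[substr(dna, i, i + 2L)]] == "*")
      hits <- c(hits, i)
  }
  hits
}
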