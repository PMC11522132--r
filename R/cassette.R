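#' @import methods
#' @importFrom Biostrings DNAString readDNAStringSet
NULL

# Sequences printed in the package FASTA (inst/extdata/en2_splice_acceptor.fasta).
# The retained insert is the prefix of the full acceptor ending at the "ag" of
# the cryptic "aggt" splice donor.
.EN2_FULL <- paste0(
  "gtcccaggtcccgaaaaccaaagaagaagaaccctaacaaagaggacaagcggcctcgca",
  "cagccttcactgctgagcagctccagaggctcaaggctgagtttcagaccaacaggtacc",
  "tgacagagcagcggcgccagagtctggcacaggagctc"
)
.EN2_INSERT <- substr(.EN2_FULL, 1L, 115L)

.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' En2 splice-acceptor cassette
#'
#' Immutable record of the En2 splice-acceptor sequence used in IKMC
#' knockout-first cassettes: the full 158 bp acceptor, the 115 bp fragment
#' retained in mutant transcripts when the cryptic splice donor inside the
#' acceptor is used, and the 1-based position of the "aggt" donor motif whose
#' "ag" terminates the retained insert.
#'
#' @slot fullSequence [Biostrings::DNAString] of length 158.
#' @slot insertSequence [Biostrings::DNAString] of length 115; the prefix of
#'   \code{fullSequence} ending at the cryptic donor "ag".
#' @slot crypticDonorStart integer, 1-based start of the "aggt" motif on the
#'   full sequence (114).
#'
#' @seealso [en2Cassette()] for the bundled default instance.
#' @exportClass En2Cassette
setClass("En2Cassette",
  representation(
    fullSequence = "DNAString",
    insertSequence = "DNAString",
    crypticDonorStart = "integer"
  )
)

setValidity("En2Cassette", function(object) {
  full <- tolower(as.character(object@fullSequence))
  ins <- tolower(as.character(object@insertSequence))
  msg <- character()
  if (nchar(full) != 158L)
    msg <- c(msg, "full sequence must be 158 bases")
  if (nchar(ins) != 115L)
    msg <- c(msg, "insert sequence must be 115 bases")
  if (substr(full, 1L, nchar(ins)) != ins)
    msg <- c(msg, "insert must be a prefix of the full sequence")
  ds <- object@crypticDonorStart
  if (length(ds) != 1L || is.na(ds))
    msg <- c(msg, "crypticDonorStart must be a single integer")
  else {
    if (substr(full, ds, ds + 3L) != "aggt")
      msg <- c(msg, "cryptic donor motif 'aggt' not found at crypticDonorStart")
    if (ds + 1L != nchar(ins))
      msg <- c(msg, "insert must end at the 'ag' of the cryptic donor")
  }
  if (!grepl("ag$", ins))
    msg <- c(msg, "insert must end with 'ag'")
  if (length(msg)) msg else TRUE
})

#' Construct the En2 cassette record
#'
#' With no arguments, returns the bundled cassette (the sequences shipped in
#' \code{inst/extdata/en2_splice_acceptor.fasta}). Custom sequences may be
#' supplied for testing; they must satisfy the class invariants (158/115 bp,
#' prefix relationship, "aggt" donor at the insert boundary).
#'
#' @param fullSequence character or DNAString, the full splice acceptor.
#' @param insertSequence character or DNAString, the retained insert.
#' @param crypticDonorStart 1-based start of the "aggt" donor on the full
#'   sequence.
#' @return An [En2Cassette-class] object.
#' @examples
#' cas <- en2Cassette()
#' length(insertSequence(cas))  # 115
#' @export
en2Cassette <- function(fullSequence = .EN2_FULL,
                        insertSequence = .EN2_INSERT,
                        crypticDonorStart = 114L) {
  new("En2Cassette",
    fullSequence = Biostrings::DNAString(tolower(as.character(fullSequence))),
    insertSequence = Biostrings::DNAString(tolower(as.character(insertSequence))),
    crypticDonorStart = as.integer(crypticDonorStart)
  )
}

#' Read the bundled cassette FASTA
#'
#' Loads the two-record FASTA shipped with the package (full 158 bp acceptor
#' and 115 bp retained insert) and returns it as an [En2Cassette-class],
#' verifying the class invariants on the way in.
#'
#' @param path path to a two-record FASTA; defaults to the bundled file.
#' @return An [En2Cassette-class] object.
#' @export
readEn2Cassette <- function(path = system.file("extdata",
                                               "en2_splice_acceptor.fasta",
                                               package = "en2splice")) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 2L)
    stop("expected a two-record FASTA (full acceptor, retained insert)")
  en2Cassette(fullSequence = as.character(seqs[[1L]]),
              insertSequence = as.character(seqs[[2L]]))
}

#' @describeIn en2Cassette Accessor for the full 158 bp acceptor sequence.
#' @param x an \code{En2Cassette}.
#' @export
fullSequence <- function(x) x@fullSequence

#' @describeIn en2Cassette Accessor for the 115 bp retained insert.
#' @export
insertSequence <- function(x) x@insertSequence

#' @describeIn en2Cassette Accessor for the 1-based "aggt" donor position.
#' @export
crypticDonorStart <- function(x) x@crypticDonorStart

setMethod("show", "En2Cassette", function(object) {
  ins <- as.character(object@insertSequence)
  cat("En2 splice-acceptor cassette\n")
  cat("  full acceptor : ", length(object@fullSequence), " bp\n", sep = "")
  cat("  retained insert: ", length(object@insertSequence),
      " bp (115 mod 3 = ", length(object@insertSequence) %% 3L, ")\n", sep = "")
  cat("  cryptic donor 'aggt' at ", object@crypticDonorStart, "-",
      object@crypticDonorStart + 3L, "\n", sep = "")
  cat("  insert ends   : ...", substr(ins, nchar(ins) - 7L, nchar(ins)), "\n",
      sep = "")
})

# lowercase character view of the insert, used by the frame/translation code
.insertChar <- function(cassette) tolower(as.character(cassette@insertSequence))
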