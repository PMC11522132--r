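#' @importFrom Biostrings translate
NULL

# bases of the insert consumed to complete the codon split across the
# upstream junction: phase 0 -> 0, phase 1 -> 2, phase 2 -> 1
.consumedBases <- function(startPhase) c(0L, 2L, 1L)[startPhase + 1L]

#' Translate the retained En2 insert in a given reading frame
#'
#' Translates the 115 bp retained insert as it would be read when spliced
#' into a transcript whose critical exon starts in \code{startPhase}. Under
#' the Ensembl phase convention the previous exon contributes
#' \code{startPhase} bases of the junction codon, so the first
#' 0 / 2 / 1 bases of the insert (phases 0 / 1 / 2) complete that codon and
#' cannot be translated without the upstream sequence; they are returned as
#' \code{consumedPrefix}. Translation then scans full codons left to right
#' with the standard nuclear genetic code and halts at the first stop codon.
#'
#' @param cassette an [En2Cassette-class]; defaults to the bundled cassette.
#' @param startPhase integer in \{0, 1, 2\}.
#' @return A list of class \code{"TranslationResult"} with elements
#'   \describe{
#'     \item{startPhase}{the frame used}
#'     \item{consumedPrefix}{0-2 bases completing the upstream codon}
#'     \item{peptide}{one-letter amino acids; a stop, if reached, is the
#'       final \code{"*"}}
#'     \item{remainder}{0-2 leftover bases after the last full codon
#'       (empty when translation halted at a stop)}
#'     \item{stopStart, stopEnd}{1-based inclusive coordinates of the first
#'       in-frame stop codon on the insert, or \code{NA} if none}
#'   }
#' @examples
#' translateInsert(startPhase = 2)$peptide  # "SQVPKTKEEEP*"
#' @export
translateInsert <- function(cassette = en2Cassette(), startPhase) {
  startPhase <- .checkPhase(startPhase, allowNegative = FALSE, "start phase")
  stopifnot(length(startPhase) == 1L)
  ins <- .insertChar(cassette)
  if (grepl("[^acgt]", ins))
    stop("insert sequence contains non-ACGT characters")
  n <- nchar(ins)
  consumed <- .consumedBases(startPhase)
  body <- substr(ins, consumed + 1L, n)
  nCodon <- nchar(body) %/% 3L
  codonEnd <- consumed + nCodon * 3L
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(toupper(substr(ins, consumed + 1L, codonEnd)))))
  stopAt <- regexpr("*", aa, fixed = TRUE)
  if (stopAt > 0L) {
    peptide <- substr(aa, 1L, stopAt)
    stopStart <- consumed + (stopAt - 1L) * 3L + 1L
    stopEnd <- stopStart + 2L
    remainder <- ""
  } else {
    peptide <- aa
    stopStart <- NA_integer_
    stopEnd <- NA_integer_
    remainder <- substr(ins, codonEnd + 1L, n)
  }
  structure(
    list(startPhase = startPhase,
         consumedPrefix = substr(ins, 1L, consumed),
         peptide = peptide,
         remainder = remainder,
         stopStart = as.integer(stopStart),
         stopEnd = as.integer(stopEnd)),
    class = "TranslationResult"
  )
}

#' @export
print.TranslationResult <- function(x, ...) {
  pre <- if (nzchar(x$consumedPrefix)) paste0("(", x$consumedPrefix, ")") else ""
  post <- if (nzchar(x$remainder)) paste0("(", x$remainder, ")") else ""
  cat(sprintf("phase %d: %s%s%s\n", x$startPhase, pre, x$peptide, post))
  if (!is.na(x$stopStart))
    cat(sprintf("  first in-frame stop at insert bases %d-%d\n",
                x$stopStart, x$stopEnd))
  invisible(x)
}

#' Display string for a translated frame
#'
#' Table-style rendering of a [translateInsert()] result: untranslatable
#' partial codons in lowercase brackets, amino acids in one-letter code,
#' a stop as \code{"*"}. E.g. \code{"(gt)PRSRK...QTN(ag)"}.
#'
#' @param result a \code{TranslationResult}.
#' @return A single character string.
#' @export
formatTranslation <- function(result) {
  pre <- if (nzchar(result$consumedPrefix))
    paste0("(", result$consumedPrefix, ")") else ""
  post <- if (nzchar(result$remainder))
    paste0("(", result$remainder, ")") else ""
  paste0(pre, result$peptide, post)
}

#' Stop codon straddling the upstream junction
#'
#' When the insertion point falls inside a codon, the last bases of the
#' upstream exon combine with the first bases of the insert. This checks
#' whether that split codon is a stop. With this insert (which starts
#' "gt..."), only a phase-2 junction whose upstream exon ends in "ta" can
#' produce one ("ta" + "g" = TAG); a single upstream base ("t" + "gt" = TGT)
#' or a phase-0 junction (no split codon) never can.
#'
#' @param upstreamSuffix 0-2 bases of the upstream exon belonging to the
#'   split codon; its length is the start phase of the insertion site.
#' @param cassette an [En2Cassette-class].
#' @return \code{TRUE} iff the junction codon is a stop (TAA/TAG/TGA).
#' @examples
#' boundaryStopCheck("ta")  # TRUE: TA + G -> TAG
#' @export
boundaryStopCheck <- function(upstreamSuffix, cassette = en2Cassette()) {
  upstreamSuffix <- tolower(as.character(upstreamSuffix))
  stopifnot(length(upstreamSuffix) == 1L)
  k <- nchar(upstreamSuffix)
  if (k > 2L)
    stop("upstream suffix must be 0-2 bases (the start phase of the junction)")
  if (k == 0L)
    return(FALSE)
  if (grepl("[^acgt]", upstreamSuffix))
    stop("upstream suffix contains non-ACGT characters")
  codon <- toupper(paste0(upstreamSuffix, substr(.insertChar(cassette), 1L, 3L - k)))
  codon %in% .STOP_CODONS
}

#' Scan a reading frame of the insert for stop codons
#'
#' Utility used by tests and the cassette report: positions of every stop
#' codon in the frame beginning after the consumed prefix of a phase.
#'
#' @param cassette an [En2Cassette-class].
#' @param startPhase integer in \{0, 1, 2\}.
#' @return Integer vector of 1-based stop-codon start positions (possibly
#'   empty).
#' @export
scanFrameStops <- function(cassette = en2Cassette(), startPhase) {
  startPhase <- .checkPhase(startPhase, allowNegative = FALSE, "start phase")
  ins <- toupper(.insertChar(cassette))
  first <- .consumedBases(startPhase) + 1L
  starts <- seq.int(first, nchar(ins) - 2L, by = 3L)
  codons <- substring(ins, starts, starts + 2L)
  starts[codons %in% .STOP_CODONS]
}
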