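#' Outcome categories
#'
#' The four predicted transcription outcomes for a critical exon affected by
#' the retained En2 insert, in the package's canonical order. STOP_IN_INSERT
#' is the "En2-induced stop codon" outcome: the insert read in the phase-2
#' frame contains an in-frame TAA.
#'
#' @return Character vector of the four category labels.
#' @export
outcomeCategories <- function() {
  c("READTHROUGH", "FRAMESHIFT", "STOP_IN_INSERT", "OTHER")
}

# factor with the canonical category levels
.asOutcome <- function(x) factor(x, levels = outcomeCategories())

.checkPhase <- function(phase, allowNegative = FALSE, what = "phase") {
  ok <- if (allowNegative) c(-1L, 0L, 1L, 2L) else c(0L, 1L, 2L)
  phase <- as.integer(phase)
  bad <- is.na(phase) | !(phase %in% ok)
  if (any(bad))
    stop(sprintf("%s must be in {%s}; got: %s", what,
                 paste(ok, collapse = ","),
                 paste(unique(phase[bad]), collapse = ",")))
  phase
}

#' Validate a (start, end) phase pair
#'
#' Exon phases follow the Ensembl convention: the start phase of an exon is
#' the number of bases of the split codon contributed by the \emph{previous}
#' exon (so the end phase of one exon equals the start phase of the next);
#' -1 marks an exon/intron boundary lying in non-coding sequence.
#'
#' @param startPhase,endPhase integers in \{-1, 0, 1, 2\} (vectorised).
#' @return Invisibly, a two-column integer matrix of validated phases.
#' @export
phasePair <- function(startPhase, endPhase) {
  startPhase <- .checkPhase(startPhase, allowNegative = TRUE, "start phase")
  endPhase <- .checkPhase(endPhase, allowNegative = TRUE, "end phase")
  if (length(startPhase) != length(endPhase))
    stop("start and end phase vectors must have equal length")
  invisible(cbind(start_phase = startPhase, end_phase = endPhase))
}

#' Phase after reading through a coding stretch
#'
#' The end phase of a fully coding exon (or any coding stretch) of length
#' \code{lengthBp} entered at \code{startPhase}: \code{(start + length) mod 3}.
#' This is the chain rule that makes exon phases compose along a transcript.
#' Negative (non-coding) phases never enter frame arithmetic and are rejected.
#'
#' @param startPhase integer in \{0, 1, 2\} (vectorised).
#' @param lengthBp positive integer length in bases (vectorised).
#' @return Integer end phase in \{0, 1, 2\}.
#' @examples
#' endPhaseAfter(0, 115)  # 1: the insert shifts phase 0 to phase 1
#' @export
endPhaseAfter <- function(startPhase, lengthBp) {
  startPhase <- .checkPhase(startPhase, allowNegative = FALSE, "start phase")
  lengthBp <- as.integer(lengthBp)
  if (any(is.na(lengthBp) | lengthBp < 1L))
    stop("lengthBp must be a positive integer")
  (startPhase + lengthBp) %% 3L
}
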