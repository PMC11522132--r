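#' Classify a critical exon replaced by the En2 insert
#'
#' Outcome when the retained insert takes the place of the critical exon
#' (lacZ-tagged deletion alleles, and occasionally knockout-first alleles).
#' An exon entered in phase 2 reads the insert in the frame containing the
#' internal TAA, so the outcome is an En2-induced stop regardless of end
#' phase. Otherwise the insert permits readthrough exactly when the exon's
#' end phase matches the phase the 115 bp insert itself ends in,
#' \code{endPhaseAfter(start, 115)}; any mismatch is a frameshift.
#'
#' @param startPhase,endPhase integers in \{0, 1, 2\} (vectorised; negative
#'   phases are routed by [classifyDesign()]).
#' @param cassette an [En2Cassette-class]; supplies the insert length.
#' @return Factor with levels [outcomeCategories()].
#' @examples
#' classifyReplacement(0, 1)  # READTHROUGH
#' classifyReplacement(2, 0)  # STOP_IN_INSERT
#' @export
classifyReplacement <- function(startPhase, endPhase, cassette = en2Cassette()) {
  startPhase <- .checkPhase(startPhase, allowNegative = FALSE,
                            "start phase (negative phases: use classifyDesign)")
  endPhase <- .checkPhase(endPhase, allowNegative = FALSE,
                          "end phase (negative phases: use classifyDesign)")
  insLen <- length(insertSequence(cassette))
  out <- ifelse(startPhase == 2L, "STOP_IN_INSERT",
         ifelse(endPhase == endPhaseAfter(pmax(startPhase, 0L), insLen),
                "READTHROUGH", "FRAMESHIFT"))
  .asOutcome(out)
}

#' Classify an En2 insertion before the critical exon
#'
#' Outcome when the insert lands in the transcript immediately before an
#' intact critical exon (the usual knockout-first behaviour). Because
#' 115 is not a multiple of 3, insertion at a phase-0 or phase-1 junction
#' always shifts the downstream frame. At a phase-2 junction the insert is
#' read in the frame containing the internal TAA, terminating translation
#' inside the insert; \code{collapseStop = TRUE} folds that case into
#' FRAMESHIFT for callers who only care that the frame (or protein) is lost.
#'
#' @param startPhase integer in \{0, 1, 2\} (vectorised): the start phase of
#'   the critical exon, i.e. the phase at the insertion junction.
#' @param cassette an [En2Cassette-class].
#' @param collapseStop collapse phase-2 stops into FRAMESHIFT.
#' @return Factor with levels [outcomeCategories()].
#' @export
classifyInsertionBefore <- function(startPhase, cassette = en2Cassette(),
                                    collapseStop = FALSE) {
  startPhase <- .checkPhase(startPhase, allowNegative = FALSE, "start phase")
  out <- ifelse(startPhase == 2L & !collapseStop, "STOP_IN_INSERT", "FRAMESHIFT")
  .asOutcome(out)
}

#' Classify an allele design from its critical-exon phase pair
#'
#' Full classifier including the non-coding (-1) phases. In REPLACES mode,
#' exons starting in phase 2 but ending in a negative phase still read the
#' insert into the internal TAA, so they join the En2-induced-stop category;
#' every other design touching a negative phase goes to OTHER (the boundary
#' lies in untranslated sequence and frame arithmetic does not apply).
#' In BEFORE mode only the start phase matters; a negative start phase goes
#' to OTHER.
#'
#' @param startPhase,endPhase integers in \{-1, 0, 1, 2\} (vectorised).
#' @param mode \code{"REPLACES"} or \code{"BEFORE"} (recycled).
#' @param cassette an [En2Cassette-class].
#' @param collapseStop passed to [classifyInsertionBefore()].
#' @return Factor with levels [outcomeCategories()].
#' @examples
#' classifyDesign(2, -1, "REPLACES")  # STOP_IN_INSERT
#' classifyDesign(-1, 0, "REPLACES")  # OTHER
#' @export
classifyDesign <- function(startPhase, endPhase, mode = c("REPLACES", "BEFORE"),
                           cassette = en2Cassette(), collapseStop = FALSE) {
  startPhase <- .checkPhase(startPhase, allowNegative = TRUE, "start phase")
  endPhase <- .checkPhase(endPhase, allowNegative = TRUE, "end phase")
  n <- max(length(startPhase), length(endPhase))
  startPhase <- rep_len(startPhase, n)
  endPhase <- rep_len(endPhase, n)
  if (identical(mode, c("REPLACES", "BEFORE")))
    mode <- "REPLACES"
  if (!all(mode %in% c("REPLACES", "BEFORE")))
    stop("mode must be 'REPLACES' or 'BEFORE'")
  mode <- rep_len(mode, n)
  out <- character(n)

  isBefore <- mode == "BEFORE"
  # BEFORE: only the junction (start) phase matters
  bNeg <- isBefore & startPhase < 0L
  bOk <- isBefore & !bNeg
  out[bNeg] <- "OTHER"
  if (any(bOk))
    out[bOk] <- as.character(classifyInsertionBefore(startPhase[bOk],
                                                     cassette = cassette,
                                                     collapseStop = collapseStop))
  # REPLACES: phase-2 start with a negative end still hits the internal TAA
  rStop <- !isBefore & startPhase == 2L & endPhase < 0L
  rNeg <- !isBefore & !rStop & (startPhase < 0L | endPhase < 0L)
  rOk <- !isBefore & !rStop & !rNeg
  out[rStop] <- "STOP_IN_INSERT"
  out[rNeg] <- "OTHER"
  if (any(rOk))
    out[rOk] <- as.character(classifyReplacement(startPhase[rOk], endPhase[rOk],
                                                 cassette = cassette))
  .asOutcome(out)
}

#' Enumerate the nine non-negative phase combinations
#'
#' Convenience table of the classifier over all (start, end) pairs with both
#' phases in \{0, 1, 2\}, in REPLACES mode, together with the display form of
#' the translated insert for each start phase.
#'
#' @param cassette an [En2Cassette-class].
#' @return data.frame with columns \code{start_phase}, \code{end_phase},
#'   \code{category}, \code{translation}.
#' @export
phaseCombinationTable <- function(cassette = en2Cassette()) {
  grid <- expand.grid(end_phase = 0:2, start_phase = 0:2)[, 2:1]
  tr <- vapply(0:2, function(p)
    formatTranslation(translateInsert(cassette, p)), character(1L))
  data.frame(
    start_phase = grid$start_phase,
    end_phase = grid$end_phase,
    category = classifyReplacement(grid$start_phase, grid$end_phase,
                                   cassette = cassette),
    translation = tr[grid$start_phase + 1L],
    row.names = NULL
  )
}
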