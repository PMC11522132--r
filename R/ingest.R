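#' @importFrom utils read.csv read.delim write.csv
NULL

# canonical column names used internally
.EXON_COLS <- c("gene_id", "transcript_id", "exon_id", "rank",
                "start_phase", "end_phase", "length_bp")
.DESIGN_COLS <- c("design_id", "gene_id", "allele_class", "transcript_id",
                  "critical_exon_ids")

# BioMart attribute-header dialect for exon tables
.BIOMART_EXON_MAP <- c(
  gene_id = "Gene stable ID",
  transcript_id = "Transcript stable ID",
  exon_id = "Exon stable ID",
  rank = "Exon rank in transcript",
  start_phase = "Start phase",
  end_phase = "End phase",
  length_bp = "Exon length"
)

#' Read a column-name mapping file
#'
#' Flat \code{key: value} text file mapping the package's canonical column
#' names (e.g. \code{gene_id}) to the headers used in an input file. Lines
#' starting with \code{#} and blank lines are ignored.
#'
#' @param path path to the mapping file.
#' @return Named character vector (canonical name -> file header).
#' @export
readColumnMap <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!all(grepl(":", lines, fixed = TRUE)))
    stop("column map lines must be 'canonical: file header'")
  key <- trimws(sub(":.*$", "", lines))
  val <- trimws(sub("^[^:]*:", "", lines))
  stats::setNames(val, key)
}

# sniff separator from the first non-comment line
.sniffSep <- function(path) {
  con <- file(path, "r"); on.exit(close(con))
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) return(",")
    if (nzchar(ln) && !startsWith(ln, "#")) break
  }
  if (lengths(regmatches(ln, gregexpr("\t", ln))) > 0L) "\t" else ","
}

.readTable <- function(path, sep = NULL) {
  if (is.null(sep)) sep <- .sniffSep(path)
  utils::read.csv(path, sep = sep, check.names = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE)
}

# rename file columns to canonical names; error on missing mandatory columns
.applyColumnMap <- function(df, map, mandatory, what) {
  for (canon in names(map)) {
    src <- map[[canon]]
    if (src %in% names(df) && !(canon %in% names(df)))
      names(df)[names(df) == src] <- canon
  }
  missing <- setdiff(mandatory, names(df))
  if (length(missing))
    stop(sprintf("%s is missing mandatory column(s): %s", what,
                 paste(missing, collapse = ", ")))
  df
}

#' Parse an exon-phase table
#'
#' Reads a TSV/CSV exon table (one row per exon) into validated records.
#' The default dialect uses the canonical headers \code{gene_id,
#' transcript_id, exon_id, rank, start_phase, end_phase, length_bp};
#' \code{dialect = "biomart"} accepts the Ensembl BioMart attribute headers
#' ("Gene stable ID", "Exon rank in transcript", ...). A \code{columnMap}
#' (see [readColumnMap()]) overrides either. Phases must lie in
#' \{-1, 0, 1, 2\}; rows violating that (or with unparseable rank/length)
#' are rejected and reported with their line numbers via the
#' \code{"rejected"} attribute. Duplicate (transcript, rank) pairs are a
#' hard error.
#'
#' @param path path to the table; separator is sniffed (tab or comma).
#' @param dialect \code{"canonical"} or \code{"biomart"}.
#' @param columnMap optional named character vector, canonical -> header.
#' @param quiet suppress the rejected-row message.
#' @return data.frame of validated exon records (extra columns carried
#'   through untouched), with attribute \code{"rejected"} (integer row
#'   numbers of dropped rows, on the parsed table).
#' @export
parseExonTable <- function(path, dialect = c("canonical", "biomart"),
                           columnMap = NULL, quiet = FALSE) {
  dialect <- match.arg(dialect)
  df <- .readTable(path)
  map <- if (dialect == "biomart") .BIOMART_EXON_MAP else
    stats::setNames(.EXON_COLS, .EXON_COLS)
  if (!is.null(columnMap)) map[names(columnMap)] <- columnMap
  df <- .applyColumnMap(df, map, .EXON_COLS, "exon table")
  if (nrow(df) == 0L) {
    attr(df, "rejected") <- integer()
    return(df)
  }
  sp <- suppressWarnings(as.integer(df$start_phase))
  ep <- suppressWarnings(as.integer(df$end_phase))
  rk <- suppressWarnings(as.integer(df$rank))
  len <- suppressWarnings(as.integer(df$length_bp))
  ok <- !is.na(sp) & sp %in% c(-1L, 0L, 1L, 2L) &
        !is.na(ep) & ep %in% c(-1L, 0L, 1L, 2L) &
        !is.na(rk) & rk >= 1L & !is.na(len) & len >= 1L
  if (any(!ok) && !quiet)
    message(sprintf("exon table: rejected %d row(s) with invalid phase/rank/length (rows: %s)",
                    sum(!ok), paste(which(!ok), collapse = ", ")))
  rejected <- which(!ok)
  df$start_phase <- sp; df$end_phase <- ep; df$rank <- rk; df$length_bp <- len
  df <- df[ok, , drop = FALSE]
  key <- paste(df$transcript_id, df$rank, sep = "\r")
  if (anyDuplicated(key))
    stop("exon table: duplicate (transcript_id, rank) pairs: ",
         paste(unique(df$transcript_id[duplicated(key)]), collapse = ", "))
  gap <- vapply(split(df$rank, df$transcript_id),
                function(r) !setequal(r, seq_along(r)), logical(1L))
  if (any(gap))
    warning("exon table: non-contiguous exon ranks in transcript(s): ",
            paste(names(gap)[gap], collapse = ", "))
  rownames(df) <- NULL
  attr(df, "rejected") <- rejected
  df
}

# normalise an allele-class string ("tm1a", "Gene<tm2e(KOMP)>", enum name)
# to the internal enum; NA when unrecognised
.ALLELE_ENUM <- c(a = "KNOCKOUT_FIRST", e = "TARGETED_NONCOND",
                  b = "LACZ_DELETION", c = "CONDITIONAL")

.normalizeAlleleClass <- function(x) {
  x <- as.character(x)
  out <- ifelse(toupper(x) %in% .ALLELE_ENUM, toupper(x), NA_character_)
  m <- regmatches(tolower(x), regexpr("tm[0-9]+[a-z]", tolower(x)))
  hasTm <- regexpr("tm[0-9]+[a-z]", tolower(x)) > 0L
  letter <- rep(NA_character_, length(x))
  letter[hasTm] <- substring(m, nchar(m), nchar(m))
  fromTm <- unname(.ALLELE_ENUM[letter])
  ifelse(is.na(out), fromTm, out)
}

#' Parse an allele-design table
#'
#' CSV with header \code{design_id, gene_id, allele_class, transcript_id,
#' critical_exon_ids}; the last column is a semicolon-joined list of exon
#' ids (consecutive exons of one transcript). Allele classes may be given
#' as tm-style codes (\code{tm1a}, \code{tm2e}, \code{tm1b}, ...) or as the
#' enum names \code{KNOCKOUT_FIRST}, \code{TARGETED_NONCOND},
#' \code{LACZ_DELETION}, \code{CONDITIONAL}.
#'
#' @param path path to the CSV.
#' @param columnMap optional named character vector, canonical -> header.
#' @return data.frame with normalised \code{allele_class} and a list column
#'   \code{critical_exon_ids}.
#' @export
parseDesignTable <- function(path, columnMap = NULL) {
  df <- .readTable(path)
  map <- stats::setNames(.DESIGN_COLS, .DESIGN_COLS)
  if (!is.null(columnMap)) map[names(columnMap)] <- columnMap
  df <- .applyColumnMap(df, map, .DESIGN_COLS, "design table")
  if (nrow(df) == 0L) {
    df$critical_exon_ids <- list()
    return(df)
  }
  cls <- .normalizeAlleleClass(df$allele_class)
  if (anyNA(cls))
    warning("design table: unrecognised allele class for design(s): ",
            paste(df$design_id[is.na(cls)], collapse = ", "))
  df$allele_class <- cls
  df$critical_exon_ids <- strsplit(as.character(df$critical_exon_ids), ";",
                                   fixed = TRUE)
  df
}

#' Resolve the phase pair of a design's critical exon block
#'
#' Looks up the design's critical exon id(s) in the exon table, picks the
#' reference transcript (the design's named transcript if it carries all the
#' ids; otherwise any transcript containing all of them, ties broken by
#' lexicographically smallest id with a warning), checks the exons occupy
#' consecutive ranks, and returns the start phase of the first exon paired
#' with the end phase of the last: the insert replaces the whole block and
#' interior boundaries are spliced out.
#'
#' @param exonIds character vector of critical exon ids (length >= 1).
#' @param exons exon table from [parseExonTable()].
#' @param transcriptId optional preferred transcript id.
#' @return list with \code{start_phase}, \code{end_phase},
#'   \code{transcript_id}; or \code{NULL} (with attribute-free semantics)
#'   when an exon id is absent from the table, meaning the design has no
#'   phase information and should be skipped.
#' @export
resolveCriticalPhases <- function(exonIds, exons, transcriptId = NULL) {
  hit <- exons[exons$exon_id %in% exonIds, , drop = FALSE]
  byTx <- split(hit, hit$transcript_id)
  full <- names(byTx)[vapply(byTx, function(d)
    all(exonIds %in% d$exon_id), logical(1L))]
  if (!length(full))
    return(NULL)
  tx <- if (!is.null(transcriptId) && !is.na(transcriptId) &&
            transcriptId %in% full) {
    transcriptId
  } else if (length(full) == 1L) {
    full
  } else {
    warning("critical exons found on several transcripts (",
            paste(sort(full), collapse = ", "),
            "); using ", sort(full)[1L])
    sort(full)[1L]
  }
  blk <- byTx[[tx]]
  blk <- blk[blk$exon_id %in% exonIds, , drop = FALSE]
  blk <- blk[order(blk$rank), , drop = FALSE]
  if (nrow(blk) > 1L && any(diff(blk$rank) != 1L))
    stop("critical exons are not consecutive on transcript ", tx, ": ranks ",
         paste(blk$rank, collapse = ", "))
  list(start_phase = blk$start_phase[1L],
       end_phase = blk$end_phase[nrow(blk)],
       transcript_id = tx)
}

# default allele class -> insertion mode
.modeForClass <- function(cls) {
  ifelse(cls %in% c("KNOCKOUT_FIRST", "TARGETED_NONCOND"), "BEFORE",
  ifelse(cls == "LACZ_DELETION", "REPLACES", NA_character_))
}

#' Predict transcription outcomes for a design table
#'
#' The bulk classification step: resolves each design's critical-exon phase
#' pair and runs [classifyDesign()]. The insertion mode defaults from the
#' allele class (knockout-first and targeted non-conditional insert BEFORE
#' the critical exon; lacZ-tagged deletions REPLACE it; conditional alleles
#' rescue splicing and are skipped) but can be forced with \code{mode}, or
#' doubled with \code{bothModes = TRUE} since a knockout-first allele can in
#' practice behave in REPLACES mode. Designs whose exons cannot be found are
#' skipped and tallied, not dropped silently.
#'
#' @param designs design table from [parseDesignTable()].
#' @param exons exon table from [parseExonTable()].
#' @param mode \code{NULL} (per-class default), \code{"REPLACES"} or
#'   \code{"BEFORE"} applied to every design.
#' @param bothModes emit one prediction per design per mode.
#' @param collapseStop collapse BEFORE-mode phase-2 stops into FRAMESHIFT.
#' @param cassette an [En2Cassette-class].
#' @return data.frame with columns \code{design_id, gene_id, allele_class,
#'   mode, start_phase, end_phase, category}; attribute \code{"skipped"}
#'   is a data.frame (design_id, reason) of designs without predictions.
#' @export
predictAll <- function(designs, exons, mode = NULL, bothModes = FALSE,
                       collapseStop = FALSE, cassette = en2Cassette()) {
  n <- nrow(designs)
  designs$allele_class <- .normalizeAlleleClass(designs$allele_class)
  sp <- integer(n); ep <- integer(n)
  reason <- rep(NA_character_, n)
  if (n > 0L && !anyDuplicated(exons$exon_id)) {
    # fast path: exon ids are globally unique, so hashed match() resolves
    # every design without scanning the table per design
    nIds <- lengths(designs$critical_exon_ids)
    allIds <- unlist(designs$critical_exon_ids, use.names = FALSE)
    rows <- match(allIds, exons$exon_id)
    off <- c(0L, cumsum(nIds))
    single <- nIds == 1L
    r1 <- rows[off[seq_len(n)] + 1L]
    miss <- single & is.na(r1)
    okS <- single & !is.na(r1)
    reason[miss] <- "no phase information"
    sp[okS] <- exons$start_phase[r1[okS]]
    ep[okS] <- exons$end_phase[r1[okS]]
    for (i in which(!single)) {
      ri <- rows[(off[i] + 1L):off[i + 1L]]
      if (anyNA(ri)) {
        reason[i] <- "no phase information"
        next
      }
      if (length(unique(exons$transcript_id[ri])) != 1L) {
        reason[i] <- "no phase information"
        next
      }
      ri <- ri[order(exons$rank[ri])]
      if (any(diff(exons$rank[ri]) != 1L))
        stop("critical exons are not consecutive for design ",
             designs$design_id[i])
      sp[i] <- exons$start_phase[ri[1L]]
      ep[i] <- exons$end_phase[ri[length(ri)]]
    }
  } else {
    for (i in seq_len(n)) {
      res <- resolveCriticalPhases(designs$critical_exon_ids[[i]], exons,
                                   transcriptId = designs$transcript_id[i])
      if (is.null(res)) {
        reason[i] <- "no phase information"
      } else {
        sp[i] <- res$start_phase
        ep[i] <- res$end_phase
      }
    }
  }
  dmode <- if (is.null(mode)) .modeForClass(designs$allele_class)
           else rep_len(mode, n)
  reason[is.na(reason) & is.na(dmode)] <- "no insertion mode for allele class"
  keep <- is.na(reason)
  base <- data.frame(design_id = designs$design_id[keep],
                     gene_id = designs$gene_id[keep],
                     allele_class = designs$allele_class[keep],
                     mode = dmode[keep],
                     start_phase = sp[keep],
                     end_phase = ep[keep],
                     stringsAsFactors = FALSE)
  if (bothModes) {
    alt <- base
    alt$mode <- ifelse(base$mode == "REPLACES", "BEFORE", "REPLACES")
    base <- rbind(base, alt)
    base <- base[order(base$design_id, base$mode), , drop = FALSE]
    rownames(base) <- NULL
  }
  base$category <- classifyDesign(base$start_phase, base$end_phase,
                                  mode = if (nrow(base)) base$mode else "REPLACES",
                                  cassette = cassette,
                                  collapseStop = collapseStop)
  attr(base, "skipped") <- data.frame(
    design_id = designs$design_id[!keep],
    reason = reason[!keep],
    stringsAsFactors = FALSE)
  base
}

#' Per-category design totals
#'
#' @param predictions output of [predictAll()].
#' @return Named integer vector over the four [outcomeCategories()].
#' @export
categoryTotals <- function(predictions) {
  table(factor(predictions$category, levels = outcomeCategories()))
}

#' Genes with designs in more than one category
#'
#' Genes whose designs (built around different critical exons) land in two
#' or more outcome categories. Phenotype aggregation excludes these genes,
#' since phenotype data cannot be matched to a specific design.
#'
#' @param predictions output of [predictAll()].
#' @return Character vector of gene ids (each once), possibly empty.
#' @export
multiCategoryGenes <- function(predictions) {
  k <- vapply(split(as.character(predictions$category), predictions$gene_id),
              function(x) length(unique(x)), integer(1L))
  names(k)[k >= 2L]
}

#' Write predictions and their JSON summary
#'
#' @param predictions output of [predictAll()].
#' @param csvPath output CSV path (RFC-4180, header included).
#' @param jsonPath optional path for a JSON summary holding per-category
#'   totals, per-gene category sets, multi-category genes and the skipped
#'   tally.
#' @return Invisibly, the summary list.
#' @export
writePredictions <- function(predictions, csvPath, jsonPath = NULL) {
  out <- predictions
  out$category <- as.character(out$category)
  utils::write.csv(out, csvPath, row.names = FALSE, quote = TRUE)
  summary <- list(
    n_designs = nrow(predictions),
    category_totals = as.list(categoryTotals(predictions)),
    multi_category_genes = multiCategoryGenes(predictions),
    genes_per_category = lapply(
      split(predictions$gene_id, predictions$category),
      function(g) length(unique(g))),
    n_skipped = nrow(attr(predictions, "skipped") %||% data.frame())
  )
  if (!is.null(jsonPath))
    jsonlite::write_json(summary, jsonPath, auto_unbox = TRUE, pretty = TRUE)
  invisible(summary)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
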