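# IMPC-style phenotype and lacZ aggregation by predicted outcome category.

.PHENO_COLS <- c("gene_id", "line_id", "allele_symbol")
.IMPC_PHENO_MAP <- c(
  gene_id = "Gene Accession Id",
  line_id = "Colony Id",
  allele_symbol = "Allele Symbol",
  mp_term_id = "MP Term Id",
  mp_term_name = "MP Term Name"
)
.LACZ_COLS <- c("gene_id", "tissue", "expressed")
.IMPC_LACZ_MAP <- c(
  gene_id = "Gene Accession Id",
  tissue = "Tissue",
  expressed = "Expression"
)

#' Parse a phenotype-hit CSV
#'
#' Reads an IMPC-style table of mutant-line phenotype hits, where every MP
#' (Mammalian Phenotype) term attached to a line records one significant
#' mutant-versus-control difference. Two layouts are accepted: \emph{long}
#' (one row per line x MP term, columns \code{mp_term_id} and/or
#' \code{mp_term_name}, blank when a row records a tested line with no hit)
#' and \emph{delimited} (one row per line, hits semicolon-joined inside the
#' term columns). Rows are grouped per \code{line_id} and term sets unioned,
#' so a line split across rows keeps each distinct term once.
#'
#' @param path path to the CSV.
#' @param columnMap optional named character vector, canonical -> header;
#'   the IMPC export headers ("Gene Accession Id", "Colony Id", "Allele
#'   Symbol", "MP Term Id", "MP Term Name") are recognised automatically.
#' @return data.frame with one row per line: \code{gene_id, line_id,
#'   allele_symbol, allele_group, n_terms, n_lethal_terms}, plus a list
#'   column \code{mp_term_names} of the distinct term names.
#' @export
parsePhenotypeCsv <- function(path, columnMap = NULL) {
  df <- .readTable(path)
  map <- stats::setNames(c(.PHENO_COLS, "mp_term_id", "mp_term_name"),
                         c(.PHENO_COLS, "mp_term_id", "mp_term_name"))
  map[names(.IMPC_PHENO_MAP)] <- .IMPC_PHENO_MAP
  # prefer exact canonical headers, then IMPC headers, then user map
  for (canon in c(.PHENO_COLS, "mp_term_id", "mp_term_name")) {
    if (!(canon %in% names(df)) && .IMPC_PHENO_MAP[canon] %in% names(df))
      names(df)[names(df) == .IMPC_PHENO_MAP[canon]] <- canon
  }
  if (!is.null(columnMap)) {
    for (canon in names(columnMap))
      if (columnMap[[canon]] %in% names(df))
        names(df)[names(df) == columnMap[[canon]]] <- canon
  }
  missing <- setdiff(.PHENO_COLS, names(df))
  if (length(missing))
    stop("phenotype table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  if (!("mp_term_name" %in% names(df)))
    df$mp_term_name <- ""
  if (nrow(df) == 0L) {
    return(data.frame(gene_id = character(), line_id = character(),
                      allele_symbol = character(), allele_group = character(),
                      n_terms = integer(), n_lethal_terms = integer(),
                      mp_term_names = I(list())))
  }
  terms <- strsplit(ifelse(is.na(df$mp_term_name), "",
                           as.character(df$mp_term_name)), ";", fixed = TRUE)
  terms <- lapply(terms, function(x) {
    x <- trimws(x)
    x[nzchar(x)]
  })
  idx <- split(seq_len(nrow(df)), df$line_id)
  lines <- lapply(idx, function(i) {
    tt <- unique(unlist(terms[i], use.names = FALSE))
    data.frame(gene_id = df$gene_id[i[1L]],
               line_id = df$line_id[i[1L]],
               allele_symbol = df$allele_symbol[i[1L]],
               n_terms = length(tt),
               n_lethal_terms = sum(isLethal(tt)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, lines)
  out$allele_group <- alleleGroupOf(out$allele_symbol)
  out$mp_term_names <- lapply(idx, function(i)
    unique(unlist(terms[i], use.names = FALSE)))
  rownames(out) <- NULL
  out[, c("gene_id", "line_id", "allele_symbol", "allele_group",
          "n_terms", "n_lethal_terms", "mp_term_names")]
}

#' Allele group of a mutant allele symbol
#'
#' Maps IKMC targeted-mutation codes embedded in allele symbols to the two
#' groups aggregated in the phenotype summary: \code{tm<digit>a} (knockout-
#' first) and \code{tm<digit>e} (targeted non-conditional) to
#' \code{KO_FIRST_AND_NONCOND}; \code{tm<digit>b} (lacZ-tagged deletion) to
#' \code{LACZ_DELETION}. Conditional (\code{tm<digit>c}) and unrecognised
#' symbols return \code{NA} and are excluded from aggregation, since a
#' conditional allele rescues gene function and is not phenotyped as a null.
#'
#' @param alleleSymbol character vector, e.g. \code{"Xyz<tm1a(EUCOMM)Wtsi>"}.
#' @return Character vector: \code{"KO_FIRST_AND_NONCOND"},
#'   \code{"LACZ_DELETION"} or \code{NA}.
#' @export
alleleGroupOf <- function(alleleSymbol) {
  s <- tolower(as.character(alleleSymbol))
  m <- regexpr("tm[0-9]+[a-z]", s)
  code <- rep(NA_character_, length(s))
  code[m > 0L] <- regmatches(s, m)
  letter <- substring(code, nchar(code), nchar(code))
  out <- rep(NA_character_, length(s))
  out[letter %in% c("a", "e")] <- "KO_FIRST_AND_NONCOND"
  out[letter %in% "b"] <- "LACZ_DELETION"
  out
}

#' Is an MP term a lethality phenotype?
#'
#' Case-insensitive substring match for "lethal" on the term name, which
#' captures the preweaning/embryonic/postnatal lethality families without
#' shipping the MP ontology. An optional id allowlist supports stricter
#' ontology-based matching when term ids are available.
#'
#' @param mpTermName character vector of MP term names.
#' @param mpTermId optional character vector of MP ids, matched against
#'   \code{idAllowlist} instead of the substring rule when supplied.
#' @param idAllowlist character vector of MP ids counted as lethal.
#' @return Logical vector.
#' @export
isLethal <- function(mpTermName, mpTermId = NULL, idAllowlist = NULL) {
  if (!is.null(idAllowlist) && !is.null(mpTermId))
    return(mpTermId %in% idAllowlist)
  grepl("lethal", as.character(mpTermName), ignore.case = TRUE)
}

#' Parse a lacZ-expression CSV
#'
#' One row per gene x tissue with an expression call. Tissue names are
#' trimmed and lower-cased before comparison; duplicated gene x tissue rows
#' collapse by logical OR on \code{expressed}. Calls may be logical,
#' \code{0/1}, \code{yes/no}, or IMPC-style \code{"expression"} /
#' \code{"no expression"}.
#'
#' @param path path to the CSV.
#' @param columnMap optional named character vector, canonical -> header.
#' @return data.frame \code{gene_id, tissue, expressed} with one row per
#'   distinct gene x tissue.
#' @export
parseLaczCsv <- function(path, columnMap = NULL) {
  df <- .readTable(path)
  for (canon in .LACZ_COLS) {
    if (!(canon %in% names(df)) && .IMPC_LACZ_MAP[canon] %in% names(df))
      names(df)[names(df) == .IMPC_LACZ_MAP[canon]] <- canon
  }
  if (!is.null(columnMap)) {
    for (canon in names(columnMap))
      if (columnMap[[canon]] %in% names(df))
        names(df)[names(df) == columnMap[[canon]]] <- canon
  }
  missing <- setdiff(.LACZ_COLS, names(df))
  if (length(missing))
    stop("lacZ table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0L)
    return(data.frame(gene_id = character(), tissue = character(),
                      expressed = logical()))
  raw <- tolower(trimws(as.character(df$expressed)))
  expressed <- raw %in% c("true", "t", "1", "yes", "y", "expression", "expressed")
  notExpr <- raw %in% c("false", "f", "0", "no", "n", "no expression",
                        "not expressed", "absent")
  if (any(!expressed & !notExpr))
    warning("lacZ table: unrecognised expression call(s) treated as not expressed: ",
            paste(unique(raw[!expressed & !notExpr]), collapse = ", "))
  tissue <- tolower(trimws(as.character(df$tissue)))
  key <- paste(df$gene_id, tissue, sep = "\r")
  agg <- tapply(expressed, key, any)
  first <- !duplicated(key)
  out <- data.frame(gene_id = df$gene_id[first], tissue = tissue[first],
                    stringsAsFactors = FALSE)
  out$expressed <- unname(agg[key[first]])
  rownames(out) <- NULL
  out
}

#' Genes with no lacZ expression anywhere
#'
#' Genes assayed in at least \code{minTissues} distinct tissues with no
#' expression recorded in any of them. Genes assayed in fewer tissues are
#' never reported silent: the coverage is insufficient to call absence.
#'
#' @param lacz table from [parseLaczCsv()].
#' @param minTissues minimum number of distinct assayed tissues (default 27).
#' @return Character vector of gene ids.
#' @export
laczSilentGenes <- function(lacz, minTissues = 27L) {
  if (nrow(lacz) == 0L) return(character())
  byGene <- split(lacz$expressed, lacz$gene_id)
  ok <- vapply(byGene, function(e) length(e) >= minTissues && !any(e),
               logical(1L))
  names(byGene)[ok]
}

#' Aggregate phenotype metrics by outcome category and allele group
#'
#' Reproduces the structure of the published per-category phenotype audit:
#' for every outcome category x allele group it counts predicted genes,
#' genes with no phenotype data for that group ("untested"), tested lines,
#' lines with no significant phenotype, lines with at least one lethality
#' phenotype, and the mean number of MP terms per tested line. Genes whose
#' designs span several categories are excluded from every row, because
#' available phenotype data cannot be attributed to one design.
#'
#' @param predictions output of [predictAll()].
#' @param phenotypes per-line table from [parsePhenotypeCsv()].
#' @param multiCatGenes genes to exclude; defaults to
#'   [multiCategoryGenes()] of \code{predictions}.
#' @param categories categories to report (default: all but OTHER, which is
#'   not analysed further).
#' @return data.frame with one row per category x allele group and columns
#'   \code{category, allele_group, genes_total, genes_untested,
#'   lines_tested, lines_no_phenotype, lines_lethal, phenotypes_per_line}
#'   (\code{NaN} when no lines were tested).
#' @export
summarizeCategories <- function(predictions, phenotypes,
                                multiCatGenes = multiCategoryGenes(predictions),
                                categories = setdiff(outcomeCategories(),
                                                     "OTHER")) {
  pred <- predictions[!(predictions$gene_id %in% multiCatGenes), , drop = FALSE]
  ph <- phenotypes[!(phenotypes$gene_id %in% multiCatGenes) &
                     !is.na(phenotypes$allele_group), , drop = FALSE]
  geneCat <- unique(data.frame(gene_id = pred$gene_id,
                               category = as.character(pred$category),
                               stringsAsFactors = FALSE))
  groups <- c("KO_FIRST_AND_NONCOND", "LACZ_DELETION")
  rows <- list()
  for (cat in categories) {
    genes <- geneCat$gene_id[geneCat$category == cat]
    for (grp in groups) {
      sub <- ph[ph$gene_id %in% genes & ph$allele_group == grp, , drop = FALSE]
      nLines <- nrow(sub)
      rows[[length(rows) + 1L]] <- data.frame(
        category = cat,
        allele_group = grp,
        genes_total = length(genes),
        genes_untested = sum(!(genes %in% sub$gene_id)),
        lines_tested = nLines,
        lines_no_phenotype = sum(sub$n_terms == 0L),
        lines_lethal = sum(sub$n_lethal_terms > 0L),
        phenotypes_per_line = if (nLines) sum(sub$n_terms) / nLines else NaN,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Long-format view of a category summary
#'
#' One row per category x allele group x metric, with raw numerators and
#' denominators alongside any percentage, convenient for plotting or
#' downstream tabulation.
#'
#' @param summary output of [summarizeCategories()].
#' @return data.frame with columns \code{category, allele_group, metric,
#'   numerator, denominator, value}.
#' @export
summaryLong <- function(summary) {
  rows <- list()
  for (i in seq_len(nrow(summary))) {
    s <- summary[i, ]
    add <- function(metric, num, den, value)
      rows[[length(rows) + 1L]] <<- data.frame(
        category = s$category, allele_group = s$allele_group,
        metric = metric, numerator = num, denominator = den, value = value,
        stringsAsFactors = FALSE)
    add("genes_total", s$genes_total, NA_integer_, s$genes_total)
    add("genes_untested_pct", s$genes_untested, s$genes_total,
        if (s$genes_total) 100 * s$genes_untested / s$genes_total else NaN)
    add("lines_tested", s$lines_tested, NA_integer_, s$lines_tested)
    add("lines_no_phenotype_pct", s$lines_no_phenotype, s$lines_tested,
        if (s$lines_tested) 100 * s$lines_no_phenotype / s$lines_tested else NaN)
    add("lines_lethal_pct", s$lines_lethal, s$lines_tested,
        if (s$lines_tested) 100 * s$lines_lethal / s$lines_tested else NaN)
    add("phenotypes_per_line", NA_integer_, s$lines_tested,
        s$phenotypes_per_line)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
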