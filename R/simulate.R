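# Seeded generators for phase-consistent gene models, allele designs and
# IMPC-style phenotype/lacZ tables with known ground truth. These stand in
# for the Ensembl/IMPC bulk exports so the whole pipeline is testable
# offline; they emulate phase structure and outcome proportions, not
# genomic coordinates or sequence content.

#' @importFrom stats rbinom runif qpois dpois setNames uniroot rpois
NULL

# the nine non-negative phase pairs in canonical order
.PHASE_PAIRS <- cbind(
  start = rep(0:2, each = 3L),
  end = rep(0:2, times = 3L)
)

# small MP-style vocabulary so lethality detection is exercised without
# bundling the ontology
.MP_LETHAL <- c(
  "preweaning lethality, complete penetrance",
  "preweaning lethality, incomplete penetrance",
  "embryonic lethality prior to organogenesis",
  "embryonic lethality during organogenesis",
  "postnatal lethality, incomplete penetrance"
)
.MP_NONLETHAL <- c(
  "increased circulating glucose level", "decreased body weight",
  "abnormal gait", "hyperactivity", "decreased grip strength",
  "abnormal retina morphology", "increased startle reflex",
  "abnormal kidney morphology", "decreased bone mineral density",
  "abnormal heart rate", "increased circulating cholesterol level",
  "abnormal coat appearance", "decreased hematocrit",
  "abnormal lens morphology", "increased anxiety-related response",
  "abnormal spleen morphology", "decreased locomotor activity",
  "abnormal tooth morphology", "increased mean corpuscular volume",
  "abnormal ear morphology", "decreased circulating triglyceride level",
  "abnormal sternum morphology", "increased leukocyte cell number",
  "abnormal vibrissa morphology", "decreased fasting glucose",
  "abnormal craniofacial morphology", "increased urine protein level",
  "abnormal rib morphology", "decreased erythrocyte cell number",
  "abnormal skin morphology", "increased heart weight",
  "abnormal tail morphology", "decreased thermal nociception",
  "abnormal eye pigmentation", "increased liver weight",
  "abnormal digit morphology", "impaired glucose tolerance",
  "abnormal snout morphology", "increased platelet cell number",
  "abnormal pinna reflex"
)
.TISSUES <- c(
  "brain", "spinal cord", "eye", "inner ear", "heart", "lung", "liver",
  "kidney", "spleen", "thymus", "stomach", "small intestine",
  "large intestine", "pancreas", "adrenal gland", "testis", "ovary",
  "uterus", "bladder", "skeletal muscle", "skin", "white adipose tissue",
  "brown adipose tissue", "bone", "cartilage", "trachea", "oesophagus",
  "salivary gland", "lymph node", "blood vessel", "peripheral nerve",
  "pituitary gland", "thyroid gland", "mammary gland", "prostate",
  "epididymis", "tongue", "diaphragm", "aorta", "gall bladder"
)

#' Simulation configuration
#'
#' Parameters of the synthetic-data generators. Defaults describe a cohort
#' with the broad characteristics of the IMPC knockout-first resource:
#' roughly 70\% of predicted genes without phenotype data, about 15\% of
#' tested lines with no significant phenotype, about 35\% with a lethality
#' phenotype, a mean of 4.5 MP terms per tested line, lacZ assayed in 30
#' tissues with about 1.2\% of genes silent everywhere, and a
#' knockout-first-heavy allele mix.
#'
#' @param seed integer seed; all generators are deterministic given it
#'   (Mersenne-Twister via \code{set.seed}).
#' @param n_genes number of genes (one reference transcript each unless
#'   \code{n_transcripts_per_gene > 1}).
#' @param exons_per_gene integer range \code{c(min, max)}; at least 3 so an
#'   internal critical exon exists.
#' @param exon_length_range integer range of exon lengths in bp.
#' @param utr_flank_probability probability that the outermost boundary of
#'   the first/last exon carries phase -1 (boundary in the UTR).
#' @param phase_pair_weights weights over the nine non-negative (start, end)
#'   phase pairs of the critical-exon block, in the order (0,0), (0,1),
#'   (0,2), (1,0), ..., (2,2).
#' @param balanced_phase_pairs if \code{TRUE}, assign phase pairs by cycling
#'   through the nine pairs in order instead of sampling, giving exact
#'   composition when \code{n_genes} is a multiple of 9.
#' @param pair_exon_fraction probability that the critical block spans two
#'   consecutive exons instead of one (the block-level phase pair is still
#'   the assigned one; the interior boundary phase is random).
#' @param allele_class_mix named proportions over \code{KNOCKOUT_FIRST},
#'   \code{TARGETED_NONCOND}, \code{LACZ_DELETION}.
#' @param fraction_untested probability a gene has no phenotype rows.
#' @param no_phenotype_fraction probability a tested line has zero MP terms.
#' @param lethal_fraction marginal probability a tested line carries at
#'   least one lethality term; must not exceed
#'   \code{1 - no_phenotype_fraction}.
#' @param mp_terms_per_line_mean expected MP terms per tested line
#'   (marginal, i.e. averaged over no-phenotype lines as well).
#' @param n_tissues tissues per gene in the lacZ table (max 40).
#' @param silent_gene_fraction probability a gene is lacZ-silent in every
#'   tissue.
#' @param n_transcripts_per_gene 1 by default; 2 duplicates each gene model
#'   under a second transcript id, solely to exercise reference-transcript
#'   tie-breaking.
#' @return A validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(seed = 1L,
                             n_genes = 200L,
                             exons_per_gene = c(4L, 9L),
                             exon_length_range = c(40L, 300L),
                             utr_flank_probability = 0.7,
                             phase_pair_weights = rep(1, 9L),
                             balanced_phase_pairs = FALSE,
                             pair_exon_fraction = 0.1,
                             allele_class_mix = c(KNOCKOUT_FIRST = 0.55,
                                                  TARGETED_NONCOND = 0.10,
                                                  LACZ_DELETION = 0.35),
                             fraction_untested = 0.70,
                             no_phenotype_fraction = 0.15,
                             lethal_fraction = 0.35,
                             mp_terms_per_line_mean = 4.5,
                             n_tissues = 30L,
                             silent_gene_fraction = 36 / 2909,
                             n_transcripts_per_gene = 1L) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_length_range = as.integer(exon_length_range),
              utr_flank_probability = utr_flank_probability,
              phase_pair_weights = as.numeric(phase_pair_weights),
              balanced_phase_pairs = isTRUE(balanced_phase_pairs),
              pair_exon_fraction = pair_exon_fraction,
              allele_class_mix = allele_class_mix,
              fraction_untested = fraction_untested,
              no_phenotype_fraction = no_phenotype_fraction,
              lethal_fraction = lethal_fraction,
              mp_terms_per_line_mean = mp_terms_per_line_mean,
              n_tissues = as.integer(n_tissues),
              silent_gene_fraction = silent_gene_fraction,
              n_transcripts_per_gene = as.integer(n_transcripts_per_gene))
  probs <- c(utr = cfg$utr_flank_probability, pair = cfg$pair_exon_fraction,
             untested = cfg$fraction_untested,
             nophen = cfg$no_phenotype_fraction,
             lethal = cfg$lethal_fraction,
             silent = cfg$silent_gene_fraction)
  if (any(is.na(probs) | probs < 0 | probs > 1))
    stop("invalid probability parameter: ",
         paste(names(probs)[is.na(probs) | probs < 0 | probs > 1],
               collapse = ", "))
  if (length(cfg$phase_pair_weights) != 9L ||
      any(cfg$phase_pair_weights < 0) || sum(cfg$phase_pair_weights) == 0)
    stop("phase_pair_weights must be 9 non-negative values, not all zero")
  if (cfg$lethal_fraction > 1 - cfg$no_phenotype_fraction + 1e-12)
    stop("lethal_fraction cannot exceed 1 - no_phenotype_fraction ",
         "(a line with no phenotype has no lethality term)")
  if (length(cfg$exons_per_gene) != 2L || cfg$exons_per_gene[1L] < 3L)
    stop("exons_per_gene must be a range with minimum >= 3")
  if (cfg$n_genes < 0L) stop("n_genes must be non-negative")
  if (cfg$n_tissues > length(.TISSUES))
    stop("n_tissues must be <= ", length(.TISSUES))
  if (is.null(names(cfg$allele_class_mix)) ||
      !all(names(cfg$allele_class_mix) %in%
             c("KNOCKOUT_FIRST", "TARGETED_NONCOND", "LACZ_DELETION")))
    stop("allele_class_mix must be named with KNOCKOUT_FIRST, ",
         "TARGETED_NONCOND, LACZ_DELETION")
  if (cfg$mp_terms_per_line_mean <= 0)
    stop("mp_terms_per_line_mean must be positive")
  class(cfg) <- "SimulationConfig"
  cfg
}

#' Read a simulation config from a flat key:value file
#'
#' Lines of the form \code{key: value}; vector-valued keys
#' (\code{exons_per_gene}, \code{exon_length_range},
#' \code{phase_pair_weights}, \code{allele_class_mix}) take comma-separated
#' values, \code{allele_class_mix} as \code{NAME=prop} entries. Unknown keys
#' are an error naming the key.
#'
#' @param path path to the config file.
#' @return A \code{SimulationConfig}.
#' @export
readSimulationConfig <- function(path) {
  kv <- readColumnMap(path)
  args <- list()
  for (key in names(kv)) {
    val <- kv[[key]]
    args[[key]] <- switch(key,
      seed = , n_genes = , n_tissues = , n_transcripts_per_gene =
        as.integer(val),
      exons_per_gene = , exon_length_range =
        as.integer(strsplit(val, ",")[[1L]]),
      phase_pair_weights = as.numeric(strsplit(val, ",")[[1L]]),
      balanced_phase_pairs = toupper(val) %in% c("TRUE", "YES", "1"),
      allele_class_mix = {
        parts <- strsplit(strsplit(val, ",")[[1L]], "=")
        stats::setNames(vapply(parts, function(p) as.numeric(p[2L]),
                               numeric(1L)),
                        vapply(parts, function(p) trimws(p[1L]),
                               character(1L)))
      },
      utr_flank_probability = , pair_exon_fraction = , fraction_untested = ,
      no_phenotype_fraction = , lethal_fraction = ,
      mp_terms_per_line_mean = , silent_gene_fraction = as.numeric(val),
      stop("unknown simulation config key: ", key)
    )
  }
  do.call(simulationConfig, args)
}

# draw one element of x (safe for length-1 x, unlike sample(x, 1))
.sampleOne <- function(x) x[sample.int(length(x), 1L)]

# sample one exon length congruent to `residue` (mod 3) within the range
.sampleLength <- function(range, residue = NULL, avoidMod3 = FALSE) {
  cand <- seq.int(range[1L], range[2L])
  if (!is.null(residue)) cand <- cand[cand %% 3L == residue %% 3L]
  else if (avoidMod3 && any(cand %% 3L != 0L)) cand <- cand[cand %% 3L != 0L]
  cand[sample.int(length(cand), 1L)]
}

#' Generate phase-consistent gene models
#'
#' One transcript per gene whose exon phases form a valid chain: the end
#' phase of exon i equals the start phase of exon i+1, and every fully
#' coding exon satisfies \code{end == (start + length) mod 3}. Each gene
#' carries a designated internal critical block (one exon, or two
#' consecutive exons with probability \code{pair_exon_fraction}) whose
#' block-level (start, end) phase pair is drawn from
#' \code{phase_pair_weights} (or cycled when \code{balanced_phase_pairs}).
#' The outermost first/last exon boundaries carry phase -1 with probability
#' \code{utr_flank_probability}, mimicking boundaries inside UTRs.
#' Critical-exon lengths avoid multiples of 3 whenever the assigned phase
#' pair permits (pairs with equal start and end phases force a length
#' divisible by 3).
#'
#' @param config a [simulationConfig()].
#' @return Exon-table data.frame (canonical columns), with attribute
#'   \code{"critical"}: per-gene data.frame of the critical block
#'   (\code{gene_id, transcript_id, exon_ids} semicolon-joined,
#'   \code{start_phase, end_phase}).
#' @export
generateGeneModels <- function(config) {
  set.seed(config$seed)
  nG <- config$n_genes
  gStart <- vector("list", nG); gEnd <- vector("list", nG)
  gLen <- vector("list", nG); gN <- integer(nG)
  critBlock <- integer(nG); critRankV <- integer(nG)
  critS <- integer(nG); critE <- integer(nG)
  for (i in seq_len(nG)) {
    nEx <- .sampleOne(seq.int(config$exons_per_gene[1L],
                              config$exons_per_gene[2L]))
    twoExon <- stats::runif(1L) < config$pair_exon_fraction && nEx >= 4L
    blockLen <- if (twoExon) 2L else 1L
    critRank <- .sampleOne(seq.int(2L, nEx - blockLen))
    pairIdx <- if (config$balanced_phase_pairs) (i - 1L) %% 9L + 1L
               else sample.int(9L, 1L, prob = config$phase_pair_weights)
    s <- .PHASE_PAIRS[pairIdx, "start"]
    e <- .PHASE_PAIRS[pairIdx, "end"]
    startPh <- integer(nEx); endPh <- integer(nEx); lens <- integer(nEx)
    if (twoExon) {
      mid <- sample(0:2, 1L)
      startPh[critRank] <- s; endPh[critRank] <- mid
      lens[critRank] <- .sampleLength(config$exon_length_range, mid - s)
      startPh[critRank + 1L] <- mid; endPh[critRank + 1L] <- e
      lens[critRank + 1L] <- .sampleLength(config$exon_length_range, e - mid)
    } else {
      startPh[critRank] <- s; endPh[critRank] <- e
      lens[critRank] <- .sampleLength(config$exon_length_range, e - s,
                                      avoidMod3 = TRUE)
    }
    # chain upstream of the block
    for (r in seq.int(critRank - 1L, 1L)) {
      endPh[r] <- startPh[r + 1L]
      lens[r] <- .sampleLength(config$exon_length_range)
      startPh[r] <- (endPh[r] - lens[r]) %% 3L
    }
    # chain downstream of the block
    dn <- seq.int(critRank + blockLen, nEx)
    dn <- dn[dn <= nEx]
    for (r in dn) {
      startPh[r] <- endPh[r - 1L]
      lens[r] <- .sampleLength(config$exon_length_range)
      endPh[r] <- (startPh[r] + lens[r]) %% 3L
    }
    if (stats::runif(1L) < config$utr_flank_probability) startPh[1L] <- -1L
    if (stats::runif(1L) < config$utr_flank_probability) endPh[nEx] <- -1L
    gStart[[i]] <- startPh; gEnd[[i]] <- endPh; gLen[[i]] <- lens
    gN[i] <- nEx; critBlock[i] <- blockLen; critRankV[i] <- critRank
    critS[i] <- s; critE[i] <- e
  }
  geneIdx <- rep.int(seq_len(nG), gN)
  ranks <- sequence(gN)
  exons <- data.frame(
    gene_id = sprintf("GENE%05d", geneIdx),
    transcript_id = sprintf("TX%05d.1", geneIdx),
    exon_id = sprintf("EX%05d.%d", geneIdx, ranks),
    rank = ranks,
    start_phase = unlist(gStart, use.names = FALSE) %||% integer(),
    end_phase = unlist(gEnd, use.names = FALSE) %||% integer(),
    length_bp = unlist(gLen, use.names = FALSE) %||% integer(),
    stringsAsFactors = FALSE)
  if (config$n_transcripts_per_gene > 1L && nG) {
    extra <- exons
    extra$transcript_id <- sub("\\.1$", ".2", extra$transcript_id)
    exons <- rbind(exons, extra)
  }
  critIds <- vapply(seq_len(nG), function(i)
    paste(sprintf("EX%05d.%d", i,
                  seq.int(critRankV[i], critRankV[i] + critBlock[i] - 1L)),
          collapse = ";"), character(1L))
  attr(exons, "critical") <- data.frame(
    gene_id = sprintf("GENE%05d", seq_len(nG)),
    transcript_id = sprintf("TX%05d.1", seq_len(nG)),
    exon_ids = critIds,
    start_phase = critS, end_phase = critE,
    stringsAsFactors = FALSE)
  exons
}

#' Generate an allele-design table with ground-truth categories
#'
#' One design per gene, targeting the gene's designated critical block,
#' with the allele class drawn from \code{allele_class_mix}. The true
#' outcome category is computed with [classifyDesign()] under the class's
#' default insertion mode and stored alongside, supporting round-trip tests
#' of the whole pipeline. Genes too short to host an internal critical exon
#' are skipped with a message.
#'
#' @param config a [simulationConfig()].
#' @param exonTable output of [generateGeneModels()].
#' @return list with \code{designs} (data.frame in the design-table schema,
#'   \code{critical_exon_ids} as a list column) and \code{truth} (data.frame
#'   \code{design_id, gene_id, mode, category}).
#' @export
generateDesigns <- function(config, exonTable) {
  set.seed(config$seed + 1L)
  crit <- attr(exonTable, "critical")
  if (is.null(crit))
    stop("exon table lacks the 'critical' attribute; ",
         "use generateGeneModels()")
  n <- nrow(crit)
  if (n == 0L) {
    return(list(
      designs = data.frame(design_id = character(), gene_id = character(),
                           allele_class = character(),
                           transcript_id = character(),
                           critical_exon_ids = I(list())),
      truth = data.frame(design_id = character(), gene_id = character(),
                         mode = character(), category = character())))
  }
  mix <- config$allele_class_mix / sum(config$allele_class_mix)
  cls <- names(mix)[sample.int(length(mix), n, replace = TRUE, prob = mix)]
  mode <- .modeForClass(cls)
  designs <- data.frame(
    design_id = sprintf("DES%05d", seq_len(n)),
    gene_id = crit$gene_id,
    allele_class = cls,
    transcript_id = crit$transcript_id,
    stringsAsFactors = FALSE)
  designs$critical_exon_ids <- strsplit(crit$exon_ids, ";", fixed = TRUE)
  truth <- data.frame(
    design_id = designs$design_id,
    gene_id = designs$gene_id,
    mode = mode,
    category = as.character(classifyDesign(crit$start_phase, crit$end_phase,
                                           mode = mode)),
    stringsAsFactors = FALSE)
  list(designs = designs, truth = truth)
}

# zero-truncated Poisson parameter lambda such that the marginal mean of
# the mixture {0 w.p. f, ZTP(lambda) otherwise} equals `mean`
.ztpLambda <- function(mean, f) {
  target <- mean / (1 - f)
  if (target <= 1) stop("mp_terms_per_line_mean too small for ",
                        "no_phenotype_fraction (phenotyped lines must ",
                        "average > 1 term)")
  stats::uniroot(function(l) l / (1 - exp(-l)) - target,
                 interval = c(1e-8, max(10, 3 * target)), tol = 1e-10)$root
}

.rztp <- function(n, lambda) {
  u <- stats::runif(n, min = stats::dpois(0L, lambda), max = 1)
  stats::qpois(u, lambda)
}

#' Generate a phenotype cohort and lacZ table for a design set
#'
#' Per design: the gene is untested with probability
#' \code{fraction_untested}; otherwise one mutant line is produced whose MP
#' term count is 0 with probability \code{no_phenotype_fraction} and
#' otherwise zero-truncated Poisson, calibrated so the marginal mean per
#' tested line equals \code{mp_terms_per_line_mean}. A lethality term is
#' included so that the marginal probability a tested line is lethal equals
#' \code{lethal_fraction}. The lacZ table covers every design gene in
#' \code{n_tissues} tissues; silent genes are negative everywhere, others
#' express in a random non-empty subset.
#'
#' @param config a [simulationConfig()].
#' @param designs \code{designs} element of [generateDesigns()].
#' @return list with \code{phenotypes} (long-layout data.frame
#'   \code{gene_id, line_id, allele_symbol, mp_term_id, mp_term_name}; one
#'   row with empty term fields for tested no-phenotype lines) and
#'   \code{lacz} (\code{gene_id, tissue, expressed}).
#' @export
generatePhenotypeCohort <- function(config, designs) {
  set.seed(config$seed + 2L)
  n <- nrow(designs)
  phRows <- list()
  lethalGivenTested <- if (config$fraction_untested < 1 && n > 0L)
    config$lethal_fraction / (1 - config$no_phenotype_fraction) else 0
  lambda <- if (config$no_phenotype_fraction < 1)
    .ztpLambda(config$mp_terms_per_line_mean, config$no_phenotype_fraction)
  else NA_real_
  letterOf <- c(KNOCKOUT_FIRST = "a", TARGETED_NONCOND = "e",
                LACZ_DELETION = "b")
  for (i in seq_len(n)) {
    if (stats::runif(1L) < config$fraction_untested) next
    gene <- designs$gene_id[i]
    lineId <- sprintf("LINE%05d", i)
    sym <- sprintf("%s<tm1%s(EUCOMM)Syn>", gene,
                   letterOf[[designs$allele_class[i]]])
    if (stats::runif(1L) < config$no_phenotype_fraction) {
      phRows[[length(phRows) + 1L]] <- data.frame(
        gene_id = gene, line_id = lineId, allele_symbol = sym,
        mp_term_id = "", mp_term_name = "", stringsAsFactors = FALSE)
      next
    }
    count <- min(.rztp(1L, lambda), length(.MP_NONLETHAL))
    lethal <- stats::runif(1L) < lethalGivenTested
    names_i <- sample(.MP_NONLETHAL, count)
    if (lethal) names_i[1L] <- sample(.MP_LETHAL, 1L)
    ids_i <- sprintf("MP:%07d", match(names_i, c(.MP_LETHAL, .MP_NONLETHAL)))
    phRows[[length(phRows) + 1L]] <- data.frame(
      gene_id = gene, line_id = lineId, allele_symbol = sym,
      mp_term_id = ids_i, mp_term_name = names_i, stringsAsFactors = FALSE)
  }
  phenotypes <- if (length(phRows)) do.call(rbind, phRows) else
    data.frame(gene_id = character(), line_id = character(),
               allele_symbol = character(), mp_term_id = character(),
               mp_term_name = character())
  genes <- unique(designs$gene_id)
  tissues <- .TISSUES[seq_len(config$n_tissues)]
  lzRows <- vector("list", length(genes))
  for (j in seq_along(genes)) {
    silent <- stats::runif(1L) < config$silent_gene_fraction
    expr <- if (silent) rep(FALSE, length(tissues))
            else stats::runif(length(tissues)) < 0.5
    if (!silent && !any(expr)) expr[sample.int(length(expr), 1L)] <- TRUE
    lzRows[[j]] <- data.frame(gene_id = genes[j], tissue = tissues,
                              expressed = expr, stringsAsFactors = FALSE)
  }
  lacz <- if (length(lzRows)) do.call(rbind, lzRows) else
    data.frame(gene_id = character(), tissue = character(),
               expressed = logical())
  rownames(phenotypes) <- NULL
  rownames(lacz) <- NULL
  list(phenotypes = phenotypes, lacz = lacz)
}

# write a table with a seed-bearing comment header
.writeSeeded <- function(df, path, seed, sep = ",") {
  listCols <- vapply(df, is.list, logical(1L))
  for (cn in names(df)[listCols])
    df[[cn]] <- vapply(df[[cn]], paste, character(1L), collapse = ";")
  con <- file(path, "w")
  writeLines(sprintf("# generated by en2splice; seed: %d", seed), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = TRUE)
  close(con)
}

#' Write a full synthetic bundle to disk
#'
#' Emits, in the exact dialects the parsers consume: \code{exons.tsv},
#' \code{designs.csv}, \code{phenotypes.csv}, \code{lacz.csv}, the
#' ground-truth \code{truth.csv}, and a \code{manifest.json} recording the
#' seed, config and package version. Every table starts with a \code{#}
#' comment line carrying the seed.
#'
#' @param config a [simulationConfig()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of the file paths.
#' @export
writeSimulatedBundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  exons <- generateGeneModels(config)
  gd <- generateDesigns(config, exons)
  cohort <- generatePhenotypeCohort(config, gd$designs)
  paths <- list(
    exons = file.path(dir, "exons.tsv"),
    designs = file.path(dir, "designs.csv"),
    phenotypes = file.path(dir, "phenotypes.csv"),
    lacz = file.path(dir, "lacz.csv"),
    truth = file.path(dir, "truth.csv"),
    manifest = file.path(dir, "manifest.json"))
  .writeSeeded(exons, paths$exons, config$seed, sep = "\t")
  .writeSeeded(gd$designs, paths$designs, config$seed)
  .writeSeeded(cohort$phenotypes, paths$phenotypes, config$seed)
  .writeSeeded(cohort$lacz, paths$lacz, config$seed)
  .writeSeeded(gd$truth, paths$truth, config$seed)
  writeRunManifest(paths$manifest, subcommand = "simulate",
                   inputs = character(), seed = config$seed,
                   config = unclass(config))
  invisible(paths)
}
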