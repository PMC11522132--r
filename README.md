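# en2splice

Transcription-outcome prediction for the cryptic splice site in the *En2*
splice-acceptor sequence used by IKMC/IMPC knockout-first mouse alleles.

## The problem

The disruption cassette of knockout-first (tm1a) alleles — and of the
tm1b (lacZ-tagged deletion) and tm1e (targeted non-conditional) alleles
derived from it — begins with the 158 bp *En2* splice-acceptor sequence.
That sequence contains a cryptic splice donor (`aggt`) 115 bases in.
When the spliceosome uses it, a 115 bp fragment of *En2* sequence is
retained in the mature transcript, either before the critical exon or in
its place. Because 115 mod 3 = 1, the consequence depends entirely on
reading-frame phases:

| start phase | end phase | predicted effect |
|---|---|---|
| 0 or 1 | matches `(start + 115) mod 3` | **Readthrough** — the insert substitutes 38 codons in-frame |
| 0 or 1 | anything else | **Frameshift** — premature stop downstream |
| 2 | any | **Stop in insert** — an in-frame TAA at insert bases 35–37 truncates translation |
| negative (non-coding boundary) | — | **Other** (except phase-2 starts, which still hit the TAA) |

A readthrough allele may produce a partially functional protein instead of
the intended null — something anyone interpreting a mutant phenotype needs
to know. `en2splice` provides:

* the cassette sequences and frame-aware translation of the retained
  insert (`en2Cassette()`, `translateInsert()`, `boundaryStopCheck()`);
* the phase-pair classifier (`classifyReplacement()`,
  `classifyInsertionBefore()`, `classifyDesign()`);
* bulk application to Ensembl/BioMart-style exon-phase tables and
  allele-design tables (`parseExonTable()`, `parseDesignTable()`,
  `predictAll()`);
* aggregation of IMPC-style phenotype-hit and lacZ-expression tables by
  predicted category (`parsePhenotypeCsv()`, `summarizeCategories()`,
  `laczSilentGenes()`);
* a seeded synthetic-data generator with known ground truth
  (`simulationConfig()`, `writeSimulatedBundle()`), so every stage is
  testable without network access;
* a command-line front end (`inst/scripts/en2splice-cli.R`) with
  `classify`, `summarize`, `simulate` and `show-cassette` subcommands.

## Worked example

The nine phase combinations and the insert translation in each frame:

```r
library(en2splice)
phaseCombinationTable()
#>   start_phase end_phase       category                                    translation
#> 1           0         0     FRAMESHIFT     VPGPENQRRRTLTKRTSGLAQPSLLSSSRGSRLSFRPT(g)
#> 2           0         1    READTHROUGH     VPGPENQRRRTLTKRTSGLAQPSLLSSSRGSRLSFRPT(g)
#> 3           0         2     FRAMESHIFT     VPGPENQRRRTLTKRTSGLAQPSLLSSSRGSRLSFRPT(g)
#> 4           1         0     FRAMESHIFT (gt)PRSRKPKKKNPNKEDKRPRTAFTAEQLQRLKAEFQTN(ag)
#> 5           1         1     FRAMESHIFT (gt)PRSRKPKKKNPNKEDKRPRTAFTAEQLQRLKAEFQTN(ag)
#> 6           1         2    READTHROUGH (gt)PRSRKPKKKNPNKEDKRPRTAFTAEQLQRLKAEFQTN(ag)
#> 7           2         0 STOP_IN_INSERT                               (g)SQVPKTKEEEP*
#> 8           2         1 STOP_IN_INSERT                               (g)SQVPKTKEEEP*
#> 9           2         2 STOP_IN_INSERT                               (g)SQVPKTKEEEP*
```

Bracketed lowercase bases are partial codons that need the neighbouring
exon to translate; `*` is the stop introduced when the exon starts in
phase 2 (the TAA occupies insert bases 35–37). The same one-off lookup is
available from a shell:

```sh
$ Rscript inst/scripts/en2splice-cli.R classify --phase-pair 2,1
STOP_IN_INSERT
(g)SQVPKTKEEEP*
```

A full pipeline round trip on a simulated bundle:

```r
dir <- tempfile(); paths <- runSimulate(NULL, dir, seed = 7)   # 200 genes
pred <- runClassify(paths$exons, paths$designs, file.path(dir, "out"))
categoryTotals(pred)
#>    READTHROUGH     FRAMESHIFT STOP_IN_INSERT          OTHER
#>             21            106             73              0
runSummarize(file.path(dir, "out", "predictions.csv"), paths$phenotypes,
             file.path(dir, "sum"), laczFile = paths$lacz)
#>         category         allele_group genes_total genes_untested lines_tested
#> 1    READTHROUGH KO_FIRST_AND_NONCOND          21             21            0
#> 2    READTHROUGH        LACZ_DELETION          21             15            6
#> 3     FRAMESHIFT KO_FIRST_AND_NONCOND         106             81           25
#> 4     FRAMESHIFT        LACZ_DELETION         106             99            7
#> 5 STOP_IN_INSERT KO_FIRST_AND_NONCOND          73             53           20
#> 6 STOP_IN_INSERT        LACZ_DELETION          73             66            7
#>   lines_no_phenotype lines_lethal phenotypes_per_line
#> 1                  0            0                 NaN
#> 2                  2            1                3.00
#> ...
```

Frameshift dominates here because most simulated designs are tm1a-like
(classified in BEFORE mode, where phases 0 and 1 both shift the frame);
`lines_tested` is low because, as in the real resource, ~70% of genes have
no phenotype data. Percentages with raw numerators/denominators are in
`category_summary_long.csv`.

Input schemas: exon tables are TSV/CSV with columns `gene_id,
transcript_id, exon_id, rank, start_phase, end_phase, length_bp` (BioMart
headers or a custom column map also accepted); design tables are CSV with
`design_id, gene_id, allele_class, transcript_id, critical_exon_ids`
(semicolon-joined exon list); phenotype tables need `gene_id, line_id,
allele_symbol` plus MP term columns in long or delimited layout. A "line"
is whatever the line/colony id column identifies — the package does not
merge colonies or zygosities.

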