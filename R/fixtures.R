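# Packaged reference tables for the 20-tumor usual penile carcinoma study:
# the 47 integratively scored driver candidates and the 22 filtered
# driver-module associations. Both are plain-TSV transcriptions shipped under
# inst/extdata. Zero entries in the effect columns encode "layer absent".
# Signs follow the package convention that the aggregated miRNA effect
# opposes the expression direction of the target gene (one published row was
# normalized to that convention so that every printed score is reproduced by
# the additive concordance formula).

#' Packaged table of 47 integratively scored driver candidates
#'
#' Columns: `gene`, `chromosome`, `lr_cna` (copy-number log ratio), `fc_ge`
#' (log2 expression fold change), `fc_me` (methylation fold change, positive
#' = hypermethylated in tumor), `fc_mirna` (aggregated opposing miRNA fold
#' change) and the published integrative `score`. `0` in `lr_cna` / `fc_me` /
#' `fc_mirna` encodes an absent layer.
#'
#' @return 47-row `data.frame`.
#' @export
table1_fixture <- function() {
  read.delim(system.file("extdata", "table1_driver_candidates.tsv",
                         package = "omidriver"),
             colClasses = c("character", "character", rep("numeric", 5)))
}

#' Packaged table of 22 driver-module associations
#'
#' Columns: `regulator`, `module`, published `assignment_score`, module size
#' `n_genes`, `n_passengers`, annotation `categories` (comma-separated
#' abbreviations) and a `drug_target` flag.
#'
#' @return 22-row `data.frame`.
#' @export
table2_fixture <- function() {
  read.delim(system.file("extdata", "table2_driver_module_associations.tsv",
                         package = "omidriver"),
             colClasses = c("character", "integer", "numeric", "integer",
                            "integer", "character", "integer"))
}

#' Evidence table from the packaged driver-candidate fixture
#'
#' Converts [table1_fixture()] into the evidence layout of
#' [build_evidence()]: zero effect entries become `NA` (absent layer) and the
#' frequency criterion is marked met (`alpha_met = TRUE`), as stated for
#' every gene in the packaged table (alterations present in more than 20% of
#' patients; per-gene frequencies are not part of the table).
#'
#' @return Evidence `data.frame` with a `printed_score` column for
#'   comparison.
#' @export
evidence_from_table1 <- function() {
  t1 <- table1_fixture()
  zero_na <- function(x) ifelse(x == 0, NA_real_, x)
  data.frame(gene_id = t1$gene, ge_fc = t1$fc_ge,
             cna_lr = zero_na(t1$lr_cna), me_fc = zero_na(t1$fc_me),
             mirna_fc = zero_na(t1$fc_mirna),
             cna_fraction = NA_real_, alpha_met = TRUE,
             chromosome = t1$chromosome, printed_score = t1$score,
             stringsAsFactors = FALSE, row.names = NULL)
}
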