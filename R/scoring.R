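# Integrative driver scoring: per-gene evidence assembly across the four
# molecular layers, concordance classification, the alpha/beta bonus score
# and the driver/passenger split.
#
# An evidence table has one row per differentially expressed gene with
# columns gene_id, ge_fc, cna_lr, me_fc, mirna_fc, cna_fraction (and
# optionally chromosome / alpha_met). Absent layers are NA, never silent
# zeros.

#' Aggregate opposing miRNA regulation for one gene
#'
#' Selects the significantly deregulated miRNAs that (a) target the gene and
#' (b) change in the direction opposite to the gene's expression (candidate
#' active regulators), and returns the sum of their signed effects. `NA`
#' when no opposing regulator exists.
#'
#' @param gene_id Gene identifier.
#' @param mirna_diff Differential records from [diff_mirna()].
#' @param targets A [target_map()].
#' @param ge_direction Sign of the gene's expression change (+1 or -1).
#' @return Signed sum of opposing regulator effects, or `NA_real_`.
#' @export
aggregate_mirna <- function(gene_id, mirna_diff, targets, ge_direction) {
  stopifnot(ge_direction %in% c(-1, 1), inherits(targets, "target_map"))
  sig <- mirna_diff[mirna_diff$significant, , drop = FALSE]
  if (!nrow(sig)) return(NA_real_)
  hits <- vapply(sig$feature_id, function(mi) {
    tg <- targets$entries[[mi]]
    !is.null(tg) && gene_id %in% tg
  }, logical(1))
  opposing <- hits & sign(sig$effect) == -ge_direction
  if (!any(opposing)) return(NA_real_)
  sum(sig$effect[opposing])
}

#' Assemble per-gene four-layer evidence
#'
#' Builds the evidence table consumed by the scoring step from the per-layer
#' differential records. Only differentially expressed genes are kept; a
#' non-expression layer contributes its effect only where it was itself
#' called significant, and is `NA` (absent) otherwise.
#'
#' @param ge_diff Records from [diff_expression()].
#' @param cna_diff,me_diff Optional records from [diff_cna()] /
#'   [diff_methylation()].
#' @param mirna_diff Optional records from [diff_mirna()]; requires `targets`.
#' @param targets Optional [target_map()] used for miRNA aggregation.
#' @return Evidence `data.frame`.
#' @export
build_evidence <- function(ge_diff, cna_diff = NULL, me_diff = NULL,
                           mirna_diff = NULL, targets = NULL) {
  de <- ge_diff[ge_diff$significant, , drop = FALSE]
  blank <- rep(NA_real_, nrow(de))
  ev <- data.frame(gene_id = de$feature_id, ge_fc = de$effect,
                   cna_lr = blank, me_fc = blank, mirna_fc = blank,
                   cna_fraction = blank,
                   stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(cna_diff)) {
    sig <- cna_diff[cna_diff$significant, , drop = FALSE]
    idx <- match(ev$gene_id, sig$feature_id)
    ev$cna_lr <- sig$effect[idx]
    ev$cna_fraction <- sig$altered_fraction[idx]
  }
  if (!is.null(me_diff)) {
    sig <- me_diff[me_diff$significant, , drop = FALSE]
    ev$me_fc <- sig$effect[match(ev$gene_id, sig$feature_id)]
  }
  if (!is.null(mirna_diff)) {
    if (is.null(targets))
      stop("miRNA aggregation requires a target map")
    ev$mirna_fc <- vapply(seq_len(nrow(ev)), function(i)
      aggregate_mirna(ev$gene_id[i], mirna_diff, targets, sign(ev$ge_fc[i])),
      numeric(1))
  }
  ev
}

#' Classify layer concordance against the expression change
#'
#' Copy number is concordant when its sign matches the expression change;
#' methylation and miRNA are concordant when their signs oppose it (promoter
#' hypomethylation with overexpression, repressor loss with overexpression,
#' and vice versa). Absent (`NA`) layers are never concordant.
#'
#' @param evidence Evidence `data.frame` (see [build_evidence()]); `ge_fc`
#'   must be non-zero.
#' @return `data.frame` with `cna_concordant`, `me_concordant`,
#'   `mirna_concordant` and `n_other` (0-3).
#' @export
classify_concordance <- function(evidence) {
  if (any(evidence$ge_fc == 0))
    stop("ge_fc = 0: gene is not differentially expressed")
  ge_sign <- sign(evidence$ge_fc)
  conc <- function(x, want_sign) !is.na(x) & x != 0 & sign(x) == want_sign
  cna <- conc(evidence$cna_lr, ge_sign)
  me <- conc(evidence$me_fc, -ge_sign)
  mi <- conc(evidence$mirna_fc, -ge_sign)
  data.frame(cna_concordant = cna, me_concordant = me, mirna_concordant = mi,
             n_other = cna + me + mi, row.names = NULL)
}

#' Concordance-bonus integrative score
#'
#' For each gene the score is the sum of the absolute expression effect and
#' the absolute effects of every *concordant* non-expression layer,
#' multiplied by two bonuses: `alpha` (= `alpha_bonus` when the gene's
#' alterations meet the frequency criterion, else 1) and
#' `beta = 1 + n_other` (2 for one concordant companion event, 3 for two,
#' 4 when all three other layers agree with the expression change).
#' Discordant or absent layers contribute nothing.
#'
#' @param evidence Evidence `data.frame`. An optional logical column
#'   `alpha_met` forces the frequency criterion (used for packaged tables
#'   that state the criterion without per-gene frequencies).
#' @param profile Optional precomputed [classify_concordance()] output.
#' @param alpha_bonus Frequency bonus multiplier (default 2).
#' @param freq_threshold Minimum altered fraction of tumors for the alpha
#'   bonus (default 0.20).
#' @return `data.frame` of scored genes: evidence columns plus the
#'   concordance flags, `alpha`, `beta` and `score`.
#' @export
integrative_score <- function(evidence, profile = NULL, alpha_bonus = 2,
                              freq_threshold = 0.20) {
  if (is.null(profile)) profile <- classify_concordance(evidence)
  abs0 <- function(x, on) ifelse(on, abs(x), 0)
  total <- abs(evidence$ge_fc) +
    abs0(evidence$cna_lr, profile$cna_concordant) +
    abs0(evidence$me_fc, profile$me_concordant) +
    abs0(evidence$mirna_fc, profile$mirna_concordant)
  freq_met <- !is.na(evidence$cna_fraction) &
    evidence$cna_fraction >= freq_threshold
  if (!is.null(evidence$alpha_met)) freq_met <- freq_met | evidence$alpha_met
  alpha <- ifelse(freq_met, alpha_bonus, 1)
  beta <- 1L + profile$n_other
  cbind(evidence[setdiff(names(evidence), "alpha_met")], profile,
        data.frame(alpha = alpha, beta = beta, score = total * alpha * beta,
                   row.names = NULL))
}

#' Split scored genes into driver and passenger candidates
#'
#' Genes supported by fewer than `min_other_layers` concordant non-expression
#' layers are ineligible. Among eligible genes, drivers are those whose score
#' reaches the cutoff; `cutoff = "midpoint"` uses the midpoint between the
#' lowest and highest eligible score, a numeric value overrides it.
#'
#' @param scored Output of [integrative_score()].
#' @param cutoff `"midpoint"` or a numeric score cutoff.
#' @param min_other_layers Minimum concordant non-expression layers for
#'   eligibility (default 2).
#' @return List with `drivers`, `passengers` (character vectors), the
#'   `cutoff` used and the `scored` table extended by a `klass` column
#'   (`driver` / `passenger` / `ineligible`).
#' @export
select_candidates <- function(scored, cutoff = "midpoint", min_other_layers = 2L) {
  if (!nrow(scored)) stop("scored table is empty")
  eligible <- scored$n_other >= min_other_layers
  klass <- rep("ineligible", nrow(scored))
  if (!any(eligible)) {
    warning("no gene is supported by enough concordant layers")
    scored$klass <- klass
    return(list(drivers = character(0), passengers = character(0),
                cutoff = NA_real_, scored = scored))
  }
  if (identical(cutoff, "midpoint")) {
    s <- scored$score[eligible]
    cutoff <- (min(s) + max(s)) / 2
  } else if (!is.numeric(cutoff)) {
    stop("cutoff must be \"midpoint\" or numeric")
  }
  klass[eligible] <- ifelse(scored$score[eligible] >= cutoff,
                            "driver", "passenger")
  scored$klass <- klass
  list(drivers = scored$gene_id[klass == "driver"],
       passengers = scored$gene_id[klass == "passenger"],
       cutoff = cutoff, scored = scored)
}
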