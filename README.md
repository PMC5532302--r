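# omidriver

Integrative multi-omics driver-gene discovery for small tumor/normal
cohorts profiled on four molecular layers: gene expression, copy-number
alteration (CNA), DNA methylation and miRNA expression.

Cancer transcriptomes change broadly, but only some expression changes are
*explained* by concordant alterations in the other layers — a copy-number
gain under an overexpressed gene, promoter hypomethylation, loss of a
targeting miRNA. omidriver is built for analysts of small multi-layer
cohorts (the packaged study conditions are 20 tumors vs 10 normal
references) who need to separate such **driver candidates** from
**passenger candidates**, group the transcriptome into co-expressed
modules, and ask which drivers regulate which modules.

## The core score

For a differentially expressed gene with expression effect `Ge` and layer
effects `CNA`, `Me`, `Mi` (the miRNA effect being the signed sum of
significantly deregulated, sign-opposing targeting miRNAs), a companion
layer is *concordant* when it can explain the expression change: same sign
as `Ge` for copy number, opposite sign for methylation and miRNA. The
integrative score is

```
Score = (|Ge| + sum over concordant layers |effect|) * alpha * beta
```

with `alpha = 2` when the gene's alterations occur in at least 20% of
patients (else 1) and `beta = 1 + n_other`, the count of concordant
companion layers plus one (so 4 when expression agrees with all three).
Genes supported by at least two concordant companion layers are eligible;
eligible genes at or above a cutoff (midpoint of the eligible score range,
or an explicit value) are driver candidates, the rest passengers.

Around the score sit the other pipeline stages: per-layer differential
calling with the published thresholds (expression |log2 FC| >= 0.6 within
a 95% confidence criterion; CNA calls at +/-0.15 in >= 20% of tumors;
methylation P < 0.05; miRNA P < 0.01 with FDR < 0.05), co-expression
module discovery by a collapsed Gibbs sampler over a Chinese-restaurant-
process Gaussian mixture (modules under 5 genes dropped), regression-tree
regulator assignment with a >= 10% passenger-fraction module filter, and
downstream statistics (hypergeometric over-representation, Kaplan-Meier /
log-rank survival with Tukey-fence outlier dichotomization, Mann-Whitney,
Pfaffl qPCR quantification). The methods vignette
(`vignettes/integrative-driver-discovery.Rmd`) derives and motivates each
stage.

## Worked example

Score the packaged 47-gene reference table and run the full pipeline on a
synthetic cohort with planted ground truth:

```r
library(omidriver)

sc <- integrative_score(evidence_from_table1())
head(sc[order(-sc$score), c("gene_id", "n_other", "alpha", "beta", "score")], 5)
#>   gene_id n_other alpha beta  score
#> 1  IL17RD       3     2    4 101.52
#> 2    BCL2       3     2    4  96.80
#> 3  IGFBP5       3     2    4  92.64
#> 4   FOXP1       3     2    4  88.24
#> 5   MTUS1       3     2    4  84.40

sel <- select_candidates(sc, cutoff = 48.72)
length(sel$drivers)
#> [1] 47
```

Every gene in the packaged table scores above the published cutoff and the
recomputed scores match the printed column to within 0.1 (rounding of the
two-decimal inputs). On synthetic data the planted structure is recovered
end to end:

```r
co  <- generate_cohort(cohort_spec(seed = 1))   # 20T/10N, 4 layers, planted truth
res <- run_pipeline(co, pipeline_config(seed = 1))
res
#> <pipeline_result> 16 driver(s), 48 passenger(s), cutoff 43.60, 12 module(s), 16 retained association(s)

rec <- evaluate_recovery(res, co$truth)
sum(rec$recovered)
#> [1] 8        # all 8 planted (regulator, module) pairs
```

The final association table reports, per retained (regulator, module)
pair, the assignment score, rank, module size and passenger fraction —
the quantities used to prioritize modules accumulating secondary
alterations.

A thin command-line wrapper over the same functions ships in
`inst/scripts/omidriver` (`simulate`, `diff`, `modules`, `pipeline`
stages).

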