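test_that("concordance classification matches the packaged reference rows", {
  ev <- evidence_from_table1()
  prof <- classify_concordance(ev)
  rownames(prof) <- ev$gene_id
  # AR: copy-number loss with downexpression (concordant), hypomethylation
  # with downexpression (discordant), opposing miRNA up (concordant)
  expect_equal(unlist(prof["AR", ]),
               c(cna_concordant = TRUE, me_concordant = FALSE,
                 mirna_concordant = TRUE, n_other = 2))
  # IL17RD: all three companion layers agree
  expect_equal(prof["IL17RD", "n_other"], 3)
  # absent layers are never concordant
  solo <- data.frame(gene_id = "X", ge_fc = -2, cna_lr = NA_real_,
                     me_fc = NA_real_, mirna_fc = NA_real_,
                     cna_fraction = NA_real_)
  expect_equal(classify_concordance(solo)$n_other, 0)
  expect_error(classify_concordance(transform(solo, ge_fc = 0)),
               "not differentially expressed")
})

test_that("integrative score reproduces the packaged reference scores", {
  ev <- evidence_from_table1()
  sc <- integrative_score(ev)
  rownames(sc) <- sc$gene_id
  expect_equal(sc["AR", "score"], 79.20, tolerance = 1e-10)
  expect_equal(sc["FGFR2", "score"], 52.24, tolerance = 1e-10)
  expect_equal(sc["PML", "score"], 60.78, tolerance = 1e-10)
  expect_equal(sc["AR", "beta"], 3L)
  expect_equal(sc["FGFR2", "beta"], 4L)
  expect_true(all(abs(sc$score - ev$printed_score) <= 0.1))
  # degenerate beta = 1 case: no concordant companion layer, no alpha bonus
  lone <- data.frame(gene_id = "X", ge_fc = 1, cna_lr = NA_real_,
                     me_fc = NA_real_, mirna_fc = NA_real_, cna_fraction = 0.1)
  expect_equal(integrative_score(lone)$score, 1)
})

test_that("score is monotone in concordant evidence and symmetric under global sign flip", {
  set.seed(21)
  for (i in 1:20) {
    ge <- sample(c(-1, 1)) [1] * runif(1, 0.6, 5)
    ev <- data.frame(gene_id = "g", ge_fc = ge,
                     cna_lr = sign(ge) * runif(1, 0.1, 1),
                     me_fc = -sign(ge) * runif(1, 0.1, 2),
                     mirna_fc = NA_real_, cna_fraction = runif(1))
    s0 <- integrative_score(ev)$score
    # adding a concordant miRNA layer never decreases the score
    ev_mi <- transform(ev, mirna_fc = -sign(ge) * runif(1, 0.1, 8))
    expect_gt(integrative_score(ev_mi)$score, s0)
    # increasing a concordant |effect| strictly increases it
    ev_up <- transform(ev, cna_lr = cna_lr * 2)
    expect_gt(integrative_score(ev_up)$score, s0)
    # negating every layer leaves score and flags unchanged
    ev_neg <- transform(ev_mi, ge_fc = -ge_fc, cna_lr = -cna_lr,
                        me_fc = -me_fc, mirna_fc = -mirna_fc)
    expect_equal(integrative_score(ev_neg)$score,
                 integrative_score(ev_mi)$score)
    expect_equal(classify_concordance(ev_neg), classify_concordance(ev_mi))
  }
})

test_that("alpha and beta bonuses scale the evidence sum as stated", {
  ev <- data.frame(gene_id = "g", ge_fc = 2, cna_lr = 0.5, me_fc = -1,
                   mirna_fc = -3, cna_fraction = 0.5)
  s_full <- integrative_score(ev)$score            # alpha 2, beta 4
  ev_lowfreq <- transform(ev, cna_fraction = 0.1, mirna_fc = NA_real_)
  s_af <- integrative_score(ev_lowfreq)            # alpha 1, beta 3
  expect_equal(s_af$alpha, 1)
  expect_equal(s_full / (2 * 4), (2 + 0.5 + 1 + 3))
  expect_equal(s_af$score, (2 + 0.5 + 1) * 1 * 3)
})

test_that("miRNA aggregation sums opposing significant regulators only", {
  mk <- function(id, effect, sig = TRUE)
    data.frame(feature_id = id, layer = "mirna", effect = effect,
               statistic = 0, p_value = 0.001, q_value = 0.01,
               altered_fraction = 0.5, significant = sig)
  recs <- rbind(mk("m1", 3.1), mk("m2", 2.4), mk("m3", 2.53),
                mk("m4", 5, sig = FALSE), mk("m5", -2))
  tm <- target_map(list(m1 = "GENE", m2 = "GENE", m3 = "GENE",
                        m4 = "GENE", m5 = "GENE", m6 = "OTHER"))
  # downexpressed gene: the three up-regulated significant targeting miRNAs
  expect_equal(aggregate_mirna("GENE", recs, tm, -1), 8.03)
  # upregulated gene with only up-regulated targeting miRNAs: absent
  expect_true(is.na(aggregate_mirna("GENE", rbind(mk("m1", 3.1)), tm, 1)))
  # no targeting miRNA at all: absent
  expect_true(is.na(aggregate_mirna("LONE", recs, tm, -1)))
})

test_that("candidate selection splits eligible genes at the cutoff", {
  ev <- evidence_from_table1()
  sel <- select_candidates(integrative_score(ev), cutoff = 48.72)
  expect_length(sel$drivers, 47L)
  expect_length(sel$passengers, 0L)

  toy <- data.frame(gene_id = c("a", "b"), ge_fc = c(1, 1),
                    cna_lr = c(0.5, 0.5), me_fc = c(-1, -1),
                    mirna_fc = NA_real_, cna_fraction = c(0.5, 0.5))
  sc <- integrative_score(toy)
  sc$score <- c(10, 90)
  sel <- select_candidates(sc, "midpoint")
  expect_equal(sel$cutoff, 50)
  expect_equal(sel$drivers, "b")
  expect_equal(sel$passengers, "a")

  ineligible <- transform(sc, n_other = 1L)
  expect_warning(sel0 <- select_candidates(ineligible), "concordant layers")
  expect_length(sel0$drivers, 0L)
  expect_true(all(sel0$scored$klass == "ineligible"))
})

test_that("evidence assembly keeps only DE genes and marks absent layers NA", {
  ge <- data.frame(feature_id = c("A", "B", "C"), layer = "expression",
                   effect = c(2, -1, 0.1), statistic = 1, p_value = 0.01,
                   q_value = 0.02, altered_fraction = 0.5,
                   significant = c(TRUE, TRUE, FALSE))
  cna <- data.frame(feature_id = c("A", "C"), layer = "cna",
                    effect = c(0.4, 0.3), statistic = 0.5, p_value = NA,
                    q_value = NA, altered_fraction = c(0.45, 0.3),
                    significant = TRUE)
  ev <- build_evidence(ge, cna)
  expect_equal(ev$gene_id, c("A", "B"))
  expect_equal(ev$cna_lr, c(0.4, NA))
  expect_equal(ev$cna_fraction, c(0.45, NA))
  expect_true(all(is.na(ev$me_fc)))
})
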