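test_that("cohort generation is a deterministic function of the spec", {
  s <- cohort_spec(seed = 5, n_genes = 400, n_mirnas = 60, n_modules = 3,
                   n_drivers = 6, n_scattered = 10)
  a <- generate_cohort(s)
  b <- generate_cohort(s)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$cna$values, b$cna$values)
  expect_identical(a$methylation$values, b$methylation$values)
  expect_identical(a$mirna$values, b$mirna$values)
  expect_identical(a$targets$entries, b$targets$entries)
  expect_identical(a$clinical, b$clinical)
  # a different seed changes the draw
  expect_false(identical(a$expression$values,
                         generate_cohort(cohort_spec(seed = 6, n_genes = 400,
                                                     n_mirnas = 60,
                                                     n_modules = 3,
                                                     n_drivers = 6,
                                                     n_scattered = 10))$expression$values))
})

test_that("planted effects appear in the group means at the stated magnitudes", {
  co <- generate_cohort(cohort_spec(seed = 2))
  tr <- co$truth
  expr_eff <- rowMeans(group_values(co$expression, "tumor")) -
    rowMeans(group_values(co$expression, "normal"))
  # driver expression shifts recover the planted values within noise
  expect_equal(unname(expr_eff[tr$drivers$gene_id]), tr$drivers$ge_fc,
               tolerance = 0.5)
  # unplanted background genes center on zero
  background <- setdiff(rownames(co$expression$values),
                        c(tr$drivers$gene_id, unlist(tr$modules), tr$scattered))
  expect_lt(abs(mean(expr_eff[background])), 0.05)
  # methylation opposes expression for every driver
  me_eff <- rowMeans(group_values(co$methylation, "tumor")) -
    rowMeans(group_values(co$methylation, "normal"))
  expect_true(all(sign(me_eff[tr$drivers$gene_id]) ==
                    -sign(tr$drivers$ge_fc)))
  # copy number shares the expression sign in carrier tumors
  d_cna <- diff_cna(co$cna)
  idx <- match(tr$drivers$gene_id, d_cna$feature_id)
  expect_true(all(d_cna$significant[idx]))
  expect_true(all(sign(d_cna$effect[idx]) == sign(tr$drivers$ge_fc)))
})

test_that("planted opposing miRNAs always target their driver", {
  co <- generate_cohort(cohort_spec(seed = 9))
  d_mi <- diff_mirna(co$mirna)
  for (i in seq_len(nrow(co$truth$drivers))) {
    drv <- co$truth$drivers[i, ]
    mi_ids <- names(Filter(function(g) drv$gene_id %in% g, co$targets$entries))
    opposing <- d_mi[d_mi$feature_id %in% mi_ids & d_mi$significant &
                       sign(d_mi$effect) == -sign(drv$ge_fc), ]
    expect_gte(nrow(opposing), 1)
  }
})

test_that("driver scores dominate passenger scores on the default cohort", {
  co <- generate_cohort(cohort_spec(seed = 42))
  res <- run_pipeline(co, pipeline_config(seed = 42))
  sc <- res$scored
  d_scores <- sc$score[sc$gene_id %in% co$truth$drivers$gene_id]
  p_scores <- sc$score[sc$gene_id %in% co$truth$passengers]
  expect_gte(length(d_scores), 14)
  expect_gt(median(d_scores), quantile(p_scores, 0.95))
})

test_that("a cohort without planted effects yields indistinguishable classes", {
  # with zero effects essentially nothing passes the differential filters, so
  # either too few genes are scored to compare, or the rank-sum test finds no
  # separation between truth-labelled drivers and passengers
  ok <- vapply(1:5, function(s) {
    co <- generate_cohort(null_cohort_spec(seed = 200 + s))
    res <- suppressWarnings(run_pipeline(co, pipeline_config(seed = s)))
    sc <- res$scored
    if (is.null(sc)) return(TRUE)
    d <- sc$score[sc$gene_id %in% co$truth$drivers$gene_id]
    p <- sc$score[sc$gene_id %in% co$truth$passengers]
    if (length(d) < 3 || length(p) < 3) return(TRUE)
    mannwhitney(d, p)$p_value > 0.05
  }, logical(1))
  expect_true(all(ok))
})

test_that("clinical table links hazard to the prognostic gene", {
  co <- generate_cohort(cohort_spec(seed = 3, prognostic_hr = 6))
  expect_equal(co$clinical$sample_id, group_samples(co$expression, "tumor"))
  expect_true(all(co$clinical$time_months >= 0))
  expect_true(all(co$clinical$event %in% 0:1))
  z <- co$expression$values[co$truth$prognostic_gene, co$clinical$sample_id]
  grp <- ifelse(z > median(z), "high", "low")
  res <- logrank_test(co$clinical$time_months, co$clinical$event, grp)
  expect_lt(res$p_value, 0.2)  # strong planted hazard shows at n = 20
})

test_that("spec invariants are enforced", {
  expect_error(cohort_spec(n_drivers = 30, n_modules = 40), "n_modules")
  expect_error(cohort_spec(n_genes = 50), "n_genes too small")
  expect_error(cohort_spec(n_mirnas = 10), "n_mirnas too small")
  expect_error(cohort_spec(cna_penetrance = 0))
})
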