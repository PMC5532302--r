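test_that("hypergeometric ORA matches exhaustive enumeration", {
  universe <- sprintf("u%02d", 1:10)
  res <- ora_test(universe[1:3], universe[1:3], universe)
  # enumeration oracle: of all C(10,3) draws, exactly one contains the set
  draws <- combn(10, 3)
  p_enum <- mean(apply(draws, 2, function(d) sum(d %in% 1:3) >= 3))
  expect_equal(p_enum, 1 / 120)
  expect_equal(res$p_value, p_enum)
  # random instances against enumeration
  set.seed(13)
  for (i in 1:10) {
    mod <- sample(universe, 4)
    gs <- sample(universe, 5)
    obs <- length(intersect(mod, gs))
    p_enum <- mean(apply(combn(10, 4), 2,
                         function(d) sum(universe[d] %in% gs) >= obs))
    expect_equal(ora_test(mod, gs, universe)$p_value, p_enum,
                 tolerance = 1e-12)
  }
  # zero overlap is never significant
  expect_equal(ora_test(universe[1:3], universe[4:10], universe)$p_value, 1)
  expect_error(ora_test("a", "a", character(0)), "empty universe")
})

test_that("module enrichment adjusts jointly across all pairs", {
  members <- list(`1` = sprintf("g%d", 1:10), `2` = sprintf("g%d", 11:20))
  coll <- gene_set_collection(list(S1 = sprintf("g%d", 1:10),
                                   S2 = sprintf("g%d", 31:40)))
  res <- enrich_modules(members, coll, universe = sprintf("g%d", 1:40))
  expect_equal(nrow(res), 4L)
  hit <- res[res$module_id == "1" & res$set_id == "S1", ]
  expect_equal(hit$overlap, 10L)
  expect_lt(hit$p_value, 1e-6)
  expect_equal(res$q_value, bh_fdr(res$p_value))
})

test_that("degree summaries count association edges", {
  star <- data.frame(a = rep("hub", 5), b = sprintf("leaf%d", 1:5))
  expect_equal(ppi_degree(star)[["hub"]], 5L)
  expect_equal(unname(ppi_degree(data.frame(a = character(0),
                                            b = character(0)),
                                 nodes = c("x", "y"))), c(0L, 0L))
  t2 <- table2_fixture()
  deg <- ppi_degree(data.frame(a = t2$regulator, b = paste0("mod", t2$module)))
  expect_equal(deg[["BIRC5"]], 4L)
  expect_equal(deg[["STAT1"]], 2L)
  expect_equal(deg[["mod49"]], 2L)
})

test_that("outlier dichotomization uses Tukey fences on the reference", {
  labels <- dichotomize_by_outlier(c(9, 0, -3), c(1, 2, 3, 4, 5))
  expect_equal(as.character(labels), c("high", "neither", "low"))
  # all tumors inside the fences
  expect_true(all(dichotomize_by_outlier(c(1, 3), c(1, 2, 3, 4, 5)) == "neither"))
  # constant reference: collapsed fences, any deviation is an outlier
  expect_equal(as.character(dichotomize_by_outlier(c(2, 3), rep(2, 5))),
               c("neither", "high"))
  expect_error(dichotomize_by_outlier(1, c(1, 2)), ">= 3 reference")
})

test_that("log-rank statistic matches the hand-computed risk tables", {
  # deaths at 1,2 (group A) and 3,4 (group B), no censoring:
  # U = 7/6, V = 1/4 + 2/9 = 17/36, chi-square = 49/17
  res <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("A", "A", "B", "B"))
  expect_equal(res$statistic, 49 / 17, tolerance = 1e-10)
  expect_equal(res$p_value, pchisq(49 / 17, 1, lower.tail = FALSE))
  # identical event times in both groups
  sym <- logrank_test(c(1, 2, 1, 2), rep(1, 4), c("A", "A", "B", "B"))
  expect_equal(sym$statistic, 0, tolerance = 1e-10)
  expect_equal(sym$p_value, 1, tolerance = 1e-10)
  # fully censored cohort
  cens <- logrank_test(1:6, rep(0, 6), rep(c("A", "B"), 3))
  expect_equal(cens$statistic, 0)
  expect_equal(cens$p_value, 1)
  expect_error(logrank_test(1:3, c(1, 1, 1), c("A", "A", "A")), "two")
})

test_that("Kaplan-Meier curves equal the empirical survival without censoring", {
  res <- logrank_test(c(1, 2, 3, 10, 20, 30), rep(1, 6),
                      rep(c("A", "B"), each = 3))
  kmA <- res$km[res$km$group == "A", ]
  expect_equal(kmA$survival, c(2 / 3, 1 / 3, 0))
  # curves are non-increasing and start at or below 1
  expect_true(all(diff(kmA$survival) <= 0))
  expect_true(all(res$km$survival <= 1 & res$km$survival >= 0))
  # statistic invariant under time-units rescaling
  res_days <- logrank_test(c(1, 2, 3, 10, 20, 30) * 30.44, rep(1, 6),
                           rep(c("A", "B"), each = 3))
  expect_equal(res$statistic, res_days$statistic)
})

test_that("Mann-Whitney U equals the brute-force pair count", {
  expect_equal(mannwhitney(1:3, 4:6)$U, 0)
  expect_equal(mannwhitney(c(1, 2, 5), c(3, 4))$U,
               sum(outer(c(1, 2, 5), c(3, 4), ">")))
  expect_gt(mannwhitney(1:6, 1:6)$p_value, 0.9)
  set.seed(17)
  for (i in 1:10) {
    x <- rnorm(7); y <- rnorm(5)
    expect_equal(mannwhitney(x, y)$U, sum(outer(x, y, ">")))
  }
  expect_error(mannwhitney(numeric(0), 1), "non-empty")
})

test_that("Pfaffl ratio is the efficiency-corrected quotient", {
  expect_equal(pfaffl_ratio(2, 3, 2, 0), 8)
  expect_equal(pfaffl_ratio(2, 0, 2, 0), 1)
  expect_equal(pfaffl_ratio(1.9, 2, 2, 1), 1.9^2 / 2)
  expect_error(pfaffl_ratio(-1, 1, 2, 1), "positive")
  expect_warning(pfaffl_ratio(2.5, 1, 2, 1), "usually")
})
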