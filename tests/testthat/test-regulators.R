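test_that("regression tree splits a bimodal profile perfectly and stops on constants", {
  prof <- setNames(rep(c(-1, 1), each = 10), sprintf("S%02d", 1:20))
  tree <- build_tree(prof)
  expect_s3_class(tree, "regression_tree")
  root <- tree$root
  expect_false(root$leaf)
  expect_equal(root$split, 0)
  expect_equal(sort(root$left$samples), sprintf("S%02d", 1:10))
  # variance reduction at the root equals the total sum of squares
  expect_equal(root$ss_reduction, sum((prof - mean(prof))^2))

  const <- setNames(rep(2, 12), sprintf("S%02d", 1:12))
  t0 <- build_tree(const)
  expect_true(t0$root$leaf)
  expect_equal(score_association(t0, const + rnorm(12)), 0)
})

test_that("tree invariants hold and the root split matches a brute-force scan", {
  brute_best <- function(x, min_leaf = 5L) {
    cand <- sort(unique(x))
    best <- -Inf
    for (thr in cand[-length(cand)]) {
      l <- x[x <= thr]; r <- x[x > thr]
      if (length(l) < min_leaf || length(r) < min_leaf) next
      red <- sum((x - mean(x))^2) - sum((l - mean(l))^2) - sum((r - mean(r))^2)
      if (red > best) best <- red
    }
    best
  }
  set.seed(3)
  for (i in 1:10) {
    prof <- setNames(rnorm(40), sprintf("S%02d", 1:40))
    tree <- build_tree(prof)
    expect_equal(tree$root$ss_reduction, brute_best(prof), tolerance = 1e-10)
    # leaves are disjoint, cover all samples, and respect min_leaf
    leaves <- omidriver:::tree_leaves(tree)
    leaf_samples <- unlist(lapply(leaves, `[[`, "samples"))
    expect_equal(sort(leaf_samples), sort(names(prof)))
    expect_true(all(lengths(lapply(leaves, `[[`, "samples")) >= 5))
    # children partition their parent at every internal node
    for (nd in omidriver:::internal_nodes(tree)) {
      expect_setequal(c(nd$left$samples, nd$right$samples), nd$samples)
      expect_gte(nd$ss_reduction, 0)
    }
  }
})

test_that("association scoring favours the module's own driver and ignores scale", {
  set.seed(5)
  state <- rep(c(0, 1), each = 10)
  prof <- setNames(2 * state - 1, sprintf("S%02d", 1:20))
  tree <- build_tree(prof)
  self_score <- score_association(tree, prof)
  decoys <- replicate(30, score_association(tree,
    setNames(rnorm(20), names(prof))))
  expect_gt(self_score, max(decoys))
  # constant regulator scores zero
  expect_equal(score_association(tree, setNames(rep(1, 20), names(prof))), 0)
  # affine rescaling leaves the score unchanged (t statistics are scale-free)
  reg <- setNames(state * 2 + rnorm(20), names(prof))
  expect_equal(score_association(tree, reg),
               score_association(tree, 3.7 * reg - 11), tolerance = 1e-10)
})

test_that("ranking keeps a ceil top percentage with deterministic tie-breaks", {
  set.seed(8)
  assoc <- expand.grid(regulator_id = sprintf("r%02d", 1:81),
                       module_id = sprintf("m%02d", 1:81),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  assoc$score <- runif(nrow(assoc))            # 6561 associations
  top <- rank_top(assoc, 1)
  expect_equal(nrow(top), 66L)
  expect_equal(top$rank, 1:66)
  expect_true(all(diff(top$score) <= 0))
  # prefix property: top 1% is a prefix of top 5%
  top5 <- rank_top(assoc, 5)
  expect_equal(top5[1:66, c("regulator_id", "module_id")],
               top[, c("regulator_id", "module_id")])
  # ceil rule on tiny sets
  expect_equal(nrow(rank_top(assoc[1:5, ], 1)), 1L)
  # equal scores break ties by regulator then module id
  tie <- data.frame(regulator_id = c("b", "a"), module_id = c("1", "1"),
                    score = c(0.5, 0.5))
  expect_equal(rank_top(tie, 100)$regulator_id, c("a", "b"))
  expect_error(rank_top(assoc, 0), "top_percent")
  expect_error(rank_top(assoc, 101), "top_percent")
})

test_that("passenger filter recomputes fractions and keeps the packaged associations", {
  mem <- table2_membership()
  t2 <- table2_fixture()
  assoc <- data.frame(regulator_id = t2$regulator,
                      module_id = as.character(t2$module),
                      score = t2$assignment_score)
  kept <- passenger_filter(rank_top(assoc, 100), mem$passengers, mem$members)
  expect_equal(nrow(kept), 22L)
  expect_equal(length(unique(kept$module_id)), 19L)
  expect_equal(length(unique(kept$regulator_id)), 16L)
  # module 48: 17 of 70 genes are passengers -> 24%
  m48 <- kept[kept$module_id == "48", ][1, ]
  expect_equal(m48$passenger_count, 17L)
  expect_equal(round(100 * m48$passenger_fraction), 24)
  # three modules carry two regulators
  expect_equal(sum(table(kept$module_id) == 2L), 3L)
  # a passenger-free module is dropped
  clean <- passenger_filter(
    data.frame(regulator_id = "r", module_id = "m", score = 1, rank = 1L),
    passengers = character(0), members = list(m = sprintf("g%d", 1:10)))
  expect_equal(nrow(clean), 0L)
  expect_error(passenger_filter(assoc[1, ], "x", list(`38` = character(0))),
               "empty module")
})

test_that("planted regulator ranks first among decoys in most trials", {
  hits <- vapply(1:20, function(s) regulator_benchmark(seed = s)$top1,
                 logical(1))
  expect_gte(mean(hits), 0.8)
})
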