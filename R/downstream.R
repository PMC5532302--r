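# Post-pipeline biomarker statistics: hypergeometric over-representation of
# module genes in annotation sets, interaction-degree summaries, Tukey-fence
# expression dichotomization against a normal-tissue reference,
# Kaplan-Meier / log-rank survival comparison, Mann-Whitney rank tests and
# Pfaffl efficiency-corrected relative quantification.

#' Hypergeometric over-representation test
#'
#' One-sided upper-tail probability `P(X >= overlap)` of drawing at least the
#' observed overlap when `module_size` genes are sampled without replacement
#' from a universe containing `set_size` annotated genes.
#'
#' @param module_genes Character vector of module member ids.
#' @param gene_set Character vector of annotation-set member ids.
#' @param universe Character vector of all considered gene ids; both inputs
#'   must be subsets of it.
#' @return List with `overlap`, `module_size`, `set_size`, `universe_size`,
#'   `p_value`.
#' @export
ora_test <- function(module_genes, gene_set, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  module_genes <- unique(module_genes); gene_set <- unique(gene_set)
  if (length(setdiff(module_genes, universe)) ||
      length(setdiff(gene_set, universe)))
    stop("module and gene set must be subsets of the universe")
  overlap <- length(intersect(module_genes, gene_set))
  p <- phyper(overlap - 1L, length(gene_set),
              length(universe) - length(gene_set), length(module_genes),
              lower.tail = FALSE)
  list(overlap = overlap, module_size = length(module_genes),
       set_size = length(gene_set), universe_size = length(universe),
       p_value = p)
}

#' Over-representation of every module in every annotation set
#'
#' Applies [ora_test()] across all (module, set) pairs and adjusts the
#' p-values jointly by Benjamini-Hochberg.
#'
#' @param members Named list module id -> member gene ids, or a `module_set`.
#' @param collection A [gene_set_collection()].
#' @param universe Gene universe (defaults to the union of all module
#'   members and set members).
#' @return `data.frame` with one row per (module, set) pair.
#' @export
enrich_modules <- function(members, collection, universe = NULL) {
  if (inherits(members, "module_set")) members <- module_members(members)
  if (is.null(universe))
    universe <- union(unlist(members), unlist(collection$sets))
  grid <- expand.grid(module_id = names(members),
                      set_id = names(collection$sets),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- mapply(function(m, s) {
    r <- ora_test(intersect(members[[m]], universe),
                  intersect(collection$sets[[s]], universe), universe)
    c(r$overlap, r$module_size, r$set_size, r$p_value)
  }, grid$module_id, grid$set_id)
  grid$overlap <- as.integer(res[1, ])
  grid$module_size <- as.integer(res[2, ])
  grid$set_size <- as.integer(res[3, ])
  grid$universe_size <- length(unique(universe))
  grid$p_value <- res[4, ]
  grid$q_value <- bh_fdr(grid$p_value)
  grid
}

#' Node degrees of an interaction table
#'
#' @param edges `data.frame` with two id columns (see [read_edges()]), e.g.
#'   a bipartite driver-module association list.
#' @param nodes Optional ids to report (defaults to all ids seen in the
#'   edges); unknown ids get degree 0.
#' @return Named integer vector of degrees.
#' @export
ppi_degree <- function(edges, nodes = NULL) {
  ids <- c(as.character(edges[[1]]), as.character(edges[[2]]))
  tab <- table(ids)
  if (is.null(nodes)) nodes <- sort(names(tab))
  out <- setNames(integer(length(nodes)), nodes)
  hit <- intersect(nodes, names(tab))
  out[hit] <- as.integer(tab[hit])
  out
}

#' Dichotomize tumor expression by outliers of a reference distribution
#'
#' Tukey fences (`Q1 - 1.5 IQR`, `Q3 + 1.5 IQR`) are computed on the
#' normal-reference values; tumor samples above the upper fence are `high`,
#' below the lower fence `low`, otherwise `neither`. A constant reference
#' collapses both fences onto its value, so any deviation from it is an
#' outlier.
#'
#' @param tumor_expr Named numeric vector of tumor expression values.
#' @param reference_expr Numeric vector of >= 3 normal-reference values.
#' @return Character vector (`high` / `low` / `neither`) aligned with
#'   `tumor_expr`, with the fences in attribute `"fences"`.
#' @export
dichotomize_by_outlier <- function(tumor_expr, reference_expr) {
  if (length(reference_expr) < 3L) stop("need >= 3 reference values")
  q <- quantile(reference_expr, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(lower = q[1] - 1.5 * iqr, upper = q[2] + 1.5 * iqr)
  labels <- ifelse(tumor_expr > fences["upper"], "high",
            ifelse(tumor_expr < fences["lower"], "low", "neither"))
  attr(labels, "fences") <- fences
  labels
}

#' Log-rank test with Kaplan-Meier curves
#'
#' Standard two-group log-rank chi-square (1 df) with right censoring,
#' computed through [survival::survdiff()]; per-group Kaplan-Meier curves
#' come from [survival::survfit()]. A cohort without any event returns
#' statistic 0 and P = 1.
#'
#' @param times Follow-up times (e.g. months).
#' @param events Event indicator (1 = death, 0 = censored).
#' @param groups Two-level grouping vector (e.g. `high` / `low`).
#' @return List of class `survival_comparison` with `statistic`, `p_value`,
#'   and `km`, a `data.frame` of step-function points (`group`, `time`,
#'   `survival`, `n_risk`).
#' @export
logrank_test <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2L)
    stop("exactly two non-empty groups are required")
  stopifnot(length(times) == length(events), length(times) == length(groups))
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  km <- data.frame(
    group = rep(sub("^groups=", "", names(fit$strata)), fit$strata),
    time = fit$time, survival = fit$surv, n_risk = fit$n.risk)
  if (sum(events) == 0) {
    out <- list(statistic = 0, p_value = 1, km = km)
  } else {
    sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
    out <- list(statistic = unname(sd$chisq),
                p_value = pchisq(sd$chisq, df = 1L, lower.tail = FALSE),
                km = km)
  }
  structure(out, class = "survival_comparison")
}

#' @export
print.survival_comparison <- function(x, ...) {
  cat(sprintf("<survival_comparison> log-rank chi-square = %.4g, P = %.4g\n",
              x$statistic, x$p_value))
  invisible(x)
}

#' Mann-Whitney rank test
#'
#' Exact U statistic (number of `(x_i, y_j)` pairs with `x_i > y_j`, ties
#' counted half) with a two-sided p-value from the tie-corrected normal
#' approximation, via [stats::wilcox.test()].
#'
#' @param x,y Non-empty numeric samples.
#' @return List with `U` and `p_value`.
#' @export
mannwhitney <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  wt <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Pfaffl efficiency-corrected relative expression ratio
#'
#' `ratio = E_target^dCt_target / E_ref^dCt_ref`, with amplification
#' efficiencies `E` in \[1, 2\] (2 = perfect doubling per cycle) and
#' `dCt = Ct(control) - Ct(sample)`.
#'
#' @param e_target,e_ref Amplification efficiencies of the target and
#'   reference assays.
#' @param dct_target,dct_ref Ct differences (control - sample).
#' @return Relative expression ratio.
#' @export
pfaffl_ratio <- function(e_target, dct_target, e_ref, dct_ref) {
  if (e_target <= 0 || e_ref <= 0) stop("efficiencies must be positive")
  if (e_target > 2 || e_ref > 2 || e_target < 1 || e_ref < 1)
    warning("amplification efficiencies are usually in [1, 2]")
  e_target^dct_target / e_ref^dct_ref
}
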