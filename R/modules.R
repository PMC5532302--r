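# Co-expression module discovery: collapsed Gibbs sampling over a
# Chinese-restaurant-process mixture of diagonal Gaussians, followed by a
# minimum-size filter. The reported partition is the post-burn-in sample
# with the highest joint log posterior (MAP-sample reporting), so a given
# input + seed always yields one deterministic module set.

#' Gibbs sampler parameters
#'
#' @param n_iter Total sweeps (default 500).
#' @param burn_in Sweeps discarded before MAP tracking starts (default 250;
#'   must be < `n_iter`).
#' @param concentration CRP concentration gamma (default 1): larger values
#'   favour more modules a priori.
#' @param prior_scale,prior_shape,prior_rate Normal-Gamma hyperparameters
#'   (lambda0, a0, b0) of the per-dimension Gaussian components; the prior
#'   mean is 0, matching standardized profiles.
#' @param min_module_size Minimum retained module size (default 5).
#' @param seed Integer seed driving the per-gene sampling streams.
#' @return Validated parameter list of class `gibbs_params`.
#' @export
gibbs_params <- function(n_iter = 500L, burn_in = 250L, concentration = 1,
                         prior_scale = 1, prior_shape = 2, prior_rate = 1,
                         min_module_size = 5L, seed = 1L) {
  stopifnot(burn_in < n_iter, burn_in >= 0, n_iter >= 1,
            concentration > 0, prior_scale > 0, prior_shape > 0,
            prior_rate > 0, min_module_size >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 concentration = concentration, prior_scale = prior_scale,
                 prior_shape = prior_shape, prior_rate = prior_rate,
                 min_module_size = as.integer(min_module_size),
                 seed = as.integer(seed)),
            class = "gibbs_params")
}

# Deterministic 31-bit stream seed for one gene id, mixed with the run seed.
# Keeps each gene's sampling stream a function of (seed, gene id) only, so
# the chain does not depend on input row order.
gene_stream_seed <- function(seed, gene_id) {
  h <- 0
  for (c in utf8ToInt(gene_id)) h <- (h * 31 + c) %% 2147483629
  as.integer((h + as.double(seed) * 2654435761) %% 2147483629) + 1L
}

#' Cluster gene expression profiles into co-expression modules
#'
#' Runs a collapsed Gibbs sampler over tumor-sample expression profiles
#' (each gene standardized to mean 0 / variance 1 across samples): a
#' Chinese-restaurant-process mixture of diagonal Gaussians with
#' Normal-Gamma conjugate priors. Each sweep resamples every gene's module
#' from the collapsed Student-t predictive of each existing module plus a
#' fresh one; the returned partition is the post-burn-in sample with the
#' highest joint log posterior. Genes are swept in sorted-id order with
#' per-gene random streams derived from `(seed, gene id)`, so the result is
#' invariant to input row order and fully determined by the seed.
#'
#' @param expr An `"expression"` [omics_matrix()] (tumor columns are used) or
#'   a plain numeric gene x sample matrix.
#' @param params A [gibbs_params()] list.
#' @return A list of class `module_set`: `assignment` (named integer vector;
#'   module ids 1..K labelled by decreasing size), `n_modules`, `sizes`,
#'   `log_posterior`, `initial_log_posterior`, `trace`, `params`.
#' @export
gibbs_cluster <- function(expr, params = gibbs_params()) {
  x <- if (inherits(expr, "omics_matrix")) group_values(expr, "tumor") else expr
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  if (ncol(x) < 2L) stop("need >= 2 samples to cluster")
  x <- x[order(rownames(x)), , drop = FALSE]
  mu <- rowMeans(x); s <- apply(x, 1L, sd)
  s[s == 0 | is.na(s)] <- 1
  xs <- (x - mu) / s
  genes <- rownames(xs)
  if (nrow(xs) < params$min_module_size) {
    warning("fewer genes than min_module_size: returning a single unfiltered module")
    assignment <- setNames(rep(1L, nrow(xs)), genes)
    return(structure(list(assignment = assignment, n_modules = 1L,
                          sizes = c(`1` = nrow(xs)),
                          log_posterior = NA_real_,
                          initial_log_posterior = NA_real_,
                          trace = numeric(0), params = params),
                     class = "module_set"))
  }
  u <- vapply(genes, function(g) {
    set.seed(gene_stream_seed(params$seed, g))
    runif(params$n_iter)
  }, numeric(params$n_iter))
  if (params$n_iter == 1L) u <- matrix(u, nrow = 1L)
  fit <- gibbs_crp_cpp(xs, u, params$concentration, params$prior_scale,
                       params$prior_shape, params$prior_rate,
                       params$n_iter, params$burn_in)
  raw <- fit$assignment + 1L
  # canonical labels: 1..K by decreasing size, ties by smallest member id
  tab <- table(raw)
  first_gene <- tapply(genes, raw, min)
  ord <- order(-as.integer(tab), first_gene[names(tab)])
  relabel <- setNames(seq_along(ord), names(tab)[ord])
  assignment <- setNames(as.integer(relabel[as.character(raw)]), genes)
  sizes <- table(assignment)
  structure(list(assignment = assignment,
                 n_modules = length(sizes),
                 sizes = setNames(as.integer(sizes), names(sizes)),
                 log_posterior = fit$log_posterior,
                 initial_log_posterior = fit$initial_log_posterior,
                 trace = fit$trace, params = params),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("<module_set> %d module(s), %d assigned / %d gene(s), log posterior %.2f\n",
              x$n_modules, sum(!is.na(x$assignment)), length(x$assignment),
              x$log_posterior))
  invisible(x)
}

#' Drop modules below the minimum size
#'
#' Removes modules smaller than `min_size`; their genes become unassigned
#' (`NA`). Retained modules keep their membership and are relabelled
#' 1..K by decreasing size.
#'
#' @param ms A `module_set`.
#' @param min_size Minimum retained module size (default 5).
#' @return Filtered `module_set`.
#' @export
filter_modules <- function(ms, min_size = 5L) {
  stopifnot(inherits(ms, "module_set"))
  sizes <- table(ms$assignment)
  keep <- names(sizes)[as.integer(sizes) >= min_size]
  assignment <- ms$assignment
  assignment[!(as.character(assignment) %in% keep)] <- NA_integer_
  if (length(keep)) {
    # compress labels while preserving their original (numeric) order, so
    # filtering a set where every module survives is the identity
    keep <- keep[order(suppressWarnings(as.numeric(keep)))]
    relabel <- setNames(seq_along(keep), keep)
    assignment[!is.na(assignment)] <-
      as.integer(relabel[as.character(assignment[!is.na(assignment)])])
  }
  new_sizes <- table(assignment)
  ms$assignment <- assignment
  ms$n_modules <- length(new_sizes)
  ms$sizes <- setNames(as.integer(new_sizes), names(new_sizes))
  ms
}

#' Module membership as a named list
#' @param ms A `module_set`.
#' @return List mapping module id -> character vector of member gene ids
#'   (unassigned genes are omitted).
#' @export
module_members <- function(ms) {
  a <- ms$assignment[!is.na(ms$assignment)]
  split(names(a), a)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between an inferred partition and a reference
#' labelling (1 = identical up to relabelling, ~0 = random). Wraps
#' [mclust::adjustedRandIndex()].
#'
#' @param a,b Two label vectors over the same items (names are aligned when
#'   both are named).
#' @return Numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  mclust::adjustedRandIndex(a, b)
}
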