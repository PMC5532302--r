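# Module-network regulator assignment: a regression tree partitions the
# cohort samples on the module's mean expression profile; candidate
# regulators are scored by how sharply their own expression separates the
# tree's sample partitions (sample-size-weighted sum of absolute Welch t
# statistics over internal nodes). Associations are ranked, cut at a top
# percentage, and filtered by the module's passenger-candidate fraction.

#' Regression tree over samples on a module profile
#'
#' Recursively splits the sample set by thresholding the module profile at
#' the value that maximizes the within-node sum-of-squares reduction
#' (exhaustive scan over midpoints of consecutive distinct sorted values).
#' Recursion stops when a child would fall below `min_leaf` samples, at
#' `max_depth`, or when no split reduces the SS (e.g. a constant profile,
#' which yields a depth-0 single-leaf tree).
#'
#' @param module_profile Named numeric vector: per-sample mean expression of
#'   the module's member genes.
#' @param min_leaf Minimum samples per leaf (default 5).
#' @param max_depth Maximum depth (default 3; root = depth 0 counts as a
#'   split level).
#' @return A list of class `regression_tree`; nodes carry `samples`, `mean`,
#'   `sd`, and internal nodes add `split` (threshold), `ss_reduction`,
#'   `left`, `right`.
#' @export
build_tree <- function(module_profile, min_leaf = 5L, max_depth = 3L) {
  stopifnot(is.numeric(module_profile), !is.null(names(module_profile)))
  if (length(module_profile) < 2L * min_leaf)
    stop("need at least 2 * min_leaf samples")
  grow <- function(idx, depth) {
    x <- module_profile[idx]
    node <- list(samples = names(x), mean = mean(x), sd = sd(x))
    if (depth >= max_depth || length(x) < 2L * min_leaf) {
      node$leaf <- TRUE
      return(node)
    }
    best <- find_split(x, min_leaf)
    if (is.null(best)) {
      node$leaf <- TRUE
      return(node)
    }
    node$leaf <- FALSE
    node$split <- best$threshold
    node$ss_reduction <- best$reduction
    node$left <- grow(idx[x <= best$threshold], depth + 1L)
    node$right <- grow(idx[x > best$threshold], depth + 1L)
    node
  }
  root <- grow(seq_along(module_profile), 0L)
  structure(list(root = root, n_samples = length(module_profile)),
            class = "regression_tree")
}

# Best SS-reducing threshold on a numeric vector, or NULL when no valid
# split exists. Thresholds are midpoints between consecutive distinct sorted
# values; both children must hold >= min_leaf samples.
find_split <- function(x, min_leaf) {
  n <- length(x)
  ord <- order(x)
  xs <- x[ord]
  # cumulative sums give left/right SS for every split position in O(n)
  cs <- cumsum(xs); css <- cumsum(xs^2)
  tot_ss <- css[n] - cs[n]^2 / n
  pos <- which(diff(xs) > 0)                       # split after position i
  pos <- pos[pos >= min_leaf & (n - pos) >= min_leaf]
  if (!length(pos)) return(NULL)
  ss_left <- css[pos] - cs[pos]^2 / pos
  ss_right <- (css[n] - css[pos]) - (cs[n] - cs[pos])^2 / (n - pos)
  reduction <- tot_ss - ss_left - ss_right
  best <- which.max(reduction)
  if (reduction[best] <= 0) return(NULL)
  list(threshold = unname((xs[pos[best]] + xs[pos[best] + 1L]) / 2),
       reduction = unname(reduction[best]))
}

# Flat list of internal nodes of a regression_tree
internal_nodes <- function(tree) {
  out <- list()
  walk <- function(node) {
    if (isTRUE(node$leaf)) return(invisible())
    out[[length(out) + 1L]] <<- node
    walk(node$left); walk(node$right)
  }
  walk(tree$root)
  out
}

# Leaf nodes of a regression_tree
tree_leaves <- function(tree) {
  out <- list()
  walk <- function(node) {
    if (isTRUE(node$leaf)) { out[[length(out) + 1L]] <<- node; return(invisible()) }
    walk(node$left); walk(node$right)
  }
  walk(tree$root)
  out
}

#' Score one regulator against a module's regulatory program
#'
#' For every internal node of the tree the regulator's expression is compared
#' between the left and right sample partitions by a Welch t statistic; the
#' association score is the sum of |t| weighted by the fraction of cohort
#' samples under each node. A constant regulator, or a depth-0 tree, scores
#' 0. The score is invariant under affine rescaling of the regulator values.
#'
#' @param tree A [build_tree()] result.
#' @param regulator_expr Named numeric vector covering the tree's samples.
#' @return Nonnegative numeric score.
#' @export
score_association <- function(tree, regulator_expr) {
  stopifnot(inherits(tree, "regression_tree"))
  nodes <- internal_nodes(tree)
  if (!length(nodes)) return(0)
  if (sd(regulator_expr, na.rm = TRUE) == 0) return(0)
  missing <- setdiff(unlist(lapply(nodes, function(n)
    c(n$left$samples, n$right$samples))), names(regulator_expr))
  if (length(missing))
    stop("regulator expression missing for sample(s): ",
         paste(head(missing, 5), collapse = ", "))
  total <- tree$n_samples
  sum(vapply(nodes, function(node) {
    xl <- regulator_expr[node$left$samples]
    xr <- regulator_expr[node$right$samples]
    vl <- if (length(xl) > 1L) var(xl) else 0
    vr <- if (length(xr) > 1L) var(xr) else 0
    se <- sqrt(max(vl / length(xl) + vr / length(xr), 1e-16))
    w <- (length(xl) + length(xr)) / total
    w * abs(mean(xl) - mean(xr)) / se
  }, numeric(1)))
}

#' Score every regulator x module pair
#'
#' Builds one regression tree per module (on the per-sample mean profile of
#' its member genes) and scores every candidate regulator against it.
#'
#' @param expr Gene x sample numeric matrix (tumor samples) or an
#'   `"expression"` [omics_matrix()].
#' @param ms A `module_set` (filtered or not); unassigned genes are ignored.
#' @param regulators Character vector of candidate regulator gene ids
#'   present in `expr`.
#' @param min_leaf,max_depth Tree controls, see [build_tree()].
#' @return `data.frame` with columns `regulator_id`, `module_id`, `score`.
#' @export
assign_regulators <- function(expr, ms, regulators, min_leaf = 5L, max_depth = 3L) {
  x <- if (inherits(expr, "omics_matrix")) group_values(expr, "tumor") else expr
  members <- module_members(ms)
  if (!length(members)) stop("module set has no assigned modules")
  regulators <- intersect(regulators, rownames(x))
  if (!length(regulators)) stop("no candidate regulator present in the matrix")
  trees <- lapply(members, function(g) {
    prof <- colMeans(x[intersect(g, rownames(x)), , drop = FALSE])
    build_tree(prof, min_leaf = min_leaf, max_depth = max_depth)
  })
  grid <- expand.grid(regulator_id = regulators, module_id = names(members),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$score <- mapply(function(r, m)
    score_association(trees[[m]], x[r, ]), grid$regulator_id, grid$module_id)
  grid
}

#' Rank associations and keep the top percentage
#'
#' Sorts by score descending (ties broken by regulator id then module id,
#' ascending) and keeps `ceil(top_percent/100 * N)` associations with ranks
#' 1..k.
#'
#' @param associations `data.frame` with `regulator_id`, `module_id`, `score`.
#' @param top_percent Percentage kept, in (0, 100\] (default 1).
#' @return The retained associations with a `rank` column.
#' @export
rank_top <- function(associations, top_percent = 1) {
  if (!nrow(associations)) stop("no associations to rank")
  if (!is.numeric(top_percent) || top_percent <= 0 || top_percent > 100)
    stop("top_percent must lie in (0, 100]")
  ord <- order(-associations$score, associations$regulator_id,
               associations$module_id)
  k <- ceiling(top_percent / 100 * nrow(associations))
  out <- associations[ord[seq_len(k)], , drop = FALSE]
  out$rank <- seq_len(k)
  rownames(out) <- NULL
  out
}

#' Passenger-enrichment filter over ranked associations
#'
#' Computes the passenger-candidate fraction of every module and keeps only
#' associations whose module reaches `min_fraction` (the accumulation of
#' secondary alterations that marks disease-relevant modules).
#'
#' @param associations Ranked associations (see [rank_top()]).
#' @param passengers Character vector of passenger-candidate gene ids.
#' @param members Named list module id -> member gene ids (see
#'   [module_members()]), or a `module_set`.
#' @param min_fraction Minimum passenger fraction (default 0.10).
#' @return Associations extended by `module_size`, `passenger_count`,
#'   `passenger_fraction`, restricted to modules passing the filter.
#' @export
passenger_filter <- function(associations, passengers, members,
                             min_fraction = 0.10) {
  if (inherits(members, "module_set")) members <- module_members(members)
  sizes <- lengths(members)
  if (any(sizes == 0L)) stop("empty module in membership map")
  counts <- vapply(members, function(g) length(intersect(g, passengers)),
                   integer(1))
  idx <- match(as.character(associations$module_id), names(members))
  if (anyNA(idx)) stop("association references unknown module")
  associations$module_size <- as.integer(sizes[idx])
  associations$passenger_count <- counts[idx]
  associations$passenger_fraction <- counts[idx] / sizes[idx]
  out <- associations[associations$passenger_fraction >= min_fraction, ,
                      drop = FALSE]
  rownames(out) <- NULL
  out
}
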