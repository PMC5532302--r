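#' Construct a single-layer omics matrix
#'
#' The basic container for one molecular layer: a feature x sample matrix of
#' real values (log2 expression ratios, copy-number log ratios, signed
#' methylation signal, or log2 miRNA expression) with a tumor/normal label for
#' every sample column.
#'
#' @param values Numeric matrix with unique rownames (feature ids) and unique
#'   colnames (sample ids). Missing values (`NA`) are permitted.
#' @param layer One of `"expression"`, `"cna"`, `"methylation"`, `"mirna"`.
#' @param group Named character vector mapping every sample id to `"tumor"` or
#'   `"normal"`.
#' @return An object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, layer = c("expression", "cna", "methylation", "mirna"),
                         group) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  fid <- rownames(values); sid <- colnames(values)
  if (is.null(fid) || is.null(sid))
    stop("`values` must carry feature rownames and sample colnames")
  if (anyDuplicated(fid)) stop("duplicate feature ids")
  if (anyDuplicated(sid)) stop("duplicate sample ids")
  group <- vapply(group, as.character, character(1))
  missing_grp <- setdiff(sid, names(group))
  if (length(missing_grp))
    stop("samples without a group label: ", paste(missing_grp, collapse = ", "))
  group <- group[sid]
  if (!all(group %in% c("tumor", "normal")))
    stop("group labels must be 'tumor' or 'normal'")
  structure(list(values = values, layer = layer, group = group),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix> layer=%s  %d features x %d samples (%d tumor / %d normal)\n",
              x$layer, nrow(x$values), ncol(x$values),
              sum(x$group == "tumor"), sum(x$group == "normal")))
  invisible(x)
}

#' Sample ids of one group
#' @param m An `omics_matrix`.
#' @param group `"tumor"` or `"normal"`.
#' @return Character vector of sample ids.
#' @export
group_samples <- function(m, group = c("tumor", "normal")) {
  group <- match.arg(group)
  names(m$group)[m$group == group]
}

#' Submatrix of tumor (or normal) columns
#' @inheritParams group_samples
#' @return Numeric matrix restricted to the requested group.
#' @export
group_values <- function(m, group = c("tumor", "normal")) {
  m$values[, group_samples(m, group), drop = FALSE]
}

#' Read a tab-separated feature x sample matrix
#'
#' The single matrix dialect used throughout: tab-separated text, first column
#' the feature id, header row of sample ids, decimal point `.`, missing values
#' `NA`. Duplicate feature rows are collapsed by their mean with a warning;
#' features with more than `max_missing` missing entries are dropped (the
#' count is reported). Rows are canonically sorted by feature id, so the
#' result does not depend on the row order of the file.
#'
#' @param path Path to the TSV file.
#' @param layer Molecular layer of the matrix (see [omics_matrix()]).
#' @param groups Either a named character vector (sample id -> group) or the
#'   path to a two-column TSV sidecar `sample_id<TAB>group`.
#' @param max_missing Maximum tolerated fraction of missing entries per
#'   feature (default 0.2); features above it are dropped with a warning.
#' @return A validated [omics_matrix()].
#' @export
read_matrix <- function(path, layer, groups, max_missing = 0.2) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L)
    stop("malformed header: expected a feature-id column plus >=1 sample column")
  sample_ids <- header[-1]
  if (anyDuplicated(sample_ids))
    stop("malformed header: repeated sample id ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = c("character", rep("numeric", length(sample_ids))))
  feats <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (anyDuplicated(feats)) {
    dup <- unique(feats[duplicated(feats)])
    warning(sprintf("%d duplicated feature id(s) collapsed by mean: %s",
                    length(dup), paste(head(dup, 5), collapse = ", ")))
    vals <- rowsum(vals, group = feats, reorder = FALSE) /
      as.vector(table(factor(feats, levels = unique(feats))))
    feats <- unique(feats)
  }
  rownames(vals) <- feats
  frac_na <- rowMeans(is.na(vals))
  if (any(frac_na > max_missing)) {
    warning(sprintf("dropping %d feature(s) with > %.0f%% missing values",
                    sum(frac_na > max_missing), 100 * max_missing))
    vals <- vals[frac_na <= max_missing, , drop = FALSE]
  }
  vals <- vals[order(rownames(vals)), , drop = FALSE]
  if (is.character(groups) && length(groups) == 1L && file.exists(groups))
    groups <- read_groups(groups)
  absent <- setdiff(colnames(vals), names(groups))
  if (length(absent))
    stop("sample(s) absent from the group specification: ",
         paste(absent, collapse = ", "))
  omics_matrix(vals, layer = layer, group = groups)
}

#' Read a two-column sample group sidecar
#' @param path TSV with columns `sample_id` and `group`.
#' @return Named character vector sample id -> group.
#' @export
read_groups <- function(path) {
  g <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  if (ncol(g) < 2L) stop("group sidecar needs two columns (sample_id, group)")
  setNames(g[[2]], g[[1]])
}

#' Write an omics matrix back to TSV
#' @param m An `omics_matrix`.
#' @param path Output path.
#' @param id_column Name for the feature-id column (default `feature_id`).
#' @export
write_matrix <- function(m, path, id_column = "feature_id") {
  df <- data.frame(rownames(m$values), m$values, check.names = FALSE)
  names(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Gene set collection
#'
#' @param sets Named list of character vectors (unique member ids).
#' @param description Optional named character vector of set descriptions.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("sets must have unique names")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) < 1L)) stop("empty gene sets are not allowed")
  if (is.null(description))
    description <- setNames(rep("", length(sets)), names(sets))
  structure(list(sets = sets, description = description[names(sets)]),
            class = "gene_set_collection")
}

#' Read / write GMT gene set files
#'
#' Standard GMT dialect: one set per line, tab-separated
#' `set_id<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path Path to a GMT file.
#' @return [gene_set_collection()] for `read_gmt`; the path, invisibly, for
#'   `write_gmt`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad))
    stop(sprintf("GMT format error at line %d: fewer than 3 tab-separated fields", bad[1]))
  ids <- vapply(parts, `[[`, character(1), 1L)
  desc <- vapply(parts, `[[`, character(1), 2L)
  sets <- lapply(parts, function(p) p[-(1:2)])
  gene_set_collection(setNames(sets, ids), setNames(desc, ids))
}

#' @param collection A `gene_set_collection`.
#' @rdname read_gmt
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$sets), function(id) {
    paste(c(id, collection$description[[id]], collection$sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' miRNA -> target map
#'
#' @param entries Named list: miRNA id -> character vector of target gene ids.
#' @param min_algorithms Metadata: minimum number of prediction algorithms
#'   supporting each edge in the source map (the packaged convention is >= 6).
#' @return An object of class `target_map`.
#' @export
target_map <- function(entries, min_algorithms = 6L) {
  if (is.null(names(entries)) || anyDuplicated(names(entries)))
    stop("entries must be named by unique miRNA ids")
  entries <- lapply(entries, function(g) unique(as.character(g)))
  if (any(lengths(entries) < 1L)) stop("empty target sets are not allowed")
  if (min_algorithms < 1L) stop("min_algorithms must be >= 1")
  structure(list(entries = entries, min_algorithms = as.integer(min_algorithms)),
            class = "target_map")
}

#' Read a two-column miRNA target map
#' @param path TSV with header and columns `mirna_id`, `gene_id` (one edge per row).
#' @param min_algorithms See [target_map()].
#' @return A [target_map()].
#' @export
read_target_map <- function(path, min_algorithms = 6L) {
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  if (ncol(df) < 2L) stop("target map needs two columns (mirna_id, gene_id)")
  target_map(split(df[[2]], df[[1]]), min_algorithms = min_algorithms)
}

#' Read a clinical follow-up table
#'
#' @param path TSV with header and columns `sample_id`, `time_months`,
#'   `event` (1 = death, 0 = censored); any further columns are kept as
#'   categorical covariates.
#' @return A `data.frame` with validated survival columns.
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  req <- c("sample_id", "time_months", "event")
  if (!all(req %in% names(df)))
    stop("clinical table must have columns: ", paste(req, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in clinical table")
  if (any(df$time_months < 0, na.rm = TRUE)) stop("time_months must be >= 0")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0 (censored) or 1 (death)")
  df
}

#' Read an interaction edge list
#'
#' @param path TSV with header and two id columns; edges are unordered,
#'   self-loops are rejected, duplicates are removed with a warning.
#' @return A `data.frame` with columns `a` and `b`.
#' @export
read_edges <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  if (ncol(df) < 2L) stop("edge list needs two columns")
  a <- df[[1]]; b <- df[[2]]
  if (any(a == b)) stop("self-loops are not allowed")
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  if (anyDuplicated(key)) {
    warning(sprintf("%d duplicate edge(s) removed", sum(duplicated(key))))
    keep <- !duplicated(key)
    a <- a[keep]; b <- b[keep]
  }
  data.frame(a = a, b = b, stringsAsFactors = FALSE)
}

#' Cross-layer cohort validation
#'
#' Checks that the molecular layers of a cohort can be integrated: reports
#' tumor/normal counts per layer and pairwise tumor-sample intersections,
#' fails when any layer carries fewer than two tumors or two normals or when
#' two layers share no tumor samples, and warns about tumor samples missing
#' from the clinical table.
#'
#' @param matrices Named list of [omics_matrix()] objects (>= 1).
#' @param clinical Optional clinical `data.frame` (see [read_clinical()]).
#' @return A list of class `cohort_report` with per-layer counts and pairwise
#'   tumor/normal intersections.
#' @export
validate_cohort <- function(matrices, clinical = NULL) {
  if (!length(matrices)) stop("at least one matrix is required")
  if (is.null(names(matrices)))
    names(matrices) <- vapply(matrices, `[[`, character(1), "layer")
  counts <- t(vapply(matrices, function(m)
    c(tumor = sum(m$group == "tumor"), normal = sum(m$group == "normal")),
    integer(2)))
  low <- counts[, "tumor"] < 2L | counts[, "normal"] < 2L
  if (any(low))
    stop("layer(s) with fewer than 2 tumors or 2 normals: ",
         paste(rownames(counts)[low], collapse = ", "))
  layers <- names(matrices)
  pairs <- if (length(layers) > 1L) t(utils::combn(layers, 2L)) else
    matrix(character(0), ncol = 2)
  inter <- data.frame(layer_a = pairs[, 1], layer_b = pairs[, 2],
                      tumor = rep(NA_integer_, nrow(pairs)),
                      normal = rep(NA_integer_, nrow(pairs)),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(inter))) {
    ma <- matrices[[inter$layer_a[i]]]; mb <- matrices[[inter$layer_b[i]]]
    it <- length(intersect(group_samples(ma, "tumor"), group_samples(mb, "tumor")))
    if (it == 0L)
      stop(sprintf("disjoint tumor sample sets between layers '%s' and '%s': integration impossible",
                   inter$layer_a[i], inter$layer_b[i]))
    inter$tumor[i] <- it
    inter$normal[i] <- length(intersect(group_samples(ma, "normal"),
                                        group_samples(mb, "normal")))
  }
  missing_clinical <- character(0)
  if (!is.null(clinical)) {
    tumors <- unique(unlist(lapply(matrices, group_samples, "tumor")))
    missing_clinical <- setdiff(tumors, clinical$sample_id)
    if (length(missing_clinical))
      warning("tumor sample(s) missing from the clinical table: ",
              paste(missing_clinical, collapse = ", "))
  }
  structure(list(counts = counts, intersections = inter,
                 missing_clinical = missing_clinical),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n per-layer sample counts:\n")
  print(x$counts)
  if (nrow(x$intersections)) {
    cat(" pairwise shared samples:\n")
    print(x$intersections, row.names = FALSE)
  }
  if (length(x$missing_clinical))
    cat(" tumors without clinical record:",
        paste(x$missing_clinical, collapse = ", "), "\n")
  invisible(x)
}

#' Pipeline configuration with validated defaults
#'
#' Collects every tunable threshold of the integrative pipeline in one place.
#' Defaults follow the study conditions of the packaged analysis: expression
#' |log2 FC| >= 0.6 inside a 95% confidence criterion, copy-number call
#' thresholds of +/-0.15 present in >= 20% of tumors, methylation P < 0.05,
#' miRNA P < 0.01 with FDR < 0.05, alpha bonus 2 at the 20% frequency
#' criterion, eligibility at >= 2 concordant non-expression layers, module
#' size >= 5 and a >= 10% passenger fraction for retained modules.
#'
#' @param ... Named overrides of any default listed above plus
#'   `top_percent` (association ranking depth, default 10 at cohort scale),
#'   `cutoff` (`"midpoint"` or numeric), `gibbs` (a [gibbs_params()] list)
#'   and `seed`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    fc_threshold = 0.6, ci_level = 0.95,
    gain_thr = 0.15, loss_thr = -0.15, cna_min_fraction = 0.20,
    me_alpha = 0.05, mirna_p = 0.01, mirna_fdr = 0.05,
    alpha_bonus = 2, freq_threshold = 0.20, min_other_layers = 2L,
    cutoff = "midpoint",
    gibbs = gibbs_params(n_iter = 200L, burn_in = 100L),
    min_module_size = 5L,
    top_percent = 10, min_passenger_fraction = 0.10,
    seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown configuration field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  stopifnot(cfg$fc_threshold >= 0, cfg$ci_level > 0, cfg$ci_level < 1,
            cfg$gain_thr > 0, cfg$loss_thr < 0,
            cfg$cna_min_fraction >= 0, cfg$cna_min_fraction <= 1,
            cfg$me_alpha > 0, cfg$me_alpha < 1,
            cfg$mirna_p > 0, cfg$mirna_p < 1,
            cfg$mirna_fdr > 0, cfg$mirna_fdr <= 1,
            cfg$alpha_bonus >= 1,
            cfg$freq_threshold >= 0, cfg$freq_threshold <= 1,
            cfg$min_other_layers >= 0, cfg$min_other_layers <= 3,
            cfg$top_percent > 0, cfg$top_percent <= 100,
            cfg$min_passenger_fraction >= 0, cfg$min_passenger_fraction <= 1,
            cfg$min_module_size >= 1)
  structure(cfg, class = "pipeline_config")
}
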