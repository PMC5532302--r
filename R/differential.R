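# Per-layer differential alteration calling. Each diff_* function returns one
# data.frame ("differential records") with the columns
#   feature_id, layer, effect, statistic, p_value, q_value,
#   altered_fraction, significant
# where `effect` is on the log scale of the input layer and `significant`
# encodes the layer's published selection criterion exactly.

# Vectorized Welch two-sample statistics over matrix rows.
# Returns effect (rowMeans x - rowMeans y), t statistic, Welch-Satterthwaite
# df, two-sided p and the half-width needed for a ci_level CI of the mean
# difference. Zero-variance rows are handled with an epsilon guard: equal
# means give t = 0 / p = 1, separated constants give a huge t / p ~ 0.
welch_rows <- function(x, y, ci_level = 0.95) {
  nx <- rowSums(!is.na(x)); ny <- rowSums(!is.na(y))
  mx <- rowMeans(x, na.rm = TRUE); my <- rowMeans(y, na.rm = TRUE)
  vx <- apply(x, 1L, var, na.rm = TRUE); vy <- apply(y, 1L, var, na.rm = TRUE)
  vx[is.na(vx)] <- 0; vy[is.na(vy)] <- 0
  effect <- mx - my
  se2 <- vx / nx + vy / ny
  df <- se2^2 / (vx^2 / (nx^2 * (nx - 1)) + vy^2 / (ny^2 * (ny - 1)))
  df[!is.finite(df)] <- nx[!is.finite(df)] + ny[!is.finite(df)] - 2
  eps <- 1e-12
  tstat <- effect / sqrt(pmax(se2, eps))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  zero_se <- se2 < eps
  p[zero_se & abs(effect) < eps] <- 1
  tstat[zero_se & abs(effect) < eps] <- 0
  half_width <- qt(1 - (1 - ci_level) / 2, df) * sqrt(pmax(se2, eps))
  data.frame(effect = effect, statistic = tstat, df = df, p_value = p,
             ci_lower = effect - half_width, ci_upper = effect + half_width)
}

# Fraction of tumor samples lying on the effect side of the normal-group
# mean; a simple per-sample alteration proxy for the test-based layers.
directional_fraction <- function(tum, nor, effect) {
  ref <- rowMeans(nor, na.rm = TRUE)
  up <- rowMeans(tum > ref, na.rm = TRUE)
  down <- rowMeans(tum < ref, na.rm = TRUE)
  ifelse(effect >= 0, up, down)
}

#' Differential expression with a fold-change + confidence criterion
#'
#' A gene is differentially expressed when the absolute tumor - normal mean
#' log2 difference reaches `fc_threshold` *and* the Welch confidence interval
#' of the difference (at `ci_level`) excludes zero.
#'
#' @param m [omics_matrix()] of layer `"expression"`.
#' @param fc_threshold Minimum |mean log2 difference| (default 0.6).
#' @param ci_level Confidence level of the Welch interval (default 0.95).
#' @return Differential-record `data.frame`, one row per gene.
#' @export
diff_expression <- function(m, fc_threshold = 0.6, ci_level = 0.95) {
  stopifnot(inherits(m, "omics_matrix"), m$layer == "expression")
  tum <- group_values(m, "tumor"); nor <- group_values(m, "normal")
  if (ncol(tum) < 2L || ncol(nor) < 2L)
    stop("need >= 2 tumor and >= 2 normal samples")
  w <- welch_rows(tum, nor, ci_level)
  ci_excludes_zero <- w$ci_lower > 0 | w$ci_upper < 0
  data.frame(
    feature_id = rownames(m$values), layer = "expression",
    effect = w$effect, statistic = w$statistic, p_value = w$p_value,
    q_value = bh_fdr(w$p_value),
    altered_fraction = directional_fraction(tum, nor, w$effect),
    significant = abs(w$effect) >= fc_threshold & ci_excludes_zero,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Copy-number alteration calling by per-sample thresholds and frequency
#'
#' Per tumor sample a gene is called gained when its log ratio reaches
#' `gain_thr` and lost when it falls below `loss_thr`. The dominant direction
#' is the more frequent call (ties resolved by the sign of the overall tumor
#' mean; a zero mean leaves the gene not significant), the reported effect is
#' the mean log ratio over the tumors carrying the dominant call, and the
#' gene is significant when `altered_fraction = max(freq_gain, freq_loss)`
#' reaches `min_fraction`.
#'
#' @param m [omics_matrix()] of layer `"cna"`.
#' @param gain_thr,loss_thr Per-sample call thresholds (defaults +0.15 / -0.15).
#' @param min_fraction Minimum fraction of tumors carrying the dominant call
#'   (default 0.20).
#' @return Differential-record `data.frame`. The frequency criterion is a
#'   call-rate rule, not a test, so `p_value`/`q_value` are `NA`.
#' @export
diff_cna <- function(m, gain_thr = 0.15, loss_thr = -0.15, min_fraction = 0.20) {
  stopifnot(inherits(m, "omics_matrix"), m$layer == "cna")
  tum <- group_values(m, "tumor")
  if (ncol(tum) < 5L)
    stop("need >= 5 tumor samples for a meaningful frequency criterion")
  all_na <- rowSums(!is.na(tum)) == 0L
  if (any(all_na)) {
    warning(sprintf("dropping %d gene(s) with no copy-number values", sum(all_na)))
    tum <- tum[!all_na, , drop = FALSE]
  }
  freq_gain <- rowMeans(tum >= gain_thr, na.rm = TRUE)
  freq_loss <- rowMeans(tum <= loss_thr, na.rm = TRUE)
  overall_mean <- rowMeans(tum, na.rm = TRUE)
  direction <- ifelse(freq_gain > freq_loss, 1,
               ifelse(freq_loss > freq_gain, -1, sign(overall_mean)))
  altered_fraction <- pmax(freq_gain, freq_loss)
  effect <- vapply(seq_len(nrow(tum)), function(i) {
    x <- tum[i, ]
    carriers <- if (direction[i] > 0) x[!is.na(x) & x >= gain_thr]
                else if (direction[i] < 0) x[!is.na(x) & x <= loss_thr]
                else numeric(0)
    if (length(carriers)) mean(carriers) else overall_mean[i]
  }, numeric(1))
  data.frame(
    feature_id = rownames(tum), layer = "cna",
    effect = effect, statistic = altered_fraction,
    p_value = NA_real_, q_value = NA_real_,
    altered_fraction = altered_fraction,
    significant = altered_fraction >= min_fraction & direction != 0,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential methylation by Welch test
#'
#' @param m [omics_matrix()] of layer `"methylation"`.
#' @param alpha Significance level (default 0.05). Positive effects denote
#'   hypermethylation in tumors.
#' @return Differential-record `data.frame`.
#' @export
diff_methylation <- function(m, alpha = 0.05) {
  stopifnot(inherits(m, "omics_matrix"), m$layer == "methylation")
  tum <- group_values(m, "tumor"); nor <- group_values(m, "normal")
  if (ncol(tum) < 2L || ncol(nor) < 2L)
    stop("need >= 2 samples per group")
  w <- welch_rows(tum, nor)
  data.frame(
    feature_id = rownames(m$values), layer = "methylation",
    effect = w$effect, statistic = w$statistic, p_value = w$p_value,
    q_value = bh_fdr(w$p_value),
    altered_fraction = directional_fraction(tum, nor, w$effect),
    significant = w$p_value < alpha,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential miRNA expression with a joint P and FDR criterion
#'
#' Per-miRNA two-sample (Welch) t-test; q-values by Benjamini-Hochberg over
#' all tested miRNAs; significant when `p < p_thr` and `q < fdr_thr`.
#'
#' @param m [omics_matrix()] of layer `"mirna"`.
#' @param p_thr Raw P threshold (default 0.01).
#' @param fdr_thr FDR threshold (default 0.05).
#' @return Differential-record `data.frame`.
#' @export
diff_mirna <- function(m, p_thr = 0.01, fdr_thr = 0.05) {
  stopifnot(inherits(m, "omics_matrix"), m$layer == "mirna")
  tum <- group_values(m, "tumor"); nor <- group_values(m, "normal")
  if (ncol(tum) < 2L || ncol(nor) < 2L)
    stop("need >= 2 samples per group")
  w <- welch_rows(tum, nor)
  q <- bh_fdr(w$p_value)
  data.frame(
    feature_id = rownames(m$values), layer = "mirna",
    effect = w$effect, statistic = w$statistic, p_value = w$p_value,
    q_value = q,
    altered_fraction = directional_fraction(tum, nor, w$effect),
    significant = w$p_value < p_thr & q < fdr_thr,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Thin validated front end over [stats::p.adjust()] with `method = "BH"`:
#' `q_i = min_{j : p_(j) >= p_(i)} m p_(j) / j`, capped at 1 and returned in
#' the original order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
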