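#' Normalize spectral counts to the 0-100 range per protein
#'
#' Each protein row is scaled so that its largest spectral count maps to 100
#' (the usual semi-quantitative SpC normalization). All-zero rows are left at
#' zero. The transform is monotone within each protein, so rank-based
#' statistics (Spearman networks) are unchanged by it.
#'
#' @param m protein x sample spectral-count matrix.
#' @return numeric matrix of the same shape with values in [0, 100].
#' @examples
#' m <- matrix(c(2, 5, 10), nrow = 1, dimnames = list("p1", c("s1", "s2", "s3")))
#' normalize_spc(m)
#' @export
normalize_spc <- function(m) {
  validate_spc_matrix(m)
  rmax <- apply(m, 1L, max)
  scale <- ifelse(rmax > 0, 100 / rmax, 0)
  m * scale
}

#' Prevalence filter: proteins identified in at least a fraction of samples
#'
#' A protein is "identified" in a sample when its spectral count is positive.
#' Proteins identified in at least `min_fraction` of the considered samples
#' are retained; with the default 0.51, 7 of 13 samples (53.8\%) passes while
#' 7 of 14 (exactly 50\%) does not.
#'
#' @param m spectral-count matrix.
#' @param samples sample ids to consider (e.g. one condition grouping).
#' @param min_fraction minimum identification fraction, default 0.51;
#'   the comparison is `fraction >= min_fraction`.
#' @return character vector of retained protein ids.
#' @export
prevalence_filter <- function(m, samples = colnames(m), min_fraction = 0.51) {
  validate_spc_matrix(m)
  if (length(samples) == 0L) stop("empty sample set")
  missing <- setdiff(samples, colnames(m))
  if (length(missing) > 0L) {
    stop("sample(s) not in matrix: ", paste(missing, collapse = ", "))
  }
  frac <- rowMeans(m[, samples, drop = FALSE] > 0)
  rownames(m)[frac >= min_fraction]
}

#' Differential-expression selection by one-way F ratio
#'
#' For each protein, computes the fixed-effects F ratio (between-condition
#' mean square over within-condition mean square) across the base
#' conditions, with an upper-tail p-value on (k - 1, N - k) degrees of
#' freedom. A protein is selected when `p_value < alpha` and
#' `f_ratio > f_min` (defaults 0.05 and 3). For a single feature this F is
#' the univariate discriminant F ratio. Zero within-condition variance with
#' unequal means yields `F = Inf`, `p = 0` (selected); identical values
#' everywhere yield `F = 0`, `p = 1`.
#'
#' No multiple-testing correction is applied; the selection is a per-protein
#' screen.
#'
#' @param m matrix of (normalized) abundances, proteins x samples.
#' @param meta sample metadata (`sample`, `condition`).
#' @param alpha p-value threshold, default 0.05.
#' @param f_min F-ratio threshold, default 3.
#' @return data.frame with columns `protein`, `f_ratio`, `p_value`,
#'   `selected`.
#' @export
f_ratio_selection <- function(m, meta, alpha = 0.05, f_min = 3) {
  validate_metadata(meta)
  meta <- meta[meta$sample %in% colnames(m), , drop = FALSE]
  m <- m[, meta$sample, drop = FALSE]
  grp <- factor(meta$condition)
  sizes <- table(grp)
  if (length(sizes) < 2L || any(sizes < 2L)) {
    stop("need >= 2 conditions with >= 2 samples each")
  }
  k <- nlevels(grp)
  n <- ncol(m)
  grand <- rowMeans(m)
  group_means <- vapply(levels(grp), function(g) {
    rowMeans(m[, grp == g, drop = FALSE])
  }, numeric(nrow(m)))
  if (is.null(dim(group_means))) group_means <- matrix(group_means, nrow = 1)
  ssb <- as.vector((group_means - grand)^2 %*% as.vector(sizes))
  ssw <- rowSums((m - group_means[, as.integer(grp), drop = FALSE])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  f <- ifelse(msw > 0, msb / msw, ifelse(msb > 0, Inf, 0))
  p <- ifelse(is.infinite(f), 0,
              ifelse(f == 0 & msw == 0, 1, stats::pf(f, k - 1, n - k, lower.tail = FALSE)))
  data.frame(protein = rownames(m), f_ratio = f, p_value = p,
             selected = p < alpha & f > f_min,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Proteins identified in a base condition
#'
#' @param m spectral-count matrix.
#' @param meta sample metadata.
#' @param condition one base condition label.
#' @param min_samples minimum number of samples of the condition with a
#'   positive count (default 1).
#' @return character vector of protein ids present in the condition.
#' @export
condition_presence <- function(m, meta, condition, min_samples = 1L) {
  validate_metadata(meta)
  if (!condition %in% base_conditions()) {
    stop("unknown condition: ", condition)
  }
  samples <- meta$sample[meta$condition == condition]
  samples <- intersect(samples, colnames(m))
  if (length(samples) == 0L) stop("no samples for condition ", condition)
  hits <- rowSums(m[, samples, drop = FALSE] > 0)
  rownames(m)[hits >= min_samples]
}
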