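#' All-pairs Spearman correlation of protein profiles
#'
#' Computes, for every protein pair, the Spearman rank correlation across the
#' given samples (Pearson correlation of average-ranked values, the standard
#' tie handling) and a two-sided p-value from the t transform
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom
#' (`|rho| = 1` gives p = 0). Proteins whose ranks have zero variance
#' (constant profiles) have no defined correlation; they are excluded and
#' reported in `dropped`.
#'
#' The t approximation is the usual choice at these sample sizes; it is
#' anti-conservative in the extreme tails (`|rho| -> 1`) compared with the
#' exact permutation law.
#'
#' @param m abundance matrix (raw or 0-100 normalized; the result is
#'   identical because ranks are unchanged).
#' @param samples sample ids to use, default all columns.
#' @return object of class `correlation_result`: list with `rho` and `p`
#'   (symmetric matrices), `n_used` (number of samples), `proteins`,
#'   `dropped`.
#' @export
spearman_all_pairs <- function(m, samples = colnames(m)) {
  if (length(samples) < 4L) stop("need >= 4 samples")
  missing <- setdiff(samples, colnames(m))
  if (length(missing) > 0L) {
    stop("sample(s) not in matrix: ", paste(missing, collapse = ", "))
  }
  sub <- m[, samples, drop = FALSE]
  ranks <- t(apply(sub, 1L, rank))          # average ranks for ties
  constant <- apply(ranks, 1L, function(r) max(r) == min(r))
  dropped <- rownames(sub)[constant]
  ranks <- ranks[!constant, , drop = FALSE]
  n <- length(samples)
  rho <- stats::cor(t(ranks))
  rho <- pmin(pmax(rho, -1), 1)
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[abs(rho) == 1] <- 0
  diag(p) <- 0
  structure(list(rho = rho, p = p, n_used = n,
                 proteins = rownames(ranks), dropped = dropped),
            class = "correlation_result")
}

#' Build a signed co-expression network from correlation results
#'
#' An edge joins each protein pair with `|rho| > rho_min` and `p < p_max`
#' (both strict; a pair at exactly rho = 0.7 is excluded). Edges carry
#' `rho`, `p` and `sign` ("positive"/"negative") attributes. By default
#' proteins without any passing edge are dropped from the node set, matching
#' the convention that co-expression network sizes count connected proteins
#' only.
#'
#' @param cres a `correlation_result` from [spearman_all_pairs()].
#' @param rho_min absolute-correlation threshold, default 0.7.
#' @param p_max p-value threshold, default 0.01.
#' @param keep_isolated keep proteins with no passing edge as isolated
#'   nodes? Default FALSE.
#' @return an undirected [igraph::graph] with edge attributes `rho`, `p`,
#'   `sign`.
#' @export
build_coexpression_network <- function(cres, rho_min = 0.7, p_max = 0.01,
                                       keep_isolated = FALSE) {
  stopifnot(inherits(cres, "correlation_result"))
  rho <- cres$rho
  p <- cres$p
  hit <- abs(rho) > rho_min & p < p_max
  hit[lower.tri(hit, diag = TRUE)] <- FALSE
  idx <- which(hit, arr.ind = TRUE)
  prot <- cres$proteins
  edges <- data.frame(from = prot[idx[, 1]], to = prot[idx[, 2]],
                      rho = rho[idx], p = p[idx],
                      sign = ifelse(rho[idx] > 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  vertices <- if (keep_isolated) prot else sort(unique(c(edges$from, edges$to)))
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = vertices))
}

#' Build one co-expression network per condition grouping
#'
#' For each grouping (Fe sufficiency / starvation, Mo sufficiency /
#' starvation), the grouping's pooled samples are taken, the prevalence
#' filter is applied on those same samples, and a signed Spearman network is
#' built from the retained proteins.
#'
#' @param m spectral-count matrix.
#' @param meta sample metadata.
#' @param groupings named list of grouping -> base conditions, default
#'   [condition_groupings()].
#' @param min_fraction prevalence threshold, default 0.51.
#' @param rho_min,p_max edge thresholds (defaults 0.7, 0.01).
#' @param keep_isolated see [build_coexpression_network()].
#' @return named list of igraph networks, one per grouping.
#' @export
build_grouping_networks <- function(m, meta, groupings = condition_groupings(),
                                    min_fraction = 0.51, rho_min = 0.7,
                                    p_max = 0.01, keep_isolated = FALSE) {
  validate_spc_matrix(m)
  validate_metadata(meta)
  out <- lapply(groupings, function(members) {
    samples <- meta$sample[meta$condition %in% members]
    retained <- prevalence_filter(m, samples, min_fraction)
    if (length(retained) < 2L) {
      return(igraph::make_empty_graph(directed = FALSE))
    }
    cres <- spearman_all_pairs(m[retained, , drop = FALSE], samples)
    build_coexpression_network(cres, rho_min, p_max, keep_isolated)
  })
  names(out) <- names(groupings)
  out
}
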