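#' Betweenness centrality (unnormalized, undirected)
#'
#' Unweighted shortest-path betweenness with each unordered node pair counted
#' once and endpoints excluded: for node v,
#' `B(v) = sum over pairs {s,t} != v of sigma_st(v) / sigma_st`,
#' where `sigma_st` is the number of shortest s--t paths. Pairs in different
#' components contribute nothing.
#'
#' @param net undirected simple igraph.
#' @return named numeric vector of betweenness values.
#' @export
betweenness_centrality <- function(net) {
  if (igraph::vcount(net) == 0L) return(stats::setNames(numeric(0), character(0)))
  b <- igraph::betweenness(net, directed = FALSE, normalized = FALSE)
  stats::setNames(as.numeric(b), igraph::V(net)$name)
}

#' Centroid centrality (per connected component)
#'
#' For node v, `C(v) = min over other nodes w in v's component of
#' f(v, w)` with `f(v, w) = gamma_v(w) - gamma_w(v)`, where `gamma_v(w)`
#' counts the nodes strictly closer to v than to w (equidistant nodes count
#' for neither). Positive values mark nodes near the topological center of
#' their component. Computed from BFS distance matrices per component;
#' a singleton component scores 0.
#'
#' @param net undirected simple igraph.
#' @return named numeric vector of centroid values (integers).
#' @export
centroid_centrality <- function(net) {
  n <- igraph::vcount(net)
  out <- stats::setNames(numeric(n), igraph::V(net)$name)
  if (n == 0L) return(out)
  comp <- igraph::components(net)
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    if (length(members) == 1L) {
      out[members] <- 0
      next
    }
    d <- igraph::distances(net, v = members, to = members)
    m <- length(members)
    for (i in seq_len(m)) {
      # gamma_i[w]: nodes strictly closer to i than to w (and vice versa)
      closer_i <- colSums(d[i, ] < d)      # for each w, #{u: d(u,i) < d(u,w)}
      closer_w <- colSums(d[i, ] > d)
      f <- closer_i - closer_w
      out[members[i]] <- min(f[-i])
    }
  }
  out
}

#' Per-node centrality table with network-wide means
#'
#' @param net undirected simple igraph.
#' @return data.frame of class `centrality_table` with columns `node`,
#'   `degree`, `betweenness`, `centroid`; attributes `mean_degree`,
#'   `mean_betweenness`, `mean_centroid` hold means over all network nodes.
#' @export
centrality_table <- function(net) {
  deg <- igraph::degree(net)
  ct <- data.frame(node = igraph::V(net)$name,
                   degree = as.numeric(deg),
                   betweenness = as.numeric(betweenness_centrality(net)),
                   centroid = as.numeric(centroid_centrality(net)),
                   row.names = NULL, stringsAsFactors = FALSE)
  attr(ct, "mean_degree") <- if (nrow(ct)) mean(ct$degree) else NaN
  attr(ct, "mean_betweenness") <- if (nrow(ct)) mean(ct$betweenness) else NaN
  attr(ct, "mean_centroid") <- if (nrow(ct)) mean(ct$centroid) else NaN
  class(ct) <- c("centrality_table", "data.frame")
  ct
}

#' Call hubs as nodes with above-average centrality
#'
#' PPI mode: nodes whose betweenness and centroid both exceed (strictly) the
#' network-wide mean of that centrality (`combine = "or"` relaxes to either).
#' Co-expression mode: nodes whose degree strictly exceeds the mean degree.
#'
#' @param ct a [centrality_table()].
#' @param mode "ppi" (betweenness + centroid) or "coexpression" (degree).
#' @param combine for PPI mode, "and" (default) or "or".
#' @return character vector of hub node ids.
#' @export
call_hubs <- function(ct, mode = c("ppi", "coexpression"),
                      combine = c("and", "or")) {
  stopifnot(inherits(ct, "centrality_table"))
  mode <- match.arg(mode)
  combine <- match.arg(combine)
  if (nrow(ct) == 0L) return(character(0))
  if (mode == "coexpression") {
    return(ct$node[ct$degree > attr(ct, "mean_degree")])
  }
  above_b <- ct$betweenness > attr(ct, "mean_betweenness")
  above_c <- ct$centroid > attr(ct, "mean_centroid")
  hit <- if (combine == "and") above_b & above_c else above_b | above_c
  ct$node[hit]
}

#' Hubs specific to one level of the Fe or Mo factor
#'
#' A protein is specific to level L of factor F (e.g. level "-Fe" of factor
#' Fe) when it is a hub in both base-condition networks carrying that level
#' and in neither network of the opposite level (`rule = "both"`, default);
#' `rule = "any"` relaxes "both" to "at least one".
#'
#' @param hub_sets named list of hub sets, one per base condition
#'   (`+Mo+Fe`, `+Mo-Fe`, `-Mo+Fe`, `-Mo-Fe`).
#' @param factor "Fe" or "Mo".
#' @param rule "both" (default) or "any".
#' @return named list with the two level-specific protein sets, e.g.
#'   `list("+Fe" = ..., "-Fe" = ...)`; the two sets are disjoint.
#' @export
condition_specific_hubs <- function(hub_sets, factor = c("Fe", "Mo"),
                                    rule = c("both", "any")) {
  factor <- match.arg(factor)
  rule <- match.arg(rule)
  missing <- setdiff(base_conditions(), names(hub_sets))
  if (length(missing) > 0L) {
    stop("missing hub set(s) for: ", paste(missing, collapse = ", "))
  }
  levels <- if (factor == "Fe") {
    list("+Fe" = c("+Mo+Fe", "-Mo+Fe"), "-Fe" = c("+Mo-Fe", "-Mo-Fe"))
  } else {
    list("+Mo" = c("+Mo+Fe", "+Mo-Fe"), "-Mo" = c("-Mo+Fe", "-Mo-Fe"))
  }
  specific <- lapply(seq_along(levels), function(i) {
    own <- levels[[i]]
    other <- levels[[setdiff(1:2, i)]]
    own_sets <- hub_sets[own]
    in_level <- if (rule == "both") {
      intersect(own_sets[[1]], own_sets[[2]])
    } else {
      union(own_sets[[1]], own_sets[[2]])
    }
    sort(setdiff(in_level, union(hub_sets[[other[1]]], hub_sets[[other[2]]])))
  })
  names(specific) <- names(levels)
  specific
}

#' Degrees of every protein across the grouping networks
#'
#' @param networks named list of co-expression networks (one per grouping).
#' @return list with `degrees` (protein x grouping matrix, 0 for proteins
#'   absent from a network) and `mean_degree` (per-grouping mean over that
#'   network's own nodes).
#' @export
grouping_degrees <- function(networks) {
  all_prot <- sort(unique(unlist(lapply(networks, function(g) igraph::V(g)$name))))
  degrees <- matrix(0, nrow = length(all_prot), ncol = length(networks),
                    dimnames = list(all_prot, names(networks)))
  mean_degree <- stats::setNames(numeric(length(networks)), names(networks))
  for (g in names(networks)) {
    d <- igraph::degree(networks[[g]])
    if (length(d) > 0) degrees[names(d), g] <- d
    mean_degree[g] <- if (length(d) > 0) mean(d) else NaN
  }
  list(degrees = degrees, mean_degree = mean_degree)
}

#' Differentially correlated proteins across condition groupings
#'
#' A protein is called differentially correlated with focal grouping g when
#' its degree in g strictly exceeds g's network-wide mean degree AND is the
#' strict maximum of its degrees over all groupings. At most one focal
#' grouping per protein; proteins absent from a network have degree 0 there.
#'
#' @param degrees protein x grouping degree matrix (see
#'   [grouping_degrees()]).
#' @param mean_degree named vector of per-grouping mean degrees.
#' @return data.frame with the degree columns plus `called` (logical) and
#'   `focal_grouping` (NA when not called).
#' @export
differential_correlation <- function(degrees, mean_degree) {
  stopifnot(is.matrix(degrees), !is.null(colnames(degrees)),
            all(colnames(degrees) %in% names(mean_degree)))
  mean_degree <- mean_degree[colnames(degrees)]
  focal <- rep(NA_character_, nrow(degrees))
  for (i in seq_len(nrow(degrees))) {
    d <- degrees[i, ]
    top <- which.max(d)
    if (sum(d == d[top]) > 1L) next              # no strict maximum
    if (!is.finite(mean_degree[top]) || d[top] <= mean_degree[top]) next
    focal[i] <- colnames(degrees)[top]
  }
  out <- as.data.frame(degrees)
  out <- cbind(data.frame(protein = rownames(degrees), stringsAsFactors = FALSE,
                          row.names = NULL),
               out, data.frame(called = !is.na(focal), focal_grouping = focal,
                               stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Ego network of a hub: the hub, its neighbors, and all edges among them
#'
#' @param net igraph network with edge attributes (e.g. `rho`, `sign`).
#' @param hub protein id; if absent from the network an empty graph is
#'   returned.
#' @return induced igraph subnetwork retaining edge attributes.
#' @export
ego_network <- function(net, hub) {
  if (!hub %in% igraph::V(net)$name) {
    return(igraph::make_empty_graph(directed = FALSE))
  }
  nodes <- igraph::ego(net, order = 1, nodes = hub)[[1]]
  igraph::induced_subgraph(net, nodes)
}

#' Overlap between co-expression and PPI edges
#'
#' Reports (a) pair-level overlap: the percentage of co-expression edges
#' that are also PPI edges, and (b) protein-level overlap: the percentage of
#' co-expression nodes incident to at least one shared edge. Pair-level is
#' the headline figure.
#'
#' @param coex co-expression igraph.
#' @param ppi PPI igraph (same protein id space).
#' @return list with `pair_pct`, `protein_pct`, `shared_edges`
#'   (data.frame); percentages are `NA` when the co-expression network has
#'   no edges.
#' @export
edge_overlap <- function(coex, ppi) {
  ce <- edge_keys(coex)
  pe <- edge_keys(ppi)
  if (length(ce) == 0L) {
    return(list(pair_pct = NA_real_, protein_pct = NA_real_,
                shared_edges = data.frame(protein_a = character(0),
                                          protein_b = character(0))))
  }
  shared <- intersect(ce, pe)
  parts <- strsplit(shared, "\r", fixed = TRUE)
  shared_df <- data.frame(
    protein_a = vapply(parts, `[`, "", 1L),
    protein_b = vapply(parts, `[`, "", 2L),
    stringsAsFactors = FALSE
  )
  touched <- unique(unlist(parts))
  list(pair_pct = 100 * length(shared) / length(ce),
       protein_pct = 100 * length(intersect(igraph::V(coex)$name, touched)) /
         igraph::vcount(coex),
       shared_edges = shared_df)
}

edge_keys <- function(net) {
  if (igraph::ecount(net) == 0L) return(character(0))
  el <- igraph::as_edgelist(net)
  paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\r")
}
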