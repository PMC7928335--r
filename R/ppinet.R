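#' Canonicalize an interaction table
#'
#' Orders each gene pair lexicographically, removes self-pairs, and merges
#' duplicate pairs by taking the per-channel maximum score.
#'
#' @param tab data.frame with columns `gene_a`, `gene_b`, `database_score`,
#'   `experimental_score`.
#' @return canonical interaction table (unordered pairs, unique, no
#'   self-pairs).
#' @export
normalize_interactions <- function(tab) {
  validate_interactions(tab)
  a <- pmin(tab$gene_a, tab$gene_b)
  b <- pmax(tab$gene_a, tab$gene_b)
  tab$gene_a <- a
  tab$gene_b <- b
  tab <- tab[a != b, , drop = FALSE]
  if (nrow(tab) == 0L) return(tab)
  key <- paste(tab$gene_a, tab$gene_b, sep = "\r")
  db <- tapply(tab$database_score, key, max)
  ex <- tapply(tab$experimental_score, key, max)
  keys <- sort(unique(key))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  data.frame(gene_a = vapply(parts, `[`, "", 1L),
             gene_b = vapply(parts, `[`, "", 2L),
             database_score = as.numeric(db[keys]),
             experimental_score = as.numeric(ex[keys]),
             row.names = NULL, stringsAsFactors = FALSE)
}

validate_interactions <- function(tab) {
  need <- c("gene_a", "gene_b", "database_score", "experimental_score")
  if (!is.data.frame(tab) || !all(need %in% names(tab))) {
    stop("interaction table needs columns: ", paste(need, collapse = ", "))
  }
  scores <- c(tab$database_score, tab$experimental_score)
  if (any(scores < 0 | scores > 1)) stop("channel scores must lie in [0, 1]")
  invisible(tab)
}

#' Filter interactions on evidence-channel scores
#'
#' Keeps a row when its database score exceeds `db_min` or its experimental
#' score exceeds `exp_min` (strict inequalities, OR-combined: database
#' annotated and/or experimentally determined evidence). A row at exactly
#' (0.15, 0.35) is dropped.
#'
#' @param tab interaction table.
#' @param db_min database-channel threshold, default 0.15.
#' @param exp_min experimental-channel threshold, default 0.35.
#' @return filtered interaction table.
#' @export
filter_interactions <- function(tab, db_min = 0.15, exp_min = 0.35) {
  validate_interactions(tab)
  stopifnot(db_min >= 0, db_min <= 1, exp_min >= 0, exp_min <= 1)
  tab[tab$database_score > db_min | tab$experimental_score > exp_min, ,
      drop = FALSE]
}

#' Transfer reference-species interactions onto proteins via orthology
#'
#' For every interacting gene pair (G1, G2) and every pair of proteins
#' mapping to them (p1 -> G1, p2 -> G2), an edge p1--p2 is added (interolog
#' transfer). Two proteins mapping to the same gene receive no edge unless a
#' self-interaction row exists — and self-pairs are removed by
#' canonicalization, so paralog pairs are never linked. Each edge retains the
#' gene pair and channel scores that justify it.
#'
#' @param tab interaction table (will be canonicalized; filter first with
#'   [filter_interactions()]).
#' @param orth_map data.frame `protein`, `gene`, `homology_pct`.
#' @param proteins optional protein universe; mapped proteins outside it are
#'   kept with a warning. Defaults to the proteins of the map.
#' @return undirected igraph whose nodes are all mapped proteins (isolated
#'   ones included) and whose edges carry `gene_a`, `gene_b`,
#'   `database_score`, `experimental_score`.
#' @export
transfer_interactions <- function(tab, orth_map, proteins = NULL) {
  stopifnot(is.data.frame(orth_map),
            all(c("protein", "gene", "homology_pct") %in% names(orth_map)))
  if (anyDuplicated(orth_map$protein)) {
    stop("each protein must map to exactly one gene")
  }
  tab <- normalize_interactions(tab)
  if (!is.null(proteins)) {
    extra <- setdiff(orth_map$protein, proteins)
    if (length(extra) > 0L) {
      warning(length(extra), " mapped protein(s) absent from the proteome list; kept")
    }
  }
  by_gene <- split(orth_map$protein, orth_map$gene)
  edge_rows <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    pa <- by_gene[[tab$gene_a[i]]]
    pb <- by_gene[[tab$gene_b[i]]]
    if (is.null(pa) || is.null(pb)) next
    grid <- expand.grid(from = pa, to = pb, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    grid <- grid[grid$from != grid$to, , drop = FALSE]
    if (nrow(grid) == 0L) next
    grid$gene_a <- tab$gene_a[i]
    grid$gene_b <- tab$gene_b[i]
    grid$database_score <- tab$database_score[i]
    grid$experimental_score <- tab$experimental_score[i]
    edge_rows[[i]] <- grid
  }
  edges <- do.call(rbind, edge_rows)
  if (is.null(edges)) {
    edges <- data.frame(from = character(0), to = character(0),
                        gene_a = character(0), gene_b = character(0),
                        database_score = numeric(0),
                        experimental_score = numeric(0))
  }
  # deduplicate protein pairs (possible when both endpoints map many-to-one)
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  edges$from <- a
  edges$to <- b
  edges <- edges[!duplicated(paste(a, b, sep = "\r")), , drop = FALSE]
  igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = sort(unique(orth_map$protein)))
  )
}

#' Extract the subnetwork induced by the proteins present in a condition
#'
#' @param net a PPI (or any) igraph network.
#' @param present protein ids identified in the condition.
#' @param drop_isolated drop nodes left without edges (default TRUE).
#' @param largest_component keep only the largest connected component
#'   (default FALSE).
#' @return induced igraph subnetwork.
#' @export
extract_condition_subnetwork <- function(net, present, drop_isolated = TRUE,
                                         largest_component = FALSE) {
  keep <- intersect(igraph::V(net)$name, present)
  sub <- igraph::induced_subgraph(net, keep)
  if (drop_isolated) {
    sub <- igraph::delete_vertices(sub, igraph::V(sub)[igraph::degree(sub) == 0])
  }
  if (largest_component && igraph::vcount(sub) > 0L) {
    comp <- igraph::components(sub)
    sub <- igraph::induced_subgraph(
      sub, igraph::V(sub)[comp$membership == which.max(comp$csize)])
  }
  sub
}

#' Mean percent homology of mapped proteins
#'
#' @param orth_map ortholog map (`protein`, `gene`, `homology_pct`).
#' @param proteins optional subset of proteins; defaults to all mapped.
#' @return arithmetic mean homology percent.
#' @export
mean_homology <- function(orth_map, proteins = NULL) {
  h <- if (is.null(proteins)) {
    orth_map$homology_pct
  } else {
    orth_map$homology_pct[orth_map$protein %in% proteins]
  }
  if (length(h) == 0L) stop("no mapped proteins")
  mean(h)
}
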