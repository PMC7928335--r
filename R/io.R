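# Readers and writers for the pipeline's plain-text formats. All tables are
# tab-separated with '#' comment headers; networks are written as SIF and
# GraphML for Cytoscape interoperability.

write_tsv <- function(df, path, comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read / write spectral-count matrices and companion tables
#'
#' Tab-separated formats: the count matrix has a `protein` id column followed
#' by one column per sample; sample metadata has columns `sample`,
#' `condition`; the ortholog map has `protein`, `gene`, `homology_pct`; the
#' interaction table has `gene_a`, `gene_b`, `database_score`,
#' `experimental_score`. Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return `read_spc_matrix()` returns a protein x sample numeric matrix;
#'   the other readers return data.frames.
#' @name spcnet-io
#' @export
read_spc_matrix <- function(path) {
  df <- read_tsv(path)
  if (names(df)[1] != "protein") stop("first column must be 'protein'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$protein
  validate_spc_matrix(m)
  m
}

#' @rdname spcnet-io
#' @param m protein x sample matrix.
#' @export
write_spc_matrix <- function(m, path) {
  df <- data.frame(protein = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path, comment = "spectral counts: proteins x samples")
}

#' @rdname spcnet-io
#' @export
read_sample_metadata <- function(path) {
  meta <- read_tsv(path)
  validate_metadata(meta)
  meta
}

#' @rdname spcnet-io
#' @param meta sample metadata data.frame.
#' @export
write_sample_metadata <- function(meta, path) {
  validate_metadata(meta)
  write_tsv(meta[, c("sample", "condition")], path,
            comment = "sample -> base condition")
}

#' @rdname spcnet-io
#' @export
read_ortholog_map <- function(path) {
  map <- read_tsv(path)
  need <- c("protein", "gene", "homology_pct")
  if (!all(need %in% names(map))) {
    stop("ortholog map needs columns: ", paste(need, collapse = ", "))
  }
  map
}

#' @rdname spcnet-io
#' @param orth_map ortholog map data.frame.
#' @export
write_ortholog_map <- function(orth_map, path) {
  write_tsv(orth_map[, c("protein", "gene", "homology_pct")], path,
            comment = "protein -> reference ortholog, percent homology")
}

#' @rdname spcnet-io
#' @export
read_interaction_table <- function(path) {
  tab <- read_tsv(path)
  validate_interactions(tab)
  tab
}

#' @rdname spcnet-io
#' @param tab interaction table data.frame.
#' @export
write_interaction_table <- function(tab, path) {
  validate_interactions(tab)
  write_tsv(tab[, c("gene_a", "gene_b", "database_score", "experimental_score")],
            path, comment = "reference-species interactions, channel scores")
}

#' Write a network in SIF and GraphML formats
#'
#' SIF rows are `node <relation> node`; the relation is the edge `sign`
#' attribute when present (co-expression networks) and `pp` otherwise.
#' Isolated nodes are written as single-column SIF rows. GraphML retains all
#' edge attributes (e.g. `rho`, `p`, `sign`, channel scores).
#'
#' @param net igraph network.
#' @param path output path (extension included by the caller).
#' @name write-networks
#' @export
write_network_sif <- function(net, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (igraph::ecount(net) > 0L) {
    el <- igraph::as_edgelist(net)
    rel <- if ("sign" %in% igraph::edge_attr_names(net)) {
      igraph::E(net)$sign
    } else {
      rep("pp", nrow(el))
    }
    writeLines(paste(el[, 1], rel, el[, 2], sep = "\t"), con)
  }
  isolated <- igraph::V(net)$name[igraph::degree(net) == 0]
  if (length(isolated) > 0L) writeLines(isolated, con)
  invisible(path)
}

#' @rdname write-networks
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' @rdname write-networks
#' @export
write_edge_table <- function(net, path) {
  if (igraph::ecount(net) == 0L) {
    df <- data.frame(protein_a = character(0), protein_b = character(0))
  } else {
    el <- igraph::as_edgelist(net)
    df <- data.frame(protein_a = el[, 1], protein_b = el[, 2],
                     stringsAsFactors = FALSE)
    for (a in igraph::edge_attr_names(net)) df[[a]] <- igraph::edge_attr(net, a)
  }
  write_tsv(df, path, comment = "edge list with attributes")
}
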