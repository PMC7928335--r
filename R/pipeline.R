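#' Pipeline configuration: every threshold of the analysis in one place
#'
#' @param db_min,exp_min PPI evidence-channel score thresholds (strict,
#'   OR-combined), defaults 0.15 and 0.35.
#' @param rho_min,p_max co-expression edge thresholds (|rho| > 0.7,
#'   p < 0.01).
#' @param prevalence minimum identification fraction per grouping, 0.51.
#' @param alpha,f_min differential-expression selection (p < 0.05, F > 3).
#' @param hub_combine "and"/"or" combiner for PPI hub calling.
#' @param min_samples_presence samples with a positive count required for a
#'   protein to count as identified in a base condition.
#' @param seed integer seed driving every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(db_min = 0.15, exp_min = 0.35,
                            rho_min = 0.7, p_max = 0.01,
                            prevalence = 0.51, alpha = 0.05, f_min = 3,
                            hub_combine = c("and", "or"),
                            min_samples_presence = 1L,
                            seed = 1L) {
  hub_combine <- match.arg(hub_combine)
  stopifnot(db_min >= 0, db_min <= 1, exp_min >= 0, exp_min <= 1,
            rho_min >= 0, rho_min <= 1, p_max > 0, p_max <= 1,
            prevalence > 0, prevalence <= 1, alpha > 0, alpha <= 1, f_min >= 0)
  structure(list(db_min = db_min, exp_min = exp_min, rho_min = rho_min,
                 p_max = p_max, prevalence = prevalence, alpha = alpha,
                 f_min = f_min, hub_combine = hub_combine,
                 min_samples_presence = as.integer(min_samples_presence),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Simulate a complete input bundle for the pipeline
#'
#' Generates the spectral-count matrix with planted structure, an ortholog
#' map over its proteins, and an interaction table consistent with the
#' planted modules. Sub-seeds for the map and the table are derived from
#' `sim_config$seed`.
#'
#' @param sim_config a [simulation_config()].
#' @param mean_homology mean percent homology of the synthetic map.
#' @param p_in,p_out interaction probabilities (see
#'   [generate_interaction_table()]).
#' @param frac_subthreshold fraction of interactions failing both score
#'   filters.
#' @return list with `counts`, `metadata`, `orthologs`, `interactions`,
#'   `truth`.
#' @export
simulate_inputs <- function(sim_config = simulation_config(),
                            mean_homology = 67, p_in = 0.9, p_out = 0.02,
                            frac_subthreshold = 0.2) {
  sim <- generate_spc_dataset(sim_config)
  orth <- generate_ortholog_map(rownames(sim$counts),
                                mean_homology = mean_homology,
                                seed = sim_config$seed + 1L)
  inter <- generate_interaction_table(sim$truth, orth,
                                      p_in = p_in, p_out = p_out,
                                      frac_subthreshold = frac_subthreshold,
                                      seed = sim_config$seed + 2L)
  list(counts = sim$counts, metadata = sim$metadata, orthologs = orth,
       interactions = inter, truth = sim$truth)
}

#' Run the full condition-stratified network analysis
#'
#' Executes, in order: SpC normalization; F-ratio differential-expression
#' selection; homology transfer of the score-filtered interaction table into
#' a PPI network with four per-condition subnetworks, centralities and hub
#' sets, plus Fe- and Mo-specific hub sets; per-grouping prevalence
#' filtering and signed Spearman co-expression networks with degree-based
#' hubs and differential-correlation calls; and the PPI/co-expression edge
#' overlap.
#'
#' @param inputs list with `counts`, `metadata`, `orthologs`,
#'   `interactions`, optionally `truth` (see [simulate_inputs()]); if NULL,
#'   inputs are simulated from `sim_config`.
#' @param config a [pipeline_config()].
#' @param sim_config simulation configuration used when `inputs` is NULL;
#'   its seed defaults to `config$seed`.
#' @return object of class `spcnet_pipeline`; see [pipeline_report()] for
#'   the summary tables. Components include the normalized matrix, the DE
#'   table, the PPI network and subnetworks with centralities and hub sets,
#'   the grouping co-expression networks with degrees and
#'   differential-correlation calls, and the overlap report.
#' @examples
#' res <- run_pipeline(config = pipeline_config(seed = 7),
#'                     sim_config = simulation_config(n_proteins = 60,
#'                                                    module_size = 8,
#'                                                    n_de_proteins = 5,
#'                                                    seed = 7))
#' print(res)
#' @export
run_pipeline <- function(inputs = NULL, config = pipeline_config(),
                         sim_config = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(inputs)) {
    if (is.null(sim_config)) sim_config <- simulation_config(seed = config$seed)
    inputs <- simulate_inputs(sim_config)
  }
  need <- c("counts", "metadata", "orthologs", "interactions")
  missing <- setdiff(need, names(inputs))
  if (length(missing) > 0L) {
    stop("inputs missing component(s): ", paste(missing, collapse = ", "))
  }
  m <- inputs$counts
  meta <- inputs$metadata
  validate_spc_matrix(m)
  validate_metadata(meta)
  if (!all(colnames(m) %in% meta$sample)) {
    stop("count matrix has samples without metadata")
  }

  normalized <- normalize_spc(m)
  de <- f_ratio_selection(normalized, meta, alpha = config$alpha,
                          f_min = config$f_min)

  # --- PPI branch ---------------------------------------------------------
  filtered <- filter_interactions(inputs$interactions,
                                  db_min = config$db_min,
                                  exp_min = config$exp_min)
  ppi <- transfer_interactions(filtered, inputs$orthologs,
                               proteins = rownames(m))
  presence <- lapply(stats::setNames(nm = base_conditions()), function(cond) {
    condition_presence(m, meta, cond, min_samples = config$min_samples_presence)
  })
  ppi_sub <- lapply(presence, function(pr) extract_condition_subnetwork(ppi, pr))
  ppi_centrality <- lapply(ppi_sub, centrality_table)
  ppi_hubs <- lapply(ppi_centrality, call_hubs, mode = "ppi",
                     combine = config$hub_combine)
  specific_hubs <- list(Fe = condition_specific_hubs(ppi_hubs, "Fe"),
                        Mo = condition_specific_hubs(ppi_hubs, "Mo"))

  # --- co-expression branch ----------------------------------------------
  coex <- build_grouping_networks(m, meta,
                                  min_fraction = config$prevalence,
                                  rho_min = config$rho_min,
                                  p_max = config$p_max)
  gd <- grouping_degrees(coex)
  coex_hubs <- lapply(stats::setNames(nm = names(coex)), function(g) {
    d <- igraph::degree(coex[[g]])
    sort(names(d)[d > mean(d)])
  })
  diffcor <- differential_correlation(gd$degrees, gd$mean_degree)

  overlap <- lapply(coex, edge_overlap, ppi = ppi)

  structure(list(
    inputs = inputs,
    config = config,
    normalized = normalized,
    de = de,
    ppi = ppi,
    ppi_subnetworks = ppi_sub,
    ppi_centrality = ppi_centrality,
    ppi_hubs = ppi_hubs,
    specific_hubs = specific_hubs,
    coexpression = coex,
    degrees = gd$degrees,
    mean_degree = gd$mean_degree,
    coexpression_hubs = coex_hubs,
    differential_correlation = diffcor,
    overlap = overlap,
    mean_homology = mean_homology(inputs$orthologs, rownames(m))
  ), class = "spcnet_pipeline")
}

#' Summary tables of a pipeline run
#'
#' @param result an `spcnet_pipeline` object.
#' @return list with `network_summary` (one row per network: nodes, edges,
#'   mean degree, hub count) and `protein_table` (one row per protein seen
#'   in any co-expression network: ortholog, homology, F ratio, p, per-
#'   grouping degree, differential-correlation call).
#' @export
pipeline_report <- function(result) {
  stopifnot(inherits(result, "spcnet_pipeline"))
  nets <- c(list(PPI_full = result$ppi),
            stats::setNames(result$ppi_subnetworks,
                            paste0("PPI_", names(result$ppi_subnetworks))),
            stats::setNames(result$coexpression,
                            paste0("coex_", names(result$coexpression))))
  hubs <- c(list(PPI_full = NA_integer_),
            stats::setNames(lapply(result$ppi_hubs, length),
                            paste0("PPI_", names(result$ppi_hubs))),
            stats::setNames(lapply(result$coexpression_hubs, length),
                            paste0("coex_", names(result$coexpression_hubs))))
  network_summary <- data.frame(
    network = names(nets),
    nodes = vapply(nets, function(g) as.integer(igraph::vcount(g)), integer(1)),
    edges = vapply(nets, function(g) as.integer(igraph::ecount(g)), integer(1)),
    mean_degree = vapply(nets, function(g) {
      if (igraph::vcount(g) == 0L) NaN else 2 * igraph::ecount(g) / igraph::vcount(g)
    }, numeric(1)),
    hub_count = suppressWarnings(as.integer(unlist(hubs))),
    row.names = NULL, stringsAsFactors = FALSE
  )
  dc <- result$differential_correlation
  orth <- result$inputs$orthologs
  idx <- match(dc$protein, orth$protein)
  de_idx <- match(dc$protein, result$de$protein)
  protein_table <- cbind(
    data.frame(protein = dc$protein,
               ortholog = orth$gene[idx],
               homology_pct = orth$homology_pct[idx],
               f_ratio = result$de$f_ratio[de_idx],
               p_value = result$de$p_value[de_idx],
               de_selected = result$de$selected[de_idx],
               stringsAsFactors = FALSE),
    dc[, setdiff(names(dc), "protein"), drop = FALSE]
  )
  list(network_summary = network_summary, protein_table = protein_table)
}

#' @export
print.spcnet_pipeline <- function(x, ...) {
  rep <- pipeline_report(x)
  ns <- rep$network_summary
  cat("Condition-stratified proteomic network analysis\n")
  cat(sprintf("  %d proteins x %d samples; mean ortholog homology %.1f%%\n",
              nrow(x$inputs$counts), ncol(x$inputs$counts), x$mean_homology))
  for (i in seq_len(nrow(ns))) {
    cat(sprintf("  %-22s %4d nodes, %5d edges%s\n", ns$network[i], ns$nodes[i],
                ns$edges[i],
                if (is.na(ns$hub_count[i])) "" else sprintf(", %3d hubs", ns$hub_count[i])))
  }
  called <- sum(x$differential_correlation$called)
  cat(sprintf("  differentially correlated proteins: %d\n", called))
  invisible(x)
}

#' @export
summary.spcnet_pipeline <- function(object, ...) {
  rep <- pipeline_report(object)
  rep$specific_hubs <- object$specific_hubs
  rep$overlap_pair_pct <- vapply(object$overlap, `[[`, numeric(1), "pair_pct")
  class(rep) <- "summary.spcnet_pipeline"
  rep
}

#' @export
print.summary.spcnet_pipeline <- function(x, ...) {
  print(x$network_summary, row.names = FALSE)
  cat("\nPPI/co-expression pair-level edge overlap (%):\n")
  print(round(x$overlap_pair_pct, 2))
  cat("\nCondition-specific PPI hubs:\n")
  for (f in names(x$specific_hubs)) {
    for (l in names(x$specific_hubs[[f]])) {
      cat(sprintf("  %-4s: %d\n", l, length(x$specific_hubs[[f]][[l]])))
    }
  }
  invisible(x)
}

#' Write every pipeline output plus a reproducibility manifest
#'
#' Writes the normalized matrix, DE table, per-network edge lists, SIF and
#' GraphML files, centrality tables, a hub-report JSON, the
#' differential-correlation table, and `manifest.json` containing the
#' configuration, package version and md5 hash of every written file. The
#' manifest carries no timestamps, so identical runs produce byte-identical
#' output trees.
#'
#' @param result an `spcnet_pipeline` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
write_pipeline_outputs <- function(result, dir) {
  stopifnot(inherits(result, "spcnet_pipeline"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wp <- function(fun, obj, name) {
    p <- file.path(dir, name)
    fun(obj, p)
    paths[[length(paths) + 1L]] <<- p
  }
  wp(write_spc_matrix, result$inputs$counts, "counts.tsv")
  wp(write_spc_matrix, result$normalized, "normalized.tsv")
  wp(write_sample_metadata, result$inputs$metadata, "samples.tsv")
  wp(write_ortholog_map, result$inputs$orthologs, "orthologs.tsv")
  wp(write_interaction_table, result$inputs$interactions, "interactions.tsv")
  wp(write_tsv, result$de, "de_table.tsv")
  nets <- c(list(ppi_full = result$ppi),
            stats::setNames(result$ppi_subnetworks,
                            paste0("ppi_", gsub("[+]", "p", gsub("-", "m", names(result$ppi_subnetworks))))),
            stats::setNames(result$coexpression,
                            paste0("coex_", names(result$coexpression))))
  for (nm in names(nets)) {
    wp(write_network_sif, nets[[nm]], paste0(nm, ".sif"))
    wp(write_network_graphml, nets[[nm]], paste0(nm, ".graphml"))
    wp(write_edge_table, nets[[nm]], paste0(nm, "_edges.tsv"))
  }
  for (nm in names(result$ppi_centrality)) {
    ct <- result$ppi_centrality[[nm]]
    ct$is_hub <- ct$node %in% result$ppi_hubs[[nm]]
    wp(write_tsv, ct,
       paste0("centrality_ppi_", gsub("[+]", "p", gsub("-", "m", nm)), ".tsv"))
  }
  wp(write_tsv, result$differential_correlation, "differential_correlation.tsv")
  hub_report <- list(ppi_hubs = result$ppi_hubs,
                     specific_hubs = result$specific_hubs,
                     coexpression_hubs = result$coexpression_hubs)
  hub_path <- file.path(dir, "hub_report.json")
  jsonlite::write_json(hub_report, hub_path, auto_unbox = FALSE, pretty = TRUE)
  paths[[length(paths) + 1L]] <- hub_path

  files <- sort(basename(unlist(paths)))
  hashes <- tools::md5sum(file.path(dir, files))
  manifest <- list(
    package = "spcnet",
    version = as.character(utils::packageVersion("spcnet")),
    config = unclass(result$config),
    files = as.list(stats::setNames(as.character(hashes), files))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
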