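#' Configuration for the synthetic spectral-count generator
#'
#' Describes a simulated label-free proteomic experiment: a negative-binomial
#' spectral-count matrix over the four crossed nutritional conditions, with
#' planted condition-specific co-expression modules (whose members are the
#' planted differential-correlation hubs), planted differentially expressed
#' proteins, and abundance-dependent detection dropout.
#'
#' The default replicate split (6, 8, 6, 7 over `+Mo+Fe`, `+Mo-Fe`, `-Mo+Fe`,
#' `-Mo-Fe`) is the unique non-negative integer solution to the pooled
#' grouping sizes of the study design (+Fe n = 12, +Mo n = 14, -Fe n = 15,
#' -Mo n = 13).
#'
#' @param n_proteins number of simulated proteins.
#' @param reps_per_condition named integer vector of replicates per base
#'   condition; names must cover [base_conditions()].
#' @param n_modules number of planted co-expression modules; module k is
#'   active in grouping `condition_groupings()[[((k-1) %% 4) + 1]]`.
#' @param module_size proteins per module (`n_modules * module_size` must not
#'   exceed `n_proteins`).
#' @param hub_spec optional data.frame with columns `protein`, `grouping`
#'   overriding the planted-hub ground truth; by default every member of a
#'   module is a planted hub for that module's active grouping.
#' @param n_de_proteins number of planted differentially expressed proteins
#'   (drawn outside the modules).
#' @param de_log2_effect log2 shift applied to one randomly chosen base
#'   condition of each DE protein.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); must be > 0.
#' @param baseline_log2_mean_range range of per-protein baseline log2 mean
#'   counts, drawn uniformly.
#' @param module_baseline_range baseline range for module proteins; kept in
#'   the well-detected abundance band so planted structure survives the
#'   prevalence filter, as hub proteins do in real prevalence-filtered data.
#' @param de_baseline_range baseline range for DE proteins; confined to the
#'   quantifiable band, since differential abundance is only observable for
#'   proteins that are identified in the first place.
#' @param factor_sd_active,factor_sd_inactive standard deviation of a module's
#'   latent factor in samples inside / outside its active grouping.
#' @param dropout_midpoint log2-mean at which the probability of failing
#'   MS/MS identification is 0.5.
#' @param dropout_slope steepness of the logistic dropout curve; dropout
#'   probability is `plogis(-dropout_slope * (log2_mean - dropout_midpoint))`.
#' @param seed integer seed; all randomness of the generator flows from it.
#' @return an object of class `simulation_config` (a validated list).
#' @seealso [generate_spc_dataset()]
#' @export
simulation_config <- function(n_proteins = 300,
                              reps_per_condition = c("+Mo+Fe" = 6, "+Mo-Fe" = 8,
                                                     "-Mo+Fe" = 6, "-Mo-Fe" = 7),
                              n_modules = 4,
                              module_size = 25,
                              hub_spec = NULL,
                              n_de_proteins = 20,
                              de_log2_effect = 2,
                              nb_dispersion = 0.25,
                              baseline_log2_mean_range = c(0.5, 6.5),
                              module_baseline_range = c(5.5, 7.5),
                              de_baseline_range = c(3.5, 6.5),
                              factor_sd_active = 2.5,
                              factor_sd_inactive = 0,
                              dropout_midpoint = 3.5,
                              dropout_slope = 2,
                              seed = 1) {
  missing_cond <- setdiff(base_conditions(), names(reps_per_condition))
  if (length(missing_cond) > 0L) {
    stop("reps_per_condition is missing base condition(s): ",
         paste(missing_cond, collapse = ", "))
  }
  reps_per_condition <- reps_per_condition[base_conditions()]
  if (any(reps_per_condition < 1)) stop("each base condition needs >= 1 replicate")
  if (n_modules * module_size > n_proteins) {
    stop("module_size * n_modules exceeds n_proteins")
  }
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (de_log2_effect < 0) stop("de_log2_effect must be >= 0")
  if (!is.null(hub_spec)) {
    stopifnot(is.data.frame(hub_spec),
              all(c("protein", "grouping") %in% names(hub_spec)))
  }
  structure(list(
    n_proteins = as.integer(n_proteins),
    reps_per_condition = reps_per_condition,
    n_modules = as.integer(n_modules),
    module_size = as.integer(module_size),
    hub_spec = hub_spec,
    n_de_proteins = as.integer(n_de_proteins),
    de_log2_effect = de_log2_effect,
    nb_dispersion = nb_dispersion,
    baseline_log2_mean_range = baseline_log2_mean_range,
    module_baseline_range = module_baseline_range,
    de_baseline_range = de_baseline_range,
    factor_sd_active = factor_sd_active,
    factor_sd_inactive = factor_sd_inactive,
    dropout_midpoint = dropout_midpoint,
    dropout_slope = dropout_slope,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Generate a synthetic spectral-count dataset with known planted structure
#'
#' Counts are drawn from a negative binomial whose log2 mean is
#' `baseline_p + f_k(sample)` for proteins in module k, where the latent
#' factor `f_k` has large variance only in samples of the module's active
#' grouping — planting grouping-specific co-expression whose members are the
#' planted differential-correlation hubs. DE proteins additionally receive a
#' `de_log2_effect` baseline shift in one base condition. Each count is then
#' zeroed with probability logistic in `-(log2 mean - dropout_midpoint)`,
#' emulating failed MS/MS identification of low-abundance proteins.
#'
#' @param config a [simulation_config()].
#' @return a list of class `spc_simulation` with components
#'   \describe{
#'     \item{counts}{protein x sample integer matrix of spectral counts}
#'     \item{metadata}{data.frame with columns `sample`, `condition`}
#'     \item{truth}{ground truth: `module_assignment` (named integer, NA for
#'       background), `module_grouping`, `planted_hubs` (list grouping ->
#'       protein set), `de_proteins`, `de_condition`, `true_interactions`
#'       (within-module protein pairs)}
#'   }
#' @examples
#' sim <- generate_spc_dataset(simulation_config(n_proteins = 50, module_size = 5))
#' dim(sim$counts)
#' table(sim$metadata$condition)
#' @export
generate_spc_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    conds <- rep(base_conditions(), times = config$reps_per_condition)
    sample_ids <- paste0(conds, "_", unlist(lapply(config$reps_per_condition, seq_len)))
    n_s <- length(sample_ids)
    proteins <- sprintf("P%04d", seq_len(config$n_proteins))

    groupings <- condition_groupings()
    module_assignment <- rep(NA_integer_, config$n_proteins)
    names(module_assignment) <- proteins
    module_grouping <- character(0)
    if (config$n_modules > 0L) {
      module_grouping <- names(groupings)[((seq_len(config$n_modules) - 1L) %% 4L) + 1L]
      for (k in seq_len(config$n_modules)) {
        idx <- ((k - 1L) * config$module_size + 1L):(k * config$module_size)
        module_assignment[idx] <- k
      }
    }
    module_proteins <- proteins[!is.na(module_assignment)]

    background <- setdiff(proteins, module_proteins)
    n_de <- min(config$n_de_proteins, length(background))
    de_proteins <- sort(sample(background, n_de))
    de_condition <- stats::setNames(sample(base_conditions(), n_de, replace = TRUE),
                                    de_proteins)

    baseline <- stats::runif(config$n_proteins,
                             config$baseline_log2_mean_range[1],
                             config$baseline_log2_mean_range[2])
    names(baseline) <- proteins
    baseline[module_proteins] <- stats::runif(length(module_proteins),
                                              config$module_baseline_range[1],
                                              config$module_baseline_range[2])
    baseline[de_proteins] <- stats::runif(length(de_proteins),
                                          config$de_baseline_range[1],
                                          config$de_baseline_range[2])

    # one latent factor per module, variance structured by grouping membership
    log2mu <- matrix(baseline, nrow = config$n_proteins, ncol = n_s,
                     dimnames = list(proteins, sample_ids))
    if (config$n_modules > 0L) {
      for (k in seq_len(config$n_modules)) {
        active <- conds %in% groupings[[module_grouping[k]]]
        f <- stats::rnorm(n_s, 0, ifelse(active, config$factor_sd_active,
                                         config$factor_sd_inactive))
        # center within each base condition: the factor carries co-regulation
        # variability only, never a condition-mean (DE-like) component
        f <- f - stats::ave(f, conds)
        members <- proteins[which(module_assignment == k)]
        log2mu[members, ] <- sweep(log2mu[members, , drop = FALSE], 2, f, "+")
      }
    }
    for (p in de_proteins) {
      shifted <- conds == de_condition[[p]]
      log2mu[p, shifted] <- log2mu[p, shifted] + config$de_log2_effect
    }

    mu <- 2^log2mu
    counts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                                    size = 1 / config$nb_dispersion),
                     nrow = nrow(mu), dimnames = dimnames(mu))
    p_drop <- stats::plogis(-config$dropout_slope * (log2mu - config$dropout_midpoint))
    dropped <- matrix(stats::runif(length(mu)) < as.vector(p_drop), nrow = nrow(mu))
    counts[dropped] <- 0L
    storage.mode(counts) <- "integer"

    hub_spec <- config$hub_spec
    if (is.null(hub_spec) && config$n_modules > 0L) {
      hub_spec <- data.frame(
        protein = module_proteins,
        grouping = module_grouping[module_assignment[module_proteins]],
        stringsAsFactors = FALSE
      )
    }
    planted_hubs <- lapply(stats::setNames(nm = names(groupings)), function(g) {
      if (is.null(hub_spec)) character(0) else hub_spec$protein[hub_spec$grouping == g]
    })

    true_interactions <- within_module_pairs(module_assignment)

    truth <- list(
      module_assignment = module_assignment,
      module_grouping = module_grouping,
      planted_hubs = planted_hubs,
      de_proteins = de_proteins,
      de_condition = de_condition,
      true_interactions = true_interactions
    )
    structure(list(
      counts = counts,
      metadata = data.frame(sample = sample_ids, condition = conds,
                            stringsAsFactors = FALSE),
      truth = truth
    ), class = "spc_simulation")
  })
}

within_module_pairs <- function(module_assignment) {
  out <- list()
  for (k in unique(stats::na.omit(module_assignment))) {
    members <- names(module_assignment)[which(module_assignment == k)]
    if (length(members) >= 2L) {
      cmb <- utils::combn(sort(members), 2L)
      out[[length(out) + 1L]] <- data.frame(protein_a = cmb[1, ], protein_b = cmb[2, ],
                                            stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(protein_a = character(0), protein_b = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Generate a synthetic protein-to-ortholog map
#'
#' Maps each protein to a single gene of the reference species with a
#' percent-homology drawn from a normal distribution truncated to (0, 100].
#' A configurable fraction of genes receive two proteins (many-to-one), as
#' happens with recent paralogs mapping to one ortholog.
#'
#' @param proteins character vector of protein ids.
#' @param mean_homology target mean homology percent (default 67).
#' @param sd_homology standard deviation of the homology distribution.
#' @param fraction_many_to_one fraction of proteins assigned to an
#'   already-used gene (0 gives a bijection).
#' @param seed integer seed.
#' @return data.frame with columns `protein`, `gene`, `homology_pct`.
#' @export
generate_ortholog_map <- function(proteins, mean_homology = 67, sd_homology = 10,
                                  fraction_many_to_one = 0.1, seed = 1) {
  stopifnot(length(proteins) > 0, mean_homology > 0, mean_homology <= 100,
            fraction_many_to_one >= 0, fraction_many_to_one < 1)
  with_seed(seed, {
    n <- length(proteins)
    n_shared <- floor(fraction_many_to_one * n)
    n_genes <- n - n_shared
    if (n_genes < 1L) stop("fraction_many_to_one too large")
    genes <- sprintf("ATG%05d", seq_len(n_genes))
    assignment <- c(genes,
                    if (n_shared > 0) sample(genes, n_shared, replace = FALSE))
    homology <- rtrunc_norm(n, mean_homology, sd_homology, lower = 0, upper = 100)
    data.frame(protein = proteins, gene = assignment, homology_pct = homology,
               stringsAsFactors = FALSE)
  })
}

# truncated-normal sampling by rejection; bounds are far enough from the mean
# at the defaults that this terminates quickly
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0L) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw > lower & draw <= upper
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Generate a synthetic STRING-like interaction table
#'
#' Gene pairs whose proteins share a planted co-expression module interact
#' with probability `p_in`, all other pairs with probability `p_out`. Each
#' interaction receives a database-evidence and an experimental-evidence
#' score in [0, 1]; a configurable fraction of rows is forced below both
#' filter thresholds so that score filtering is exercised downstream.
#'
#' @param truth ground truth from [generate_spc_dataset()] (needs
#'   `module_assignment`).
#' @param orth_map ortholog map from [generate_ortholog_map()].
#' @param p_in,p_out interaction probabilities for within-module / other gene
#'   pairs (`p_in >= p_out` required).
#' @param frac_subthreshold fraction of interactions whose scores fall below
#'   both the database (0.15) and experimental (0.35) filter thresholds.
#' @param seed integer seed.
#' @return data.frame with columns `gene_a`, `gene_b`, `database_score`,
#'   `experimental_score`; unordered pairs, no self-pairs.
#' @export
generate_interaction_table <- function(truth, orth_map, p_in = 0.9, p_out = 0.02,
                                       frac_subthreshold = 0.2, seed = 1) {
  stopifnot(p_in >= p_out, p_in <= 1, p_out >= 0,
            frac_subthreshold >= 0, frac_subthreshold <= 1)
  with_seed(seed, {
    genes <- sort(unique(orth_map$gene))
    # a gene's module: the module of any of its proteins (NA if background)
    gene_module <- vapply(genes, function(g) {
      mods <- truth$module_assignment[orth_map$protein[orth_map$gene == g]]
      mods <- mods[!is.na(mods)]
      if (length(mods) == 0L) NA_integer_ else mods[[1L]]
    }, integer(1))
    pairs <- utils::combn(genes, 2L)
    same_module <- !is.na(gene_module[pairs[1, ]]) &
      !is.na(gene_module[pairs[2, ]]) &
      gene_module[pairs[1, ]] == gene_module[pairs[2, ]]
    p <- ifelse(same_module, p_in, p_out)
    keep <- stats::runif(ncol(pairs)) < p
    ga <- pairs[1, keep]
    gb <- pairs[2, keep]
    n_int <- length(ga)
    sub <- stats::runif(n_int) < frac_subthreshold
    db <- numeric(n_int)
    ex <- numeric(n_int)
    # sub-threshold rows fail both channels; the rest pass at least one
    db[sub] <- stats::runif(sum(sub), 0, 0.15)
    ex[sub] <- stats::runif(sum(sub), 0, 0.35)
    n_hi <- sum(!sub)
    if (n_hi > 0) {
      which_channel <- sample(c("db", "exp", "both"), n_hi, replace = TRUE,
                              prob = c(0.4, 0.4, 0.2))
      db[!sub] <- ifelse(which_channel %in% c("db", "both"),
                         stats::runif(n_hi, 0.15, 1), stats::runif(n_hi, 0, 0.15))
      ex[!sub] <- ifelse(which_channel %in% c("exp", "both"),
                         stats::runif(n_hi, 0.35, 1), stats::runif(n_hi, 0, 0.35))
    }
    data.frame(gene_a = ga, gene_b = gb,
               database_score = db, experimental_score = ex,
               stringsAsFactors = FALSE)
  })
}

#' Precision and recall of differential-correlation calls vs planted truth
#'
#' A call is a true positive when the called protein is a planted hub of its
#' focal grouping. Recall is measured against all planted hub proteins.
#'
#' @param diffcor data.frame from [differential_correlation()].
#' @param truth ground truth from [generate_spc_dataset()].
#' @return named numeric vector with `precision`, `recall`, `n_called`,
#'   `n_planted`.
#' @export
recovery_metrics <- function(diffcor, truth) {
  called <- which(diffcor$called)
  planted <- unique(unlist(truth$planted_hubs))
  tp <- sum(mapply(function(p, g) p %in% truth$planted_hubs[[g]],
                   diffcor$protein[called], diffcor$focal_grouping[called]))
  c(precision = if (length(called)) tp / length(called) else NaN,
    recall = if (length(planted)) tp / length(planted) else NaN,
    n_called = length(called), n_planted = length(planted))
}
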