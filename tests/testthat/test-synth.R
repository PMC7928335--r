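test_that("replicate defaults solve the pooled grouping sizes", {
  sim <- generate_spc_dataset(simulation_config(n_proteins = 40, module_size = 5))
  meta <- sim$metadata
  expect_equal(nrow(meta), 27L)
  expect_length(grouping_samples(meta, "Fe_sufficiency"), 12L)
  expect_length(grouping_samples(meta, "Mo_sufficiency"), 14L)
  expect_length(grouping_samples(meta, "Fe_starvation"), 15L)
  expect_length(grouping_samples(meta, "Mo_starvation"), 13L)
})

test_that("generator is deterministic under a fixed seed and leaks no RNG state", {
  cfg <- simulation_config(n_proteins = 60, module_size = 6, seed = 11)
  set.seed(99)
  a <- generate_spc_dataset(cfg)
  after_a <- stats::runif(1)
  set.seed(99)
  b <- generate_spc_dataset(cfg)
  after_b <- stats::runif(1)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(a$metadata, b$metadata)
  expect_identical(after_a, after_b)  # caller's RNG stream untouched

  m1 <- generate_ortholog_map(rownames(a$counts), seed = 5)
  m2 <- generate_ortholog_map(rownames(a$counts), seed = 5)
  expect_identical(m1, m2)
  t1 <- generate_interaction_table(a$truth, m1, seed = 5)
  t2 <- generate_interaction_table(a$truth, m1, seed = 5)
  expect_identical(t1, t2)
})

test_that("counts are non-negative integers with planted truth consistent", {
  sim <- generate_spc_dataset(simulation_config(n_proteins = 80, module_size = 10,
                                                n_de_proteins = 8, seed = 2))
  expect_true(all(sim$counts >= 0))
  expect_type(sim$counts[1, 1], "integer")
  truth <- sim$truth
  prot <- rownames(sim$counts)
  expect_true(all(unlist(truth$planted_hubs) %in% prot))
  expect_true(all(truth$de_proteins %in% prot))
  # DE proteins are drawn outside the planted modules
  expect_false(any(truth$de_proteins %in% names(which(!is.na(truth$module_assignment)))))
  # planted hub sets match module membership
  for (k in seq_along(truth$module_grouping)) {
    mem <- names(truth$module_assignment)[which(truth$module_assignment == k)]
    expect_true(all(mem %in% truth$planted_hubs[[truth$module_grouping[k]]]))
  }
})

test_that("config validation rejects inconsistent designs", {
  expect_error(simulation_config(reps_per_condition = c("+Mo+Fe" = 6)),
               "missing base condition")
  expect_error(simulation_config(n_proteins = 10, n_modules = 4, module_size = 5),
               "exceeds n_proteins")
  expect_error(simulation_config(nb_dispersion = 0), "nb_dispersion")
})

test_that("i.i.d. null config yields no co-expression structure", {
  # no modules, no DE: proteins are exchangeable; the double threshold keeps
  # the edge rate at or below its nominal level
  cfg <- simulation_config(n_proteins = 120, n_modules = 0, module_size = 0,
                           n_de_proteins = 0, seed = 4,
                           baseline_log2_mean_range = c(3, 6),
                           dropout_midpoint = -20)
  sim <- generate_spc_dataset(cfg)
  gs <- grouping_samples(sim$metadata, "Mo_starvation")
  cres <- spearman_all_pairs(sim$counts, gs)
  hit <- abs(cres$rho) > 0.7 & cres$p < 0.01
  rate <- mean(hit[upper.tri(hit)])
  expect_lte(rate, 0.015)
})

test_that("ortholog map hits the target mean homology and supports bijection", {
  prot <- sprintf("P%04d", 1:500)
  map <- generate_ortholog_map(prot, mean_homology = 67, seed = 3)
  expect_equal(nrow(map), 500L)
  expect_true(abs(mean(map$homology_pct) - 67) < 3)
  expect_true(all(map$homology_pct > 0 & map$homology_pct <= 100))

  bij <- generate_ortholog_map(prot, fraction_many_to_one = 0, seed = 3)
  expect_equal(anyDuplicated(bij$gene), 0L)

  shared <- generate_ortholog_map(prot, fraction_many_to_one = 0.2, seed = 3)
  expect_equal(sum(table(shared$gene) == 2), 100L)
})

test_that("interaction generator reproduces module structure at p_in=1, p_out=0", {
  sim <- generate_spc_dataset(simulation_config(n_proteins = 40, module_size = 8,
                                                n_modules = 3, n_de_proteins = 0,
                                                seed = 6))
  map <- generate_ortholog_map(rownames(sim$counts), fraction_many_to_one = 0, seed = 6)
  tab <- generate_interaction_table(sim$truth, map, p_in = 1, p_out = 0,
                                    frac_subthreshold = 0, seed = 6)
  # expected: exactly the within-module gene pairs
  g_of <- stats::setNames(map$gene, map$protein)
  want <- sim$truth$true_interactions
  want_keys <- sort(paste(pmin(g_of[want$protein_a], g_of[want$protein_b]),
                          pmax(g_of[want$protein_a], g_of[want$protein_b])))
  got_keys <- sort(paste(pmin(tab$gene_a, tab$gene_b),
                         pmax(tab$gene_a, tab$gene_b)))
  expect_identical(got_keys, want_keys)
  # frac_subthreshold = 0: every row passes at least one channel filter
  expect_true(all(tab$database_score > 0.15 | tab$experimental_score > 0.35))

  low <- generate_interaction_table(sim$truth, map, p_in = 1, p_out = 0,
                                    frac_subthreshold = 1, seed = 6)
  expect_equal(nrow(filter_interactions(low)), 0L)
})

test_that("interaction presence is independent of modules when p_in equals p_out", {
  sim <- generate_spc_dataset(simulation_config(n_proteins = 60, module_size = 10,
                                                n_modules = 4, n_de_proteins = 0,
                                                seed = 1))
  map <- generate_ortholog_map(rownames(sim$counts), fraction_many_to_one = 0, seed = 1)
  g_of <- stats::setNames(map$gene, map$protein)
  mod_of <- sim$truth$module_assignment
  pairs <- utils::combn(map$gene, 2)
  same <- !is.na(mod_of[map$protein[match(pairs[1, ], map$gene)]]) &
    !is.na(mod_of[map$protein[match(pairs[2, ], map$gene)]]) &
    mod_of[map$protein[match(pairs[1, ], map$gene)]] ==
      mod_of[map$protein[match(pairs[2, ], map$gene)]]
  nonsig <- 0L
  for (s in 1:20) {
    tab <- generate_interaction_table(sim$truth, map, p_in = 0.3, p_out = 0.3,
                                      seed = s)
    keys <- paste(tab$gene_a, tab$gene_b)
    present <- paste(pmin(pairs[1, ], pairs[2, ]), pmax(pairs[1, ], pairs[2, ])) %in%
      paste(pmin(tab$gene_a, tab$gene_b), pmax(tab$gene_a, tab$gene_b))
    pval <- suppressWarnings(stats::chisq.test(table(same, present))$p.value)
    if (pval >= 0.01) nonsig <- nonsig + 1L
  }
  expect_gte(nonsig, 18L)
})

test_that("recovery metrics score calls against the planted truth", {
  truth <- list(planted_hubs = list(A = c("p1", "p2"), B = "p3"))
  dc <- data.frame(protein = c("p1", "p2", "p3", "p4"),
                   called = c(TRUE, FALSE, TRUE, TRUE),
                   focal_grouping = c("A", NA, "B", "A"),
                   stringsAsFactors = FALSE)
  m <- recovery_metrics(dc, truth)
  expect_equal(unname(m["precision"]), 2 / 3)
  expect_equal(unname(m["recall"]), 2 / 3)
})
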