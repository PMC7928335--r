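test_that("betweenness on canonical small graphs", {
  path3 <- graph_from_pairs(c("a", "b", "b", "c"))
  b <- betweenness_centrality(path3)
  expect_equal(unname(b[c("a", "b", "c")]), c(0, 1, 0))

  star <- graph_from_pairs(c("c0", "l1", "c0", "l2", "c0", "l3"))
  bs <- betweenness_centrality(star)
  expect_equal(unname(bs["c0"]), 3)  # three leaf pairs, unique paths
  expect_equal(unname(bs[c("l1", "l2", "l3")]), c(0, 0, 0))

  cyc4 <- graph_from_pairs(c("a", "b", "b", "c", "c", "d", "d", "a"))
  bc <- betweenness_centrality(cyc4)
  expect_equal(unname(bc), rep(0.5, 4))  # opposite pairs split two paths
})

test_that("centroid on canonical small graphs", {
  star <- graph_from_pairs(c("c0", "l1", "c0", "l2", "c0", "l3"))
  cs <- centroid_centrality(star)
  expect_equal(unname(cs["c0"]), 2)
  expect_equal(unname(cs[c("l1", "l2", "l3")]), c(-2, -2, -2))

  path3 <- graph_from_pairs(c("a", "b", "b", "c"))
  cp <- centroid_centrality(path3)
  expect_equal(unname(cp[c("a", "b", "c")]), c(-1, 1, -1))

  k4 <- graph_from_pairs(c("a", "b", "a", "c", "a", "d", "b", "c", "b", "d", "c", "d"))
  expect_equal(unname(centroid_centrality(k4)), rep(0, 4))
})

test_that("centralities equal brute-force oracles on random graphs", {
  set.seed(23)
  for (i in 1:40) {
    n <- sample(3:8, 1)
    rg <- random_test_graph(n, runif(1, 0.3, 0.7))
    b <- betweenness_centrality(rg$graph)
    expect_equal(unname(b), oracle_betweenness(rg$adj), tolerance = 1e-12)
    ce <- centroid_centrality(rg$graph)
    expect_equal(unname(ce), oracle_centroid(rg$adj), tolerance = 1e-12)
  }
})

test_that("centroid is computed per connected component, singletons scoring 0", {
  net <- graph_from_pairs(c("a", "b", "b", "c"), isolated = "z")
  ce <- centroid_centrality(net)
  expect_equal(unname(ce["z"]), 0)
  expect_equal(unname(ce["b"]), 1)
})

test_that("tree betweenness sums to the path-length identity", {
  # for trees: sum_v B(v) = sum over connected pairs of (path length - 1)
  set.seed(29)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    edges <- character(0)
    for (v in 2:n) {
      edges <- c(edges, paste0("n", sample(v - 1, 1)), paste0("n", v))
    }
    tree <- graph_from_pairs(edges)
    b <- betweenness_centrality(tree)
    d <- igraph::distances(tree)
    expect_equal(sum(b), sum(d[upper.tri(d)] - 1))
  }
})

test_that("hub calling uses strict above-the-mean rules", {
  star <- graph_from_pairs(c("c0", "l1", "c0", "l2", "c0", "l3"))
  ct <- centrality_table(star)
  expect_identical(call_hubs(ct, mode = "ppi"), "c0")

  cyc <- graph_from_pairs(c("a", "b", "b", "c", "c", "a"))  # 2-regular
  expect_identical(call_hubs(centrality_table(cyc), mode = "coexpression"),
                   character(0))

  path4 <- graph_from_pairs(c("a", "b", "b", "c", "c", "d"))
  expect_setequal(call_hubs(centrality_table(path4), mode = "coexpression"),
                  c("b", "c"))  # degrees 1,2,2,1; mean 1.5
})

test_that("OR-combined PPI hub sets contain the AND-combined sets", {
  set.seed(37)
  for (i in 1:10) {
    rg <- random_test_graph(10, 0.35)$graph
    ct <- centrality_table(rg)
    and_set <- call_hubs(ct, mode = "ppi", combine = "and")
    or_set <- call_hubs(ct, mode = "ppi", combine = "or")
    expect_true(all(and_set %in% or_set))
  }
})

test_that("condition-specific hubs follow the both-and-neither rule", {
  hub_sets <- list("+Mo+Fe" = c("h1", "h4", "h5"),
                   "+Mo-Fe" = c("h2", "h4"),
                   "-Mo+Fe" = c("h1", "h4", "h6"),
                   "-Mo-Fe" = c("h4", "h6"))
  fe <- condition_specific_hubs(hub_sets, "Fe")
  # h1: hub in both +Fe networks, in neither -Fe network
  expect_identical(fe[["+Fe"]], "h1")
  # h4: hub everywhere -> specific to no level
  expect_false("h4" %in% unlist(fe))
  # h2: hub in only one -Fe network -> not specific under "both"
  expect_false("h2" %in% fe[["-Fe"]])
  # h6 is in -Mo+Fe (a +Fe network) so not -Fe specific either
  expect_identical(fe[["-Fe"]], character(0))
  expect_length(intersect(fe[["+Fe"]], fe[["-Fe"]]), 0)

  any_rule <- condition_specific_hubs(hub_sets, "Fe", rule = "any")
  expect_true("h5" %in% any_rule[["+Fe"]])

  expect_error(condition_specific_hubs(hub_sets[1:3], "Fe"), "missing hub set")
})

test_that("differential correlation needs a strict maximum above the focal mean", {
  groupings <- names(condition_groupings())
  deg <- rbind(flat = c(5, 5, 5, 5),
               below = c(30, 1, 1, 1),
               good = c(2, 2, 1, 22))
  colnames(deg) <- groupings
  means <- stats::setNames(c(35, 10, 10, 12.9), groupings)
  dc <- differential_correlation(deg, means)
  expect_false(dc$called[dc$protein == "flat"])   # no strict maximum
  expect_false(dc$called[dc$protein == "below"])  # below focal mean
  expect_true(dc$called[dc$protein == "good"])
  expect_equal(dc$focal_grouping[dc$protein == "good"], "Mo_starvation")
})

test_that("grouping degree matrix fills absences with zero", {
  nets <- list(g1 = graph_from_pairs(c("a", "b", "b", "c")),
               g2 = graph_from_pairs(c("a", "d")))
  gd <- grouping_degrees(nets)
  expect_equal(gd$degrees["c", "g2"], 0)
  expect_equal(gd$degrees["b", "g1"], 2)
  expect_equal(unname(gd$mean_degree["g1"]), 4 / 3)
})

test_that("ego networks retain neighbors, induced edges and attributes", {
  cres <- fake_cres(c("h", "n1", "n2", "far"), list(
    list("h", "n1", 0.9, 1e-4),
    list("h", "n2", -0.8, 1e-3),
    list("n1", "n2", 0.95, 1e-5),
    list("n2", "far", 0.92, 1e-4)))
  net <- build_coexpression_network(cres)
  ego <- ego_network(net, "h")
  expect_setequal(igraph::V(ego)$name, c("h", "n1", "n2"))
  expect_equal(igraph::ecount(ego), 3L)
  expect_setequal(igraph::E(ego)$sign, c("positive", "negative", "positive"))

  lone <- build_coexpression_network(cres, keep_isolated = TRUE)
  lone <- igraph::add_vertices(lone, 1, name = "alone")
  expect_equal(igraph::vcount(ego_network(lone, "alone")), 1L)
  expect_equal(igraph::vcount(ego_network(net, "missing")), 0L)
})

test_that("ego size equals hub degree plus one when neighbors share no edges", {
  star <- graph_from_pairs(c("c0", "l1", "c0", "l2", "c0", "l3"))
  ego <- ego_network(star, "c0")
  expect_equal(igraph::vcount(ego), unname(igraph::degree(star, "c0")) + 1)
  expect_equal(igraph::ecount(ego), igraph::ecount(star))
})

test_that("edge overlap reports pair-level and protein-level percentages", {
  coex <- graph_from_pairs(c("a", "b", "b", "c"))
  ppi <- graph_from_pairs(c("a", "b", "x", "y"))
  ov <- edge_overlap(coex, ppi)
  expect_equal(ov$pair_pct, 50)
  expect_equal(ov$protein_pct, 100 * 2 / 3)

  expect_equal(edge_overlap(coex, coex)$pair_pct, 100)
  expect_equal(edge_overlap(coex, graph_from_pairs(c("x", "y")))$pair_pct, 0)
  empty <- igraph::make_empty_graph(directed = FALSE)
  expect_true(is.na(edge_overlap(empty, ppi)$pair_pct))
})
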