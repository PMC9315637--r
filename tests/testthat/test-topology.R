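test_that("degree distribution covers the standard small fixtures", {
  tri <- igraph::make_ring(3)
  expect_equal(degree_distribution_table(tri), c("2" = 1.0))
  star <- igraph::make_star(5, mode = "undirected")
  expect_equal(degree_distribution_table(star), c("1" = 0.8, "4" = 0.2))
  iso <- igraph::make_empty_graph(3, directed = FALSE)
  expect_equal(degree_distribution_table(iso), c("0" = 1.0))
  expect_error(degree_distribution_table(igraph::make_empty_graph(0)),
               class = "dilinet_validation_error")
  # probabilities always sum to 1 on arbitrary graphs
  set.seed(8)
  g <- igraph::sample_gnp(40, 0.1)
  expect_equal(sum(degree_distribution_table(g)), 1)
})

test_that("power-law fit recovers a planted exponent and accepts the fit", {
  set.seed(11)
  x <- rpl_discrete(2000, 2.5, 1)
  res <- powerlaw_goodness_of_fit(x, n_bootstrap = 50, seed = 3)
  expect_lt(abs(res$exponent - 2.5), 0.2)
  expect_gt(res$ks_p_value, 0.1)
})

test_that("exponent recovery bias stays within 0.2 across seeds and exponents", {
  for (alpha in c(2.2, 2.5, 3.0)) {
    errs <- vapply(1:20, function(s) {
      set.seed(s)
      x <- rpl_discrete(2000, alpha, 1)
      abs(igraph::fit_power_law(x, implementation = "plfit")$alpha - alpha)
    }, numeric(1))
    expect_lt(mean(errs), 0.2)
  }
})

test_that("Poisson-like degrees from a random graph reject the power law", {
  set.seed(12)
  g <- igraph::sample_gnm(1000, 10000)  # mean degree 20
  res <- powerlaw_goodness_of_fit(igraph::degree(g), n_bootstrap = 50, seed = 3)
  expect_lt(res$ks_p_value, 0.05)
})

test_that("power-law fit enforces its preconditions", {
  expect_error(powerlaw_goodness_of_fit(c(1, 2, 3)),
               class = "dilinet_validation_error")
  expect_error(powerlaw_goodness_of_fit(rep(5, 50)),
               class = "dilinet_degenerate_error")
})

test_that("scale-free reference matches requested size exactly and is reproducible", {
  g <- scale_free_reference(202, 2695, seed = 5)
  expect_equal(igraph::vcount(g), 202)
  expect_equal(igraph::ecount(g), 2695)
  g2 <- scale_free_reference(202, 2695, seed = 5)
  expect_identical(igraph::as_edgelist(g), igraph::as_edgelist(g2))
  # its own degree distribution passes the power-law goodness of fit
  res <- powerlaw_goodness_of_fit(igraph::degree(g), n_bootstrap = 50, seed = 2)
  expect_gt(res$ks_p_value, 0.05)
  # tiny case: 5 nodes, 4 edges is a feasible star-like seed
  small <- scale_free_reference(5, 4, seed = 1)
  expect_equal(igraph::ecount(small), 4)
  expect_error(scale_free_reference(4, 10, seed = 1),
               class = "dilinet_validation_error")
})

test_that("assortativity attains the exact extreme and hand-computed values", {
  # two 4-cliques, no cross edges: perfectly assortative
  two_cliques <- igraph::disjoint_union(igraph::make_full_graph(4),
                                        igraph::make_full_graph(4))
  labels <- rep(c("X", "Y"), each = 4)
  expect_equal(assortativity_by_class(two_cliques, labels), 1)
  # complete bipartite between the classes: perfectly disassortative
  bip <- igraph::make_full_bipartite_graph(4, 4)
  expect_equal(assortativity_by_class(bip, labels), -1)
  # path a-b-c-d labelled X,X,Y,Y: Newman mixing matrix gives 1/3
  path <- igraph::make_graph(~ a - b, b - c, c - d)
  expect_equal(assortativity_by_class(
    path, c(a = "X", b = "X", c = "Y", d = "Y")), 1 / 3)
  # single class: undefined
  expect_warning(A <- assortativity_by_class(path, c(a = "X", b = "X",
                                                     c = "X", d = "X")),
                 "one class")
  expect_true(is.na(A))
})

test_that("modularity matches closed forms on clique fixtures", {
  clique5 <- igraph::make_full_graph(5)
  two <- igraph::disjoint_union(clique5, clique5)
  expect_equal(modularity_score(two)$M, 0.5)
  bridged <- igraph::add_edges(two, c(1, 6))
  ms <- modularity_score(bridged)
  # closed form: 2 (10/21 - (21/42)^2)
  expect_equal(ms$M, 2 * (10 / 21 - 0.25), tolerance = 1e-12)
  expect_lt(abs(ms$M - 0.5), 0.05)
  expect_equal(length(unique(ms$partition)), 2L)
  # complete graph: single community, M = 0
  comp <- igraph::make_full_graph(6)
  expect_equal(modularity_score(comp)$M, 0)
  expect_error(modularity_score(igraph::make_empty_graph(3)),
               class = "dilinet_validation_error")
})

test_that("extreme rewiring moves the target metric and preserves degrees", {
  set.seed(13)
  g <- igraph::sample_gnm(40, 120)
  igraph::V(g)$name <- sprintf("n%02d", 1:40)
  labels <- setNames(rep(c("X", "Y"), each = 20), igraph::V(g)$name)
  deg0 <- sort(igraph::degree(g))
  A0 <- assortativity_by_class(g, labels)
  up <- reference_extreme_networks(g, labels, "assortative", seed = 2)
  down <- reference_extreme_networks(g, labels, "unassortative", seed = 2)
  expect_gte(assortativity_by_class(up, labels[igraph::V(up)$name]), A0)
  expect_lte(assortativity_by_class(down, labels[igraph::V(down)$name]), A0)
  # degree sequence preserved exactly, per node
  expect_equal(igraph::degree(up)[igraph::V(g)$name], igraph::degree(g))
  expect_equal(igraph::degree(down)[igraph::V(g)$name], igraph::degree(g))
  # determinism under the seed
  up2 <- reference_extreme_networks(g, labels, "assortative", seed = 2)
  expect_identical(igraph::as_edgelist(up), igraph::as_edgelist(up2))
})

test_that("modularity extremes move the greedy modularity in the right direction", {
  set.seed(14)
  g <- igraph::sample_gnm(40, 120)
  igraph::V(g)$name <- sprintf("n%02d", 1:40)
  M0 <- modularity_score(g)$M
  mod_up <- reference_extreme_networks(g, target = "modular", seed = 3)
  mod_down <- reference_extreme_networks(g, target = "unmodular", seed = 3)
  expect_gte(modularity_score(mod_up)$M, M0)
  expect_lte(modularity_score(mod_down)$M, M0 + 0.02)
  expect_equal(sort(igraph::degree(mod_up)), sort(igraph::degree(g)))
  expect_equal(sort(igraph::degree(mod_down)), sort(igraph::degree(g)))
})

test_that("complete graphs cannot be rewired and warn", {
  comp <- igraph::make_full_graph(5)
  igraph::V(comp)$name <- letters[1:5]
  labels <- setNames(c("X", "X", "Y", "Y", "Y"), letters[1:5])
  expect_warning(out <- reference_extreme_networks(comp, labels, "assortative"),
                 "complete")
  expect_equal(igraph::ecount(out), 10)
})

test_that("topology summary collects the per-network diagnostics", {
  nodes <- data.frame(drug_id = letters[1:6],
                      toxicity_class = rep(c("toxic", "safe"), each = 3),
                      category = NA_character_)
  e <- expand.grid(i = 1:6, j = 1:6)
  e <- e[e$i < e$j & ((e$i <= 3) == (e$j <= 3)), ]
  edges <- data.frame(drug_i = letters[e$i], drug_j = letters[e$j],
                      h_protein = 3, h_domain = 3, alpha = 3 * sqrt(2),
                      gamma = 45)
  net <- network_bundle(nodes, edges)
  ts <- topology_summary(net, n_bootstrap = 10, seed = 1)
  expect_equal(ts$n_nodes, 6L)
  expect_equal(ts$n_edges, 6L)
  expect_equal(sum(ts$degree_distribution), 1)
  expect_equal(ts$assortativity_A, 1)  # two toxic/safe triangles
  expect_equal(ts$modularity_M, 0.5)
  expect_true(is.na(ts$powerlaw_exponent))  # too few positive degrees
})
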