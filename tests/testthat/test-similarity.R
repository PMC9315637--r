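test_that("hypergeometric index matches exact enumeration on small cases", {
  # universe 10, |A| = |B| = 3, full overlap: p = 1/C(10,3) = 1/120
  idx <- hypergeometric_index(c("a", "b", "c"), c("a", "b", "c"), 10)
  expect_equal(idx, log10(120), tolerance = 1e-12)
  # disjoint profiles give index 0
  expect_equal(hypergeometric_index(c("a", "b"), c("c", "d"), 10), 0)
  # identical singletons in a tiny universe
  expect_equal(hypergeometric_index("a", "a", 3), log10(3), tolerance = 1e-12)
})

test_that("index agrees with the brute-force oracle for universes up to 25", {
  set.seed(5)
  for (i in 1:300) {
    u <- sample(2:25, 1)
    n_a <- sample(1:u, 1)
    n_b <- sample(1:u, 1)
    k_min <- max(0, n_a + n_b - u)
    k <- sample(k_min:min(n_a, n_b), 1)
    # construct explicit sets realising (k, n_a, n_b, u)
    a <- seq_len(n_a)
    b <- c(seq_len(k), if (n_b > k) (n_a + 1):(n_a + n_b - k))
    idx <- hypergeometric_index(as.character(a), as.character(b), u)
    p_oracle <- oracle_hyper_tail(k, n_a, n_b, u)
    if (k == 0) {
      expect_equal(idx, 0)
    } else {
      expect_equal(idx, -log10(p_oracle), tolerance = 1e-9)
    }
  }
})

test_that("index is symmetric for all profile shapes in small universes", {
  for (u in 2:8) {
    for (n_a in 1:u) for (n_b in 1:u) {
      k_min <- max(0, n_a + n_b - u)
      for (k in k_min:min(n_a, n_b)) {
        a <- as.character(seq_len(n_a))
        b <- as.character(c(seq_len(k),
                            if (n_b > k) (n_a + 1):(n_a + n_b - k)))
        expect_identical(hypergeometric_index(a, b, u),
                         hypergeometric_index(b, a, u))
      }
    }
  }
})

test_that("index is monotone in the overlap at fixed sizes", {
  u <- 20; n_a <- 8; n_b <- 6
  idx <- vapply(0:6, function(k) {
    a <- as.character(seq_len(n_a))
    b <- as.character(c(seq_len(k), if (n_b > k) (n_a + 1):(n_a + n_b - k)))
    hypergeometric_index(a, b, u)
  }, numeric(1))
  expect_true(all(diff(idx) >= 0))
})

test_that("an index of 3 means tail probability 1e-3; above 3, below 0.001", {
  expect_identical(index_tail_probability(3), 1e-3)
  set.seed(6)
  # any observed index above 3 corresponds to p < 0.001
  for (i in 1:50) {
    u <- sample(10:30, 1)
    n <- sample(3:6, 1)
    a <- as.character(seq_len(n))
    idx <- hypergeometric_index(a, a, u)
    if (idx > 3) {
      expect_lt(oracle_hyper_tail(n, n, n, u), 0.001)
    }
  }
})

test_that("profiles larger than the universe are rejected", {
  expect_error(hypergeometric_index(as.character(1:5), "1", 4),
               class = "dilinet_validation_error")
  expect_error(hypergeometric_index("a", "b", 0),
               class = "dilinet_validation_error")
})

test_that("pair vectors follow the axis conventions", {
  v <- pair_vector(c(3, 3, 0, 3), c(3, 0, 3, 4))
  expect_equal(v$alpha, c(3 * sqrt(2), 3, 3, 5))
  expect_equal(v$gamma, c(45, 0, 90, atan2(4, 3) * 180 / pi))
  # 3-4-5 triangle angle
  expect_equal(v$gamma[4], 53.1301, tolerance = 1e-4)
  # both-zero pairs are suppressed as NA
  z <- pair_vector(0, 0)
  expect_true(is.na(z$alpha) && is.na(z$gamma))
})

test_that("network construction emits edges per rule and keeps isolated nodes", {
  # two drugs with identical profiles in small universes: one strong edge
  prof <- list(A = c("P1", "P2", "P3"), B = c("P1", "P2", "P3"),
               C = c("P7", "P8", "P9"))
  doms <- list(A = c("F1", "F2"), B = c("F1", "F2"), C = character(0))
  net <- suppressMessages(build_network(
    prof, doms, rule = edge_rule(1),
    protein_universe = sprintf("P%d", 1:9),
    domain_universe = sprintf("F%d", 1:4)))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(sort(c(net$edges$drug_i, net$edges$drug_j)), c("A", "B"))
  expect_gt(net$edges$gamma, 0)
  expect_lt(net$edges$gamma, 90)
  # C has no overlap with anyone but stays in the node table
  expect_true("C" %in% net$nodes$drug_id)
  # cutoff above the largest observed index empties the edge set
  high <- suppressMessages(build_network(
    prof, doms, rule = edge_rule(50),
    protein_universe = sprintf("P%d", 1:9),
    domain_universe = sprintf("F%d", 1:4)))
  expect_equal(nrow(high$edges), 0L)
  expect_equal(nrow(high$nodes), 3L)
  expect_error(build_network(list(A = "P1")),
               class = "dilinet_validation_error")
})

test_that("edge sets shrink monotonically as the cutoff grows, in every mode", {
  set.seed(7)
  prof <- lapply(setNames(1:12, sprintf("D%02d", 1:12)), function(i) {
    sample(sprintf("P%d", 1:20), 8)
  })
  doms <- lapply(setNames(1:12, sprintf("D%02d", 1:12)), function(i) {
    sample(sprintf("F%d", 1:8), 3)
  })
  pairs <- suppressMessages(pair_similarities(prof, doms))
  for (mode in c("either_channel", "both_channels", "module")) {
    prev <- NULL
    for (co in c(0.5, 1, 2, 3, 5)) {
      net <- suppressMessages(build_network(prof, doms,
                                            rule = edge_rule(co, mode),
                                            pairs = pairs))
      keys <- paste(net$edges$drug_i, net$edges$drug_j)
      if (!is.null(prev)) expect_true(all(keys %in% prev))
      prev <- keys
    }
  }
})

test_that("angle distribution summarises passing pairs per cutoff", {
  single <- data.frame(drug_i = "A", drug_j = "B", h_protein = 3,
                       h_domain = 3, alpha = 3 * sqrt(2), gamma = 45)
  tab <- angle_distribution(single, c(1, 2, 3))
  expect_equal(tab$n, c(1L, 1L, 1L))
  expect_equal(tab$median_gamma, c(45, 45, 45))
  # no pairs at all: zero counts
  none <- angle_distribution(single[0, ], c(1, 2))
  expect_equal(none$n, c(0L, 0L))
  expect_true(all(is.na(none$median_gamma)))
})

test_that("median angle falls from domain-dominated to protein-dominated as cutoff rises", {
  # many weak domain-only pairs, few strong protein-only pairs
  weak <- data.frame(drug_i = sprintf("A%d", 1:20), drug_j = sprintf("B%d", 1:20),
                     h_protein = 0.2, h_domain = 1.5)
  strong <- data.frame(drug_i = sprintf("C%d", 1:5), drug_j = sprintf("E%d", 1:5),
                       h_protein = 4, h_domain = 0.3)
  pairs <- rbind(weak, strong)
  v <- pair_vector(pairs$h_protein, pairs$h_domain)
  pairs$alpha <- v$alpha
  pairs$gamma <- v$gamma
  tab <- angle_distribution(pairs, c(1, 3))
  expect_gt(tab$median_gamma[tab$cutoff == 1],
            tab$median_gamma[tab$cutoff == 3])
  expect_gt(tab$median_gamma[tab$cutoff == 1], 45)
  expect_lt(tab$median_gamma[tab$cutoff == 3], 45)
})
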