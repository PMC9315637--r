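test_that("DILI score reproduces the published small-community cells", {
  expect_identical(dili_score(td = 2, vtd = 0, d = 4), 50L)
  expect_identical(dili_score(td = 2, vtd = 0, d = 3), 67L)
  expect_identical(dili_score(td = 1, vtd = 0, d = 3), 33L)
  expect_identical(dili_score(td = 0, vtd = 0, d = 5), 0L)
  # withdrawn drugs count twice; scores can exceed 100
  expect_identical(dili_score(td = 2, vtd = 1, d = 3), 100L)
  expect_identical(dili_score(td = 3, vtd = 3, d = 3), 200L)
  # configurable withdrawn weight
  expect_identical(dili_score(td = 2, vtd = 1, d = 3, vtd_weight = 0), 67L)
})

test_that("DILI score validates its counts", {
  expect_error(dili_score(td = 3, vtd = 0, d = 2),
               class = "dilinet_validation_error")
  expect_error(dili_score(td = 1, vtd = 2, d = 3),
               class = "dilinet_validation_error")
  expect_error(dili_score(td = 0, vtd = 0, d = 0),
               class = "dilinet_validation_error")
})

test_that("score is monotone in toxic counts and antitone in size", {
  expect_gte(dili_score(3, 0, 6), dili_score(2, 0, 6))
  expect_gte(dili_score(3, 2, 6), dili_score(3, 1, 6))
  expect_lte(dili_score(2, 0, 7), dili_score(2, 0, 5))
})

test_that("community ranking orders by score, then size, then id", {
  reports <- data.frame(community_id = 1:3, d = c(4, 3, 3),
                        dili_score = c(50L, 67L, 33L))
  expect_equal(rank_communities(reports)$dili_score, c(67L, 50L, 33L))
  ties <- data.frame(community_id = c(1L, 2L), d = c(3L, 29L),
                     dili_score = c(75L, 75L))
  expect_equal(rank_communities(ties)$community_id, c(2L, 1L))
  empty <- reports[0, ]
  expect_equal(nrow(rank_communities(empty)), 0L)
})

test_that("dominant families keep ties and ignore drug ordering", {
  profiles <- list(d1 = c("PF00008", "PF03098"), d2 = c("PF00008", "PF03098"),
                   d3 = c("PF00008", "PF03098", "PF99999"))
  fams <- dominant_family(c("d1", "d2", "d3"), profiles)
  expect_equal(fams, c("PF00008", "PF03098"))
  expect_equal(dominant_family(c("d3", "d1", "d2"), profiles), fams)
  # unique maximum
  profiles2 <- list(d1 = "PF00001", d2 = c("PF00001", "PF00002"))
  expect_equal(dominant_family(c("d1", "d2"), profiles2), "PF00001")
  # no domains at all
  expect_warning(none <- dominant_family("d9", profiles2), "unnamed")
  expect_length(none, 0L)
})

test_that("category tabulation counts descending with unclassified fallback", {
  drugs <- data.frame(
    drug_id = c("d1", "d2", "d3", "d4"),
    toxicity_class = "safe",
    therapeutic_category = c("NSAIDs", "NSAIDs", "Nervous system", NA),
    stringsAsFactors = FALSE
  )
  tab <- category_tabulation(c("d1", "d2", "d3", "d4"), drugs)
  expect_equal(tab, c("NSAIDs" = 2L, "Nervous system" = 1L,
                      "unclassified" = 1L))
  expect_equal(category_tabulation(c("d1", "d2"), drugs), c("NSAIDs" = 2L))
})

test_that("target over-representation matches the enumeration oracle", {
  universe <- sprintf("P%d", 1:10)
  targets <- c("P1", "P2", "P3")
  sets <- list(exact = targets, miss = c("P8", "P9"),
               partial = c("P1", "P5"))
  res <- target_ora(targets, sets, universe)
  # term identical to the targets: p = 1/C(10,3) = 1/120
  expect_equal(res$p_value[res$term == "exact"], 1 / 120, tolerance = 1e-12)
  expect_equal(res$p_value[res$term == "exact"],
               oracle_hyper_tail(3, 3, 3, 10), tolerance = 1e-12)
  # zero overlap: p = 1
  expect_equal(res$p_value[res$term == "miss"], 1)
  expect_equal(res$q_value, bh_adjust(res$p_value))
  # the exact term ranks first
  expect_equal(res$term[1], "exact")
})

test_that("over-representation validates universe containment", {
  expect_error(target_ora("P1", list(t = c("P1", "P99")), c("P1", "P2")),
               class = "dilinet_validation_error")
  expect_error(target_ora("P1", list(), c("P1")),
               class = "dilinet_validation_error")
  expect_error(target_ora("P9", list(t = "P1"), c("P1", "P2")),
               class = "dilinet_validation_error")
})

test_that("community targets take shared proteins on links by default", {
  prof <- list(a = c("P1", "P2", "P3"), b = c("P2", "P3", "P4"),
               c = c("P3", "P9"))
  community <- list(community_id = 1L,
                    edges = rbind(c("a", "b"), c("b", "c")),
                    nodes = c("a", "b", "c"), m_c = 2L, n_c = 3L,
                    density = 0)
  expect_equal(community_targets(community, prof), c("P2", "P3"))
  expect_equal(community_targets(community, prof, mode = "union"),
               c("P1", "P2", "P3", "P4", "P9"))
})

test_that("community reports assemble counts, score, families and categories", {
  g <- igraph::make_graph(~ a - b, a - c, b - c, c - d, c - e, d - e)
  part <- link_communities(g, weighted = FALSE)
  drugs <- data.frame(
    drug_id = letters[1:5],
    toxicity_class = c("very_toxic", "toxic", "safe", "safe", "toxic"),
    therapeutic_category = c("NSAIDs", "NSAIDs", NA, "Nervous system",
                             "Nervous system"),
    stringsAsFactors = FALSE
  )
  profiles <- list(a = "PF00001", b = "PF00001", c = "PF00001",
                   d = "PF00002", e = "PF00002")
  reports <- community_reports(part, drugs, profiles)
  expect_equal(nrow(reports), 2L)
  abc <- reports[grepl("PF00001", reports$dominant_families), ]
  expect_equal(abc$d, 3L)
  expect_equal(abc$td, 2L)
  expect_equal(abc$vtd, 1L)
  expect_equal(abc$dili_score, 100L)  # round(100 * 3/3)
  cde <- reports[reports$community_id != abc$community_id, ]
  expect_equal(cde$td, 1L)
  expect_equal(cde$dili_score, 33L)
  # ranked by score
  expect_equal(reports$dili_score, sort(reports$dili_score, decreasing = TRUE))
  expect_true(all(reports$ranked))
})
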