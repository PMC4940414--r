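named_clique <- function(n, prefix) {
  g <- igraph::make_full_graph(n)
  igraph::V(g)$name <- paste0(prefix, seq_len(n))
  g
}

test_that("walktrap recovers canonical partitions", {
  one <- walktrap_communities(named_clique(5, "a"))
  expect_equal(nrow(one$sizes), 1L)

  two <- igraph::disjoint_union(named_clique(5, "a"), named_clique(5, "b"))
  two <- igraph::add_edges(two, c("a1", "b1"))
  part <- walktrap_communities(two)
  expect_equal(nrow(part$sizes), 2L)
  by_comm <- split(part$membership$feature_id, part$membership$community_id)
  expect_setequal(vapply(by_comm, function(x) paste(sort(substr(x, 1, 1)),
                                                    collapse = ""),
                         character(1)),
                  c("aaaaa", "bbbbb"))

  lonely <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(lonely)$name <- letters[1:4]
  singletons <- walktrap_communities(lonely)
  expect_equal(nrow(singletons$sizes), 4L)
  expect_true(all(singletons$sizes$size == 1L))
})

test_that("internal and residual degrees decompose the full degree", {
  g <- igraph::disjoint_union(named_clique(3, "c"), named_clique(4, "d"))
  pairs <- degree_pairs(g, c("c1", "c2", "c3"))
  expect_equal(pairs$internal_degree, c(2, 2, 2))
  expect_equal(pairs$residual_degree, c(0, 0, 0))

  set.seed(51)
  for (i in 1:10) {
    g <- named_gnp(15, 0.25)
    comm <- sample(igraph::V(g)$name, sample(3:8, 1))
    got <- degree_pairs(g, comm)
    # oracle: classify every edge as intra- or extra-community and count
    el <- igraph::as_edgelist(g)
    internal <- vapply(comm, function(v) {
      sum((el[, 1] == v & el[, 2] %in% comm) |
            (el[, 2] == v & el[, 1] %in% comm))
    }, numeric(1))
    external <- vapply(comm, function(v) {
      sum((el[, 1] == v & !el[, 2] %in% comm) |
            (el[, 2] == v & !el[, 1] %in% comm))
    }, numeric(1))
    expect_equal(got$internal_degree, unname(internal))
    expect_equal(got$residual_degree, unname(external))
    full <- igraph::degree(g)[comm]
    expect_equal(got$internal_degree + got$residual_degree, unname(full))
  }
  expect_error(degree_pairs(g, character(0)), "non-empty")
})

test_that("community significance follows the signed-rank conventions", {
  dense <- tibble::tibble(feature_id = paste0("n", 1:10),
                          internal_degree = 5, residual_degree = 1)
  res <- community_significance(dense)
  expect_true(res$tested)
  expect_equal(res$p_value, 2^-10) # all 10 differences positive, maximal W
  expect_lt(res$p_value, 0.01)

  flat <- tibble::tibble(feature_id = paste0("n", 1:6),
                         internal_degree = 2, residual_degree = 2)
  res_flat <- community_significance(flat)
  expect_equal(res_flat$p_value, 1)
  expect_equal(res_flat$n_informative, 0L)

  small <- tibble::tibble(feature_id = paste0("n", 1:4),
                          internal_degree = 3, residual_degree = 0)
  res_small <- community_significance(small)
  expect_false(res_small$tested)
  expect_true(is.na(res_small$p_value))
})

test_that("the signed-rank test agrees with wilcox.test on both code paths", {
  set.seed(52)
  x <- rnorm(12) + 0.8
  y <- rnorm(12)
  mine <- traitnet:::signed_rank_greater(x, y)
  ref <- wilcox.test(x, y, paired = TRUE, alternative = "greater",
                     exact = TRUE)
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)

  x2 <- sample(1:6, 40, replace = TRUE)
  y2 <- sample(1:6, 40, replace = TRUE)
  mine2 <- traitnet:::signed_rank_greater(x2, y2, exact_max = 0)
  ref2 <- suppressWarnings(
    wilcox.test(x2, y2, paired = TRUE, alternative = "greater",
                exact = FALSE, correct = TRUE)
  )
  expect_equal(mine2$p_value, ref2$p.value, tolerance = 1e-12)
})

test_that("an all-significant partition is a merge fixed point", {
  g <- igraph::disjoint_union(named_clique(6, "a"), named_clique(6, "b"))
  g <- igraph::add_edges(g, c("a1", "b1"))
  part <- test_communities(g, walktrap_communities(g))
  merged <- merge_communities(g, part)
  expect_equal(merged$membership, part$membership)
  expect_equal(merged$merges$original_community,
               merged$merges$merged_community)
})

test_that("a weak community is absorbed by its only significant neighbour", {
  g <- named_clique(8, "a")
  # satellite: 5 nodes with no internal edges, each tied to the clique
  g <- igraph::add_vertices(g, 5, name = paste0("s", 1:5))
  g <- igraph::add_edges(g, c(rbind(paste0("s", 1:5), paste0("a", 1:5))))
  part <- as_community_partition(tibble::tibble(
    feature_id = igraph::V(g)$name,
    community_id = rep(c(1L, 2L), c(8L, 5L))
  ))
  merged <- merge_communities(g, part)
  expect_equal(nrow(merged$sizes), 1L)
  expect_true(all(merged$membership$community_id == 1L))
  expect_equal(merged$merges$merged_community, c(1L, 1L))
  # significance was re-tested on the merged community
  expect_true(merged$significance$tested)
})

test_that("merging targets the neighbour with the most inter-community edges", {
  a <- named_clique(7, "a")
  b <- named_clique(7, "b")
  g <- igraph::disjoint_union(a, b)
  g <- igraph::add_vertices(g, 5, name = paste0("s", 1:5))
  # satellite path: weak internal structure
  g <- igraph::add_edges(g, c("s1", "s2", "s2", "s3", "s3", "s4", "s4", "s5"))
  # 5 bonds to community a, 2 bonds to community b
  g <- igraph::add_edges(g, c("s1", "a1", "s2", "a2", "s3", "a3",
                              "s4", "a4", "s5", "a5", "s1", "b1", "s5", "b2"))
  part <- as_community_partition(tibble::tibble(
    feature_id = igraph::V(g)$name,
    community_id = rep(c(1L, 2L, 3L), c(7L, 7L, 5L))
  ))
  # oracle: count satellite edges into each clique from the edge list
  el <- igraph::as_edgelist(g)
  sat <- paste0("s", 1:5)
  to_a <- sum(xor(el[, 1] %in% sat, el[, 2] %in% sat) &
                (startsWith(el[, 1], "a") | startsWith(el[, 2], "a")))
  to_b <- sum(xor(el[, 1] %in% sat, el[, 2] %in% sat) &
                (startsWith(el[, 1], "b") | startsWith(el[, 2], "b")))
  expect_equal(c(to_a, to_b), c(5, 2))

  merged <- merge_communities(g, part)
  sat_comm <- unique(merged$membership$community_id[
    merged$membership$feature_id %in% sat
  ])
  expect_equal(sat_comm, 1L) # absorbed into the 5-edge neighbour
  expect_equal(nrow(merged$sizes), 2L)
  prov <- merged$merges
  expect_equal(prov$merged_community[prov$original_community == 3L], 1L)
})

test_that("a partition with no significant community is returned unchanged", {
  g <- igraph::make_ring(10)
  igraph::V(g)$name <- paste0("r", 1:10)
  part <- as_community_partition(tibble::tibble(
    feature_id = igraph::V(g)$name,
    community_id = rep(c(1L, 2L), each = 5L)
  ))
  expect_warning(merged <- merge_communities(g, part), "No significant")
  expect_equal(merged$membership$community_id, part$membership$community_id)
})

test_that("walktrap separates planted blocks on stochastic block graphs", {
  set.seed(53)
  hits <- 0L
  for (i in 1:15) {
    g <- igraph::sample_sbm(30, matrix(c(0.4, 0.02, 0.02, 0.4), 2),
                            block.sizes = c(15, 15))
    igraph::V(g)$name <- sprintf("v%02d", 1:30)
    part <- walktrap_communities(g)
    truth <- rep(1:2, each = 15)
    if (ari(part$membership$community_id, truth) >= 0.9) hits <- hits + 1L
  }
  expect_gte(hits, 12L)
})
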