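test_that("modularity matches hand-derived values", {
  # any partition with all nodes together has Q = 0
  net <- net_from_undirected(rbind(c(1, 2), c(3, 4)), 4)
  one <- setNames(rep(1, 4), net$nodes)
  expect_equal(modularity_q(net, one, weighted = FALSE), 0)

  # two disjoint edges split into their pairs: Q = 1/2
  pairs <- setNames(c(1, 1, 2, 2), net$nodes)
  expect_equal(modularity_q(net, pairs, weighted = FALSE), 0.5)

  # K4 split into two pairs is worse than no split
  k4 <- net_from_undirected(t(combn(1:4, 2)), 4)
  expect_lt(modularity_q(k4, pairs, weighted = FALSE), 0)

  # empty graph has undefined modularity
  empty <- binarize(net, 1e12)
  expect_error(modularity_q(empty, one, weighted = FALSE), "m = 0")
})

test_that("modularity agrees with igraph on random weighted graphs", {
  skip_if_not_installed("igraph")
  set.seed(31)
  for (rep in 1:5) {
    n <- 8
    el <- random_undirected_edges(n, 0.5)
    w <- runif(nrow(el), 1, 10)
    codes <- sprintf("N%02d", 1:n)
    fl <- flows_from_edges(data.frame(exporter = codes[el[, 1]],
                                      importer = codes[el[, 2]],
                                      value = w * 1e8), year = 1)
    net <- build_network(fl, 1, countries = codes)
    memb <- sample(1:3, n, replace = TRUE)
    g <- igraph::graph_from_adjacency_matrix(net$weights + t(net$weights),
                                             mode = "undirected",
                                             weighted = TRUE)
    expect_equal(modularity_q(net, setNames(memb, codes)),
                 igraph::modularity(g, memb,
                                    weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
})

test_that("louvain separates two cliques joined by a bridge", {
  el <- rbind(t(combn(1:4, 2)), t(combn(5:8, 2)), c(1, 5))
  net <- net_from_undirected(el, 8)
  part <- louvain(net, weighted = FALSE, seed = 3)
  expect_equal(part$n_communities, 2L)
  expect_equal(length(unique(part$assignment[1:4])), 1L)
  expect_equal(length(unique(part$assignment[5:8])), 1L)
  # matches the brute-force optimum
  bf <- brute_force_modularity(net, weighted = FALSE)
  expect_equal(part$q, bf$q, tolerance = 1e-12)
})

test_that("louvain leaves a complete graph whole with Q = 0", {
  k5 <- net_from_undirected(t(combn(1:5, 2)), 5)
  part <- louvain(k5, weighted = FALSE, seed = 1)
  expect_equal(part$n_communities, 1L)
  expect_equal(part$q, 0)
})

test_that("louvain invariants: Q recomputation, monotone trace, determinism", {
  set.seed(41)
  for (rep in 1:10) {
    n <- sample(6:12, 1)
    net <- net_from_undirected(random_undirected_edges(n, 0.4), n)
    part <- louvain(net, weighted = FALSE, seed = rep)
    expect_equal(modularity_q(net, part$assignment, weighted = FALSE),
                 part$q, tolerance = 1e-12)
    expect_true(all(diff(part$q_trace) >= -1e-12))
    expect_gte(part$q, 0)  # never worse than the singleton start's best merge
    part2 <- louvain(net, weighted = FALSE, seed = rep)
    expect_identical(part$assignment, part2$assignment)
  }
})

test_that("louvain recovers a planted 5-block partition", {
  set.seed(2024)
  blocks <- rep(1:5, each = 20)
  n <- 100
  el <- t(combn(n, 2))
  p <- ifelse(blocks[el[, 1]] == blocks[el[, 2]], 0.6, 0.02)
  el <- el[runif(nrow(el)) < p, , drop = FALSE]
  net <- net_from_undirected(el, n)
  part <- louvain(net, weighted = FALSE, seed = 5)
  ari <- adjusted_rand_index(part$assignment, blocks)
  expect_gte(ari, 0.95)
})

test_that("partition quality and Q are invariant to weight rescaling", {
  set.seed(55)
  n <- 30
  el <- random_undirected_edges(n, 0.2)
  codes <- sprintf("N%02d", 1:n)
  fl <- flows_from_edges(data.frame(exporter = codes[el[, 1]],
                                    importer = codes[el[, 2]],
                                    value = rlnorm(nrow(el), log(5e8), 1)),
                         year = 1)
  net <- build_network(fl, 1, countries = codes)
  p1 <- louvain(net, weighted = TRUE, seed = 9, rescale = FALSE)
  p2 <- louvain(net, weighted = TRUE, seed = 9, rescale = TRUE)
  expect_identical(p1$assignment, p2$assignment)
  expect_equal(p1$q, p2$q, tolerance = 1e-9)
})

test_that("dependence_pairs applies the share threshold", {
  fl <- flows_from_edges(data.frame(
    exporter = c("AAA", "BBB", "CCC", "DDD", "EEE", "FFF"),
    importer = c("IMP", "IMP", "TRI", "TRI", "TRI", "SOL"),
    value = c(6e8, 4e8, 1e8, 1e8, 1e8, 5e8)))
  dp <- dependence_pairs(fl, 2019, theta = 0.5)
  expect_equal(attr(dp, "theta"), 0.5)
  # 0.6/0.4 importer: only the 0.6 supplier qualifies
  expect_equal(dp$supplier[dp$dependent == "IMP"], "AAA")
  expect_equal(dp$share[dp$dependent == "IMP"], 0.6)
  # three equal thirds: nobody reaches 0.5
  expect_false("TRI" %in% dp$dependent)
  # sole supplier qualifies even at theta = 1
  dp1 <- dependence_pairs(fl, 2019, theta = 1.0)
  expect_equal(dp1$dependent, "SOL")
  expect_equal(dp1$share, 1)
  expect_error(dependence_pairs(fl, 2019, theta = 0), "in \\(0, 1\\]")
})

test_that("theta > 0.5 yields at most one supplier per importer", {
  set.seed(61)
  for (rep in 1:10) {
    codes <- sprintf("C%02d", 1:12)
    df <- data.frame(year = 1, exporter = sample(codes, 50, TRUE),
                     importer = sample(codes, 50, TRUE),
                     value = rlnorm(50, 18, 2))
    dp <- dependence_pairs(trade_flows(df), 1, theta = 0.51)
    expect_lte(max(c(0, table(dp$dependent))), 1)
  }
})
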