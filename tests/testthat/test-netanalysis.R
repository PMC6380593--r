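graph_stats <- function(net) {
  g <- network_to_igraph(net)
  list(deg = unname(sort(as.integer(igraph::degree(g)))),
       clust = unname(sort(round(igraph::transitivity(g, "localundirected",
                                                      isolates = "zero"),
                                 10))),
       comp = igraph::count_components(g),
       n_edges = nrow(net$edges))
}

test_that("node-label shuffling preserves all isomorphism invariants", {
  for (s in 1:5) {
    net <- simulate_network(40, "scale_free", 90, seed = s)
    shuf <- shuffle_node_labels(net, seed = s + 10)
    expect_identical(graph_stats(shuf), graph_stats(net))
    expect_setequal(shuf$nodes, net$nodes)
  }
})

test_that("degree-preserving rewiring keeps every node degree and mixes edges", {
  for (s in 1:5) {
    net <- simulate_network(50, "erdos_renyi", 120, seed = s)
    rw <- rewire_preserving_degree(net, seed = s + 20)
    expect_identical(network_degree(rw), network_degree(net))
    expect_identical(sort(rw$edges$weight), sort(net$edges$weight))
  }
  # a triangle admits no valid swap
  tri <- new_network(data.frame(gene_a = c("a", "a", "b"),
                                gene_b = c("b", "c", "c"), weight = 1))
  rw_tri <- rewire_preserving_degree(tri, seed = 1)
  expect_identical(rw_tri$edges[, 1:2], tri$edges[, 1:2])

  # large ER graph: most edges moved after 10|E| swaps
  big <- simulate_network(200, "erdos_renyi", 1000, seed = 2)
  rwb <- rewire_preserving_degree(big, seed = 3)
  k1 <- paste(big$edges$gene_a, big$edges$gene_b)
  k2 <- paste(rwb$edges$gene_a, rwb$edges$gene_b)
  jac <- length(intersect(k1, k2)) / length(union(k1, k2))
  expect_lt(jac, 0.3)
})

test_that("overlap z-scores flag self-overlap and stay null on relabeled copies", {
  net <- simulate_network(60, "erdos_renyi", 150, seed = 1)
  self <- overlap_zscore(net, net, unit = "links", fractions = 1,
                         n_null = 30, seed = 2)
  expect_equal(nrow(self), 1)
  expect_equal(self$observed, 150)
  expect_gt(self$z, 3)

  rel <- shuffle_node_labels(net, seed = 5)
  z_rel <- overlap_zscore(net, rel, unit = "links", fractions = 0.5,
                          n_null = 30, seed = 6)$z
  expect_lt(abs(z_rel), 4)

  genes <- overlap_zscore(net, net, unit = "genes",
                          fractions = c(0.2, 0.6), n_null = 20, seed = 7)
  expect_equal(nrow(genes), 2)
  # rewiring keeps the node universe, so gene-level self-overlap sits
  # inside the null rather than far above it
  expect_true(all(is.na(genes$z) | abs(genes$z) < 10))
})

test_that("topological features match direct graph computation", {
  net <- new_network(data.frame(gene_a = c("a", "a", "b", "c"),
                                gene_b = c("b", "c", "c", "d"), weight = 1))
  pairs <- data.frame(gene_i = c("a", "a", "x"),
                      gene_j = c("b", "d", "y"))
  ft <- topo_features(pairs, list(net = net), dampings = c(0.5, 0.85))
  expect_equal(ft$net.direct_link, c(1, 0, 0))
  expect_equal(ft$net.shortest_path[1], 1)
  expect_equal(ft$net.shortest_path[2], 2)           # a-c-d
  expect_equal(ft$net.shortest_path[3], 3)           # absent: diameter + 1
  expect_equal(ft$net.degree_avg, c(2, 1.5, 0))   # deg: a=2 b=2 c=3 d=1
  expect_equal(ft$net.degree_diff, c(0, 1, 0))
  # a and b share neighbor c; union = {a, b, c} minus selves -> J = 1/3
  expect_equal(ft$net.neighbor_jaccard[1], 1 / 3)

  # identical neighbor sets give Jaccard 1
  twin <- new_network(data.frame(gene_a = c("u", "v"), gene_b = c("w", "w"),
                                 weight = 1))
  ftw <- topo_features(data.frame(gene_i = "u", gene_j = "v"),
                       list(t = twin))
  expect_equal(ftw$t.neighbor_jaccard, 1)
})

test_that("pagerank features agree with a power-iteration oracle", {
  net <- simulate_network(50, "scale_free", 120, seed = 8)
  g <- network_to_igraph(net)
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  for (d in c(0.3, 0.85)) {
    # independent oracle: power iteration on the PageRank recursion
    n <- nrow(A)
    deg <- rowSums(A)
    pr <- rep(1 / n, n)
    for (it in 1:500) {
      share <- ifelse(deg > 0, pr / deg, 0)
      pr_new <- (1 - d) / n + d * (drop(share %*% A) +
                                     sum(pr[deg == 0]) / n)
      if (max(abs(pr_new - pr)) < 1e-14) break
      pr <- pr_new
    }
    names(pr) <- net$nodes
    pairs <- data.frame(gene_i = net$edges$gene_a[1:10],
                        gene_j = net$edges$gene_b[1:10])
    ft <- topo_features(pairs, list(n = net), dampings = d)
    want_avg <- (pr[pairs$gene_i] + pr[pairs$gene_j]) / 2
    expect_equal(ft[[sprintf("n.pagerank%g_avg", d)]], unname(want_avg),
                 tolerance = 1e-8)
  }
})

test_that("link prediction recovers planted links and respects gene leakage", {
  gnet <- simulate_network(80, "scale_free", 200, seed = 9)
  pos <- gnet$edges[, c("gene_a", "gene_b")]
  names(pos) <- c("gene_i", "gene_j")
  neg <- sample_negative_pairs(gnet, nrow(pos), seed = 10)
  expect_false(any(pair_key(neg$gene_i, neg$gene_j) %in%
                     pair_key(pos$gene_i, pos$gene_j)))
  feats <- topo_features(rbind(pos, neg), list(gen = gnet))
  res <- suppressMessages(predict_links(feats, pos, n_folds = 15, seed = 11))
  expect_gte(res$auc[["gen"]], 0.95)
  expect_gte(res$auc[["combined"]], 0.95)

  # no training pair shares a gene with any test pair, in every fold
  for (fo in res$folds) {
    if (is.null(fo)) next
    test_genes <- unique(c(res$pairs$gene_i[fo$test],
                           res$pairs$gene_j[fo$test]))
    train_genes <- c(res$pairs$gene_i[fo$train], res$pairs$gene_j[fo$train])
    expect_length(intersect(train_genes, test_genes), 0)
  }
})

test_that("pure-noise features yield chance-level link prediction", {
  set.seed(12)
  gnet <- simulate_network(60, "erdos_renyi", 120, seed = 13)
  pos <- gnet$edges[, c("gene_a", "gene_b")]
  names(pos) <- c("gene_i", "gene_j")
  neg <- sample_negative_pairs(gnet, nrow(pos), seed = 14)
  pairs <- rbind(pos, neg)
  feats <- cbind(pairs, noise.f1 = rnorm(nrow(pairs)),
                 noise.f2 = rnorm(nrow(pairs)),
                 noise.f3 = rnorm(nrow(pairs)))
  res <- suppressMessages(predict_links(feats, pos, n_folds = 10,
                                        lambda = 0.05, seed = 15))
  expect_gt(res$auc[["combined"]], 0.4)
  expect_lt(res$auc[["combined"]], 0.6)
})
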