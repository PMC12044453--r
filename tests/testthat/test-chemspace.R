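test_that("knn graph truncates k and connects duplicates at distance 0", {
  fps <- fingerprint(c("CCO", "CCO", "c1ccccc1"), "morgan2_1024")
  g <- knn_graph(fps, k = 50)
  expect_equal(g$k, 2L)
  # complete graph on 3 nodes after deduplication of directed edges
  expect_equal(nrow(g$edges), 3L)
  dup <- g$edges[g$edges$i == 1 & g$edges$j == 2, ]
  expect_equal(dup$weight, 0)
})

test_that("exact and LSH neighbour search agree on generated libraries", {
  std <- bench_std()$sy_gen
  fps <- fingerprint(unique(std$canonical_smiles), "morgan2_1024")
  ge <- knn_graph(fps, k = 10, mode = "exact")
  gl <- knn_graph(fps, k = 10, kc = 10, mode = "lsh", seed = 2)
  ek <- paste(ge$edges$i, ge$edges$j)
  lk <- paste(gl$edges$i, gl$edges$j)
  expect_gte(mean(ek %in% lk), 0.95)
})

test_that("minimum spanning tree matches the path-graph case", {
  edges <- data.frame(i = c(1, 2, 3, 1), j = c(2, 3, 4, 4),
                      weight = c(0.1, 0.2, 0.3, 0.9))
  mst <- minimum_spanning_tree(edges, 4)
  expect_equal(nrow(mst), 3L)
  expect_equal(sum(mst$weight), 0.6)
})

test_that("mst equals the independent oracle on random graphs", {
  skip_if_not_installed("igraph")
  withr::local_seed(5)
  for (trial in 1:8) {
    n <- sample(10:100, 1)
    m <- min(n * (n - 1) / 2, n * 4L)
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    sel <- pairs[sample(nrow(pairs), m), , drop = FALSE]
    edges <- data.frame(i = sel[, 1], j = sel[, 2],
                        weight = runif(m))
    mine <- minimum_spanning_tree(edges, n)
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges$i, to = edges$j, weight = edges$weight),
      directed = FALSE, vertices = data.frame(name = 1:n))
    ref <- igraph::mst(g)
    expect_equal(sum(mine$weight),
                 sum(igraph::E(ref)$weight), tolerance = 1e-12)
    # spanning-forest size: n - number of components
    comp <- igraph::components(g)$no
    expect_equal(nrow(mine), n - comp)
  }
})

test_that("tmap layout is deterministic and covers every molecule", {
  std <- bench_std()$np_gen
  fps <- fingerprint(unique(std$canonical_smiles)[1:60], "maccs166")
  g <- knn_graph(fps, k = 8)
  t1 <- tmap_layout(g)
  t2 <- tmap_layout(g)
  expect_identical(t1$coords, t2$coords)
  expect_equal(nrow(t1$coords), 60L)
  expect_false(any(!is.finite(t1$coords$x)))
  # a spanning forest never has more than n - 1 edges
  expect_lte(nrow(t1$edges), 59L)
})

test_that("single-molecule graph lays out at the origin", {
  g <- list(edges = data.frame(i = integer(), j = integer(),
                               weight = numeric()), n = 1L)
  t1 <- tmap_layout(g)
  expect_equal(unlist(t1$coords[1, c("x", "y")], use.names = FALSE),
               c(0, 0))
  expect_error(tmap_layout(list(edges = NULL, n = 0L)), "empty")
})

test_that("planted clusters separate under both embeddings", {
  std <- bench_std()
  smi <- unique(c(std$np_gen$canonical_smiles[1:40],
                  std$sy_gen$canonical_smiles[1:40]))
  lab <- rep(c(1, 2), c(40, length(smi) - 40))
  fps <- fingerprint(smi, "morgan2_1024")

  ts <- suppressWarnings(tsne_embed(fps, seed = 3))
  co <- as.matrix(ts$coords[, c("x", "y")])
  d <- as.matrix(dist(co))
  within <- mean(d[lab == 1, lab == 1])
  between <- mean(d[lab == 1, lab == 2])
  expect_gt(between, within)

  # tmap: the MST bridges between clusters are rare relative to
  # within-cluster edges
  g <- knn_graph(fps, k = 5)
  tm <- tmap_layout(g)
  bridge <- sum(lab[tm$edges$i] != lab[tm$edges$j])
  expect_lt(bridge / nrow(tm$edges), 0.2)
})

test_that("tsne is deterministic, reduces perplexity, rejects tiny input", {
  fps <- fingerprint(c("CCO", "CCN", "CCS", "CCC", "CC(C)O", "c1ccccc1",
                       "Cc1ccccc1", "C1CCOCC1", "CCCl", "CCBr"),
                     "morgan2_1024")
  expect_warning(e1 <- tsne_embed(fps, perplexity = 40, seed = 8),
                 "perplexity")
  expect_lt(e1$params$perplexity, 40)
  e2 <- suppressWarnings(tsne_embed(fps, perplexity = 40, seed = 8))
  expect_identical(e1$coords, e2$coords)
  expect_equal(nrow(e1$coords), 10L)
  expect_error(tsne_embed(fragcompare:::fp_subset(fps, 1:4)),
               "at least 5")
})
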