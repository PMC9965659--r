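# synthetic graphs (not from SMILES) for pure graph-layer tests
make_graph <- function(features, edges) {
  structure(list(features = as.matrix(features),
                 edges = matrix(as.integer(edges), ncol = 2),
                 smiles = "<synthetic>"),
            class = "molecular_graph")
}

test_that("aggregation sums self and neighbours", {
  g1 <- make_graph(matrix(2, 1, 1), integer(0))
  expect_equal(gin_aggregate(g1, matrix(2, 1, 1)), matrix(2, 1, 1))

  path2 <- make_graph(matrix(c(1, 2), 2, 1), c(1, 2))
  expect_equal(gin_aggregate(path2, matrix(c(1, 2), 2, 1)),
               matrix(c(3, 3), 2, 1))
  # eps = -1 cancels the self term
  expect_equal(gin_aggregate(path2, matrix(c(1, 2), 2, 1), eps = -1),
               matrix(c(2, 1), 2, 1))
  expect_error(gin_aggregate(path2, matrix(1, 3, 1)), "match")
})

test_that("sum readout groups nodes per graph", {
  expect_equal(unname(sum_readout(matrix(c(1, 3, 2, 4), 2), c(1, 1))),
               matrix(c(4, 6), 1))
  expect_equal(unname(sum_readout(matrix(0, 3, 2), c(1, 2, 2))),
               matrix(0, 2, 2))
  set.seed(8)
  feats <- matrix(rnorm(200), 50, 4)
  mem <- sample(1:20, 50, replace = TRUE)
  got <- sum_readout(feats, mem)
  for (gid in sort(unique(mem))) {
    expect_equal(unname(got[as.character(gid) == rownames(got), ]),
                 colSums(feats[mem == gid, , drop = FALSE]))
  }
  expect_error(sum_readout(feats, mem[-1]), "every node")
})

test_that("the graph vector is invariant to node relabeling", {
  enc <- withr::with_seed(11, init_gin_encoder(3, depth = 3, hidden = 8,
                                               graph_dim = 8))
  set.seed(12)
  n <- 7
  feats <- matrix(rnorm(n * 3), n, 3)
  edges <- cbind(1:6, 2:7)
  base <- gin_forward(make_graph(feats, edges), enc)$graph_vectors
  for (i in 1:100) {
    perm <- sample(n)
    inv <- order(perm)
    g2 <- make_graph(feats[perm, ], matrix(inv[edges], ncol = 2))
    got <- gin_forward(g2, enc)$graph_vectors
    expect_lt(max(abs(got - base)), 1e-5)
  }
})

test_that("GIN separates the triangle from the 3-path", {
  enc <- withr::with_seed(13, init_gin_encoder(2, depth = 3, hidden = 8,
                                               graph_dim = 8))
  ones <- matrix(1, 3, 2)
  tri <- make_graph(ones, rbind(c(1, 2), c(2, 3), c(1, 3)))
  path <- make_graph(ones, rbind(c(1, 2), c(2, 3)))
  a <- gin_forward(tri, enc)$graph_vectors
  b <- gin_forward(path, enc)$graph_vectors
  expect_gt(max(abs(a - b)), 1e-4)
})

test_that("batching two disjoint graphs never mixes them", {
  enc <- withr::with_seed(14, init_gin_encoder(3, depth = 3, hidden = 6,
                                               graph_dim = 6))
  set.seed(15)
  g1 <- make_graph(matrix(rnorm(12), 4, 3), rbind(c(1, 2), c(2, 3), c(3, 4)))
  g2 <- make_graph(matrix(rnorm(9), 3, 3), rbind(c(1, 2), c(1, 3)))
  both <- gin_forward(list(g1, g2), enc)
  solo1 <- gin_forward(g1, enc)
  solo2 <- gin_forward(g2, enc)
  expect_lt(max(abs(both$graph_vectors[1, ] - solo1$graph_vectors[1, ])), 1e-5)
  expect_lt(max(abs(both$graph_vectors[2, ] - solo2$graph_vectors[1, ])), 1e-5)
  expect_identical(both$membership, rep(1:2, c(4L, 3L)))
})

test_that("sum readout is additive over disjoint unions", {
  set.seed(16)
  f1 <- matrix(rnorm(8), 4, 2)
  f2 <- matrix(rnorm(6), 3, 2)
  joint <- sum_readout(rbind(f1, f2), rep(1, 7))
  expect_equal(unname(joint),
               unname(sum_readout(f1, rep(1, 4)) + sum_readout(f2, rep(1, 3))))
})

test_that("depth outside the designed range warns and empty graphs fail", {
  expect_warning(init_gin_encoder(3, depth = 2, hidden = 4, graph_dim = 4),
                 "3..7")
  enc <- withr::with_seed(17,
    suppressWarnings(init_gin_encoder(3, depth = 3, hidden = 4, graph_dim = 4)))
  expect_error(gin_forward(list(), enc))
})

test_that("the depth sweep runs end-to-end on synthetic molecules", {
  graphs <- smiles_to_graphs(c("CCO", "c1ccccc1", "CC(=O)NC"))
  for (depth in 3:7) {
    enc <- withr::with_seed(depth, init_gin_encoder(atom_feature_dim(),
                                                    depth = depth, hidden = 8,
                                                    graph_dim = 8))
    out <- gin_forward(graphs, enc)
    expect_identical(dim(out$graph_vectors), c(3L, 8L))
    expect_true(all(is.finite(out$graph_vectors)))
  }
})
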