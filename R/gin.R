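# Graph channel: stacked graph isomorphism network layers. Each layer
# aggregates (1 + eps) * own + sum-of-neighbours, maps the result through a
# two-layer perceptron, applies node-level batch normalization and ReLU.
# The graph-level vector concatenates per-layer sum readouts and projects
# them through a linear + ReLU (+ dropout during training) head; the last
# layer's node features are kept for cross-attention and attribution.

#' Sparse adjacency of a molecular graph
#'
#' @param graph A [smiles_to_graph()] object (or list with `edges` and a
#'   node count inferred from `features`).
#' @param n Number of nodes (default from `graph$features`).
#' @return Symmetric sparse `dgCMatrix` with 1 at bonded pairs.
#' @export
graph_adjacency <- function(graph, n = nrow(graph$features)) {
  e <- graph_edges_directed(graph)
  if (any(e < 1) || any(e > n)) stop("edge endpoint out of range", call. = FALSE)
  Matrix::sparseMatrix(i = e[, 1], j = e[, 2], x = 1, dims = c(n, n))
}

#' One GIN aggregation step
#'
#' `h_v = mlp((1 + eps) * x_v + sum_{u ~ v} x_u)`. Isolated nodes aggregate
#' only themselves.
#'
#' @param graph A `molecular_graph` (only the edge list is used).
#' @param features Node-feature matrix, rows aligned with graph nodes.
#' @param eps Self-loop weight offset (learnable in the full model; 0 here
#'   by default).
#' @param mlp Function applied row-wise to the aggregated matrix (default
#'   identity).
#' @return Matrix of updated node features.
#' @export
gin_aggregate <- function(graph, features, eps = 0, mlp = identity) {
  features <- as.matrix(features)
  n <- nrow(features)
  if (n != nrow(graph$features)) {
    stop("feature rows (", n, ") do not match graph nodes (",
         nrow(graph$features), ")", call. = FALSE)
  }
  A <- graph_adjacency(graph, n)
  agg <- (1 + eps) * features + as.matrix(A %*% features)
  mlp(agg)
}

#' Sum readout of node features per graph
#'
#' @param features Node-feature matrix.
#' @param membership Integer vector assigning every node (row) to a graph.
#' @return Matrix with one row per graph: the per-graph sum of node
#'   vectors.
#' @export
sum_readout <- function(features, membership) {
  features <- as.matrix(features)
  if (length(membership) != nrow(features)) {
    stop("membership must assign every node to exactly one graph",
         call. = FALSE)
  }
  if (any(is.na(membership))) stop("orphan node: NA membership", call. = FALSE)
  ids <- sort(unique(membership))
  out <- rowsum(features, group = factor(membership, levels = ids))
  rownames(out) <- ids
  out
}

#' Initialize a GIN graph encoder
#'
#' @param feat_dim Input node-feature width ([atom_feature_dim()] for
#'   molecular graphs).
#' @param depth Number of GIN layers; 3..7 is the range the architecture
#'   was designed around (a warning is emitted outside it).
#' @param hidden Perceptron hidden width = per-layer node width.
#' @param graph_dim Width of the projected graph-level vector.
#' @param dropout Dropout rate applied to the graph vector during training.
#' @return A `gin_encoder` parameter list (epsilons initialized at 0,
#'   batch-norm scale 1 / shift 0, running statistics empty).
#' @export
init_gin_encoder <- function(feat_dim, depth = 5, hidden = 128,
                             graph_dim = hidden, dropout = 0.2) {
  if (depth < 3 || depth > 7) {
    warning("GIN depth ", depth, " outside the designed range 3..7",
            call. = FALSE)
  }
  layers <- vector("list", depth)
  c_in <- feat_dim
  for (k in seq_len(depth)) {
    layers[[k]] <- list(
      eps = 0,
      W1 = he_init(c_in, hidden), b1 = numeric(hidden),
      W2 = he_init(hidden, hidden), b2 = numeric(hidden),
      gamma = rep(1, hidden), beta = numeric(hidden)
    )
    c_in <- hidden
  }
  structure(list(
    layers = layers,
    proj = list(W = he_init(depth * hidden, graph_dim),
                b = numeric(graph_dim)),
    bn_state = list(mean = replicate(depth, numeric(hidden), simplify = FALSE),
                    var = replicate(depth, rep(1, hidden), simplify = FALSE)),
    depth = depth, hidden = hidden, feat_dim = feat_dim,
    graph_dim = graph_dim, dropout = dropout
  ), class = "gin_encoder")
}

# batch-norm over all nodes in the batch, per channel
bn_forward <- function(h, gamma, beta, running, train, momentum = 0.1,
                       eps = 1e-5) {
  if (train && nrow(h) > 1) {
    mu <- colMeans(h)
    va <- colMeans(sweep(h, 2, mu)^2)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * va
  } else {
    mu <- running$mean
    va <- running$var
  }
  xhat <- sweep(sweep(h, 2, mu), 2, sqrt(va + eps), `/`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(y = y, xhat = xhat, mu = mu, va = va, running = running, eps = eps,
       batch_stats = train && nrow(h) > 1)
}

bn_backward <- function(dy, cache, gamma) {
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, gamma, `*`)
  inv_sd <- 1 / sqrt(cache$va + cache$eps)
  if (!cache$batch_stats) {
    dh <- sweep(dxhat, 2, inv_sd, `*`)
    return(list(dh = dh, dgamma = dgamma, dbeta = dbeta))
  }
  n <- nrow(dy)
  dh <- sweep(dxhat - matrix(colMeans(dxhat), n, ncol(dy), byrow = TRUE) -
                sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), `*`),
              2, inv_sd, `*`)
  list(dh = dh, dgamma = dgamma, dbeta = dbeta)
}

# forward through the GIN stack for a node batch (block-diagonal graphs).
# A: sparse adjacency; returns caches when train-style bookkeeping is on.
gin_stack_forward <- function(X, A, encoder, train = FALSE,
                              keep_cache = FALSE) {
  caches <- vector("list", encoder$depth)
  layer_out <- vector("list", encoder$depth)
  bn_state <- encoder$bn_state
  for (k in seq_len(encoder$depth)) {
    p <- encoder$layers[[k]]
    agg <- (1 + p$eps) * X + as.matrix(A %*% X)
    h1 <- sweep(agg %*% p$W1, 2, p$b1, `+`)
    r1 <- relu(h1)
    h2 <- sweep(r1 %*% p$W2, 2, p$b2, `+`)
    bn <- bn_forward(h2, p$gamma, p$beta,
                     list(mean = bn_state$mean[[k]], var = bn_state$var[[k]]),
                     train)
    bn_state$mean[[k]] <- bn$running$mean
    bn_state$var[[k]] <- bn$running$var
    Y <- relu(bn$y)
    if (keep_cache) {
      caches[[k]] <- list(X_in = X, agg = agg, h1 = h1, r1 = r1, bn = bn,
                          y = bn$y)
    }
    layer_out[[k]] <- Y
    X <- Y
  }
  list(layer_out = layer_out, F = X, caches = caches, bn_state = bn_state)
}

#' Run a GIN encoder over one or more molecular graphs
#'
#' Produces the per-layer node features, the last-layer node feature matrix
#' `F` (used by cross-attention and Grad-AAM attribution), and the
#' graph-level vector: per-layer sum readouts concatenated across layers,
#' then linear + ReLU (dropout is only applied inside training).
#'
#' @param graphs A single `molecular_graph` or a list of them (batched as
#'   one block-diagonal graph; outputs are per graph).
#' @param encoder An [init_gin_encoder()] parameter list.
#' @param train Use batch statistics for normalization (TRUE) or running
#'   statistics (FALSE, default).
#' @return List with `graph_vectors` (one row per graph), `node_features`
#'   (last-layer F, all nodes), `membership` (node-to-graph index) and
#'   `layer_features` (list over layers).
#' @export
gin_forward <- function(graphs, encoder, train = FALSE) {
  if (inherits(graphs, "molecular_graph")) graphs <- list(graphs)
  ns <- vapply(graphs, function(g) nrow(g$features), integer(1))
  if (any(ns == 0)) stop("empty graph", call. = FALSE)
  X <- do.call(rbind, lapply(graphs, `[[`, "features"))
  offs <- cumsum(c(0L, ns[-length(ns)]))
  edges <- do.call(rbind, lapply(seq_along(graphs), function(i) {
    e <- graph_edges_directed(graphs[[i]])
    if (nrow(e) == 0) return(matrix(integer(0), ncol = 2))
    e + offs[i]
  }))
  N <- sum(ns)
  A <- if (nrow(edges) > 0) {
    Matrix::sparseMatrix(i = edges[, 1], j = edges[, 2], x = 1, dims = c(N, N))
  } else {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(N, N))
  }
  membership <- rep(seq_along(graphs), ns)
  fwd <- gin_stack_forward(X, A, encoder, train = train)
  S <- do.call(cbind, lapply(fwd$layer_out, sum_readout, membership))
  G <- relu(sweep(S %*% encoder$proj$W, 2, encoder$proj$b, `+`))
  list(graph_vectors = G, node_features = fwd$F, membership = membership,
       layer_features = fwd$layer_out)
}
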