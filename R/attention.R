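# Drug-protein interaction: cross-multi-head attention from the drug
# channels (SMILES positions; graph atoms) onto the protein positions, the
# decoupling of head-averaged attention maps into per-position drug and
# protein weights, and the fusion of reweighted representations into the
# interaction vector.

#' Scaled dot-product attention
#'
#' `map = row-softmax(Q K' / scale)` with masked keys held at `-Inf`;
#' `output = map %*% V`. Both the output and the map are returned, because
#' the interaction model consumes the maps.
#'
#' @param Q Query matrix (n_q x d).
#' @param K,V Key and value matrices with equal row counts (n_k x d,
#'   n_k x d_v).
#' @param scale Positive scaling divisor for the logits (e.g.
#'   `sqrt(d / h)`).
#' @param key_mask Optional logical vector over keys; `FALSE` keys receive
#'   exactly zero attention mass.
#' @return List with `output` (n_q x d_v) and `map` (n_q x n_k, rows
#'   summing to 1 over unmasked keys).
#' @export
scaled_dot_attention <- function(Q, K, V, scale = sqrt(ncol(Q)),
                                 key_mask = NULL) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (nrow(K) != nrow(V)) stop("K and V must have equal key counts", call. = FALSE)
  if (ncol(Q) != ncol(K)) stop("Q and K width mismatch", call. = FALSE)
  if (scale <= 0) stop("scale must be positive", call. = FALSE)
  logits <- Q %*% t(K) / scale
  if (!is.null(key_mask)) {
    if (length(key_mask) != nrow(K)) stop("key mask length mismatch", call. = FALSE)
    if (!any(key_mask)) stop("all keys masked", call. = FALSE)
    logits[, !key_mask] <- -Inf
  }
  P <- softmax_rows(logits)
  list(output = P %*% V, map = P)
}

#' Initialize cross-attention projection parameters
#'
#' One branch of the interaction model: an initial ReLU projection of the
#' drug-side features (queries) and of the protein features (keys, values)
#' into width `la`, followed by per-head linear projections and an output
#' projection. `h` must divide `la`. The logit scale follows the printed
#' form `sqrt(d_in / h)` where `d_in` is the drug-side channel width
#' (`scale_by = "input"`), with the conventional `sqrt(la / h)` available
#' via `scale_by = "head"`.
#'
#' @param d_drug,d_protein Channel widths of the drug-side and protein
#'   feature maps.
#' @param la Projected attention width.
#' @param h Number of heads (default 8).
#' @param scale_by `"input"` or `"head"`.
#' @return A `cross_attention` parameter list.
#' @export
init_cross_attention <- function(d_drug, d_protein, la = 64, h = 8,
                                 scale_by = c("input", "head")) {
  scale_by <- match.arg(scale_by)
  if (la %% h != 0) {
    stop("head count h = ", h, " must divide la = ", la, call. = FALSE)
  }
  structure(list(
    Wq = glorot_init(d_drug, la), bq = numeric(la),
    Wk = glorot_init(d_protein, la), bk = numeric(la),
    Wv = glorot_init(d_protein, la), bv = numeric(la),
    WQ = glorot_init(la, la), WK = glorot_init(la, la),
    WV = glorot_init(la, la), WO = glorot_init(la, la),
    h = as.integer(h),
    scale = if (scale_by == "input") sqrt(d_drug / h) else sqrt(la / h)
  ), class = "cross_attention")
}

head_cols <- function(la, h) {
  d <- la %/% h
  lapply(seq_len(h), function(i) ((i - 1L) * d + 1L):(i * d))
}

#' Cross-multi-head attention between a drug and a protein representation
#'
#' Projects drug features to queries and protein features to keys/values
#' (ReLU projections), runs `h` scaled dot-product heads in parallel,
#' concatenates the head outputs through the output projection, and
#' averages the per-head attention maps (the decoupling input).
#'
#' @param drug Drug-side feature matrix (positions or atoms x channels) or
#'   [feature_map()].
#' @param protein Protein feature matrix or [feature_map()]; pad positions
#'   are masked out of the attention.
#' @param params An [init_cross_attention()] parameter list.
#' @return List with `output` (drug rows x la) and `map` (drug rows x
#'   protein rows, head-averaged; masked protein columns carry zero mass).
#' @export
multi_head_cross_attention <- function(drug, protein, params) {
  dmask <- NULL; pmask <- NULL
  if (inherits(drug, "feature_map")) { dmask <- drug$mask; drug <- drug$values }
  if (inherits(protein, "feature_map")) { pmask <- protein$mask; protein <- protein$values }
  Q0 <- relu(sweep(as.matrix(drug) %*% params$Wq, 2, params$bq, `+`))
  K0 <- relu(sweep(as.matrix(protein) %*% params$Wk, 2, params$bk, `+`))
  V0 <- relu(sweep(as.matrix(protein) %*% params$Wv, 2, params$bv, `+`))
  Qh <- Q0 %*% params$WQ
  Kh <- K0 %*% params$WK
  Vh <- V0 %*% params$WV
  la <- ncol(Qh)
  cols <- head_cols(la, params$h)
  outs <- vector("list", params$h)
  map <- 0
  for (i in seq_len(params$h)) {
    att <- scaled_dot_attention(Qh[, cols[[i]], drop = FALSE],
                                Kh[, cols[[i]], drop = FALSE],
                                Vh[, cols[[i]], drop = FALSE],
                                scale = params$scale, key_mask = pmask)
    outs[[i]] <- att$output
    map <- map + att$map
  }
  list(output = do.call(cbind, outs) %*% params$WO,
       map = map / params$h)
}

#' Decouple attention maps into drug and protein position weights
#'
#' Row sums of each branch map give the per-drug-position weights (one
#' vector per branch, since SMILES positions and atoms differ in count);
#' column sums of the row-concatenated maps give the per-protein-position
#' weight. For softmax attention maps the row sums are identically 1, so
#' the drug representations pass to pooling unattenuated while the protein
#' weight concentrates on the columns that receive attention mass; scaling
#' the weights by any fixed constant would be absorbed by the regression
#' head, but a per-length normalization would shrink every fused segment
#' by 1/length and starve the sequence channels of gradient.
#'
#' @param A1 SMILES-positions x protein-positions head-averaged map.
#' @param A2 Atoms x protein-positions head-averaged map.
#' @return List with `alpha_d1`, `alpha_d2` (drug weights per branch) and
#'   `alpha_p` (protein weights).
#' @export
decouple_attention <- function(A1, A2) {
  A1 <- as.matrix(A1); A2 <- as.matrix(A2)
  if (ncol(A1) != ncol(A2)) {
    stop("maps disagree on protein-axis length", call. = FALSE)
  }
  list(alpha_d1 = rowSums(A1),
       alpha_d2 = rowSums(A2),
       alpha_p = colSums(rbind(A1, A2)))
}

#' Fuse reweighted drug and protein representations
#'
#' Scales each representation by its decoupled position weight, global-max
#' pools each over its valid positions, and concatenates the three pooled
#' vectors (SMILES branch, atom branch, protein) into the interaction
#' vector. The outer average pool of the fused vector is over a single
#' window and therefore the identity.
#'
#' @param D1 SMILES-branch feature matrix or [feature_map()].
#' @param alpha_d1 Per-position weights for `D1`.
#' @param D2 Atom-branch feature matrix.
#' @param alpha_d2 Per-atom weights.
#' @param P Protein feature matrix or [feature_map()].
#' @param alpha_p Per-position protein weights.
#' @return Numeric interaction vector of length
#'   `ncol(D1) + ncol(D2) + ncol(P)`.
#' @export
fuse_representations <- function(D1, alpha_d1, D2, alpha_d2, P, alpha_p) {
  pool <- function(X, a) {
    mask <- rep(TRUE, if (inherits(X, "feature_map")) nrow(X$values) else nrow(X))
    if (inherits(X, "feature_map")) { mask <- X$mask; X <- X$values }
    X <- as.matrix(X)
    if (length(a) != nrow(X)) stop("weight length mismatch", call. = FALSE)
    if (!any(mask)) stop("no unmasked positions to pool", call. = FALSE)
    W <- X[mask, , drop = FALSE] * a[mask]
    apply(W, 2, max)
  }
  c(pool(D1, alpha_d1), pool(D2, alpha_d2), pool(P, alpha_p))
}

#' Initialize the affinity regression head
#'
#' Affine layers of the given hidden widths, each followed by ReLU and
#' (during training) dropout, ending in a single linear output unit.
#'
#' @param input_dim Width of the fused interaction vector.
#' @param hidden Hidden widths (default `c(1024, 1024, 512)`, i.e. four
#'   affine layers in total).
#' @param dropout Dropout rate used in training.
#' @return A `regression_head` parameter list.
#' @export
init_regression_head <- function(input_dim, hidden = c(1024, 1024, 512),
                                 dropout = 0.2) {
  dims <- c(input_dim, hidden, 1L)
  nl <- length(dims) - 1L
  layers <- lapply(seq_len(nl), function(i) {
    W <- he_init(dims[i], dims[i + 1])
    if (i == nl) W <- W * 0.05   # small output init: start near the mean
    list(W = W, b = numeric(dims[i + 1]))
  })
  structure(list(layers = layers, dropout = dropout, input_dim = input_dim),
            class = "regression_head")
}

#' Regress an interaction vector to a scalar affinity
#'
#' Deterministic evaluation-mode pass (dropout off).
#'
#' @param I_dp Interaction vector (or matrix of row vectors).
#' @param head An [init_regression_head()] parameter list.
#' @return Scalar affinity (or vector, one per input row).
#' @export
predict_affinity <- function(I_dp, head) {
  H <- if (is.matrix(I_dp)) I_dp else matrix(I_dp, nrow = 1)
  if (ncol(H) != head$input_dim) {
    stop("interaction vector width ", ncol(H), " != head input ",
         head$input_dim, call. = FALSE)
  }
  nl <- length(head$layers)
  for (i in seq_len(nl)) {
    p <- head$layers[[i]]
    H <- sweep(H %*% p$W, 2, p$b, `+`)
    if (i < nl) H <- relu(H)
  }
  drop(H)
}
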