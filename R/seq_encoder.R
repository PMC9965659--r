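# Sequence channel: embedding -> [1D convolution -> squeeze-and-excitation]
# stacked blocks. The encoder keeps the position-resolved feature map (the
# attention module consumes it) and applies global max pooling only when a
# pooled vector is requested, so the map and the pooled summary stay
# consistent.

#' A position-by-channel feature map
#'
#' @param values L x C numeric matrix.
#' @param mask Logical vector of length L flagging valid (non-pad)
#'   positions.
#' @return A `feature_map` object.
#' @export
feature_map <- function(values, mask = rep(TRUE, nrow(values))) {
  values <- as.matrix(values)
  stopifnot(length(mask) == nrow(values), all(is.finite(values)))
  structure(list(values = values, mask = as.logical(mask)),
            class = "feature_map")
}

#' @export
print.feature_map <- function(x, ...) {
  cat(sprintf("<feature_map: %d positions (%d valid) x %d channels>\n",
              nrow(x$values), sum(x$mask), ncol(x$values)))
  invisible(x)
}

#' Embed an encoded sequence
#'
#' Row-wise lookup of integer codes in an embedding table whose row 0 (the
#' padding code) is frozen at the zero vector. Pad positions come out as
#' zero rows and are masked.
#'
#' @param seq An [encode_sequence()] result or plain integer vector.
#' @param table Embedding matrix with `dictionary size + 1` rows (first row
#'   = padding) as built by [embedding_table()].
#' @return A [feature_map()] of shape L x ncol(table).
#' @export
embed_sequence <- function(seq, table) {
  codes <- if (inherits(seq, "encoded_sequence")) seq$codes else as.integer(seq)
  if (any(codes < 0) || any(codes + 1L > nrow(table))) {
    bad <- which(codes < 0 | codes + 1L > nrow(table))[1]
    stop("code out of embedding range at position ", bad, call. = FALSE)
  }
  feature_map(table[codes + 1L, , drop = FALSE], mask = codes != 0L)
}

#' Build an embedding table
#'
#' @param vocab_size Dictionary size (codes 1..vocab_size).
#' @param dim Embedding dimension.
#' @return `(vocab_size + 1) x dim` matrix; row 1 (padding code 0) is zero
#'   and is kept frozen during training.
#' @export
embedding_table <- function(vocab_size, dim) {
  tab <- matrix(stats::rnorm((vocab_size + 1) * dim, 0, 0.1),
                vocab_size + 1, dim)
  tab[1, ] <- 0
  tab
}

#' Squeeze: per-channel mean statistic
#'
#' Global average pooling of a feature map into one statistic per channel.
#' The mean runs over valid (non-pad) positions so that padding never
#' influences the channel gate.
#'
#' @param U A [feature_map()] (or plain matrix, all positions valid).
#' @return Numeric vector of length C.
#' @export
se_squeeze <- function(U) {
  if (!inherits(U, "feature_map")) U <- feature_map(as.matrix(U))
  if (sum(U$mask) == 0) stop("empty feature map: nothing to squeeze", call. = FALSE)
  colMeans(U$values[U$mask, , drop = FALSE])
}

#' Squeeze-and-excitation gating parameters
#'
#' Two weight matrices forming the bottleneck `s = sigmoid(W2 relu(W1 z))`
#' with reduction ratio `r` (W1: C/r x C, W2: C x C/r). No biases, matching
#' the gating equation.
#'
#' @param channels Number of channels C; `r` must divide C.
#' @param r Reduction ratio (default 16).
#' @return An `se_params` list with `W1`, `W2`, `r`.
#' @export
se_params <- function(channels, r = 16) {
  if (channels %% r != 0) {
    stop("reduction ratio r = ", r, " must divide channels = ", channels,
         call. = FALSE)
  }
  structure(list(W1 = glorot_init(channels %/% r, channels),
                 W2 = glorot_init(channels, channels %/% r),
                 r = r),
            class = "se_params")
}

#' Excite: channel gates from the squeezed statistic
#'
#' `s = sigmoid(W2 relu(W1 z))`; every gate lies strictly in (0, 1).
#'
#' @param z Channel statistic from [se_squeeze()].
#' @param params An [se_params()] object (or list with `W1`, `W2`).
#' @return Gate vector s of length C.
#' @export
se_excite <- function(z, params) {
  if (ncol(params$W1) != length(z) || nrow(params$W2) != length(z)) {
    stop("shape mismatch between z and gating weights", call. = FALSE)
  }
  as.vector(sigmoid(params$W2 %*% relu(params$W1 %*% z)))
}

#' Reweight: scale each channel by its gate
#'
#' @param U A [feature_map()].
#' @param s Gate vector, one entry per channel.
#' @return A [feature_map()] with channel c multiplied by `s[c]`; the mask
#'   is unchanged.
#' @export
se_reweight <- function(U, s) {
  if (!inherits(U, "feature_map")) U <- feature_map(as.matrix(U))
  if (length(s) != ncol(U$values)) {
    stop("gate length ", length(s), " != channel count ", ncol(U$values),
         call. = FALSE)
  }
  feature_map(sweep(U$values, 2, s, `*`), U$mask)
}

#' One full squeeze-and-excitation block
#'
#' @inheritParams se_reweight
#' @inheritParams se_excite
#' @return The reweighted [feature_map()].
#' @export
se_block <- function(U, params) {
  se_reweight(U, se_excite(se_squeeze(U), params))
}

# ---- full sequence encoder -------------------------------------------------

#' Initialize a convolutional SE sequence encoder
#'
#' A stack of `length(filters)` blocks, each a same-padded 1D convolution
#' (stride 1) followed by ReLU and a squeeze-and-excitation gate. Pad
#' positions are re-zeroed after every block so padding never leaks into
#' subsequent receptive fields or pooled outputs.
#'
#' @param vocab_size Token dictionary size.
#' @param embed_dim Embedding dimension.
#' @param filters Integer vector of per-layer filter counts (the last entry
#'   is the channel width handed to the attention module).
#' @param kernel Convolution kernel width.
#' @param se_r Squeeze-and-excitation reduction ratio; must divide every
#'   entry of `filters`.
#' @return A `sequence_encoder` parameter list.
#' @export
init_sequence_encoder <- function(vocab_size, embed_dim = 128,
                                  filters = c(16, 32, 48), kernel = 4,
                                  se_r = 16) {
  layers <- vector("list", length(filters))
  c_in <- embed_dim
  for (j in seq_along(filters)) {
    c_out <- filters[j]
    layers[[j]] <- list(
      W = he_init(kernel * c_in, c_out),
      b = numeric(c_out),
      se = unclass(se_params(c_out, se_r))[c("W1", "W2")]
    )
    c_in <- c_out
  }
  structure(list(embed = embedding_table(vocab_size, embed_dim),
                 layers = layers, kernel = kernel, filters = filters,
                 embed_dim = embed_dim, se_r = se_r),
            class = "sequence_encoder")
}

# same-padding gather indices for an L-position sequence, kernel k.
# Returns L x k matrix of source positions; 0 marks out-of-range.
conv_gather_index <- function(L, k) {
  left <- (k - 1L) %/% 2L
  off <- seq_len(k) - 1L - left
  idx <- outer(seq_len(L), off, `+`)
  idx[idx < 1L | idx > L] <- 0L
  idx
}

#' Encode an integer sequence into SE-convolutional features
#'
#' Runs the full encoder stack on one sequence: embedding, then each
#' convolution + SE block. Returns the position-resolved feature map (for
#' cross-attention) together with its global-max-pooled vector over valid
#' positions.
#'
#' @param seq An [encode_sequence()] result (or integer code vector).
#' @param encoder An [init_sequence_encoder()] parameter list.
#' @return List with `map` (a [feature_map()], L x C_last) and `pooled`
#'   (length C_last vector).
#' @export
encode_sequence_features <- function(seq, encoder) {
  fm <- embed_sequence(seq, encoder$embed)
  if (sum(fm$mask) == 0) {
    stop("sequence has no valid positions after truncation", call. = FALSE)
  }
  out <- seq_encoder_forward_single(fm$values, fm$mask, encoder)
  map <- feature_map(out, fm$mask)
  list(map = map,
       pooled = apply(out[fm$mask, , drop = FALSE], 2, max))
}

# single-sequence forward used by the user-facing op; the batched engine
# in model.R implements the identical arithmetic with caches
seq_encoder_forward_single <- function(X, mask, encoder) {
  L <- nrow(X)
  for (layer in encoder$layers) {
    G <- conv_gather_index(L, encoder$kernel)
    Xa <- rbind(X, 0)                       # row L+1 = zero pad source
    Gi <- ifelse(G == 0L, L + 1L, G)
    Xcol <- do.call(cbind, lapply(seq_len(encoder$kernel),
                                  function(o) Xa[Gi[, o], , drop = FALSE]))
    Y <- relu(sweep(Xcol %*% layer$W, 2, layer$b, `+`))
    Y[!mask, ] <- 0
    fm <- feature_map(Y, mask)
    s <- se_excite(se_squeeze(fm), layer$se)
    X <- sweep(Y, 2, s, `*`)
  }
  X
}
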