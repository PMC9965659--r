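# Numerical primitives for the network: initializers, activations, softmax,
# dropout, and the Adam optimizer over arbitrarily nested parameter lists.
# Forward passes keep the caches their backward passes need; gradients are
# verified against central finite differences in the test suite.

relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Row-wise softmax
#'
#' Numerically stable softmax over each row of a matrix; `-Inf` entries
#' (masked keys) receive exactly zero mass.
#'
#' @param x Numeric matrix of logits.
#' @return Matrix of the same shape with rows summing to 1.
#' @keywords internal
softmax_rows <- function(x) {
  m <- apply(x, 1, max)
  if (any(!is.finite(m))) stop("all keys masked for some query", call. = FALSE)
  e <- exp(x - m)
  e[x == -Inf] <- 0
  e / rowSums(e)
}

# d(loss)/d(logits) given d(loss)/d(softmax) and the softmax output
softmax_rows_backward <- function(dP, P) {
  P * (dP - rowSums(dP * P))
}

he_init <- function(nrow, ncol) {
  matrix(stats::rnorm(nrow * ncol, 0, sqrt(2 / nrow)), nrow, ncol)
}

glorot_init <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

dropout_mask <- function(n, p) {
  if (p <= 0) return(NULL)
  (stats::runif(n) >= p) / (1 - p)   # inverted dropout
}

apply_dropout <- function(x, mask) {
  if (is.null(mask)) x else x * mask
}

# ---- Adam over nested parameter lists -------------------------------------

zeros_like <- function(p) {
  rapply(p, function(x) x * 0, how = "replace")
}

adam_state <- function(params, lr = 1e-4, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  list(m = zeros_like(params), v = zeros_like(params),
       t = 0L, lr = lr, beta1 = beta1, beta2 = beta2, eps = eps)
}

adam_step <- function(params, grads, state) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- mapply(walk, p, g, m, v, SIMPLIFY = FALSE)
      return(list(p = lapply(out, `[[`, "p"),
                  m = lapply(out, `[[`, "m"),
                  v = lapply(out, `[[`, "v")))
    }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    p <- p - state$lr * (m / corr1) / (sqrt(v / corr2) + state$eps)
    list(p = p, m = m, v = v)
  }
  out <- walk(params, grads, state$m, state$v)
  state$m <- out$m; state$v <- out$v
  list(params = out$p, state = state)
}

# elementwise sum of two congruent nested lists
grad_accumulate <- function(a, b) {
  if (is.list(a)) return(mapply(grad_accumulate, a, b, SIMPLIFY = FALSE))
  a + b
}

# L2 norm of every leaf, named by path; the end-to-end wiring test checks
# each parameter group has nonzero gradient
grad_leaf_norms <- function(g, prefix = "") {
  if (!is.list(g)) return(stats::setNames(sqrt(sum(g^2)), prefix))
  nm <- names(g)
  if (is.null(nm)) nm <- as.character(seq_along(g))
  out <- mapply(function(x, n) grad_leaf_norms(x, paste0(prefix, "/", n)),
                g, nm, SIMPLIFY = FALSE)
  unlist(unname(out))
}
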