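# Gradient-weighted atom attribution (Grad-AAM): channel gradients of the
# predicted affinity with respect to the last GIN layer's node features
# weight those features into a per-atom contribution map, ReLU'd and
# min-max normalized to [0, 1].

#' Per-atom contribution map from features and their gradient
#'
#' The numeric core of Grad-AAM: channel weights are the node-averaged
#' gradients `W_c = mean_v dDTA/dF[v, c]`; the raw map is
#' `relu(F %*% W_c)` per node; the returned map is min-max normalized to
#' \[0, 1\]. A constant raw map (degenerate normalization) is defined as
#' all zeros, with a warning.
#'
#' @param F Last-layer node feature matrix (atoms x channels).
#' @param dF Gradient of the scalar prediction with respect to `F` (same
#'   shape).
#' @return List with `score` (normalized, length = atoms), `raw` and
#'   `channel_weights`.
#' @export
node_contribution <- function(F, dF) {
  F <- as.matrix(F); dF <- as.matrix(dF)
  if (!all(dim(F) == dim(dF))) stop("F and dF shape mismatch", call. = FALSE)
  Wc <- colMeans(dF)
  raw <- as.vector(relu(F %*% Wc))
  rng <- range(raw)
  if (diff(rng) == 0) {
    warning("constant contribution map: normalized scores set to 0",
            call. = FALSE)
    score <- rep(0, length(raw))
  } else {
    score <- (raw - rng[1]) / diff(rng)
  }
  list(score = score, raw = raw, channel_weights = Wc)
}

#' Grad-AAM atom attribution for one drug-protein pair
#'
#' Runs an evaluation-mode forward pass, backpropagates the scalar
#' prediction down to the last GIN layer's node features, and converts
#' features and gradients into a normalized per-atom contribution map (see
#' [node_contribution()]).
#'
#' @param model A `dta_model` (typically fitted via [dta_fit()]).
#' @param smiles Drug SMILES string.
#' @param protein Protein sequence string.
#' @return A `node_contribution_map` tibble with columns `atom` (1-based
#'   index in SMILES heavy-atom order), `symbol` and `score` in \[0, 1\];
#'   the molecule, prediction and channel weights ride along as
#'   attributes.
#' @export
grad_aam <- function(model, smiles, protein) {
  if (!inherits(model, "dta_model")) {
    stop("grad_aam needs a dta_model with gradient access; got ",
         class(model)[1], call. = FALSE)
  }
  data <- tibble::tibble(smiles = smiles, protein = protein)
  batch <- prepare_batch(data, model)
  fwd <- dta_forward(model, batch, train = FALSE, need_cache = TRUE)
  bwd <- dta_backward(model, batch, fwd, dpred = 1)
  nc <- node_contribution(fwd$cache$Fmat, bwd$dF)
  g <- batch$graphs[[1]]
  out <- tibble::tibble(
    atom = seq_len(nrow(g$features)),
    symbol = g$atoms$symbol,
    score = nc$score
  )
  attr(out, "smiles") <- smiles
  attr(out, "graph") <- g
  attr(out, "prediction") <- unname(fwd$pred) + model$y_offset
  attr(out, "channel_weights") <- nc$channel_weights
  attr(out, "raw") <- nc$raw
  class(out) <- c("node_contribution_map", class(out))
  out
}

#' Atoms whose normalized contribution clears a threshold
#'
#' @param contribution A [grad_aam()] result (or any data frame with
#'   `atom` and `score`).
#' @param threshold Normalized score cutoff (default 0.5).
#' @return Integer vector of atom indices.
#' @export
top_contributing_atoms <- function(contribution, threshold = 0.5) {
  contribution$atom[contribution$score >= threshold]
}

#' Overlap rate between top-contributing atoms and reference site atoms
#'
#' Mean over molecules of (number of top-contributing atoms that coincide
#' with the reference binding-site atoms) / (number of reference site
#' atoms).
#'
#' @param top_atoms List of integer vectors: per-molecule top-contributing
#'   atom indices.
#' @param site_atoms List of integer vectors: per-molecule reference
#'   binding-site atom indices (each must be non-empty).
#' @return Overlap rate in \[0, 1\].
#' @examples
#' overlap_rate(list(c(1, 2), c(1, 2, 3)), list(c(1, 2, 3, 4), c(1, 2, 3)))
#' @export
overlap_rate <- function(top_atoms, site_atoms) {
  if (length(top_atoms) != length(site_atoms)) {
    stop("top_atoms and site_atoms differ in length", call. = FALSE)
  }
  n <- length(top_atoms)
  if (n < 1) stop("need at least one molecule", call. = FALSE)
  ratios <- vapply(seq_len(n), function(i) {
    site <- site_atoms[[i]]
    if (length(site) == 0) {
      stop("empty reference site set for molecule ", i, call. = FALSE)
    }
    length(intersect(top_atoms[[i]], site)) / length(site)
  }, numeric(1))
  mean(ratios)
}

#' Plot an atom-contribution heatmap on the 2D depiction
#'
#' Atoms are drawn at their depiction coordinates, coloured by normalized
#' contribution on a fixed \[0, 1\] scale; bonds as segments. Rendering is
#' deterministic for a given molecule and score vector.
#'
#' @param object A [grad_aam()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.node_contribution_map <- function(object, ...) {
  g <- attr(object, "graph")
  xy <- as.data.frame(g$coords)
  names(xy) <- c("x", "y")
  xy$score <- object$score
  xy$symbol <- object$symbol
  e <- g$edges
  seg <- data.frame(x = xy$x[e[, 1]], y = xy$y[e[, 1]],
                    xend = xy$x[e[, 2]], yend = xy$y[e[, 2]])
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey50") +
    ggplot2::geom_point(data = xy,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     fill = .data$score),
                        shape = 21, size = 7) +
    ggplot2::geom_text(data = xy,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$symbol), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "red",
                                 limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(fill = "contribution",
                  title = attr(object, "smiles"))
}

#' Render a contribution heatmap to an image file
#'
#' @param contribution A [grad_aam()] result.
#' @param path Output file (png/pdf, chosen by extension).
#' @param width,height,dpi Device settings.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(contribution, path, width = 5, height = 4,
                           dpi = 150) {
  if (nrow(contribution) != nrow(attr(contribution, "graph")$features)) {
    stop("score length does not match atom count", call. = FALSE)
  }
  p <- autoplot(contribution)
  suppressMessages(ggplot2::ggsave(path, p, width = width, height = height,
                                   dpi = dpi))
  invisible(path)
}
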