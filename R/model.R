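# The full affinity model: two convolutional SE sequence channels (SMILES,
# protein), a GIN graph channel, cross-multi-head attention from each drug
# channel onto the protein channel, decoupled attention weights fused into
# the interaction vector, and an MLP regression head. This file holds the
# batched forward pass with caches and the hand-written backward pass; the
# arithmetic mirrors the single-sample operations in seq_encoder.R, gin.R
# and attention.R, and the gradients are finite-difference checked in the
# test suite.

#' Model and training configuration
#'
#' Dataset presets fix the published hyperparameter columns (embedding size
#' 128; three SE-convolution layers with filters 16/32/48 for the
#' Davis-style preset and 32/64/96 for KIBA/BindingDB; GIN depth 5; 8
#' attention heads; MLP hidden sizes 1024/1024/512; dropout 0.2; Adam at
#' learning rate 1e-4; 600 epochs at batch size 512 or 1024). The
#' `synthetic` preset is the desk-scale configuration used throughout the
#' package's own tests: the same architecture at small widths, sized so a
#' planted-signal dataset trains in minutes on one CPU.
#'
#' @param preset One of `"synthetic"`, `"davis"`, `"kiba"`, `"bindingdb"`.
#' @param ... Named overrides of any config field.
#' @return A `dta_config` list.
#' @export
dta_config <- function(preset = c("synthetic", "davis", "kiba", "bindingdb"),
                       ...) {
  preset <- match.arg(preset)
  base <- list(
    drug_max_len = 100, protein_max_len = 1000,
    embed_dim = 128,
    filters = c(16, 32, 48), kernel_drug = 4, kernel_protein = 8, se_r = 16,
    gin_depth = 5, gin_hidden = 128, graph_dim = 128,
    heads = 8, la = 128, scale_by = "input",
    head_hidden = c(1024, 1024, 512),
    dropout = 0.2,
    lr = 1e-4, epochs = 600, batch_size = 512,
    unknown_policy = "error"
  )
  cfg <- switch(preset,
    davis = base,
    kiba = utils::modifyList(base, list(filters = c(32, 64, 96),
                                        batch_size = 1024)),
    bindingdb = utils::modifyList(base, list(filters = c(32, 64, 96),
                                             batch_size = 1024)),
    synthetic = utils::modifyList(base, list(
      drug_max_len = 60, protein_max_len = 120,
      embed_dim = 16, filters = c(8, 16, 16), se_r = 4,
      gin_depth = 3, gin_hidden = 32, graph_dim = 32,
      heads = 2, la = 32,
      head_hidden = c(64, 32),
      lr = 1e-3, epochs = 60, batch_size = 32
    ))
  )
  over <- list(...)
  if (length(over) > 0) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad) > 0) stop("unknown config field(s): ",
                              paste(bad, collapse = ", "), call. = FALSE)
    cfg <- utils::modifyList(cfg, over)
  }
  if (cfg$la %% cfg$heads != 0) stop("heads must divide la", call. = FALSE)
  if (any(cfg$filters %% cfg$se_r != 0)) {
    stop("se_r must divide every filter count", call. = FALSE)
  }
  cfg$preset <- preset
  structure(cfg, class = "dta_config")
}

#' Initialize an untrained affinity model
#'
#' @param config A [dta_config()].
#' @param seed Integer seed for the parameter initialization.
#' @return A `dta_model`: list with `params` (trainable weights), `state`
#'   (batch-norm running statistics), `config`, and the token
#'   dictionaries.
#' @export
dta_model <- function(config = dta_config(), seed = 1) {
  dict_d <- default_dictionary("smiles")
  dict_p <- default_dictionary("protein")
  fd <- atom_feature_dim()
  withr::with_seed(as.integer(seed), {
    enc_d <- init_sequence_encoder(length(dict_d), config$embed_dim,
                                   config$filters, config$kernel_drug,
                                   config$se_r)
    enc_p <- init_sequence_encoder(length(dict_p), config$embed_dim,
                                   config$filters, config$kernel_protein,
                                   config$se_r)
    gin <- init_gin_encoder(fd, config$gin_depth, config$gin_hidden,
                            config$graph_dim, config$dropout)
    cd <- utils::tail(config$filters, 1)   # drug sequence channel width
    cp <- utils::tail(config$filters, 1)   # protein channel width
    cg <- config$gin_hidden
    la <- config$la
    att <- list(
      Wk = glorot_init(cp, la), bk = numeric(la),
      b1 = list(Wq = glorot_init(cd, la), bq = numeric(la),
                WQ = glorot_init(la, la), WK = glorot_init(la, la)),
      b2 = list(Wq = glorot_init(cg, la), bq = numeric(la),
                WQ = glorot_init(la, la), WK = glorot_init(la, la))
    )
    head <- init_regression_head(cd + cg + cp + config$graph_dim,
                                 config$head_hidden, config$dropout)
    params <- list(
      emb_d = enc_d$embed, emb_p = enc_p$embed,
      seq_d = lapply(enc_d$layers, unclass),
      seq_p = lapply(enc_p$layers, unclass),
      gin = lapply(gin$layers, unclass),
      gin_proj = gin$proj,
      att = att,
      head = lapply(head$layers, unclass)
    )
    structure(list(
      params = params,
      state = list(bn_mean = gin$bn_state$mean, bn_var = gin$bn_state$var),
      config = config,
      dict_drug = dict_d, dict_protein = dict_p,
      y_offset = 0,   # label centering constant learned by dta_fit
      seed = as.integer(seed)
    ), class = "dta_model")
  })
}

#' @export
print.dta_model <- function(x, ...) {
  np <- sum(rapply(x$params, length, how = "unlist"))
  cat(sprintf("<dta_model: preset '%s', %d parameters%s>\n",
              x$config$preset, np,
              if (!is.null(x$history)) ", trained" else ""))
  invisible(x)
}

# ---- batch preparation -----------------------------------------------------

#' Prepare a model batch from affinity records
#'
#' Encodes SMILES and protein strings as padded label vectors, parses the
#' molecular graphs (cached per unique SMILES) and assembles the
#' block-diagonal node batch.
#'
#' @param data Data frame with `smiles` and `protein` columns (and
#'   optionally `affinity`).
#' @param model A [dta_model()] (for dictionaries and lengths).
#' @param graph_cache Optional pre-parsed list of `molecular_graph`s named
#'   by SMILES.
#' @return A `dta_batch` list.
#' @export
prepare_batch <- function(data, model, graph_cache = NULL) {
  cfg <- model$config
  B <- nrow(data)
  ld <- cfg$drug_max_len; lp <- cfg$protein_max_len
  unk <- if (identical(cfg$unknown_policy, "zero")) "zero" else "error"
  enc_d <- lapply(data$smiles, encode_sequence, dict = model$dict_drug,
                  max_len = ld, unknown = unk)
  enc_p <- lapply(data$protein, encode_sequence, dict = model$dict_protein,
                  max_len = lp, unknown = unk)
  d_codes <- do.call(rbind, lapply(enc_d, `[[`, "codes"))
  p_codes <- do.call(rbind, lapply(enc_p, `[[`, "codes"))
  d_len <- vapply(enc_d, `[[`, integer(1), "original_length")
  p_len <- vapply(enc_p, `[[`, integer(1), "original_length")
  if (any(d_len == 0) || any(p_len == 0)) {
    stop("record with empty sequence after encoding", call. = FALSE)
  }
  if (is.null(graph_cache)) {
    graphs <- smiles_to_graphs(data$smiles)
  } else {
    graphs <- graph_cache[data$smiles]
    miss <- vapply(graphs, is.null, logical(1))
    if (any(miss)) graphs[miss] <- smiles_to_graphs(data$smiles[miss])
  }
  ns <- vapply(graphs, function(g) nrow(g$features), integer(1))
  offs <- cumsum(c(0L, ns[-length(ns)]))
  edges <- do.call(rbind, lapply(seq_len(B), function(i) {
    e <- graph_edges_directed(graphs[[i]])
    if (nrow(e) == 0) matrix(integer(0), ncol = 2) else e + offs[i]
  }))
  structure(list(
    B = B,
    d_codes = d_codes, p_codes = p_codes, d_len = d_len, p_len = p_len,
    X0 = do.call(rbind, lapply(graphs, `[[`, "features")),
    edges = edges, graph_id = rep(seq_len(B), ns), n_atoms = ns,
    graphs = graphs,
    y = if ("affinity" %in% names(data)) data$affinity else NULL
  ), class = "dta_batch")
}

#' Parse and cache the graphs of a dataset once
#'
#' @param data Data frame with a `smiles` column.
#' @return Named list of `molecular_graph` objects keyed by SMILES.
#' @export
build_graph_cache <- function(data) {
  uniq <- unique(data$smiles)
  gs <- smiles_to_graphs(uniq)
  names(gs) <- uniq
  gs
}

# ---- sequence channel (batched) -------------------------------------------

# gather index for sample-major layout: rows (b-1)*L + t; dummy row B*L + 1
seq_gather_index <- function(B, L, k) {
  Gi <- conv_gather_index(L, k)            # L x k, 0 = out of range
  dummy <- B * L + 1L
  idx <- matrix(0L, B * L, k)
  base <- rep((seq_len(B) - 1L) * L, each = L)
  for (o in seq_len(k)) {
    col <- Gi[, o]
    glob <- rep(col, B) + ifelse(rep(col, B) == 0L, 0L, base)
    glob[rep(col, B) == 0L] <- dummy
    idx[, o] <- glob
  }
  idx
}

seq_forward_batch <- function(emb, layers, codes, lens, kernel, train) {
  B <- nrow(codes); L <- ncol(codes)
  codes_flat <- as.vector(t(codes))
  X <- emb[codes_flat + 1L, , drop = FALSE]
  pos <- rep(seq_len(L), B)
  sample_id <- rep(seq_len(B), each = L)
  mask <- pos <= lens[sample_id]
  Gidx <- seq_gather_index(B, L, kernel)
  caches <- vector("list", length(layers))
  for (j in seq_along(layers)) {
    p <- layers[[j]]
    Xa <- rbind(X, 0)
    Xcol <- do.call(cbind, lapply(seq_len(kernel),
                                  function(o) Xa[Gidx[, o], , drop = FALSE]))
    pre <- sweep(Xcol %*% p$W, 2, p$b, `+`)
    Y <- relu(pre)
    Y[!mask, ] <- 0
    z <- rowsum(Y, sample_id) / lens
    a1 <- z %*% t(p$se$W1)
    r1 <- relu(a1)
    s <- sigmoid(r1 %*% t(p$se$W2))
    out <- Y * s[sample_id, , drop = FALSE]
    caches[[j]] <- list(X = X, Xcol = Xcol, pre = pre, Y = Y, z = z,
                        a1 = a1, r1 = r1, s = s)
    X <- out
  }
  list(out = X, caches = caches, mask = mask, sample_id = sample_id,
       codes_flat = codes_flat, Gidx = Gidx, L = L, B = B)
}

seq_backward_batch <- function(dX, fwd, layers, lens, kernel, vocab_rows) {
  B <- fwd$B; L <- fwd$L
  mask <- fwd$mask; sample_id <- fwd$sample_id
  grads <- vector("list", length(layers))
  for (j in rev(seq_along(layers))) {
    p <- layers[[j]]; cc <- fwd$caches[[j]]
    # out = Y * s[sample]
    dY <- dX * cc$s[sample_id, , drop = FALSE]
    ds <- rowsum(dX * cc$Y, sample_id)
    dpre2 <- ds * cc$s * (1 - cc$s)
    dW2 <- t(dpre2) %*% cc$r1
    dr1 <- dpre2 %*% p$se$W2
    da1 <- dr1 * (cc$a1 > 0)
    dW1 <- t(da1) %*% cc$z
    dz <- da1 %*% p$se$W1
    # z = rowsum(Y)/len : every valid row of sample b receives dz_b / len_b
    dY <- dY + (dz / lens)[sample_id, , drop = FALSE] * mask
    dY[!mask, ] <- 0
    dpre <- dY * (cc$pre > 0)
    db <- colSums(dpre)
    dW <- t(cc$Xcol) %*% dpre
    dXcol <- dpre %*% t(p$W)
    dXprev <- matrix(0, B * L, ncol(cc$X))
    cin <- ncol(cc$X)
    for (o in seq_len(kernel)) {
      idx <- fwd$Gidx[, o]
      keep <- idx <= B * L
      cols <- ((o - 1L) * cin + 1L):(o * cin)
      dXprev[idx[keep], ] <- dXprev[idx[keep], , drop = FALSE] +
        dXcol[keep, cols, drop = FALSE]
    }
    grads[[j]] <- list(W = dW, b = db, se = list(W1 = dW1, W2 = dW2))
    dX <- dXprev
  }
  # embedding gradient: scatter-add rows by code (pad row 0 frozen)
  demb <- matrix(0, vocab_rows, ncol(dX))
  agg <- rowsum(dX, fwd$codes_flat)
  codes_present <- as.integer(rownames(agg))
  nonpad <- codes_present != 0L
  demb[codes_present[nonpad] + 1L, ] <- agg[nonpad, , drop = FALSE]
  list(layer_grads = grads, demb = demb)
}

# ---- full forward ----------------------------------------------------------

dta_forward <- function(model, batch, train = FALSE, need_cache = train) {
  cfg <- model$config
  p <- model$params
  B <- batch$B

  fwd_d <- seq_forward_batch(p$emb_d, p$seq_d, batch$d_codes, batch$d_len,
                             cfg$kernel_drug, train)
  fwd_p <- seq_forward_batch(p$emb_p, p$seq_p, batch$p_codes, batch$p_len,
                             cfg$kernel_protein, train)
  Dsen <- fwd_d$out; Psen <- fwd_p$out

  # graph stack
  N <- nrow(batch$X0)
  A <- if (nrow(batch$edges) > 0) {
    Matrix::sparseMatrix(i = batch$edges[, 1], j = batch$edges[, 2], x = 1,
                         dims = c(N, N))
  } else {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(N, N))
  }
  gin_enc <- list(layers = p$gin, depth = length(p$gin),
                  bn_state = list(mean = model$state$bn_mean,
                                  var = model$state$bn_var))
  gfwd <- gin_stack_forward(batch$X0, A, gin_enc, train = train,
                            keep_cache = need_cache)
  Fmat <- gfwd$F
  S <- do.call(cbind, lapply(gfwd$layer_out, function(x)
    rowsum(x, batch$graph_id)))
  g0 <- sweep(S %*% p$gin_proj$W, 2, p$gin_proj$b, `+`)
  gr <- relu(g0)
  drop_g <- if (train && cfg$dropout > 0)
    matrix(dropout_mask(length(gr), cfg$dropout), nrow(gr)) else NULL
  Dgin <- apply_dropout(gr, drop_g)

  # attention + fusion per sample
  cd <- ncol(Dsen); cg <- ncol(Fmat); cp <- ncol(Psen)
  scale1 <- if (identical(cfg$scale_by, "head")) sqrt(cfg$la / cfg$heads) else sqrt(cd / cfg$heads)
  scale2 <- if (identical(cfg$scale_by, "head")) sqrt(cfg$la / cfg$heads) else sqrt(cg / cfg$heads)
  cols <- head_cols(cfg$la, cfg$heads)
  ld <- cfg$drug_max_len; lp <- cfg$protein_max_len
  I <- matrix(0, B, cd + cg + cp)
  att_cache <- if (need_cache) vector("list", B) else NULL
  maps <- vector("list", B)
  for (b in seq_len(B)) {
    rd <- (b - 1L) * ld + seq_len(batch$d_len[b])
    rp <- (b - 1L) * lp + seq_len(batch$p_len[b])
    ra <- which(batch$graph_id == b)
    Db <- Dsen[rd, , drop = FALSE]
    Pb <- Psen[rp, , drop = FALSE]
    Fb <- Fmat[ra, , drop = FALSE]
    preK <- sweep(Pb %*% p$att$Wk, 2, p$att$bk, `+`)
    K0 <- relu(preK)
    br <- function(Xq, bp, scale) {
      preQ <- sweep(Xq %*% bp$Wq, 2, bp$bq, `+`)
      Q0 <- relu(preQ)
      Qh <- Q0 %*% bp$WQ
      Kh <- K0 %*% bp$WK
      Ph <- vector("list", cfg$heads)
      Amap <- 0
      for (i in seq_len(cfg$heads)) {
        logits <- Qh[, cols[[i]], drop = FALSE] %*%
          t(Kh[, cols[[i]], drop = FALSE]) / scale
        P <- softmax_rows(logits)
        Ph[[i]] <- P
        Amap <- Amap + P
      }
      list(preQ = preQ, Q0 = Q0, Qh = Qh, Kh = Kh, Ph = Ph,
           A = Amap / cfg$heads)
    }
    a1 <- br(Db, p$att$b1, scale1)
    a2 <- br(Fb, p$att$b2, scale2)
    dec <- decouple_attention(a1$A, a2$A)
    wD1 <- Db * dec$alpha_d1
    wD2 <- Fb * dec$alpha_d2
    wP <- Pb * dec$alpha_p
    am1 <- apply(wD1, 2, which.max); g1 <- wD1[cbind(am1, seq_len(cd))]
    am2 <- apply(wD2, 2, which.max); g2 <- wD2[cbind(am2, seq_len(cg))]
    am3 <- apply(wP, 2, which.max);  g3 <- wP[cbind(am3, seq_len(cp))]
    I[b, ] <- c(g1, g2, g3)
    maps[[b]] <- list(A1 = a1$A, A2 = a2$A, alpha = dec)
    if (need_cache) {
      att_cache[[b]] <- list(rd = rd, rp = rp, ra = ra, Db = Db, Pb = Pb,
                             Fb = Fb, preK = preK, K0 = K0, b1 = a1, b2 = a2,
                             dec = dec, am1 = am1, am2 = am2, am3 = am3)
    }
  }

  # regression head
  H <- cbind(I, Dgin)
  head_cache <- list()
  nl <- length(p$head)
  drop_h <- vector("list", nl)
  Hs <- vector("list", nl)
  pre_h <- vector("list", nl)
  for (i in seq_len(nl)) {
    Hs[[i]] <- H
    hp <- p$head[[i]]
    Z <- sweep(H %*% hp$W, 2, hp$b, `+`)
    pre_h[[i]] <- Z
    if (i < nl) {
      Z <- relu(Z)
      if (train && cfg$dropout > 0) {
        drop_h[[i]] <- matrix(dropout_mask(length(Z), cfg$dropout), nrow(Z))
        Z <- apply_dropout(Z, drop_h[[i]])
      }
    }
    H <- Z
  }
  pred <- drop(H)

  cache <- NULL
  if (need_cache) {
    cache <- list(fwd_d = fwd_d, fwd_p = fwd_p, gfwd = gfwd, A = A, S = S,
                  g0 = g0, gr = gr, drop_g = drop_g, Dgin = Dgin, I = I,
                  att = att_cache, Hs = Hs, pre_h = pre_h, drop_h = drop_h,
                  Dsen = Dsen, Psen = Psen, Fmat = Fmat,
                  scale1 = scale1, scale2 = scale2, cols = cols,
                  cd = cd, cg = cg, cp = cp)
  }
  list(pred = pred, cache = cache, maps = maps,
       bn_state = list(bn_mean = gfwd$bn_state$mean,
                       bn_var = gfwd$bn_state$var))
}

# ---- full backward ---------------------------------------------------------

# dpred: vector of d(loss)/d(pred). Returns grads congruent with params,
# plus dF (gradient at the last-layer GIN node features, for Grad-AAM).
dta_backward <- function(model, batch, fwd, dpred) {
  cfg <- model$config
  p <- model$params
  cc <- fwd$cache
  B <- batch$B
  g <- zeros_like(p)

  # head
  nl <- length(p$head)
  dH <- matrix(dpred, ncol = 1)
  for (i in rev(seq_len(nl))) {
    if (i < nl) {
      dH <- apply_dropout(dH, cc$drop_h[[i]])
      dH <- dH * (cc$pre_h[[i]] > 0)
    }
    g$head[[i]]$W <- t(cc$Hs[[i]]) %*% dH
    g$head[[i]]$b <- colSums(dH)
    dH <- dH %*% t(p$head[[i]]$W)
  }
  cd <- cc$cd; cg <- cc$cg; cp <- cc$cp
  dI <- dH[, seq_len(cd + cg + cp), drop = FALSE]
  dDgin <- dH[, cd + cg + cp + seq_len(ncol(cc$Dgin)), drop = FALSE]

  # graph projection
  dgr <- apply_dropout(dDgin, cc$drop_g)
  dg0 <- dgr * (cc$g0 > 0)
  g$gin_proj$W <- t(cc$S) %*% dg0
  g$gin_proj$b <- colSums(dg0)
  dS <- dg0 %*% t(p$gin_proj$W)

  # per-layer readout scatter: node rows get their graph's slice
  depth <- length(p$gin)
  hid <- cfg$gin_hidden
  dlayer <- vector("list", depth)
  for (k in seq_len(depth)) {
    sl <- dS[, (k - 1L) * hid + seq_len(hid), drop = FALSE]
    dlayer[[k]] <- sl[batch$graph_id, , drop = FALSE]
  }

  # attention + fusion backward (accumulates into sequence/graph features)
  dDsen <- matrix(0, nrow(cc$Dsen), cd)
  dPsen <- matrix(0, nrow(cc$Psen), cp)
  dF <- matrix(0, nrow(cc$Fmat), cg)
  for (b in seq_len(B)) {
    ac <- cc$att[[b]]
    nd <- length(ac$rd); np <- length(ac$rp); na <- length(ac$ra)
    dg1 <- dI[b, seq_len(cd)]
    dg2 <- dI[b, cd + seq_len(cg)]
    dg3 <- dI[b, cd + cg + seq_len(cp)]
    # max-pool backward
    dwD1 <- matrix(0, nd, cd); dwD1[cbind(ac$am1, seq_len(cd))] <- dg1
    dwD2 <- matrix(0, na, cg); dwD2[cbind(ac$am2, seq_len(cg))] <- dg2
    dwP <- matrix(0, np, cp);  dwP[cbind(ac$am3, seq_len(cp))] <- dg3
    al <- ac$dec
    dDb <- dwD1 * al$alpha_d1
    dFb <- dwD2 * al$alpha_d2
    dPb <- dwP * al$alpha_p
    dad1 <- rowSums(dwD1 * ac$Db)
    dad2 <- rowSums(dwD2 * ac$Fb)
    dap <- rowSums(dwP * ac$Pb)
    # decouple backward: alpha_d = rowSums(A); alpha_p = colSums(rbind(A1,A2))
    dA1 <- outer(dad1, rep(1, np)) + outer(rep(1, nd), dap)
    dA2 <- outer(dad2, rep(1, np)) + outer(rep(1, na), dap)
    bwd_branch <- function(acb, dA, bp, gp, Xq, scale) {
      h <- cfg$heads
      dQh <- matrix(0, nrow(dA), cfg$la)
      dKh <- matrix(0, np, cfg$la)
      for (i in seq_len(h)) {
        dP <- dA / h
        dlog <- softmax_rows_backward(dP, acb$Ph[[i]])
        ci <- cc$cols[[i]]
        dQh[, ci] <- dQh[, ci] + dlog %*% acb$Kh[, ci, drop = FALSE] / scale
        dKh[, ci] <- dKh[, ci] + t(dlog) %*% acb$Qh[, ci, drop = FALSE] / scale
      }
      gp$WQ <- gp$WQ + t(acb$Q0) %*% dQh
      dQ0 <- dQh %*% t(bp$WQ)
      gp$WK <- gp$WK + t(ac$K0) %*% dKh
      dK0 <- dKh %*% t(bp$WK)
      dpreQ <- dQ0 * (acb$preQ > 0)
      gp$Wq <- gp$Wq + t(Xq) %*% dpreQ
      gp$bq <- gp$bq + colSums(dpreQ)
      dXq <- dpreQ %*% t(bp$Wq)
      list(gp = gp, dXq = dXq, dK0 = dK0)
    }
    r1 <- bwd_branch(ac$b1, dA1, p$att$b1, g$att$b1, ac$Db, cc$scale1)
    g$att$b1 <- r1$gp
    r2 <- bwd_branch(ac$b2, dA2, p$att$b2, g$att$b2, ac$Fb, cc$scale2)
    g$att$b2 <- r2$gp
    dK0 <- r1$dK0 + r2$dK0
    dpreK <- dK0 * (ac$preK > 0)
    g$att$Wk <- g$att$Wk + t(ac$Pb) %*% dpreK
    g$att$bk <- g$att$bk + colSums(dpreK)
    dPb <- dPb + dpreK %*% t(p$att$Wk)
    dDb <- dDb + r1$dXq
    dFb <- dFb + r2$dXq
    dDsen[ac$rd, ] <- dDsen[ac$rd, , drop = FALSE] + dDb
    dPsen[ac$rp, ] <- dPsen[ac$rp, , drop = FALSE] + dPb
    dF[ac$ra, ] <- dF[ac$ra, , drop = FALSE] + dFb
  }

  # GIN stack backward
  dX <- dF + dlayer[[depth]]
  dF_total <- dX    # full gradient at the last-layer node features
  for (k in rev(seq_len(depth))) {
    gc_ <- cc$gfwd$caches[[k]]
    pk <- p$gin[[k]]
    dy <- dX * (gc_$y > 0)
    bb <- bn_backward(dy, gc_$bn, pk$gamma)
    g$gin[[k]]$gamma <- bb$dgamma
    g$gin[[k]]$beta <- bb$dbeta
    dh2 <- bb$dh
    g$gin[[k]]$W2 <- t(gc_$r1) %*% dh2
    g$gin[[k]]$b2 <- colSums(dh2)
    dr1 <- dh2 %*% t(pk$W2)
    dh1 <- dr1 * (gc_$h1 > 0)
    g$gin[[k]]$W1 <- t(gc_$agg) %*% dh1
    g$gin[[k]]$b1 <- colSums(dh1)
    dagg <- dh1 %*% t(pk$W1)
    g$gin[[k]]$eps <- sum(dagg * gc_$X_in)
    dX <- (1 + pk$eps) * dagg + as.matrix(Matrix::t(cc$A) %*% dagg)
    if (k > 1) dX <- dX + dlayer[[k - 1]]
  }

  # sequence channels backward
  sd <- seq_backward_batch(dDsen, cc$fwd_d, p$seq_d, batch$d_len,
                           cfg$kernel_drug, nrow(p$emb_d))
  g$seq_d <- sd$layer_grads
  g$emb_d <- sd$demb
  sp <- seq_backward_batch(dPsen, cc$fwd_p, p$seq_p, batch$p_len,
                           cfg$kernel_protein, nrow(p$emb_p))
  g$seq_p <- sp$layer_grads
  g$emb_p <- sp$demb

  list(grads = g, dF = dF_total)
}

# ---- prediction ------------------------------------------------------------

#' Predict affinities for new drug-protein pairs
#'
#' Deterministic evaluation-mode forward pass (dropout off, batch
#' normalization on running statistics).
#'
#' @param object A `dta_model` (typically from [dta_fit()]).
#' @param newdata Data frame with `smiles` and `protein` columns.
#' @param batch_size Evaluation batch size.
#' @param graph_cache Optional [build_graph_cache()] result.
#' @param ... Unused.
#' @return The input as a tibble with a `.pred` column appended, row order
#'   preserved.
#' @export
predict.dta_model <- function(object, newdata, batch_size = 64,
                              graph_cache = NULL, ...) {
  out <- dplyr::as_tibble(newdata)
  n <- nrow(out)
  preds <- numeric(n)
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, n)
    batch <- prepare_batch(out[idx, ], object, graph_cache)
    preds[idx] <- dta_forward(object, batch, train = FALSE,
                              need_cache = FALSE)$pred + object$y_offset
  }
  out$.pred <- preds
  out
}
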