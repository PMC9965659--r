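test_that("node contributions follow the analytic surrogate gradient", {
  # surrogate: prediction = mean over nodes of channel 1 of F
  set.seed(51)
  n <- 6; C <- 4
  F <- matrix(rnorm(n * C), n, C)
  F[, 1] <- abs(F[, 1])           # keep the raw map positive
  dF <- matrix(0, n, C); dF[, 1] <- 1 / n
  nc <- node_contribution(F, dF)
  expect_equal(nc$channel_weights, c(1 / n, rep(0, C - 1)))
  raw_expected <- F[, 1] / n
  expect_lt(max(abs(nc$raw - raw_expected)), 1e-5)
  expect_identical(which.max(nc$score), which.max(F[, 1]))
  expect_equal(max(nc$score), 1)
  expect_equal(min(nc$score), 0)
})

test_that("raw maps are nonnegative and scores scale-invariant", {
  set.seed(52)
  for (i in 1:20) {
    F <- matrix(rnorm(20), 5, 4)
    dF <- matrix(rnorm(20), 5, 4)
    nc <- node_contribution(F, dF)
    expect_true(all(nc$raw >= 0))
    if (diff(range(nc$raw)) > 0) {
      nc2 <- node_contribution(F * 3.7, dF)   # positive rescaling of raw map
      expect_equal(nc2$score, nc$score, tolerance = 1e-9)
    }
  }
})

test_that("a constant raw map degenerates to all-zero scores", {
  F <- matrix(1, 4, 3)
  dF <- matrix(1, 4, 3)
  expect_warning(nc <- node_contribution(F, dF), "constant")
  expect_identical(nc$score, rep(0, 4))
  expect_error(node_contribution(F, dF[1:2, ]), "mismatch")
})

test_that("overlap rate reproduces forced fixtures", {
  expect_identical(overlap_rate(list(1:3, c(2L, 5L)), list(1:3, c(2L, 5L))), 1)
  expect_identical(overlap_rate(list(1:2, 3:4), list(5:6, 7:8)), 0)
  expect_identical(overlap_rate(list(c(1L, 2L), 1:3), list(1:4, 1:3)), 0.75)
  expect_error(overlap_rate(list(1:2), list(integer(0))), "empty reference")
  expect_error(overlap_rate(list(1:2), list(1:2, 1:2)), "length")
})

test_that("grad_aam produces a normalized per-atom map from the model", {
  model <- dta_model(tiny_config(), seed = 53)
  dat <- tiny_dataset(1)
  cm <- grad_aam(model, dat$smiles[1], dat$protein[1])
  g <- smiles_to_graph(dat$smiles[1])
  expect_identical(nrow(cm), nrow(g$features))
  expect_true(all(cm$score >= 0 & cm$score <= 1))
  expect_identical(cm$symbol, g$atoms$symbol)
  expect_length(attr(cm, "channel_weights"), tiny_config()$gin_hidden)
  # deterministic
  cm2 <- grad_aam(model, dat$smiles[1], dat$protein[1])
  expect_identical(cm$score, cm2$score)
  expect_error(grad_aam(lm(y ~ x, data.frame(x = 1:3, y = 1:3)), "C", "M"),
               "dta_model")
})

test_that("the attribution gradient matches finite differences on F", {
  # perturb one last-layer node feature and compare the prediction change
  model <- dta_model(tiny_config(), seed = 54)
  dat <- tiny_dataset(1, seed = 8)
  batch <- dtafuse:::prepare_batch(dat, model)
  fwd <- dtafuse:::dta_forward(model, batch, train = FALSE, need_cache = TRUE)
  bwd <- dtafuse:::dta_backward(model, batch, fwd, dpred = 1)
  dF <- bwd$dF
  # replay the fusion + head with a bumped F to get a numeric gradient
  bump <- function(i, j, eps) {
    m <- model
    f2 <- fwd
    f2$cache$Fmat[i, j] <- f2$cache$Fmat[i, j] + eps
    replay_pred(m, batch, f2$cache)
  }
  replay_pred <- function(m, batch, cache) {
    # recompute attention branch 2 + fusion + head from a modified F
    cfg <- m$config; p <- m$params
    ac <- cache$att[[1]]
    Fb <- cache$Fmat[ac$ra, , drop = FALSE]
    a2 <- local({
      preQ <- sweep(Fb %*% p$att$b2$Wq, 2, p$att$b2$bq, `+`)
      Q0 <- pmax(preQ, 0)
      Qh <- Q0 %*% p$att$b2$WQ
      Kh <- ac$K0 %*% p$att$b2$WK
      A <- 0
      for (i in seq_len(cfg$heads)) {
        ci <- cache$cols[[i]]
        logit <- Qh[, ci, drop = FALSE] %*% t(Kh[, ci, drop = FALSE]) /
          cache$scale2
        e <- exp(logit - apply(logit, 1, max))
        A <- A + e / rowSums(e)
      }
      A / cfg$heads
    })
    dec <- decouple_attention(cache$att[[1]]$b1$A, a2)
    idp <- fuse_representations(ac$Db, dec$alpha_d1, Fb, dec$alpha_d2,
                                ac$Pb, dec$alpha_p)
    # graph vector also depends on F through the last-layer readout
    S <- cache$S
    hid <- cfg$gin_hidden
    last <- (cfg$gin_depth - 1) * hid + seq_len(hid)
    S[, last] <- colSums(cache$Fmat[ac$ra, , drop = FALSE])
    G <- pmax(sweep(S %*% p$gin_proj$W, 2, p$gin_proj$b, `+`), 0)
    predict_affinity(c(idp, G[1, ]),
                     structure(list(layers = p$head, dropout = 0,
                                    input_dim = length(idp) + ncol(G)),
                               class = "regression_head"))
  }
  set.seed(55)
  ij <- cbind(sample(nrow(dF), 4, replace = TRUE),
              sample(ncol(dF), 4, replace = TRUE))
  for (r in seq_len(nrow(ij))) {
    i <- ij[r, 1]; j <- ij[r, 2]
    eps <- 1e-5
    num <- (bump(i, j, eps) - bump(i, j, -eps)) / (2 * eps)
    expect_lt(abs(num - dF[i, j]), 1e-5 + 1e-3 * abs(num),
              label = paste("dF", i, j))
  }
})

test_that("heatmap rendering is deterministic ggplot output", {
  model <- dta_model(tiny_config(), seed = 56)
  dat <- tiny_dataset(1)
  cm <- grad_aam(model, dat$smiles[1], dat$protein[1])
  p <- ggplot2::autoplot(cm)
  expect_s3_class(p, "ggplot")
  expect_identical(top_contributing_atoms(cm),
                   cm$atom[cm$score >= 0.5])
})
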