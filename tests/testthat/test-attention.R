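test_that("scaled dot attention handles degenerate key sets", {
  Q <- matrix(rnorm(6), 3, 2)
  K <- matrix(rnorm(2), 1, 2)
  V <- matrix(c(5, 7), 1, 2)
  att <- scaled_dot_attention(Q, K, V, scale = 1)
  expect_equal(att$map, matrix(1, 3, 1))
  expect_equal(att$output, matrix(rep(c(5, 7), each = 3), 3, 2))

  # zero logits give uniform rows over unmasked keys
  Z <- matrix(0, 2, 3)
  K4 <- matrix(0, 4, 3)
  att2 <- scaled_dot_attention(Z, K4, matrix(rnorm(8), 4, 2), scale = 2)
  expect_equal(att2$map, matrix(0.25, 2, 4))
  att3 <- scaled_dot_attention(Z, K4, matrix(rnorm(8), 4, 2), scale = 2,
                               key_mask = c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(att3$map[, 3], c(0, 0))
  expect_equal(att3$map[, 1], c(1, 1) / 3)
  expect_error(scaled_dot_attention(Z, K4, matrix(0, 4, 1), scale = 1,
                                    key_mask = rep(FALSE, 4)), "masked")
})

test_that("hand-computed softmax maps are reproduced", {
  # logits [[0, ln 3], [0, 0]] -> rows [[0.25, 0.75], [0.5, 0.5]]
  Q <- rbind(c(1, 0), c(0, 0))
  K <- rbind(c(0, 1), c(log(3), 1))
  V <- diag(2)
  att <- scaled_dot_attention(Q, K, V, scale = 1)
  expect_equal(att$map, rbind(c(0.25, 0.75), c(0.5, 0.5)), tolerance = 1e-12)
})

test_that("attention map rows sum to one over unmasked keys", {
  set.seed(21)
  for (i in 1:20) {
    nq <- sample(1:6, 1); nk <- sample(2:8, 1)
    mask <- runif(nk) > 0.3
    if (!any(mask)) mask[1] <- TRUE
    att <- scaled_dot_attention(matrix(rnorm(nq * 3), nq),
                                matrix(rnorm(nk * 3), nk),
                                matrix(rnorm(nk * 2), nk),
                                scale = sqrt(3), key_mask = mask)
    expect_lt(max(abs(rowSums(att$map) - 1)), 1e-5)
    expect_true(all(att$map[, !mask] == 0))
  }
})

test_that("one head reduces to plain scaled dot attention", {
  set.seed(22)
  p <- init_cross_attention(5, 4, la = 8, h = 1)
  drug <- matrix(rnorm(15), 3, 5)
  prot <- matrix(rnorm(24), 6, 4)
  got <- multi_head_cross_attention(drug, prot, p)
  Q0 <- pmax(sweep(drug %*% p$Wq, 2, p$bq, `+`), 0)
  K0 <- pmax(sweep(prot %*% p$Wk, 2, p$bk, `+`), 0)
  V0 <- pmax(sweep(prot %*% p$Wv, 2, p$bv, `+`), 0)
  ref <- scaled_dot_attention(Q0 %*% p$WQ, K0 %*% p$WK, V0 %*% p$WV,
                              scale = p$scale)
  expect_lt(max(abs(got$map - ref$map)), 1e-6)
  expect_lt(max(abs(got$output - ref$output %*% p$WO)), 1e-6)
})

test_that("multi-head attention matches a loop-over-heads oracle", {
  set.seed(23)
  h <- 8; la <- 16
  p <- init_cross_attention(6, 5, la = la, h = h)
  drug <- matrix(rnorm(24), 4, 6)
  prot <- matrix(rnorm(35), 7, 5)
  got <- multi_head_cross_attention(drug, prot, p)
  Q0 <- pmax(sweep(drug %*% p$Wq, 2, p$bq, `+`), 0)
  K0 <- pmax(sweep(prot %*% p$Wk, 2, p$bk, `+`), 0)
  V0 <- pmax(sweep(prot %*% p$Wv, 2, p$bv, `+`), 0)
  Qh <- Q0 %*% p$WQ; Kh <- K0 %*% p$WK; Vh <- V0 %*% p$WV
  d <- la / h
  outs <- NULL; msum <- 0
  for (i in seq_len(h)) {
    cols <- (i - 1) * d + seq_len(d)
    logit <- Qh[, cols] %*% t(Kh[, cols]) / p$scale
    e <- exp(logit - apply(logit, 1, max))
    P <- e / rowSums(e)
    msum <- msum + P
    outs <- cbind(outs, P %*% Vh[, cols])
  }
  expect_lt(max(abs(got$output - outs %*% p$WO)), 1e-6)
  expect_lt(max(abs(got$map - msum / h)), 1e-6)
  # identical drug rows produce identical map rows
  drug2 <- drug[c(1, 1, 2, 2), ]
  got2 <- multi_head_cross_attention(drug2, prot, p)
  expect_equal(got2$map[1, ], got2$map[2, ])
  expect_error(init_cross_attention(6, 5, la = 9, h = 2), "divide")
})

test_that("decoupling takes row and column sums of the maps", {
  # uniform softmax-normalized maps give constant weights
  u1 <- matrix(1 / 4, 3, 4)
  u2 <- matrix(1 / 4, 2, 4)
  dec <- decouple_attention(u1, u2)
  expect_equal(dec$alpha_d1, rep(1, 3))
  expect_equal(dec$alpha_d2, rep(1, 2))
  expect_equal(dec$alpha_p, rep(5 / 4, 4))

  conc <- matrix(0, 3, 4); conc[, 2] <- 1
  dec2 <- decouple_attention(conc, matrix(0.25, 2, 4))
  expect_identical(which.max(dec2$alpha_p), 2L)

  set.seed(24)
  A1 <- matrix(runif(12), 3, 4); A2 <- matrix(runif(8), 2, 4)
  dec3 <- decouple_attention(A1, A2)
  expect_lt(max(abs(dec3$alpha_d1 - apply(A1, 1, sum))), 1e-9)
  expect_lt(max(abs(dec3$alpha_p - colSums(rbind(A1, A2)))), 1e-9)
  expect_true(all(dec3$alpha_p >= 0))
  expect_error(decouple_attention(A1, matrix(1, 2, 5)), "protein-axis")
})

test_that("fusion pools each weighted representation by channel max", {
  set.seed(25)
  D1 <- matrix(rnorm(12), 4, 3)
  D2 <- matrix(rnorm(10), 5, 2)
  P <- matrix(rnorm(8), 2, 4)
  ones <- function(n) rep(1, n)
  idp <- fuse_representations(D1, ones(4), D2, ones(5), P, ones(2))
  expect_equal(idp, c(apply(D1, 2, max), apply(D2, 2, max), apply(P, 2, max)))
  expect_length(idp, 3 + 2 + 4)

  idp0 <- fuse_representations(D1, rep(0, 4), D2, ones(5), P, ones(2))
  expect_equal(idp0[1:3], rep(0, 3))

  a1 <- runif(4); a2 <- runif(5); ap <- runif(2)
  got <- fuse_representations(D1, a1, D2, a2, P, ap)
  brute <- c(vapply(1:3, function(c) max(D1[, c] * a1), numeric(1)),
             vapply(1:2, function(c) max(D2[, c] * a2), numeric(1)),
             vapply(1:4, function(c) max(P[, c] * ap), numeric(1)))
  expect_lt(max(abs(got - brute)), 1e-6)
  expect_error(fuse_representations(D1, a1[-1], D2, a2, P, ap), "mismatch")
})

test_that("the regression head is affine-exact and deterministic", {
  h <- withr::with_seed(26, init_regression_head(5, hidden = c(4), dropout = 0))
  z <- withr::with_seed(27, rnorm(5))
  # zero-initialized head propagates zero
  h0 <- h
  h0$layers <- lapply(h0$layers, function(l) list(W = l$W * 0, b = l$b * 0))
  expect_identical(predict_affinity(rep(0, 5), h0), 0)
  # single affine layer case
  h1 <- withr::with_seed(28, init_regression_head(5, hidden = integer(0)))
  w <- h1$layers[[1]]$W; b <- h1$layers[[1]]$b
  expect_equal(predict_affinity(z, h1), sum(w * z) + b)
  expect_identical(predict_affinity(z, h), predict_affinity(z, h))
  expect_error(predict_affinity(rnorm(4), h), "width")
})
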