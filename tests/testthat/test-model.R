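pluck_path <- function(l, path) { for (k in path) l <- l[[k]]; l }
poke_path <- function(l, path, v) {
  if (length(path) == 1) { l[[path[[1]]]] <- v; return(l) }
  l[[path[[1]]]] <- poke_path(l[[path[[1]]]], path[-1], v)
  l
}

test_that("config presets validate their structural constraints", {
  cfg <- dta_config("davis")
  expect_identical(cfg$filters, c(16, 32, 48))
  expect_identical(cfg$heads, 8)
  expect_identical(cfg$head_hidden, c(1024, 1024, 512))
  expect_identical(dta_config("kiba")$filters, c(32, 64, 96))
  expect_error(dta_config("synthetic", la = 30, heads = 4), "divide")
  expect_error(dta_config("synthetic", nonsense = 1), "unknown config")
})

test_that("forward pass is deterministic and shaped per config", {
  model <- dta_model(tiny_config(), seed = 41)
  dat <- tiny_dataset(4)
  batch <- dtafuse:::prepare_batch(dat, model)
  f1 <- dtafuse:::dta_forward(model, batch)
  f2 <- dtafuse:::dta_forward(model, batch)
  expect_identical(f1$pred, f2$pred)
  expect_length(f1$pred, 4L)
  expect_true(all(is.finite(f1$pred)))
  # attention maps: rows over protein positions sum to one
  for (m in f1$maps) {
    expect_lt(max(abs(rowSums(m$A1) - 1)), 1e-5)
    expect_lt(max(abs(rowSums(m$A2) - 1)), 1e-5)
    expect_true(all(m$alpha$alpha_p >= 0))
  }
})

test_that("gradient reaches every parameter group on a random batch", {
  model <- dta_model(tiny_config(), seed = 42)
  dat <- tiny_dataset(5)
  batch <- dtafuse:::prepare_batch(dat, model)
  fwd <- dtafuse:::dta_forward(model, batch, train = TRUE, need_cache = TRUE)
  resid <- fwd$pred - batch$y
  bwd <- dtafuse:::dta_backward(model, batch, fwd, 2 * resid / length(resid))
  norms <- dtafuse:::grad_leaf_norms(bwd$grads)
  groups <- c("emb_d", "emb_p", "seq_d", "seq_p", "gin", "gin_proj",
              "att", "head")
  for (g in groups) {
    total <- sum(norms[grepl(paste0("^/", g), names(norms))])
    expect_gt(total, 0)
  }
  # every leaf in the live model receives gradient
  expect_true(all(norms > 0))
})

test_that("analytic gradients match central finite differences", {
  model <- dta_model(tiny_config(), seed = 43)
  dat <- tiny_dataset(4, seed = 6)
  batch <- dtafuse:::prepare_batch(dat, model)
  fwd <- dtafuse:::dta_forward(model, batch, train = TRUE, need_cache = TRUE)
  resid <- fwd$pred - batch$y
  bwd <- dtafuse:::dta_backward(model, batch, fwd, 2 * resid / length(resid))
  loss_at <- function(params) {
    m <- model
    m$params <- params
    f <- dtafuse:::dta_forward(m, batch, train = TRUE, need_cache = FALSE)
    mean((f$pred - batch$y)^2)
  }
  paths <- list(
    list("emb_d"), list("emb_p"),
    list("seq_d", 1, "W"), list("seq_d", 2, "se", "W1"),
    list("seq_p", 2, "W"), list("seq_p", 1, "se", "W2"),
    list("gin", 1, "W1"), list("gin", 2, "W2"), list("gin", 3, "gamma"),
    list("gin", 1, "eps"), list("gin_proj", "W"),
    list("att", "Wk"), list("att", "b1", "Wq"), list("att", "b1", "WK"),
    list("att", "b2", "WQ"), list("head", 1, "W"), list("head", 2, "b"))
  set.seed(44)
  for (pp in paths) {
    leaf <- pluck_path(model$params, pp)
    gleaf <- pluck_path(bwd$grads, pp)
    nz <- which(gleaf != 0)
    if (length(nz) == 0) next
    for (i in sample(nz, min(2, length(nz)))) {
      eps <- 1e-6
      x <- leaf; x[i] <- x[i] + eps
      up <- loss_at(poke_path(model$params, pp, x))
      x <- leaf; x[i] <- x[i] - eps
      dn <- loss_at(poke_path(model$params, pp, x))
      num <- (up - dn) / (2 * eps)
      expect_lt(abs(num - gleaf[i]),
                1e-6 + 1e-3 * max(abs(num), abs(gleaf[i])),
                label = paste(paste(pp, collapse = "$"), i))
    }
  }
})

test_that("extending the protein with padding leaves predictions unchanged", {
  cfg_short <- tiny_config(protein_max_len = 25)
  cfg_long <- tiny_config(protein_max_len = 60)
  m1 <- dta_model(cfg_short, seed = 45)
  m2 <- dta_model(cfg_long, seed = 45)
  # same parameters: protein pad length only affects layout, not weights
  m2$params <- m1$params
  dat <- tiny_dataset(3)
  p1 <- predict(m1, dat)
  p2 <- predict(m2, dat)
  expect_lt(max(abs(p1$.pred - p2$.pred)), 1e-6)
})

test_that("prediction preserves order and is batch-size independent", {
  model <- dta_model(tiny_config(), seed = 46)
  dat <- tiny_dataset(7)
  a <- predict(model, dat, batch_size = 7)
  b <- predict(model, dat, batch_size = 2)
  expect_equal(a$.pred, b$.pred, tolerance = 1e-10)
  expect_identical(a$smiles, dat$smiles)
})

test_that("zero-epoch training returns the initialized model", {
  dat <- tiny_dataset(4)
  fit <- dta_fit(dat, tiny_config(), seed = 47, epochs = 0)
  init <- dta_model(tiny_config(), seed = 47)
  expect_identical(fit$params, init$params)
  expect_identical(nrow(tidy(fit)), 0L)
})

test_that("training is reproducible and tracked by tidy/glance", {
  dat <- tiny_dataset(8)
  dat$split <- factor(rep(c("train", "validation"), c(6, 2)),
                      levels = c("train", "validation", "test"))
  f1 <- dta_fit(dat, tiny_config(), seed = 48, epochs = 3)
  f2 <- dta_fit(dat, tiny_config(), seed = 48, epochs = 3)
  expect_identical(tidy(f1)$train_mse, tidy(f2)$train_mse)
  expect_identical(tidy(f1)$val_mse, tidy(f2)$val_mse)
  expect_identical(f1$params, f2$params)
  g <- glance(f1)
  expect_identical(g$epochs, 3L)
  expect_gte(g$best_epoch, 1L)
  expect_s3_class(autoplot(f1), "ggplot")
  # loss decreases on this tiny problem
  expect_lt(tidy(f1)$train_mse[3], tidy(f1)$train_mse[1])
})
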