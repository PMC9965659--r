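# Training loop: Adam on the mean-squared-error loss, per-epoch train and
# validation tracking, best-validation checkpoint selection.

#' Fit the affinity model
#'
#' Minimizes the mean squared error with Adam at the configured learning
#' rate and batch size. Each epoch logs the training MSE (over the training
#' forward passes) and the validation MSE (evaluation mode); the returned
#' model carries the weights of the epoch with the best validation MSE
#' (falling back to the final weights when no validation set is given).
#' With the same seed, data and config, two runs produce identical loss
#' curves.
#'
#' @param data Training records: data frame with `smiles`, `protein`,
#'   `affinity`. If a `split` column (from [split_affinity()]) is present,
#'   the `train` part is trained on and the `validation` part monitored.
#' @param config A [dta_config()].
#' @param seed Integer seed covering initialization, batch order and
#'   dropout.
#' @param epochs Number of epochs (default from config); 0 returns the
#'   freshly initialized model.
#' @param validation Optional explicit validation data frame (overrides the
#'   `split` column).
#' @param verbose Print per-epoch progress.
#' @return A `dta_fit` (also a `dta_model`): the fitted model with a
#'   `history` tibble (`epoch`, `train_mse`, `val_mse`) and `best_epoch`.
#' @export
dta_fit <- function(data, config = dta_config(), seed = 1,
                    epochs = config$epochs, validation = NULL,
                    verbose = FALSE) {
  if ("split" %in% names(data)) {
    if (is.null(validation)) {
      validation <- dplyr::filter(data, .data$split == "validation")
      if (nrow(validation) == 0) validation <- NULL
    }
    data <- dplyr::filter(data, .data$split == "train")
  }
  if (nrow(data) == 0) stop("empty training set", call. = FALSE)
  model <- dta_model(config, seed = seed)
  cache <- build_graph_cache(
    if (is.null(validation)) data else dplyr::bind_rows(
      data[c("smiles", "protein", "affinity")],
      validation[c("smiles", "protein", "affinity")]))
  n <- nrow(data)
  history <- tibble::tibble(epoch = integer(0), train_mse = numeric(0),
                            val_mse = numeric(0))
  if (epochs == 0) {
    model$history <- history
    model$best_epoch <- 0L
    class(model) <- c("dta_fit", class(model))
    return(model)
  }
  # centre the regression target on the training mean so the network learns
  # deviations; the offset is restored at prediction time
  model$y_offset <- mean(data$affinity)
  opt <- adam_state(model$params, lr = config$lr)
  best <- list(val = Inf, params = model$params, state = model$state,
               epoch = 0L)
  set.seed(as.integer(seed))
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    starts <- seq(1L, n, by = config$batch_size)
    sq_sum <- 0
    for (s in starts) {
      idx <- ord[s:min(s + config$batch_size - 1L, n)]
      batch <- prepare_batch(data[idx, ], model, cache)
      fwd <- dta_forward(model, batch, train = TRUE)
      resid <- fwd$pred - (batch$y - model$y_offset)
      loss <- mean(resid^2)
      if (!is.finite(loss)) {
        stop("non-finite loss at epoch ", ep,
             "; reduce the learning rate (", config$lr,
             ") or check the initialization seed", call. = FALSE)
      }
      sq_sum <- sq_sum + sum(resid^2)
      model$state <- fwd$bn_state
      bwd <- dta_backward(model, batch, fwd, 2 * resid / length(resid))
      bwd$grads$emb_d[1, ] <- 0   # padding rows stay frozen
      bwd$grads$emb_p[1, ] <- 0
      step <- adam_step(model$params, bwd$grads, opt)
      model$params <- step$params
      opt <- step$state
    }
    train_mse <- sq_sum / n
    val_mse <- NA_real_
    if (!is.null(validation)) {
      pv <- predict(model, validation, graph_cache = cache)
      val_mse <- mse(pv$.pred, validation$affinity)
      if (val_mse < best$val) {
        best <- list(val = val_mse, params = model$params,
                     state = model$state, epoch = ep)
      }
    }
    history <- dplyr::bind_rows(history, tibble::tibble(
      epoch = ep, train_mse = train_mse, val_mse = val_mse))
    if (verbose) {
      message(sprintf("epoch %3d  train MSE %.4f  val MSE %s", ep, train_mse,
                      ifelse(is.na(val_mse), "-", sprintf("%.4f", val_mse))))
    }
  }
  if (!is.null(validation) && is.finite(best$val)) {
    model$params <- best$params
    model$state <- best$state
    model$best_epoch <- best$epoch
  } else {
    model$best_epoch <- epochs
  }
  model$history <- history
  class(model) <- c("dta_fit", class(model))
  model
}

#' Evaluate a fitted model on labelled records
#'
#' @param model A `dta_model`.
#' @param data Data frame with `smiles`, `protein`, `affinity`.
#' @param graph_cache Optional [build_graph_cache()] result.
#' @return One-row tibble from [dta_metrics()].
#' @export
evaluate_affinity <- function(model, data, graph_cache = NULL) {
  pred <- predict(model, data, graph_cache = graph_cache)
  dta_metrics(truth = data$affinity, estimate = pred$.pred)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.dta_fit <- function(x, ...) {
  x$history
}

#' @exportS3Method generics::glance
glance.dta_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    epochs = nrow(h),
    best_epoch = x$best_epoch,
    train_mse = if (nrow(h) > 0) h$train_mse[nrow(h)] else NA_real_,
    val_mse = if (x$best_epoch > 0 && nrow(h) >= x$best_epoch)
      h$val_mse[x$best_epoch] else NA_real_,
    n_parameters = sum(rapply(x$params, length, how = "unlist"))
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.dta_fit <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr_pivot(h)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$mse,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "MSE", colour = NULL) +
    ggplot2::theme_minimal()
}

# minimal long-format pivot of the history (avoids a tidyr dependency)
tidyr_pivot <- function(h) {
  out <- dplyr::bind_rows(
    tibble::tibble(epoch = h$epoch, mse = h$train_mse, set = "train"),
    tibble::tibble(epoch = h$epoch, mse = h$val_mse, set = "validation"))
  dplyr::filter(out, !is.na(.data$mse))
}
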