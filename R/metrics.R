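# Evaluation metrics for affinity regression: MSE, concordance index,
# rm-squared and Pearson correlation.

.check_pair <- function(predictions, labels) {
  if (length(predictions) != length(labels)) {
    stop("predictions and labels differ in length", call. = FALSE)
  }
  if (length(predictions) == 0) stop("empty input", call. = FALSE)
  if (any(!is.finite(predictions)) || any(!is.finite(labels))) {
    stop("non-finite values in predictions or labels", call. = FALSE)
  }
}

#' Mean squared error
#'
#' @param predictions,labels Equal-length numeric vectors.
#' @return Mean of squared differences.
#' @export
mse <- function(predictions, labels) {
  .check_pair(predictions, labels)
  mean((predictions - labels)^2)
}

#' Concordance index
#'
#' Probability that, over all ordered pairs whose true affinities differ,
#' the predictions rank them the same way; tied predictions are credited
#' 0.5 (step function: 1 if concordant, 0.5 if tied, 0 if discordant),
#' normalized by the number of comparable pairs.
#'
#' @param predictions,labels Equal-length numeric vectors; labels must not
#'   be all identical.
#' @return CI in \[0, 1\]; 0.5 is chance level.
#' @examples
#' concordance_index(c(0.1, 0.2, 0.3), c(1, 2, 3))  # 1
#' @export
concordance_index <- function(predictions, labels) {
  .check_pair(predictions, labels)
  n <- length(labels)
  if (n < 2) stop("need at least two observations", call. = FALSE)
  dl <- outer(labels, labels, `-`)
  comparable <- dl > 0          # ordered pairs (i, j) with label_i > label_j
  z <- sum(comparable)
  if (z == 0) stop("all labels identical: concordance undefined", call. = FALSE)
  dp <- outer(predictions, predictions, `-`)[comparable]
  (sum(dp > 0) + 0.5 * sum(dp == 0)) / z
}

#' rm-squared external-validity index
#'
#' Combines the squared correlation of the least-squares fit with intercept
#' (r2) and of the through-origin fit (r02) as
#' `rm2 = r2 * (1 - sqrt(r2 - r02))`, the standard form of the index (the
#' radicand is clamped at zero against floating-point noise). `variant =
#' "printed"` computes the linear form `r2 * (1 - r2 - r02)` sometimes seen
#' in transcriptions, kept selectable for auditability; it is not the
#' recommended metric (it goes negative for perfect fits).
#'
#' @param predictions,labels Equal-length numeric vectors (n >= 3, both
#'   with nonzero variance).
#' @param variant `"sqrt"` (default) or `"printed"`.
#' @return rm2 value; equals r2 when the through-origin fit explains as
#'   much variance as the intercept fit.
#' @export
rm_squared <- function(predictions, labels, variant = c("sqrt", "printed")) {
  variant <- match.arg(variant)
  .check_pair(predictions, labels)
  if (length(labels) < 3) stop("need at least three observations", call. = FALSE)
  if (stats::sd(predictions) == 0 || stats::sd(labels) == 0) {
    stop("zero variance: rm2 undefined", call. = FALSE)
  }
  r2 <- stats::cor(predictions, labels)^2
  # through-origin regression of labels on predictions
  k <- sum(labels * predictions) / sum(predictions^2)
  ss_res0 <- sum((labels - k * predictions)^2)
  ss_tot <- sum((labels - mean(labels))^2)
  r02 <- 1 - ss_res0 / ss_tot
  if (variant == "sqrt") {
    r2 * (1 - sqrt(max(0, r2 - r02)))
  } else {
    r2 * (1 - r2 - r02)
  }
}

#' Pearson correlation between predictions and labels
#'
#' Sample covariance over the product of sample standard deviations.
#'
#' @param predictions,labels Equal-length numeric vectors with nonzero
#'   variance.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_r <- function(predictions, labels) {
  .check_pair(predictions, labels)
  if (stats::sd(predictions) == 0 || stats::sd(labels) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  stats::cor(predictions, labels)
}

#' Evaluate predictions with all four affinity metrics
#'
#' @param data Optional data frame holding the two columns.
#' @param truth,estimate Column names (tidy-eval) or, when `data` is
#'   omitted, numeric vectors.
#' @return A one-row tibble: `mse`, `ci`, `rm2`, `pearson`, `n`.
#' @examples
#' dta_metrics(truth = c(1, 2, 3), estimate = c(1.1, 1.9, 3.2))
#' @export
dta_metrics <- function(data = NULL, truth, estimate) {
  if (!is.null(data)) {
    truth <- rlang::eval_tidy(rlang::enquo(truth), data)
    estimate <- rlang::eval_tidy(rlang::enquo(estimate), data)
  }
  tibble::tibble(
    mse = mse(estimate, truth),
    ci = concordance_index(estimate, truth),
    rm2 = rm_squared(estimate, truth),
    pearson = pearson_r(estimate, truth),
    n = length(truth)
  )
}
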