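# independent O(n^2) oracle used throughout
ci_oracle <- function(pred, lab) {
  num <- 0; z <- 0
  n <- length(lab)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (lab[i] > lab[j]) {
      z <- z + 1
      if (pred[i] > pred[j]) num <- num + 1
      else if (pred[i] == pred[j]) num <- num + 0.5
    }
  }
  num / z
}

test_that("mse matches the elementwise definition", {
  expect_identical(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_identical(mse(c(0, 2), c(1, 1)), 1)
  set.seed(31)
  p <- rnorm(1000); l <- rnorm(1000)
  loop <- sum(vapply(seq_along(p), function(i) (p[i] - l[i])^2, numeric(1))) / 1000
  expect_lt(abs(mse(p, l) - loop), 1e-9)
  expect_error(mse(1:3, 1:4), "length")
  expect_error(mse(numeric(0), numeric(0)), "empty")
})

test_that("concordance index covers the perfect, inverted and tied cases", {
  expect_identical(concordance_index(c(0.1, 0.2, 0.3), c(1, 2, 3)), 1)
  expect_identical(concordance_index(c(0.3, 0.2, 0.1), c(1, 2, 3)), 0)
  expect_identical(concordance_index(c(1, 1, 1), c(1, 2, 3)), 0.5)
  expect_error(concordance_index(c(1, 2), c(5, 5)), "identical")
})

test_that("concordance index equals the brute-force pairwise oracle", {
  set.seed(32)
  for (i in 1:100) {
    n <- sample(3:200, 1)
    lab <- rnorm(n)
    pred <- if (i %% 3 == 0) sample(round(rnorm(n), 1)) else rnorm(n)
    expect_identical(concordance_index(pred, lab), ci_oracle(pred, lab))
  }
})

test_that("concordance index is invariant to increasing transforms", {
  set.seed(33)
  for (i in 1:20) {
    lab <- rnorm(50)
    pred <- rnorm(50)
    base <- concordance_index(pred, lab)
    expect_equal(concordance_index(exp(pred), lab), base)
    expect_equal(concordance_index(3 * pred + 10, lab), base)
    expect_equal(concordance_index(atan(pred), lab), base)
  }
})

test_that("random predictions score at chance level", {
  set.seed(34)
  lab <- rnorm(200)
  cis <- vapply(1:1000, function(i) concordance_index(sample(lab), lab),
                numeric(1))
  expect_gte(mean(cis), 0.49)
  expect_lte(mean(cis), 0.51)
})

test_that("rm-squared combines the two regression fits", {
  y <- c(1, 2, 3, 4, 5)
  expect_equal(rm_squared(y, y), 1)

  set.seed(35)
  x <- rnorm(10, 5); y <- 1.2 * x + rnorm(10, 0, 0.3)
  # independent two-regression oracle via lm()
  r2 <- summary(lm(y ~ x))$r.squared
  fit0 <- lm(y ~ x + 0)
  r02 <- 1 - sum(residuals(fit0)^2) / sum((y - mean(y))^2)
  oracle <- r2 * (1 - sqrt(max(0, r2 - r02)))
  expect_lt(abs(rm_squared(x, y) - oracle), 1e-9)
  expect_lt(abs(rm_squared(x, y, variant = "printed") -
                  r2 * (1 - r2 - r02)), 1e-9)
  expect_error(rm_squared(rep(1, 5), 1:5), "variance")
  expect_error(rm_squared(1:2, 1:2), "three")
})

test_that("rm-squared never exceeds r-squared", {
  set.seed(36)
  for (i in 1:50) {
    x <- rnorm(20); y <- rnorm(20, 0.5 * x)
    r2 <- cor(x, y)^2
    expect_lte(rm_squared(x, y), r2 + 1e-12)
  }
  # equality when the through-origin fit explains as much
  x <- c(1, 2, 3, 4)
  expect_equal(rm_squared(x, 2 * x), cor(x, 2 * x)^2)
})

test_that("pearson correlation matches the covariance formula", {
  x <- rnorm(20)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  set.seed(37)
  p <- rnorm(500); l <- rnorm(500, 0.3 * p)
  hand <- sum((p - mean(p)) * (l - mean(l))) / (length(p) - 1) /
    (sd(p) * sd(l))
  expect_lt(abs(pearson_r(p, l) - hand), 1e-9)
  expect_error(pearson_r(rep(2, 4), rnorm(4)), "variance")
})

test_that("dta_metrics bundles all four metrics over a data frame", {
  d <- tibble::tibble(truth = c(1, 2, 3, 4), est = c(1.1, 1.9, 3.2, 3.8))
  rep <- dta_metrics(d, truth, est)
  expect_named(rep, c("mse", "ci", "rm2", "pearson", "n"))
  expect_identical(rep$n, 4L)
  expect_gte(rep$ci, 0); expect_lte(rep$ci, 1)
  expect_gte(rep$pearson, -1); expect_lte(rep$pearson, 1)
  expect_gte(rep$mse, 0)
  ident <- dta_metrics(truth = c(1, 2, 3), estimate = c(1, 2, 3))
  expect_identical(ident$mse, 0)
  expect_identical(ident$ci, 1)
  expect_identical(ident$pearson, 1)
})
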