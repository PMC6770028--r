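rand_xy <- function(n, p, seed = 1, coefs = NULL, noise = 0) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  if (is.null(coefs)) coefs <- c(rep(1, min(3, p)), rep(0, p - min(3, p)))
  y <- drop(X %*% coefs) + rnorm(n, 0, noise)
  list(X = X, y = y)
}

test_that("a response linear in one column is fit exactly by one component", {
  set.seed(2)
  x1 <- rnorm(20)
  # nuisance columns orthogonal to the informative one (and hence to y)
  x2 <- stats::resid(stats::lm(rnorm(20) ~ x1))
  x3 <- stats::resid(stats::lm(rnorm(20) ~ x1))
  X <- cbind(x1, x2, x3)
  y <- 2.5 * x1 + 1
  m <- fit_pls(X, y, 1)
  expect_equal(unname(drop(predict(m, X))), y, tolerance = 1e-9)
})

test_that("full-rank PLS equals the least-squares solution", {
  d <- rand_xy(20, 5, seed = 4, coefs = rnorm(5), noise = 0.5)
  m <- fit_pls(d$X, d$y, 5)
  ls <- stats::lm.fit(cbind(1, d$X), d$y)
  expect_equal(unname(drop(predict(m, d$X))), unname(ls$fitted.values),
               tolerance = 1e-6)
})

test_that("NIPALS scores are mutually orthogonal", {
  d <- rand_xy(30, 50, seed = 1, coefs = rnorm(50), noise = 1)
  m <- fit_pls(d$X, d$y, 8)
  G <- crossprod(m$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
})

test_that("LOO Q2 is near 1 for a noiseless planted linear model", {
  d <- rand_xy(40, 10, seed = 6, coefs = rnorm(10), noise = 0)
  cv <- loo_q2(d$X, d$y, 6)
  expect_gt(cv$q2, 0.999)
  expect_lte(max(cv$q2_path), 1)
})

test_that("permuted responses are not cross-validated as predictive", {
  gen <- generate_dataset(synthetic_spec(n_compounds = 30, seed = 7))
  prep <- filter_and_scale(gen$field_matrix)
  y <- gen$dataset$activities$pic50
  set.seed(7)
  q2max <- replicate(20, max(loo_q2(prep$X, sample(y), 5)$q2_path))
  expect_lt(mean(q2max), 0.05)
  expect_lt(max(q2max), 0.2)
})

test_that("LOO predictions equal a naive per-sample refit", {
  d <- rand_xy(15, 40, seed = 11, coefs = rnorm(40, sd = 0.5), noise = 0.3)
  cmax <- 4
  fast <- comfa:::loo_predictions(d$X, d$y, cmax)
  naive <- matrix(NA_real_, 15, cmax)
  for (i in 1:15) {
    for (c in 1:cmax) {
      m <- fit_pls(d$X[-i, ], d$y[-i], c)
      naive[i, c] <- predict(m, d$X[i, , drop = FALSE])
    }
  }
  expect_equal(fast, naive, tolerance = 1e-8)
})

test_that("component selection maximises Q2 with the stated tie-breaks", {
  # single informative direction -> ONC 1
  set.seed(9)
  x1 <- rnorm(40)
  X <- cbind(x1, x1, x1)     # rank-1 descriptor block
  y <- 3 * x1 + 5
  sel <- select_onc(X, y, max_components = 5)
  expect_identical(sel$onc, 1L)
})

test_that("the planted component count is recovered at low noise", {
  # three dominant latent factors drive both X and y
  set.seed(11)
  Tmat <- matrix(rnorm(60 * 3), 60, 3)
  P <- matrix(rnorm(3 * 40), 3, 40)
  X <- Tmat %*% P + matrix(rnorm(60 * 40, sd = 0.05), 60, 40)
  y <- drop(Tmat %*% c(2, -1.5, 1)) + rnorm(60, 0, 0.05)
  sel <- select_onc(X, y, max_components = 8)
  expect_lte(abs(sel$onc - 3), 1)
})

test_that("fit statistics follow the CoMFA conventions", {
  expect_equal(f_statistic(0.5, 12, 1), 10)
  expect_equal(f_statistic(0.9167, 160, 5), 338.9, tolerance = 1e-3)
  # perfect fit: SEE 0, F infinite
  set.seed(12)
  X <- matrix(rnorm(40), 20, 2)
  y <- X[, 1] - 2 * X[, 2]
  m <- fit_pls(X, y, 2)
  st <- regression_stats(m, X, y)
  expect_equal(st$see, 0, tolerance = 1e-9)
  expect_identical(st$f, Inf)
  expect_equal(st$r2, 1, tolerance = 1e-12)
})

test_that("field contributions are |b| sd weighted and sum to 100", {
  set.seed(13)
  X <- matrix(rnorm(200), 20, 10)
  fields <- rep(c("steric", "electrostatic"), each = 5)
  y <- drop(X[, 1:5] %*% rnorm(5))      # only steric columns matter
  m <- fit_pls(X, y, 5, fields = fields)
  contrib <- field_contributions(m, X)
  expect_equal(sum(contrib), 100, tolerance = 1e-9)
  expect_gt(contrib["steric"], 90)
  # hand-check the definition
  w <- abs(m$coefficients) * apply(X, 2, sd)
  expect_equal(unname(contrib["electrostatic"]),
               100 * sum(w[6:10]) / sum(w), tolerance = 1e-12)
})

test_that("prediction handles training data and empty input", {
  d <- rand_xy(25, 6, seed = 14, coefs = rnorm(6), noise = 0.2)
  m <- fit_pls(d$X, d$y, 3)
  # predicting the training matrix reproduces the fitted values
  fitted <- m$y_mean + drop(sweep(d$X, 2, m$x_mean) %*% m$coefficients)
  expect_equal(predict(m, d$X), fitted, tolerance = 1e-12)
  expect_length(predict(m, d$X[integer(0), , drop = FALSE]), 0)
  expect_gt(external_r2(d$y, predict(m, d$X)), 0.9)
})

test_that("duplicating a row changes coefficients only through centering", {
  d <- rand_xy(30, 8, seed = 15, coefs = rnorm(8), noise = 0.1)
  m1 <- fit_pls(d$X, d$y, 3)
  X2 <- rbind(d$X, d$X[7, ]); y2 <- c(d$y, d$y[7])
  m2 <- fit_pls(X2, y2, 3)
  expect_equal(m1$coefficients, m2$coefficients, tolerance = 0.15)
})
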