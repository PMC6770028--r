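# Partial least squares (PLS1, NIPALS) regression of activity on CoMFA
# fields, with leave-one-out cross-validation, optimal-component selection
# and the standard CoMFA fit statistics.

# Core NIPALS PLS1 on already-centered X and y. Returns weights W, loadings
# P, y-loadings q, scores TT and the cumulative coefficient matrix B
# (p x cmax): B[, c] are the regression coefficients of the c-component
# model in centered coordinates.
pls1_nipals <- function(Xc, yc, cmax) {
  n <- nrow(Xc); p <- ncol(Xc)
  cmax <- min(cmax, n - 1L, p)
  W <- matrix(0, p, cmax); P <- matrix(0, p, cmax)
  q <- numeric(cmax); TT <- matrix(0, n, cmax)
  X <- Xc; y <- yc
  used <- 0L
  for (k in seq_len(cmax)) {
    w <- crossprod(X, y)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- X %*% w
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pk <- crossprod(X, t) / tt
    qk <- sum(y * t) / tt
    X <- X - tcrossprod(t, pk)
    y <- y - t * qk
    W[, k] <- w; P[, k] <- pk; q[k] <- qk; TT[, k] <- t
    used <- k
  }
  if (used == 0L) stopf("PLS found no usable component (zero-variance y?)")
  W <- W[, seq_len(used), drop = FALSE]
  P <- P[, seq_len(used), drop = FALSE]
  q <- q[seq_len(used)]
  TT <- TT[, seq_len(used), drop = FALSE]
  B <- matrix(0, p, used)
  PW <- crossprod(P, W)   # upper triangular
  for (c in seq_len(used)) {
    r <- solve(PW[seq_len(c), seq_len(c), drop = FALSE], q[seq_len(c)])
    B[, c] <- W[, seq_len(c), drop = FALSE] %*% r
  }
  list(W = W, P = P, q = q, scores = TT, B = B, n_components = used)
}

#' Fit a PLS1 model
#'
#' NIPALS partial least squares with a single response, on column-centered
#' data (CoMFA block scaling is applied beforehand by [filter_and_scale]).
#'
#' @param X descriptor matrix (compounds x retained field columns).
#' @param y response vector (pIC50).
#' @param n_components number of latent components.
#' @param fields optional per-column field labels, stored for
#'   [field_contributions].
#' @return A `pls_model` with coefficients, means, scores and loadings.
#' @export
fit_pls <- function(X, y, n_components, fields = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  if (stats::var(y) == 0) stopf("zero-variance response")
  if (n_components > min(nrow(X) - 1L, ncol(X))) {
    stopf("n_components = %d exceeds min(rows-1, cols) = %d",
          n_components, min(nrow(X) - 1L, ncol(X)))
  }
  xm <- colMeans(X); ym <- mean(y)
  fit <- pls1_nipals(sweep(X, 2, xm), y - ym, n_components)
  c_use <- min(n_components, fit$n_components)
  structure(list(n_components = c_use,
                 coefficients = fit$B[, c_use],
                 x_mean = xm, y_mean = ym,
                 scores = fit$scores, loadings = fit$P,
                 weights = fit$W, y_loadings = fit$q,
                 fields = fields),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d components, %d descriptors\n",
              x$n_components, length(x$coefficients)))
  invisible(x)
}

#' Predict from a PLS model
#'
#' @param object a `pls_model`.
#' @param newdata matrix with the same columns as the training descriptors.
#' @param ... unused.
#' @return numeric vector of predictions (empty for 0-row input).
#' @export
predict.pls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (nrow(newdata) == 0L) return(numeric(0))
  drop(object$y_mean + sweep(newdata, 2, object$x_mean) %*% object$coefficients)
}

# Leave-one-out predictions for component counts 1..cmax (n x cmax matrix).
# Each left-out sample is predicted by a model refit (including
# re-centering) on the remaining n-1 rows; the column filter/scaling of X is
# fixed beforehand, per the Sybyl-like convention.
loo_predictions <- function(X, y, cmax) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  cmax <- min(cmax, n - 2L, ncol(X))
  out <- matrix(NA_real_, n, cmax)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]
    yi <- y[-i]
    xm <- colMeans(Xi); ym <- mean(yi)
    fit <- pls1_nipals(sweep(Xi, 2, xm), yi - ym, cmax)
    xc <- X[i, ] - xm
    pred <- ym + drop(crossprod(fit$B, xc))
    if (fit$n_components < cmax) {
      pred <- c(pred, rep(pred[fit$n_components], cmax - fit$n_components))
    }
    out[i, ] <- pred
  }
  out
}

#' Leave-one-out cross-validation
#'
#' For each compound, the model is refit on the remaining n-1 compounds and
#' the held-out activity predicted. Q2 = 1 - PRESS/SS_tot and
#' SEP = sqrt(PRESS/(n - c - 1)) (cross-validated standard error of
#' prediction; set `df_correction = FALSE` for the plain n denominator).
#'
#' @inheritParams fit_pls
#' @param n_components component count at which to report the result.
#' @param df_correction use n - c - 1 (default) rather than n degrees of
#'   freedom in SEP.
#' @return A `cv_result`: `q2`, `sep`, `press`, `predictions`, and the full
#'   `q2_path`/`sep_path` over 1..n_components.
#' @export
loo_q2 <- function(X, y, n_components, df_correction = TRUE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (n <= n_components + 1L) {
    stopf("need n > c + 1 for LOO at c = %d (n = %d)", n_components, n)
  }
  preds <- loo_predictions(X, y, n_components)
  cmax <- ncol(preds)
  press <- colSums((y - preds)^2)
  sstot <- sum((y - mean(y))^2)
  q2 <- 1 - press / sstot
  dfree <- if (df_correction) n - seq_len(cmax) - 1 else rep(n, cmax)
  sep <- sqrt(press / dfree)
  c_use <- min(n_components, cmax)
  structure(list(q2 = q2[c_use], sep = sep[c_use], press = press[c_use],
                 n_components = c_use, predictions = preds[, c_use],
                 q2_path = q2, sep_path = sep, all_predictions = preds),
            class = "cv_result")
}

#' Select the optimal number of components (ONC)
#'
#' Maximises the LOO Q2; ties (within 1e-12) are broken by smaller SEP,
#' then by the smaller component count.
#'
#' @inheritParams fit_pls
#' @param max_components largest component count to scan.
#' @return list with `onc`, `q2`, `sep` and the scanned `q2_path`/`sep_path`.
#' @export
select_onc <- function(X, y, max_components = 10) {
  cv <- loo_q2(X, y, min(max_components, nrow(X) - 2L, ncol(X)))
  q2 <- cv$q2_path; sep <- cv$sep_path
  cand <- which(q2 >= max(q2) - 1e-12)
  cand <- cand[order(sep[cand], cand)]
  onc <- cand[1]
  list(onc = onc, q2 = q2[onc], sep = sep[onc],
       q2_path = q2, sep_path = sep)
}

#' Training-fit statistics
#'
#' R2 of the training fit, standard error of estimate
#' SEE = sqrt(RSS/(n - c - 1)), and F = R2 (n - c - 1) / (c (1 - R2)).
#' A perfect fit reports F = Inf.
#'
#' @param model a `pls_model`.
#' @param X,y the training data.
#' @return list with `r2`, `see`, `f`, `n`, `n_components`.
#' @export
regression_stats <- function(model, X, y) {
  pred <- predict(model, X)
  n <- length(y); c <- model$n_components
  rss <- sum((y - pred)^2)
  sstot <- sum((y - mean(y))^2)
  r2 <- 1 - rss / sstot
  see <- sqrt(rss / (n - c - 1))
  f <- if (1 - r2 < 1e-15) Inf else f_statistic(r2, n, c)
  list(r2 = r2, see = see, f = f, n = n, n_components = c)
}

#' @rdname regression_stats
#' @param r2 coefficient of determination.
#' @param n number of training compounds.
#' @param c number of PLS components.
#' @export
f_statistic <- function(r2, n, c) r2 * (n - c - 1) / (c * (1 - r2))

#' Per-field contributions
#'
#' CoMFA field contributions: for each field block f,
#' `sum_{j in f} |b_j| * sd_j`, normalised to percentages summing to 100.
#'
#' @param model a `pls_model` fitted with `fields` labels (or pass `fields`).
#' @param X the descriptor matrix used for fitting.
#' @param fields optional per-column field labels.
#' @return named numeric vector of percentages.
#' @export
field_contributions <- function(model, X, fields = NULL) {
  fields <- fields %||% model$fields
  if (is.null(fields)) stopf("no field labels available")
  sds <- apply(as.matrix(X), 2, stats::sd)
  w <- abs(model$coefficients) * sds
  contrib <- tapply(w, fields, sum)
  100 * contrib / sum(contrib)
}

#' External predictivity
#'
#' Squared Pearson correlation between observed and predicted activities of
#' an external (test) set.
#'
#' @param observed,predicted numeric vectors.
#' @return external R2.
#' @export
external_r2 <- function(observed, predicted) {
  stats::cor(observed, predicted)^2
}
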