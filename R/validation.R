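# Progressive scrambling: perturb activities within sorted bins, track the
# degradation of the cross-validated Q2, and summarise stability as the
# slope dQ2/dR2yy of the fitted quadratic at a critical perturbation level.

#' Scramble activities within sorted bins
#'
#' Sorts y, partitions the sorted values into `n_bins` contiguous bins of
#' near-equal size and permutes values within each bin (fewer bins = stronger
#' perturbation; `n_bins = n` is the identity). Reports R2yy, the squared
#' correlation between original and perturbed activities.
#'
#' @param y numeric activity vector.
#' @param n_bins number of contiguous bins, between 1 and `length(y)`.
#' @param seed optional seed for a standalone reproducible draw; inside
#'   [progressive_scrambling] the surrounding RNG stream is used.
#' @return list with `y_perturbed` (original order) and `r2yy`.
#' @export
scramble_y <- function(y, n_bins, seed = NULL) {
  n <- length(y)
  if (n_bins > n) stopf("n_bins = %d exceeds n = %d", n_bins, n)
  if (n_bins < 1) stopf("n_bins must be >= 1")
  do_draw <- function() {
    ord <- order(y)
    bins <- if (n_bins == 1L) rep(1L, n) else
      cut(seq_len(n), breaks = n_bins, labels = FALSE)
    yp <- y
    for (bin in split(ord, bins)) {
      if (length(bin) > 1L) yp[bin] <- y[bin[sample.int(length(bin))]]
    }
    yp
  }
  yp <- if (is.null(seed)) do_draw() else with_seed(seed, do_draw())
  r2yy <- if (stats::var(yp) == 0) 1 else stats::cor(y, yp)^2
  list(y_perturbed = yp, r2yy = r2yy)
}

#' Progressive scrambling stability analysis
#'
#' For each bin count in `bins_range` and each repetition, activities are
#' scrambled within sorted bins and the LOO Q2 of the perturbed model is
#' computed for every component count in `component_range` (the unperturbed
#' model, R2yy = 1, is always included). Per component count, quadratics
#' `Q2 ~ R2yy + R2yy^2` and `cSDEP ~ R2yy + R2yy^2` are fitted over the
#' perturbation points; the scrambling-adjusted `Q2s` and `cSDEP` are the
#' quadratics evaluated at `critical_point`, and the stability slope
#' `dQ2/dR2yy` is the derivative of the Q2 quadratic there. Slopes at or
#' below 1.2 (ideally near 1) indicate a stable, non-redundant model.
#'
#' @param X descriptor matrix (filtered/scaled training fields).
#' @param y activity vector.
#' @param component_range component counts to report (Table-1-style rows).
#' @param bins_range bin counts defining the perturbation ladder.
#' @param reps_per_bin scrambling repetitions per bin count.
#' @param critical_point R2yy at which Q2s, cSDEP and the slope are read off.
#' @param seed RNG seed; results are bit-reproducible given it.
#' @return A `scrambling_result`: `table` (components, q2s, csdep,
#'   dq2_dr2yy, q2_unperturbed) and `detail` (one row per perturbation and
#'   component count).
#' @export
progressive_scrambling <- function(X, y, component_range = 2:7,
                                   bins_range = 2:10, reps_per_bin = 10,
                                   critical_point = 0.85, seed = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  cmax <- max(component_range)
  stopifnot(min(component_range) >= 1, cmax <= n - 2L)
  detail <- list()
  add_point <- function(r2yy, q2_path, sep_path, label) {
    detail[[length(detail) + 1L]] <<- data.frame(
      perturbation = label, r2yy = r2yy,
      components = component_range,
      q2 = q2_path[component_range], csdep = sep_path[component_range])
  }
  base_cv <- loo_q2(X, y, cmax)
  add_point(1.0, base_cv$q2_path, base_cv$sep_path, "unperturbed")
  with_seed(seed, {
    for (nb in bins_range) {
      for (rep in seq_len(reps_per_bin)) {
        sc <- scramble_y(y, nb)
        cv <- loo_q2(X, sc$y_perturbed, cmax)
        add_point(sc$r2yy, cv$q2_path, cv$sep_path,
                  sprintf("bins%02d_rep%02d", nb, rep))
      }
    }
  })
  detail <- do.call(rbind, detail)
  tab <- do.call(rbind, lapply(component_range, function(c) {
    d <- detail[detail$components == c, ]
    if (length(unique(round(d$r2yy, 10))) < 3) {
      stopf("fewer than 3 distinct R2yy levels: quadratic fit is degenerate")
    }
    qf <- stats::lm(q2 ~ r2yy + I(r2yy^2), data = d)
    sf <- stats::lm(csdep ~ r2yy + I(r2yy^2), data = d)
    cb <- stats::coef(qf)
    data.frame(
      components = c,
      q2s = unname(stats::predict(qf, data.frame(r2yy = critical_point))),
      csdep = unname(stats::predict(sf, data.frame(r2yy = critical_point))),
      dq2_dr2yy = unname(cb[2] + 2 * cb[3] * critical_point),
      q2_unperturbed = d$q2[d$perturbation == "unperturbed"])
  }))
  structure(list(table = tab, detail = detail,
                 critical_point = critical_point, seed = seed),
            class = "scrambling_result")
}

#' @export
print.scrambling_result <- function(x, ...) {
  cat(sprintf("<scrambling_result> critical point %.2f\n", x$critical_point))
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write the scrambling table as CSV
#'
#' Columns `components`, `Q2`, `cSDEP`, `dQ2_dR2yy` (plus the unperturbed
#' Q2), one row per component count.
#'
#' @param x a `scrambling_result`.
#' @param path output CSV path.
#' @export
write_scrambling_csv <- function(x, path) {
  out <- data.frame(components = x$table$components,
                    Q2 = x$table$q2s,
                    cSDEP = x$table$csdep,
                    dQ2_dR2yy = x$table$dq2_dr2yy,
                    Q2_unperturbed = x$table$q2_unperturbed)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
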