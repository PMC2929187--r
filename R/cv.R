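## Monte-Carlo cross-validation over a hyperparameter grid, and the
## normalized coefficient ranking used to report motif candidates.

#' Default regularization grid
#'
#' 25 log-spaced penalty weights spanning near-unpenalized to
#' full-shrinkage fits.
#'
#' @param from,to Grid endpoints.
#' @param length.out Number of grid points.
#' @return Ascending numeric vector.
#' @export
lambda_grid <- function(from = 1e-4, to = 1e2, length.out = 25) {
  10^seq(log10(from), log10(to), length.out = length.out)
}

#' Cross-validated peak-score regression
#'
#' The experimental protocol around [peak_regression()]: `n_iter` repeated
#' random train/test splits (Monte-Carlo cross-validation). In each
#' iteration the model is fitted on the training set for every value of the
#' hyperparameter grid and scored by Pearson correlation between predicted
#' and observed log scores on the held-out test set.
#'
#' Two aggregations are reported: (a) the per-grid-value mean test
#' correlation, whose argmax is the selected hyperparameter, and (b) the
#' best-per-iteration correlations averaged over iterations (the optimistic
#' "keep the best grid value of each iteration" summary). The returned
#' coefficients are the average over iterations of the training fits at the
#' selected hyperparameter, so the ranking reflects all splits rather than
#' a single one.
#'
#' @param x Feature matrix or `"feature_matrix"` object.
#' @param y Response (log peak scores); defaults to the feature matrix's.
#' @param method Regression method (see [peak_regression()]).
#' @param grid Hyperparameter grid: penalty weights for `"l1"`/`"ridge"`
#'   (default [lambda_grid()]), component counts for `"pls"`/`"pcr"`
#'   (default `1:10`, capped by the data), ignored for `"ols"`.
#' @param n_iter Number of random splits (default 30).
#' @param test_fraction Fraction of peaks held out per split (default 1/3).
#' @param seed Random seed for the splits (default 17).
#' @return Object of class `c("peak_cv", "peak_fit")` with the averaged
#'   coefficients/intercept at the selected hyperparameter, the per-split
#'   correlation matrix `cor` (`n_iter` x grid), `mean_cor_by_grid`,
#'   `best_hyperparameter`, `cv_correlations` (per-split correlations at
#'   the selected value), `mean_correlation`, and
#'   `mean_best_per_iteration` (aggregation b).
#' @export
cv_peak_regression <- function(x, y = NULL,
                               method = c("l1", "ols", "ridge", "pls", "pcr"),
                               grid = NULL, n_iter = 30, test_fraction = 1/3,
                               seed = 17) {
  method <- match.arg(method)
  d <- .as_xy(x, y)
  x <- d$x; y <- d$y
  n <- nrow(x)
  p <- ncol(x)
  if (n_iter < 1) stop("n_iter must be >= 1", call. = FALSE)
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)", call. = FALSE)
  n_test <- max(1L, round(n * test_fraction))
  if (n - n_test < 2) stop("training split too small", call. = FALSE)
  if (is.null(grid)) {
    grid <- switch(method,
      l1 = lambda_grid(), ridge = lambda_grid(),
      pls = seq_len(min(10, p, n - n_test - 1)),
      pcr = seq_len(min(10, p, n - n_test - 1)),
      ols = NA_real_)
  }
  if (method == "ols") grid <- NA_real_
  k <- length(grid)
  cors <- matrix(NA_real_, n_iter, k)
  coefs <- array(0, dim = c(p, k, n_iter))
  ints <- matrix(0, n_iter, k)
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    for (try in 1:100) {
      test <- sample.int(n, n_test)
      if (sd(y[test]) > 0 && sd(y[-test]) > 0) break
      message("cv_peak_regression: resampling a zero-variance split ",
              "(iteration ", it, ")")
    }
    xtr <- x[-test, , drop = FALSE]; ytr <- y[-test]
    xte <- x[test, , drop = FALSE]; yte <- y[test]
    g <- switch(method,
      l1 = .fit_l1_grid(xtr, ytr, grid),
      ridge = .fit_ridge_grid(xtr, ytr, grid),
      pls = .fit_pls_grid(xtr, ytr, max(grid)),
      pcr = .fit_pcr_grid(xtr, ytr, max(grid)),
      ols = { f <- .fit_ols(xtr, ytr)
              list(coef = matrix(f$coef, p, 1), intercept = f$intercept) })
    if (method %in% c("pls", "pcr")) {
      g <- list(coef = g$coef[, grid, drop = FALSE],
                intercept = g$intercept[grid])
    }
    for (j in seq_len(k)) {
      pred <- drop(xte %*% g$coef[, j]) + g$intercept[j]
      cors[it, j] <- if (sd(pred) == 0) 0 else cor(pred, yte)
      coefs[, j, it] <- g$coef[, j]
      ints[it, j] <- g$intercept[j]
    }
  }
  mean_by_grid <- colMeans(cors)
  best_j <- which.max(mean_by_grid)
  cf <- apply(coefs[, best_j, , drop = FALSE], 1, mean)
  names(cf) <- colnames(x)
  intercept <- mean(ints[, best_j])
  fitted <- drop(x %*% cf) + intercept
  structure(list(coefficients = cf, intercept = intercept,
                 method = method, hyperparameter = grid[best_j],
                 grid = grid, cor = cors,
                 mean_cor_by_grid = mean_by_grid,
                 best_hyperparameter = grid[best_j],
                 best_mean_correlation = mean_by_grid[best_j],
                 cv_correlations = cors[, best_j],
                 mean_correlation = mean(cors[, best_j]),
                 best_per_iteration = apply(cors, 1, max),
                 mean_best_per_iteration = mean(apply(cors, 1, max)),
                 n_iter = n_iter, test_fraction = test_fraction,
                 seed = seed, fitted.values = fitted,
                 residuals = y - fitted, y = y, n = n,
                 call = match.call()),
            class = c("peak_cv", "peak_fit"))
}

#' @export
print.peak_cv <- function(x, ...) {
  cat("Cross-validated peak-score regression (method: ", x$method, ")\n",
      sep = "")
  cat("  ", x$n_iter, " random splits, test fraction ",
      format(x$test_fraction, digits = 3), ", seed ", x$seed, "\n", sep = "")
  if (!all(is.na(x$grid)))
    cat("  selected hyperparameter:", format(x$best_hyperparameter),
        "(grid of", length(x$grid), "values)\n")
  cat("  mean held-out correlation at selection:",
      format(x$mean_correlation, digits = 3), "\n")
  cat("  mean best-per-iteration correlation:",
      format(x$mean_best_per_iteration, digits = 3), "\n")
  cat("  nonzero coefficients:", sum(x$coefficients != 0), "of",
      length(x$coefficients), "\n")
  invisible(x)
}

#' @export
plot.peak_cv <- function(x, ...) {
  if (all(is.na(x$grid))) return(invisible(x))
  plot(x$grid, x$mean_cor_by_grid, log = if (x$method %in% c("l1", "ridge"))
    "x" else "", type = "b", xlab = "hyperparameter",
    ylab = "mean held-out correlation",
    main = paste0("Cross-validation (", x$method, ")"), ...)
  abline(v = x$best_hyperparameter, lty = 2)
  invisible(x)
}

#' Normalize and rank regression coefficients
#'
#' Divides every coefficient by the maximum absolute coefficient (so the
#' top motif has normalized magnitude 1) and sorts by descending absolute
#' value. Positive coefficients are labelled `"strengthening"` (the motif
#' increases the predicted binding signal), negative ones `"weakening"`.
#'
#' @param fit A `"peak_fit"`/`"peak_cv"` object, or a named numeric vector
#'   of coefficients.
#' @return Data frame of class `"motif_ranking"` with columns `motif_id`,
#'   `coefficient`, `normalized_coefficient`, `sign_label`. All-zero
#'   coefficients yield an empty ranking with a warning.
#' @export
normalize_and_rank <- function(fit) {
  cf <- if (is.numeric(fit)) fit else coef(fit)
  if (is.null(names(cf)))
    names(cf) <- sprintf("V%d", seq_along(cf))
  if (!length(cf) || all(cf == 0)) {
    warning("all coefficients are zero; empty ranking")
    out <- data.frame(motif_id = character(0), coefficient = numeric(0),
                      normalized_coefficient = numeric(0),
                      sign_label = character(0), stringsAsFactors = FALSE)
    class(out) <- c("motif_ranking", "data.frame")
    return(out)
  }
  norm <- cf / max(abs(cf))
  ord <- order(-abs(norm), names(cf))
  out <- data.frame(motif_id = names(cf)[ord], coefficient = unname(cf[ord]),
                    normalized_coefficient = unname(norm[ord]),
                    sign_label = ifelse(norm[ord] > 0, "strengthening",
                                        ifelse(norm[ord] < 0, "weakening",
                                               "none")),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("motif_ranking", "data.frame")
  out
}

#' @export
print.motif_ranking <- function(x, n = 10, ...) {
  cat("Motif ranking (", nrow(x), " motifs; top ", min(n, nrow(x)),
      " shown)\n", sep = "")
  print.data.frame(utils::head(x, n), row.names = FALSE, digits = 3)
  invisible(x)
}
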