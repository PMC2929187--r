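## Regression of log peak scores on motif features.
##
## Five methods behind one fitting function: L1-regularized ("l1", the
## default and the method of choice — sparse, interpretable coefficient
## vectors), ordinary least squares ("ols", minimum-norm on rank
## deficiency), ridge ("ridge"), partial least squares ("pls") and
## principal component regression ("pcr"); the latter two regress on m
## latent components and back-project the coefficients into motif space so
## rankings are comparable across methods.
##
## Objectives are on the raw residual-sum-of-squares scale:
##   l1:    sum((y - Xw - b)^2) + lambda * sum(|w|)
##   ridge: sum((y - Xw - b)^2) + lambda * sum(w^2)
## (glmnet's gaussian lasso objective is RSS/(2n) + lambda_g * ||w||_1, so
## the l1 solver is called with lambda_g = lambda / (2n) and
## standardize = FALSE; features are used exactly as the vectorization
## step produced them, with no column standardization.)

.as_xy <- function(x, y) {
  if (inherits(x, "feature_matrix")) {
    if (missing(y) || is.null(y)) y <- x$y
    x <- x$V
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  if (is.null(y)) stop("no response supplied", call. = FALSE)
  y <- as.numeric(y)
  if (length(y) != nrow(x))
    stop("length(y) must equal nrow(x)", call. = FALSE)
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y)))
    stop("NA or non-finite values in the design matrix or response",
         call. = FALSE)
  if (nrow(x) < 2) stop("need at least 2 observations", call. = FALSE)
  list(x = x, y = y)
}

# Lasso path over a vector of user-scale lambdas (descending fit order,
# returned in the order requested). Returns coefficient matrix p x k and
# intercept vector length k.
.fit_l1_grid <- function(x, y, lambda) {
  # glmnet requires >= 2 columns; pad a single-motif design with an
  # all-zero dummy column (its coefficient is always 0) and drop it after.
  if (ncol(x) == 1) {
    g <- .fit_l1_grid(cbind(x, `..dummy` = 0), y, lambda)
    return(list(coef = g$coef[1, , drop = FALSE], intercept = g$intercept))
  }
  n <- nrow(x)
  lam_g <- lambda / (2 * n)
  ord <- order(lam_g, decreasing = TRUE)
  lam_fit <- lam_g[ord]
  # glmnet is unreliable when handed a single lambda; pad the path from
  # above so coordinate descent warm-starts sensibly.
  pad <- if (length(lam_fit) < 3)
    max(lam_fit[1], 1e-3) * c(100, 10) else numeric(0)
  fit <- glmnet::glmnet(x, y, family = "gaussian", alpha = 1,
                        lambda = c(pad, lam_fit), standardize = FALSE,
                        thresh = 1e-12, maxit = 1e7)
  b <- as.matrix(coef(fit))[, length(pad) + seq_along(lam_fit), drop = FALSE]
  keep <- order(ord)  # undo the sort
  list(coef = b[-1, keep, drop = FALSE], intercept = b[1, keep])
}

# Ridge over a vector of lambdas via SVD of the centered design:
# w(lambda) = V diag(d / (d^2 + lambda)) U' yc  (exact minimizer of
# RSS + lambda ||w||^2 after profiling out the intercept).
.fit_ridge_grid <- function(x, y, lambda) {
  xm <- colMeans(x)
  xc <- sweep(x, 2, xm)
  ym <- mean(y)
  sv <- svd(xc)
  uty <- crossprod(sv$u, y - ym)
  cf <- vapply(lambda, function(l)
    drop(sv$v %*% (uty * sv$d / (sv$d^2 + l))), numeric(ncol(x)))
  cf <- matrix(cf, nrow = ncol(x))
  rownames(cf) <- colnames(x)
  list(coef = cf, intercept = ym - drop(crossprod(cf, xm)))
}

# Minimum-norm least squares via SVD pseudoinverse.
.fit_ols <- function(x, y) {
  xm <- colMeans(x)
  xc <- sweep(x, 2, xm)
  ym <- mean(y)
  sv <- svd(xc)
  tol <- max(dim(xc)) * max(sv$d, 0) * .Machine$double.eps
  pos <- sv$d > tol
  w <- drop(sv$v[, pos, drop = FALSE] %*%
              (crossprod(sv$u[, pos, drop = FALSE], y - ym) / sv$d[pos]))
  names(w) <- colnames(x)
  list(coef = w, intercept = ym - sum(w * xm))
}

# PLS1 (NIPALS). Returns back-projected coefficients for every number of
# components 1..m (components are nested).
.fit_pls_grid <- function(x, y, m) {
  xm <- colMeans(x)
  ym <- mean(y)
  Xk <- sweep(x, 2, xm)
  yk <- y - ym
  p <- ncol(x)
  W <- P <- matrix(0, p, m)
  q <- numeric(m)
  m_eff <- 0L
  for (k in seq_len(m)) {
    w <- drop(crossprod(Xk, yk))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    tk <- drop(Xk %*% w)
    tt <- sum(tk^2)
    if (tt < 1e-12) break
    pk <- drop(crossprod(Xk, tk)) / tt
    qk <- sum(yk * tk) / tt
    Xk <- Xk - tcrossprod(tk, pk)
    yk <- yk - qk * tk
    W[, k] <- w; P[, k] <- pk; q[k] <- qk
    m_eff <- k
  }
  cf <- matrix(0, p, m, dimnames = list(colnames(x), NULL))
  for (k in seq_len(m)) {
    kk <- min(k, m_eff)
    if (kk == 0) next
    Wk <- W[, 1:kk, drop = FALSE]
    cf[, k] <- drop(Wk %*% solve(crossprod(P[, 1:kk, drop = FALSE], Wk),
                                 q[1:kk]))
  }
  list(coef = cf, intercept = ym - drop(crossprod(cf, xm)), m_eff = m_eff)
}

# Principal component regression for every number of components 1..m.
.fit_pcr_grid <- function(x, y, m) {
  xm <- colMeans(x)
  ym <- mean(y)
  sv <- svd(sweep(x, 2, xm))
  tol <- max(dim(x)) * max(sv$d, 0) * .Machine$double.eps
  m_max <- sum(sv$d > tol)
  uty <- crossprod(sv$u, y - ym)
  cf <- matrix(0, ncol(x), m, dimnames = list(colnames(x), NULL))
  for (k in seq_len(m)) {
    kk <- min(k, m_max)
    cf[, k] <- drop(sv$v[, 1:kk, drop = FALSE] %*%
                      (uty[1:kk] / sv$d[1:kk]))
  }
  list(coef = cf, intercept = ym - drop(crossprod(cf, xm)))
}

#' Fit a peak-score regression model
#'
#' Regresses the log peak enrichment scores on the motif feature matrix
#' with one of five methods. `"l1"` minimizes
#' `sum((y - Xw - b)^2) + lambda * ||w||_1` (sparse solutions: redundant or
#' uninformative motifs are removed); `"ridge"` replaces the penalty with
#' `lambda * ||w||_2^2`; `"ols"` is unpenalized least squares
#' (minimum-norm when rank-deficient, with a warning when there are at
#' least as many motifs as peaks); `"pls"` and `"pcr"` regress on `ncomp`
#' latent components and back-project the coefficients into motif space.
#'
#' @param x Feature matrix (peaks x motifs) or a `"feature_matrix"` from
#'   [vectorize_peaks()] (in which case `y` defaults to its log-score
#'   response).
#' @param y Numeric response (log peak scores).
#' @param method One of `"l1"`, `"ols"`, `"ridge"`, `"pls"`, `"pcr"`.
#' @param lambda Penalty weight for `"l1"` / `"ridge"` (raw RSS scale).
#' @param ncomp Number of latent components for `"pls"` / `"pcr"`.
#' @return Object of class `"peak_fit"`: named `coefficients`,
#'   `intercept`, `method`, the hyperparameter, `fitted.values` and
#'   `residuals`.
#' @seealso [cv_peak_regression()] for the cross-validated protocol,
#'   [normalize_and_rank()] for the coefficient ranking.
#' @examples
#' set.seed(1)
#' x <- matrix(runif(200), 50, 4, dimnames = list(NULL, paste0("M", 1:4)))
#' y <- 2 * x[, 1] - x[, 3] + rnorm(50, sd = 0.01)
#' fit <- peak_regression(x, y, method = "l1", lambda = 0.01)
#' coef(fit)
#' @export
peak_regression <- function(x, y = NULL,
                            method = c("l1", "ols", "ridge", "pls", "pcr"),
                            lambda = 0, ncomp = NULL) {
  method <- match.arg(method)
  d <- .as_xy(x, y)
  x <- d$x; y <- d$y
  hyper <- NULL
  if (method %in% c("l1", "ridge")) {
    if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
    hyper <- lambda
  }
  if (method %in% c("pls", "pcr")) {
    if (is.null(ncomp)) ncomp <- min(10, ncol(x), nrow(x) - 1)
    if (ncomp < 1 || ncomp > min(nrow(x) - 1, ncol(x)))
      stop("ncomp must be in [1, min(n_peaks - 1, n_motifs)]", call. = FALSE)
    hyper <- ncomp
  }
  res <- switch(method,
    l1 = {
      g <- .fit_l1_grid(x, y, lambda)
      list(coef = g$coef[, 1], intercept = g$intercept[1])
    },
    ridge = {
      g <- .fit_ridge_grid(x, y, lambda)
      list(coef = g$coef[, 1], intercept = g$intercept[1])
    },
    ols = {
      if (ncol(x) >= nrow(x))
        warning("OLS with n_motifs >= n_peaks is prone to overfitting; ",
                "returning the minimum-norm solution")
      .fit_ols(x, y)
    },
    pls = {
      g <- .fit_pls_grid(x, y, ncomp)
      list(coef = g$coef[, ncomp], intercept = g$intercept[ncomp])
    },
    pcr = {
      g <- .fit_pcr_grid(x, y, ncomp)
      list(coef = g$coef[, ncomp], intercept = g$intercept[ncomp])
    })
  cf <- drop(res$coef)
  names(cf) <- colnames(x)
  fitted <- drop(x %*% cf) + res$intercept
  structure(list(coefficients = cf, intercept = res$intercept,
                 method = method, hyperparameter = hyper,
                 fitted.values = fitted, residuals = y - fitted,
                 y = y, n = nrow(x), call = match.call()),
            class = "peak_fit")
}

#' @export
print.peak_fit <- function(x, ...) {
  cat("Peak-score regression (method: ", x$method, ")\n", sep = "")
  if (!is.null(x$hyperparameter))
    cat("  hyperparameter:", format(x$hyperparameter), "\n")
  nz <- sum(x$coefficients != 0)
  cat("  ", length(x$coefficients), " motifs, ", nz, " with nonzero ",
      "coefficients, ", x$n, " peaks\n", sep = "")
  invisible(x)
}

#' @export
coef.peak_fit <- function(object, ...) object$coefficients

#' @export
predict.peak_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  if (inherits(newdata, "feature_matrix")) newdata <- newdata$V
  newdata <- as.matrix(newdata)
  cf <- object$coefficients
  if (!is.null(colnames(newdata)) && !is.null(names(cf)) &&
      all(names(cf) %in% colnames(newdata)))
    newdata <- newdata[, names(cf), drop = FALSE]
  drop(newdata %*% cf) + object$intercept
}

#' @export
residuals.peak_fit <- function(object, ...) object$residuals

#' @export
fitted.peak_fit <- function(object, ...) object$fitted.values

#' @export
summary.peak_fit <- function(object, ...) {
  rk <- suppressWarnings(normalize_and_rank(object))
  structure(list(fit = object, ranking = rk,
                 train_cor = evaluate_fit(object, NULL, object$y)),
            class = "summary.peak_fit")
}

#' @export
print.summary.peak_fit <- function(x, ...) {
  print(x$fit)
  cat("  training-set Pearson correlation:",
      format(x$train_cor, digits = 3), "\n")
  cat("Top motifs by |normalized coefficient|:\n")
  print(utils::head(x$ranking, 10), row.names = FALSE)
  invisible(x)
}

#' @export
plot.peak_fit <- function(x, ...) {
  plot(x$fitted.values, x$y, xlab = "predicted log peak score",
       ylab = "observed log peak score",
       main = paste0("Peak-score regression (", x$method, ")"), ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' Pearson correlation between model predictions and observed scores
#'
#' The prediction-quality summary used throughout: the Pearson correlation
#' between predicted and observed (log) peak scores on a given set. If the
#' predictions are constant (e.g. a fully shrunk L1 fit) the correlation is
#' undefined and is reported as 0 with a warning.
#'
#' @param fit A `"peak_fit"` (or anything with `coefficients` and
#'   `intercept`).
#' @param x Feature matrix of the evaluation set, or `NULL` to use the
#'   fit's own fitted values.
#' @param y Observed responses of the evaluation set.
#' @return A single correlation in `[-1, 1]`.
#' @export
evaluate_fit <- function(fit, x, y) {
  pred <- if (is.null(x)) fit$fitted.values else predict(fit, x)
  if (length(pred) != length(y))
    stop("prediction/response length mismatch", call. = FALSE)
  if (sd(pred) == 0 || sd(y) == 0) {
    warning("constant predictions or responses; correlation reported as 0")
    return(0)
  }
  cor(pred, y)
}
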