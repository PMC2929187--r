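make_design <- function(n = 30, p = 5, seed = 31) {
  set.seed(seed)
  x <- matrix(runif(n * p), n, p,
              dimnames = list(NULL, sprintf("M%02d", seq_len(p))))
  x
}

test_that("the l1 objective is solved exactly (closed form and CD oracle)", {
  # single informative feature, closed-form soft threshold
  set.seed(32)
  x <- matrix(rnorm(50), 50, 1, dimnames = list(NULL, "m1"))
  y <- 2 * x[, 1]
  f <- peak_regression(x, y, "l1", lambda = 1e-8)
  expect_equal(unname(coef(f)), 2, tolerance = 1e-6)
  expect_equal(evaluate_fit(f, x, y), 1, tolerance = 1e-9)

  xc <- x[, 1] - mean(x); yn <- y + rnorm(50, sd = 0.2); yc <- yn - mean(yn)
  for (lam in c(0.5, 3, 10)) {
    f <- peak_regression(x, yn, "l1", lambda = lam)
    w_oracle <- sign(sum(xc * yc)) *
      max(0, abs(sum(xc * yc)) - lam / 2) / sum(xc^2)
    expect_equal(unname(coef(f)), w_oracle, tolerance = 1e-8)
  }

  # full shrinkage: all coefficients zero, prediction = mean(y)
  x5 <- make_design()
  y5 <- drop(x5 %*% c(2, -1, 0, 0, 1)) + rnorm(30, sd = 0.1)
  f0 <- peak_regression(x5, y5, "l1", lambda = 1e6)
  expect_true(all(coef(f0) == 0))
  expect_equal(unname(fitted(f0)), rep(mean(y5), 30), tolerance = 1e-10)

  # multi-feature agreement with an independent coordinate-descent solver
  for (lam in c(0.2, 2, 8)) {
    f <- peak_regression(x5, y5, "l1", lambda = lam)
    orc <- oracle_cd_lasso(x5, y5, lam)
    expect_equal(unname(coef(f)), orc$coef, tolerance = 1e-6)
    expect_equal(f$intercept, orc$intercept, tolerance = 1e-6)
  }

  expect_error(peak_regression(cbind(x5, NA), y5, "l1"), "NA")
})

test_that("ridge matches its closed form and shrinks monotonically", {
  x <- make_design(n = 20, p = 5, seed = 33)
  y <- drop(x %*% c(1, 2, 0, -1, 0.5)) + rnorm(20, sd = 0.1)
  # lambda = 0 equals OLS on full-rank data
  expect_equal(coef(peak_regression(x, y, "ridge", lambda = 0)),
               coef(peak_regression(x, y, "ols")), tolerance = 1e-8)
  # explicit normal-equations oracle
  lam <- 2.5
  xc <- scale(x, scale = FALSE); yc <- y - mean(y)
  w_or <- solve(crossprod(xc) + lam * diag(5), crossprod(xc, yc))
  expect_equal(unname(coef(peak_regression(x, y, "ridge", lambda = lam))),
               unname(drop(w_or)), tolerance = 1e-8)
  # coefficient norm shrinks monotonically in lambda
  norms <- vapply(c(0, 0.1, 1, 10, 100), function(l)
    sqrt(sum(coef(peak_regression(x, y, "ridge", lambda = l))^2)),
    numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("OLS returns the stable minimum-norm split on duplicate columns", {
  set.seed(34)
  z <- runif(25)
  x <- cbind(a = z, b = z, c = runif(25))
  y <- 3 * z + rnorm(25, sd = 0.05)
  f <- expect_warning(peak_regression(x[1:2, ], y[1:2], "ols"),
                      "overfitting")
  f <- peak_regression(x, y, "ols")
  # duplicated columns share the weight equally instead of exploding
  # with opposite signs
  expect_equal(unname(coef(f)["a"]), unname(coef(f)["b"]), tolerance = 1e-8)
  expect_equal(unname(coef(f)["a"] + coef(f)["b"]), 3, tolerance = 0.2)
})

test_that("PLS and PCR reduce to OLS at full rank and back-project sensibly", {
  x <- make_design(n = 30, p = 6, seed = 35)
  y <- drop(x %*% c(2, 0, -1, 0, 0.5, 0)) + rnorm(30, sd = 0.05)
  ols <- coef(peak_regression(x, y, "ols"))
  expect_equal(coef(peak_regression(x, y, "pls", ncomp = 6)), ols,
               tolerance = 1e-6)
  expect_equal(coef(peak_regression(x, y, "pcr", ncomp = 6)), ols,
               tolerance = 1e-6)

  # PCR coefficients equal regression on the leading SVD directions
  m <- 3
  xc <- scale(x, scale = FALSE); yc <- y - mean(y)
  sv <- svd(xc)
  w_or <- sv$v[, 1:m] %*% (crossprod(sv$u[, 1:m], yc) / sv$d[1:m])
  expect_equal(unname(coef(peak_regression(x, y, "pcr", ncomp = m))),
               drop(w_or), tolerance = 1e-8)

  # m = 1 with one dominant feature puts that feature on top
  set.seed(36)
  x1 <- matrix(rnorm(40 * 4, sd = 0.05), 40, 4,
               dimnames = list(NULL, paste0("M", 1:4)))
  x1[, 2] <- rnorm(40)
  y1 <- 3 * x1[, 2] + rnorm(40, sd = 0.05)
  for (meth in c("pls", "pcr")) {
    rk <- normalize_and_rank(peak_regression(x1, y1, meth, ncomp = 1))
    expect_equal(rk$motif_id[1], "M2")
  }
  expect_error(peak_regression(x, y, "pls", ncomp = 40), "ncomp")
})

test_that("Monte-Carlo cross-validation is deterministic and well-aggregated", {
  set.seed(37)
  x <- make_design(n = 60, p = 8, seed = 37)
  w <- c(3, -2, 0, 0, 0, 1, 0, 0)
  y <- drop(x %*% w)   # noiseless
  cv1 <- cv_peak_regression(x, y, "l1", n_iter = 8, seed = 5)
  cv2 <- cv_peak_regression(x, y, "l1", n_iter = 8, seed = 5)
  expect_identical(cv1$cor, cv2$cor)
  expect_identical(coef(cv1), coef(cv2))

  # noiseless data: best-per-iteration average reaches 1
  expect_equal(cv1$mean_best_per_iteration, 1, tolerance = 1e-6)
  # aggregation (b) >= aggregation (a) by construction, on any data
  yn <- y + rnorm(60, sd = 1)
  cvn <- cv_peak_regression(x, yn, "l1", n_iter = 6, seed = 6)
  expect_gte(cvn$mean_best_per_iteration, cvn$best_mean_correlation - 1e-12)
  # invariant: reported mean is the mean of the per-split correlations
  expect_equal(cvn$mean_correlation, mean(cvn$cv_correlations),
               tolerance = 1e-12)
  expect_true(all(abs(cvn$cv_correlations) <= 1))
})

test_that("coefficient normalization and ranking follow the contract", {
  cf <- c(mA = 0.5, mB = -1.25, mC = 0.25)
  rk <- normalize_and_rank(cf)
  expect_equal(rk$motif_id, c("mB", "mA", "mC"))
  expect_equal(rk$normalized_coefficient, c(-1, 0.4, 0.2))
  expect_equal(rk$sign_label, c("weakening", "strengthening",
                                "strengthening"))
  expect_equal(max(abs(rk$normalized_coefficient)), 1)
  expect_equal(sign(rk$coefficient), sign(rk$normalized_coefficient))
  expect_warning(rk0 <- normalize_and_rank(c(a = 0, b = 0)), "zero")
  expect_equal(nrow(rk0), 0)
})

test_that("prediction quality is the Pearson correlation, 0 when degenerate", {
  set.seed(38)
  x <- make_design(n = 10, p = 2, seed = 38)
  y <- drop(x %*% c(1, 1)) + rnorm(10, sd = 0.1)
  f <- peak_regression(x, y, "ols")
  # closed-form covariance oracle
  pred <- predict(f, x)
  or <- sum((pred - mean(pred)) * (y - mean(y))) /
    sqrt(sum((pred - mean(pred))^2) * sum((y - mean(y))^2))
  expect_equal(evaluate_fit(f, x, y), or, tolerance = 1e-12)
  # perfect and anti-perfect predictions
  idf <- structure(list(coefficients = c(1, 0), intercept = 0,
                        fitted.values = NULL), class = "peak_fit")
  expect_equal(evaluate_fit(idf, x, x[, 1]), 1)
  expect_equal(evaluate_fit(idf, x, -x[, 1]), -1)
  con <- structure(list(coefficients = c(0, 0), intercept = 1,
                        fitted.values = NULL), class = "peak_fit")
  expect_warning(r <- evaluate_fit(con, x, y), "constant")
  expect_equal(r, 0)
})
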