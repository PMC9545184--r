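test_that("shape regression recovers noise-free coefficients exactly", {
  set.seed(1)
  n <- 30; q <- 8
  beta <- rnorm(q)
  x <- rnorm(n)
  Y <- outer(rep(1, n), rnorm(q)) + outer(x, beta)
  fit <- shape_regression(Y, data.frame(x = x), "x")
  expect_equal(unname(fit$coefficients[, 1]), beta, tolerance = 1e-10)
  expect_equal(fit$multivariate_r2, 1, tolerance = 1e-10)
  expect_equal(unname(fit$score_r2["x"]), 1, tolerance = 1e-10)
  # uncorrelated predictor: multivariate R2 near zero
  fit0 <- shape_regression(matrix(rnorm(n * q), n, q), data.frame(x = x), "x")
  expect_lt(fit0$multivariate_r2, 0.35)
  expect_error(shape_regression(Y, data.frame(x = rep(1, n)), "x"),
               "constant")
})

test_that("simulated covariate effects are recovered as coefficient directions", {
  tmpl <- grid_template(5, 5)
  gs <- sample_group_study(tmpl, n_per_group = 100, sigma = 0.02, seed = 2)
  sup <- gpa(gs$sample)
  covs <- gs$sample$covariates
  fit <- shape_regression(sup, covs, "covariate")
  b <- fit$coefficients[, 1]
  truth <- as.numeric(gs$covariate_vector)
  cosine <- abs(sum(b * truth)) / sqrt(sum(b^2) * sum(truth^2))
  expect_gt(cosine, 0.95)
  # allometric vector recovered as the partial coefficient of log size
  # (sex enters the model: group and size effects are confounded otherwise)
  covs$logsize <- log(covs$size)
  covs$male <- as.numeric(covs$sex == "M")
  fit2 <- shape_regression(sup, covs, c("male", "logsize"))
  b2 <- fit2$coefficients[, "logsize"]
  truth2 <- as.numeric(gs$allometry_vector)
  expect_gt(abs(sum(b2 * truth2)) / sqrt(sum(b2^2) * sum(truth2^2)), 0.95)
})

test_that("regression scores are projections on the normalized coefficient vector", {
  set.seed(3)
  n <- 40; q <- 6
  x <- rnorm(n)
  beta <- rnorm(q)
  Y <- outer(x, beta)
  fit <- shape_regression(Y, data.frame(x = x), "x")
  sc <- regression_scores(fit, Y)
  expect_equal(abs(cor(sc[, 1], x)), 1, tolerance = 1e-10)
  # variation orthogonal to the coefficient vector and uncorrelated with
  # the predictor in-sample leaves the scores unchanged
  null <- qr.Q(qr(cbind(beta, matrix(rnorm(q * (q - 1)), q))))[, 2:q]
  N <- matrix(rnorm(n * (q - 1)), n)
  xc <- x - mean(x)
  N <- N - outer(xc, drop(crossprod(xc, N)) / sum(xc^2))  # decorrelate from x
  Y2 <- Y + N %*% t(null)
  fit2 <- shape_regression(Y2, data.frame(x = x), "x")
  sc2 <- regression_scores(fit2, Y2)
  expect_equal(sc2[, 1], sc[, 1], tolerance = 1e-8)
  # dot-product recomputation oracle
  manual <- scale(Y, scale = FALSE) %*%
    (fit$coefficients[, 1] / sqrt(sum(fit$coefficients[, 1]^2)))
  expect_equal(sc[, 1], manual[, 1], ignore_attr = TRUE)
})

test_that("shape vector angles follow the arccos oracle", {
  expect_equal(shape_vector_angle(c(1, 0), c(2, 0)), 0)
  expect_equal(shape_vector_angle(c(1, 0), c(0, 3)), 90)
  expect_equal(shape_vector_angle(c(1, 1), c(-1, -1)), 180)
  set.seed(4)
  v1 <- rnorm(7); v2 <- rnorm(7)
  expect_equal(shape_vector_angle(v1, v2),
               acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi)
  expect_error(shape_vector_angle(c(0, 0), c(1, 0)), "zero")
})

test_that("PC-count sensitivity shows the documented signal/noise behaviors", {
  set.seed(5)
  n <- 150; q <- 60; sig_dim <- 8
  basis <- qr.Q(qr(matrix(rnorm(q * q), q, q)))
  x <- rnorm(n)
  # signal confined to the first sig_dim directions, noise beyond
  signal <- outer(x, rnorm(sig_dim)) + matrix(rnorm(n * sig_dim), n) * 0.7
  scores <- cbind(signal * 3, matrix(rnorm(n * (q - sig_dim)), n) * 0.8)
  Y <- scores %*% t(basis)
  covs <- data.frame(x = x)
  expect_warning(
    mr <- suppressWarnings(
      pc_sensitivity_curve("multivariate_r2", Y, covs, "x",
                           m_range = c(2, 5, 8, 20, 40, 80))),
    NA)
  expect_warning(
    pc_sensitivity_curve("multivariate_r2", Y[1:20, ], covs[1:20, , drop = FALSE],
                         "x", m_range = c(2, 25)),
    "truncated")
  expect_equal(mr$m, c(2, 5, 8, 20, 40))  # truncated to the data rank
  peak <- which.max(mr$value)
  expect_lte(mr$m[peak], 20)
  expect_lt(mr$value[nrow(mr)], mr$value[peak])     # declines past the signal
  sr <- pc_sensitivity_curve("score_r2", Y, covs, "x",
                             m_range = c(8, 20, 40, 60))
  expect_true(all(diff(sr$value) > -1e-6))          # creeps upward with noise PCs
  # angle between identical coefficient vectors is zero for every m
  g <- rep(1:2, each = n / 2)
  Ydup <- rbind(Y, Y)[seq_len(n), ]
  ang <- pc_sensitivity_curve("angle", rbind(Y, Y), data.frame(x = c(x, x)),
                              "x", groups = rep(1:2, each = n),
                              m_range = c(2, 5, 10))
  expect_lt(max(ang$value), 1e-6)
})

test_that("angle curves rise as noise PCs are added to distinct groups", {
  set.seed(6)
  n <- 200; q <- 40
  x <- rnorm(n)
  g <- rep(1:2, each = n / 2)
  beta <- rnorm(5)
  scores <- cbind(outer(x, beta) + matrix(rnorm(n * 5) * 0.3, n),
                  matrix(rnorm(n * (q - 5)) * 0.5, n))
  ang <- pc_sensitivity_curve("angle", scores, data.frame(x = x), "x",
                              groups = g, m_range = c(5, 15, 30, 39))
  expect_equal(nrow(ang), 4L)
  expect_gt(ang$value[4], ang$value[1])
})

test_that("two-block PLS matches brute-force covariance maximization", {
  set.seed(7)
  n <- 100
  X <- matrix(rnorm(n * 2), n, 2)
  Y <- cbind(X %*% c(0.8, -0.4) + rnorm(n) * 0.4, rnorm(n))
  res <- pls_two_block(X, Y)
  # grid search over unit vectors at 1 degree resolution
  best <- -Inf; best_pair <- NULL
  for (a_deg in seq(0, 179, by = 1)) for (b_deg in seq(0, 179, by = 1)) {
    a <- c(cos(a_deg * pi / 180), sin(a_deg * pi / 180))
    b <- c(cos(b_deg * pi / 180), sin(b_deg * pi / 180))
    cv <- abs(drop(cov(X %*% a, Y %*% b)))
    if (cv > best) { best <- cv; best_pair <- list(a = a, b = b) }
  }
  expect_equal(res$statistic[1], best, tolerance = 1e-3)
  expect_gte(res$statistic[1], best - 1e-10)
  expect_equal(abs(sum(res$x_coefficients[, 1] * best_pair$a)), 1,
               tolerance = 1e-3)
  # identical blocks: first singular value is the top eigenvalue of cov(x)
  res2 <- pls_two_block(X, X)
  expect_equal(res2$statistic[1], pca(X)$eigenvalues[1], tolerance = 1e-10)
  # statistics non-increasing
  expect_true(all(diff(res$statistic) <= 1e-12))
})

test_that("pre-whitened blocks collapse PLS, RRR, and CCA onto the same axes", {
  set.seed(8)
  n <- 400
  X0 <- matrix(rnorm(n * 3), n, 3)
  Y0 <- X0 %*% matrix(rnorm(9), 3, 3) + matrix(rnorm(n * 3), n, 3)
  whiten <- function(M) {
    e <- eigen(cov(M), symmetric = TRUE)
    scale(M, scale = FALSE) %*% e$vectors %*% diag(1 / sqrt(e$values)) %*%
      t(e$vectors)
  }
  Xw <- whiten(X0); Yw <- whiten(Y0)
  a1 <- pls_two_block(Xw, Yw)$x_coefficients[, 1]
  a2 <- reduced_rank_regression(Xw, Yw)$x_coefficients[, 1]
  a3 <- canonical_correlation(Xw, Yw)$x_coefficients[, 1]
  a2 <- a2 / sqrt(sum(a2^2)); a3 <- a3 / sqrt(sum(a3^2))
  expect_equal(abs(sum(a1 * a2)), 1, tolerance = 1e-8)
  expect_equal(abs(sum(a1 * a3)), 1, tolerance = 1e-8)
})

test_that("RRR prefers the strong-slope direction where PLS prefers covariance", {
  # two temperature-like predictors correlated ~0.9: one response weakly
  # tracks their (highly variable) average, another strongly tracks their
  # (low-variance) difference
  set.seed(9)
  n <- 500
  z <- rnorm(n)
  x1 <- z + rnorm(n) * sqrt(1 / 0.9 - 1)
  x2 <- z + rnorm(n) * sqrt(1 / 0.9 - 1)
  X <- cbind(x1, x2)
  Y <- cbind(0.3 * (x1 + x2) / 2 + rnorm(n) * 0.3,
             2 * (x1 - x2) + rnorm(n) * 0.3)
  pls <- pls_two_block(X, Y)
  rrr <- reduced_rank_regression(X, Y)
  pls_a <- pls$x_coefficients[, 1]
  rrr_a <- rrr$x_coefficients[, 1]
  expect_equal(prod(sign(pls_a)), 1)    # average: same-sign loadings
  expect_equal(prod(sign(rrr_a)), -1)   # difference: opposite-sign loadings
})

test_that("the first RRR pair maximizes the slope over random directions", {
  set.seed(10)
  n <- 300
  X <- matrix(rnorm(n * 4), n, 4)
  Y <- X %*% matrix(rnorm(12), 4, 3) + matrix(rnorm(n * 3), n, 3) * 2
  res <- reduced_rank_regression(X, Y)
  Sxx <- cov(X); Sxy <- cov(X, Y)
  slope_of <- function(a) {
    a <- a / sqrt(drop(t(a) %*% Sxx %*% a))   # unit-variance latent x
    sqrt(sum((t(Sxy) %*% a)^2))               # best unit-norm b
  }
  rand <- replicate(1000, slope_of(rnorm(4)))
  expect_gte(res$statistic[1] + 1e-10, max(rand))
  # univariate case: slope equals OLS slope
  x <- rnorm(50); y <- 1.7 * x + rnorm(50) * 0.2
  rr <- reduced_rank_regression(matrix(x), matrix(y))
  expect_equal(rr$slope_unit_norm[1], unname(coef(lm(y ~ x))[2]),
               tolerance = 1e-10)
})

test_that("canonical correlations match brute force and detect independence", {
  set.seed(11)
  n <- 200
  X <- matrix(rnorm(n * 3), n, 3)
  Y <- cbind(X %*% c(1, -1, 0.5) + rnorm(n), rnorm(n))
  res <- canonical_correlation(X, Y)
  ref <- cancor(scale(X, scale = FALSE), scale(Y, scale = FALSE))
  expect_equal(res$statistic[1:2], ref$cor, tolerance = 1e-10)
  expect_true(all(res$statistic >= 0 & res$statistic <= 1))
  # noiseless linear map: perfect first correlation
  Yl <- X %*% matrix(rnorm(6), 3, 2)
  expect_equal(canonical_correlation(X, Yl)$statistic[1], 1, tolerance = 1e-8)
  # independent blocks: correlations at noise level
  Z <- matrix(rnorm(n * 3), n, 3)
  expect_lt(max(canonical_correlation(X, Z)$statistic), 2.5 / sqrt(n) * 3)
})

test_that("PLS covariances inflate with variable count on pure noise, unlike RRR/CCA geometry", {
  set.seed(12)
  n <- 80
  d1 <- mean(replicate(10, pls_two_block(matrix(rnorm(n * 5), n),
                                         matrix(rnorm(n * 5), n))$statistic[1]))
  d2 <- mean(replicate(10, pls_two_block(matrix(rnorm(n * 20), n),
                                         matrix(rnorm(n * 20), n))$statistic[1]))
  d3 <- mean(replicate(10, pls_two_block(matrix(rnorm(n * 80), n),
                                         matrix(rnorm(n * 80), n))$statistic[1]))
  expect_gt(d2, d1)
  expect_gt(d3, d2)
})

test_that("RRR is invariant to x-transforms, CCA to both, PLS to neither", {
  set.seed(13)
  n <- 250
  X <- matrix(rnorm(n * 3), n, 3)
  Y <- X %*% matrix(rnorm(9), 3, 3) + matrix(rnorm(n * 3), n, 3)
  Tx <- matrix(rnorm(9), 3, 3) + 2 * diag(3)
  Ty <- matrix(rnorm(9), 3, 3) + 2 * diag(3)
  # RRR: slopes invariant to nonsingular transform of x
  expect_equal(reduced_rank_regression(X %*% Tx, Y)$statistic,
               reduced_rank_regression(X, Y)$statistic, tolerance = 1e-8)
  # CCA: correlations invariant to transforms of both blocks
  expect_equal(canonical_correlation(X %*% Tx, Y %*% Ty)$statistic,
               canonical_correlation(X, Y)$statistic, tolerance = 1e-8)
  # PLS: singular values change under the same transform
  expect_gt(max(abs(pls_two_block(X %*% Tx, Y)$statistic -
                    pls_two_block(X, Y)$statistic)), 1e-4)
})
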