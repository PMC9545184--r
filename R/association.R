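#' Multivariate regression of shape or form coordinates on predictors
#'
#' Ordinary least squares of every shape (or form) coordinate on one or
#' more numeric predictors, reported jointly: the coefficient column of a
#' predictor is the average shape change per unit of that predictor and can
#' be visualized as a deformation at caller-chosen multiples. Two summary
#' statistics are returned: the multivariate R-squared (fraction of total
#' coordinate variance explained by the model, which pools over all
#' coordinates and therefore shrinks as uninformative coordinates are
#' added) and, per predictor, the R-squared between the predictor and its
#' regression score (the projection of the data on the normalized
#' coefficient vector), which measures association only along the direction
#' of maximal effect.
#'
#' @param data an `n x q` matrix of shape/form coordinates, a
#'   `gm_superimposition`, or `gm_form_coordinates`.
#' @param covariates data frame with the predictor columns (defaults to the
#'   covariates attached to `data`).
#' @param predictors character vector of numeric predictor column names.
#' @return an object of class `gm_shape_regression`: list with
#'   `coefficients` (`q x c`), `intercept` (`q`), `multivariate_r2`,
#'   `score_r2` (named per predictor), `scores` (`n x c` regression
#'   scores), `fitted`, `residuals`, `predictors`.
#' @export
shape_regression <- function(data, covariates = NULL, predictors) {
  Y <- regression_response(data)
  if (is.null(covariates)) covariates <- regression_covariates(data)
  if (is.null(covariates)) stop("no covariates supplied or attached")
  X <- as.matrix(covariates[, predictors, drop = FALSE])
  if (!is.numeric(X)) stop("predictors must be numeric")
  if (nrow(Y) <= ncol(X) + 1L) stop("need n > number of predictors + 1")
  if (any(apply(X, 2, stats::sd) == 0)) stop("constant predictor")
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), Y)
  coefs <- t(fit$coefficients[-1, , drop = FALSE])   # q x c
  colnames(coefs) <- predictors
  fitted <- cbind(1, X) %*% fit$coefficients
  ss_tot <- sum(scale(Y, scale = FALSE)^2)
  ss_res <- sum(fit$residuals^2)
  Yc <- scale(Y, scale = FALSE)
  scores <- matrix(NA_real_, nrow(Y), ncol(X),
                   dimnames = list(rownames(Y), predictors))
  score_r2 <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    b <- coefs[, j]
    nb <- sqrt(sum(b^2))
    if (nb == 0) {
      scores[, j] <- 0; score_r2[j] <- 0
    } else {
      scores[, j] <- Yc %*% (b / nb)
      score_r2[j] <- stats::cor(scores[, j], X[, j])^2
    }
  }
  names(score_r2) <- predictors
  structure(list(coefficients = coefs,
                 intercept = fit$coefficients[1, ],
                 multivariate_r2 = 1 - ss_res / ss_tot,
                 score_r2 = score_r2,
                 scores = scores, fitted = fitted,
                 residuals = fit$residuals, predictors = predictors),
            class = "gm_shape_regression")
}

regression_response <- function(data) {
  if (inherits(data, "gm_superimposition")) data$aligned
  else if (inherits(data, "gm_form_coordinates")) data$values
  else as.matrix(data)
}

regression_covariates <- function(data) {
  if (inherits(data, "gm_superimposition") ||
      inherits(data, "gm_form_coordinates")) data$covariates
  else NULL
}

#' Regression scores of a fitted shape regression
#'
#' Projections of the centered coordinates on each predictor's normalized
#' coefficient vector (the "net partial predictor" of that covariate).
#'
#' @param result a `gm_shape_regression`.
#' @param data optional new `n x q` matrix (defaults to refitting data is
#'   not stored; pass the same matrix used in the fit).
#' @return an `n x c` matrix of scores.
#' @export
regression_scores <- function(result, data) {
  stopifnot(inherits(result, "gm_shape_regression"))
  Y <- scale(regression_response(data), scale = FALSE)
  out <- matrix(NA_real_, nrow(Y), length(result$predictors),
                dimnames = list(rownames(Y), result$predictors))
  for (j in seq_along(result$predictors)) {
    b <- result$coefficients[, j]
    nb <- sqrt(sum(b^2))
    if (nb == 0) stop("zero coefficient vector for predictor ",
                      result$predictors[j])
    out[, j] <- Y %*% (b / nb)
  }
  out
}

#' Angle between two shape vectors
#'
#' @param v1,v2 nonzero numeric vectors of equal length.
#' @return the angle in degrees, in `[0, 180]`.
#' @export
shape_vector_angle <- function(v1, v2) {
  v1 <- as.numeric(v1); v2 <- as.numeric(v2)
  if (length(v1) != length(v2)) stop("vectors differ in length")
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero vector has no direction")
  acos(max(-1, min(1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
}

#' Sensitivity of association statistics to the number of retained PCs
#'
#' Recomputes an association statistic after reducing the coordinates to
#' their first `m` principal components, for each `m` in `m_range`. With a
#' signal confined to a few PCs, the multivariate R-squared peaks near the
#' signal dimension and then declines (added PCs inflate total variance
#' without adding association); the score R-squared and the angle between
#' group-wise coefficient vectors keep creeping up with every further PC
#' because weak random associations accumulate.
#'
#' @param statistic `"angle"`, `"multivariate_r2"`, or `"score_r2"`.
#' @param data an `n x q` coordinate matrix (or superimposition).
#' @param covariates data frame of predictors.
#' @param predictor single numeric predictor column name.
#' @param groups for `"angle"`: a 2-level factor; the regression is fitted
#'   separately per group and the angle between the two coefficient vectors
#'   (in the shared PC basis) is reported.
#' @param m_range integer vector of PC counts.
#' @return data frame with columns `m` and `value`.
#' @export
pc_sensitivity_curve <- function(statistic = c("angle", "multivariate_r2",
                                               "score_r2"),
                                 data, covariates, predictor, groups = NULL,
                                 m_range = NULL) {
  statistic <- match.arg(statistic)
  Y <- regression_response(data)
  pc <- pca(Y)
  rank <- ncol(pc$scores)
  if (is.null(m_range)) m_range <- seq(2L, rank)
  if (any(m_range > rank)) {
    warning("m_range truncated to the data rank (", rank, ")")
    m_range <- m_range[m_range <= rank]
  }
  if (statistic == "angle") {
    groups <- factor(groups)
    if (nlevels(groups) != 2L) stop("angle requires exactly 2 groups")
  }
  value <- vapply(m_range, function(m) {
    S <- pc$scores[, seq_len(m), drop = FALSE]
    if (statistic == "angle") {
      bs <- lapply(levels(groups), function(g) {
        fit <- shape_regression(S[groups == g, , drop = FALSE],
                                covariates[groups == g, , drop = FALSE],
                                predictor)
        fit$coefficients[, 1]
      })
      shape_vector_angle(bs[[1]], bs[[2]])
    } else {
      fit <- shape_regression(S, covariates, predictor)
      if (statistic == "multivariate_r2") fit$multivariate_r2
      else unname(fit$score_r2[1])
    }
  }, numeric(1))
  data.frame(m = m_range, value = value)
}

# --- two-block latent variable methods ------------------------------------

# Shared scaffolding: center blocks, return centered matrices and covariances.
two_block_prep <- function(x_block, y_block) {
  X <- as.matrix(x_block); Y <- as.matrix(y_block)
  if (nrow(X) != nrow(Y)) stop("blocks must have the same number of cases")
  if (nrow(X) < 3L) stop("need at least 3 cases")
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  list(X = Xc, Y = Yc, Sxy = crossprod(Xc, Yc) / (nrow(X) - 1L),
       Sxx = stats::cov(Xc), Syy = stats::cov(Yc))
}

# Sign convention: flip each latent pair so the x score covaries
# positively with the first x variable.
latent_sign_fix <- function(xs, a, b, X) {
  for (j in seq_len(ncol(a))) {
    cv <- stats::cov(X[, 1], xs[, j])
    if (is.finite(cv) && cv < 0) {
      a[, j] <- -a[, j]; b[, j] <- -b[, j]; xs[, j] <- -xs[, j]
    }
  }
  list(xs = xs, a = a, b = b)
}

latent_result <- function(method, prep, a, b, stat, stat_name) {
  xs <- prep$X %*% a
  ys <- prep$Y %*% b
  fix <- latent_sign_fix(xs, a, b, prep$X)
  ys <- prep$Y %*% fix$b
  structure(list(method = method,
                 x_coefficients = fix$a, y_coefficients = fix$b,
                 x_scores = fix$xs, y_scores = ys,
                 statistic = stat, statistic_name = stat_name),
            class = "gm_latent_pair")
}

#' @export
print.gm_latent_pair <- function(x, ...) {
  cat("Two-block latent variable analysis (", toupper(x$method), ")\n", sep = "")
  cat(x$statistic_name, "per pair:",
      paste(signif(x$statistic, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Two-block partial least squares
#'
#' Finds pairs of latent variables, one linear combination per block, with
#' maximal covariance: the singular value decomposition of the cross-
#' covariance matrix. Coefficient vectors are unit norm and proportional to
#' the covariances of the variables with the opposite latent variable.
#' Successive pairs have non-increasing covariance. PLS needs no matrix
#' inversion, but the maximized covariances grow with the number of
#' variables even on pure noise.
#'
#' @param x_block,y_block `n x px` and `n x py` matrices (centered
#'   internally).
#' @return a `gm_latent_pair` with `statistic` = latent covariances
#'   (the singular values).
#' @export
pls_two_block <- function(x_block, y_block) {
  prep <- two_block_prep(x_block, y_block)
  if (all(abs(prep$Sxy) < 1e-14))
    warning("zero cross-covariance between blocks; latent pairs are degenerate")
  sv <- svd(prep$Sxy)
  m <- sum(sv$d > 1e-12 * max(sv$d, 1e-300))
  m <- max(m, 1L)
  latent_result("pls", prep,
                sv$u[, seq_len(m), drop = FALSE],
                sv$v[, seq_len(m), drop = FALSE],
                sv$d[seq_len(m)], "covariance")
}

#' Reduced rank regression latent pairs
#'
#' Finds latent pairs maximizing the regression slope of the dependent
#' latent variable on the independent one (the independent latent variable
#' is normalized to unit variance, the dependent coefficients to unit
#' norm): the singular value decomposition of the whitened cross-covariance
#' `Sxx^(-1/2) Sxy`. The x coefficients are proportional to partial
#' (multiple) regression coefficients — correlated x variables that carry
#' no conditional information get near-zero loadings — while the y
#' coefficients are proportional to covariances. Requires a nonsingular x
#' covariance, hence `x_pcs` reduction when x is high dimensional.
#'
#' @param x_block,y_block data blocks.
#' @param x_pcs optionally reduce the x block to its first `x_pcs` PCs.
#' @return a `gm_latent_pair`; `statistic` holds the maximized slopes
#'   (descending), and `slope_unit_norm` the slopes recomputed with
#'   unit-norm x coefficients (equal to the OLS slope in the univariate
#'   case).
#' @export
reduced_rank_regression <- function(x_block, y_block, x_pcs = NULL) {
  X <- as.matrix(x_block)
  x_map <- NULL
  if (!is.null(x_pcs)) {
    pcx <- pca(X)
    x_pcs <- min(x_pcs, ncol(pcx$scores))
    x_map <- pcx$axes[, seq_len(x_pcs), drop = FALSE]
    X <- pcx$scores[, seq_len(x_pcs), drop = FALSE]
  }
  prep <- two_block_prep(X, y_block)
  ex <- eigen(prep$Sxx, symmetric = TRUE)
  if (min(ex$values) < 1e-10 * max(ex$values))
    stop("singular x covariance; reduce the x block (x_pcs) first")
  Whalf <- ex$vectors %*% diag(1 / sqrt(ex$values), ncol(X)) %*% t(ex$vectors)
  sv <- svd(Whalf %*% prep$Sxy)
  m <- max(1L, sum(sv$d > 1e-12 * max(sv$d, 1e-300)))
  a <- Whalf %*% sv$u[, seq_len(m), drop = FALSE]   # var of x scores = 1
  b <- sv$v[, seq_len(m), drop = FALSE]
  res <- latent_result("rrr", prep, a, b, sv$d[seq_len(m)], "slope")
  # slopes under the unit-norm coefficient convention (OLS slope when px=1)
  a_unit <- sweep(res$x_coefficients, 2,
                  sqrt(colSums(res$x_coefficients^2)), `/`)
  su <- vapply(seq_len(m), function(j) {
    u <- prep$X %*% a_unit[, j]
    v <- prep$Y %*% res$y_coefficients[, j]
    stats::cov(u, v) / stats::var(u)
  }, numeric(1))
  res$slope_unit_norm <- su
  if (!is.null(x_map))
    res$x_coefficients_original <- x_map %*% res$x_coefficients
  res
}

#' Canonical correlation latent pairs
#'
#' Finds latent pairs with maximal correlation: the singular value
#' decomposition of the doubly whitened cross-covariance
#' `Sxx^(-1/2) Sxy Syy^(-1/2)`. Correlations lie in `[0, 1]` and descend
#' across pairs; coefficients are partial-type for both blocks. Both
#' covariances must be nonsingular, hence the `x_pcs`/`y_pcs` reductions
#' for high-dimensional blocks.
#'
#' @param x_block,y_block data blocks.
#' @param x_pcs,y_pcs optional PC reduction per block.
#' @return a `gm_latent_pair` with `statistic` = canonical correlations.
#' @export
canonical_correlation <- function(x_block, y_block, x_pcs = NULL, y_pcs = NULL) {
  X <- as.matrix(x_block); Y <- as.matrix(y_block)
  if (!is.null(x_pcs)) {
    pcx <- pca(X); X <- pcx$scores[, seq_len(min(x_pcs, ncol(pcx$scores))), drop = FALSE]
  }
  if (!is.null(y_pcs)) {
    pcy <- pca(Y); Y <- pcy$scores[, seq_len(min(y_pcs, ncol(pcy$scores))), drop = FALSE]
  }
  prep <- two_block_prep(X, Y)
  whiten <- function(S, what) {
    e <- eigen(S, symmetric = TRUE)
    if (min(e$values) < 1e-10 * max(e$values))
      stop("singular ", what, " covariance; reduce the block first")
    e$vectors %*% diag(1 / sqrt(e$values), nrow(S)) %*% t(e$vectors)
  }
  Wx <- whiten(prep$Sxx, "x")
  Wy <- whiten(prep$Syy, "y")
  sv <- svd(Wx %*% prep$Sxy %*% Wy)
  m <- min(ncol(X), ncol(Y))
  a <- Wx %*% sv$u[, seq_len(m), drop = FALSE]
  b <- Wy %*% sv$v[, seq_len(m), drop = FALSE]
  latent_result("cca", prep, a, b,
                pmin(1, sv$d[seq_len(m)]), "correlation")
}
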