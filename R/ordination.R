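#' Principal component analysis
#'
#' Eigendecomposition of the sample covariance matrix (denominator
#' `n - 1`), axes ordered by descending eigenvalue with the deterministic
#' sign convention that each axis's largest-magnitude loading is positive.
#'
#' @param data an `n x q` matrix (rows = cases).
#' @param center subtracted column means (computed if `TRUE`).
#' @return an object of class `gm_ordination`: list with `axes` (`q x m`
#'   orthonormal loadings), `scores` (`n x m`), `eigenvalues`,
#'   `explained` (fractions of total variance), `center`, `method`.
#' @export
pca <- function(data, center = TRUE) {
  X <- as.matrix(data)
  if (nrow(X) < 2L) stop("PCA needs at least 2 cases")
  ctr <- if (isTRUE(center)) colMeans(X) else rep(0, ncol(X))
  Xc <- sweep(X, 2, ctr)
  if (all(abs(Xc) < 1e-12)) stop("constant data: no variance to decompose")
  sv <- svd(Xc)
  keep <- sv$d > 1e-10 * max(sv$d)
  axes <- apply_sign_convention(sv$v[, keep, drop = FALSE])
  scores <- Xc %*% axes
  ev <- sv$d[keep]^2 / (nrow(X) - 1L)
  colnames(axes) <- colnames(scores) <- paste0("PC", seq_len(sum(keep)))
  rownames(scores) <- rownames(X)
  structure(list(axes = axes, scores = scores, eigenvalues = ev,
                 explained = ev / sum(sv$d^2 / (nrow(X) - 1L)),
                 center = ctr, method = "pca"),
            class = "gm_ordination")
}

apply_sign_convention <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' @export
print.gm_ordination <- function(x, ...) {
  cat("Ordination (", x$method, "): ", ncol(x$scores), " axes\n", sep = "")
  ev <- if (!is.null(x$explained)) x$explained else x$eigenvalues / sum(x$eigenvalues)
  cat("Explained variance:", paste0(round(100 * utils::head(ev, 5), 1), "%",
                                    collapse = ", "),
      if (length(ev) > 5) "...", "\n")
  invisible(x)
}

#' Between-group principal component analysis
#'
#' The axes are the principal components of the `g x q` matrix of group
#' means (each group counting equally by default); all cases are projected
#' onto them. With two groups the single axis is the normalized difference
#' of the group means. Because the axes are chosen to spread the group
#' means, scores of the very cases the means were computed from separate
#' spuriously when `q` is large relative to `n`; the leave-one-out option
#' projects each case onto axes computed from group means that exclude it,
#' which largely removes that artifact.
#'
#' @param data an `n x q` matrix.
#' @param groups a factor or vector of length `n` with at least 2 levels.
#' @param cross_validate if `TRUE`, each case's scores use group means
#'   computed without that case (axes from the full fit are kept for
#'   loadings/visualization).
#' @param weighted if `TRUE`, the mean covariance is weighted by group size.
#' @return a `gm_ordination` with additional elements `group_means`,
#'   `groups`, and (if requested) cross-validated `scores`.
#' @export
bgpca <- function(data, groups, cross_validate = FALSE, weighted = FALSE) {
  X <- as.matrix(data)
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("between-group PCA needs at least 2 groups")
  gm <- group_mean_matrix(X, groups)
  w <- if (weighted) as.numeric(table(groups)) else rep(1, nlevels(groups))
  ctr <- colSums(gm * w) / sum(w)
  Gc <- sweep(gm, 2, ctr) * sqrt(w)
  sv <- svd(Gc)
  keep <- sv$d > 1e-10 * max(sv$d)
  axes <- apply_sign_convention(sv$v[, keep, drop = FALSE])
  scores <- sweep(X, 2, ctr) %*% axes
  if (cross_validate) {
    for (i in seq_len(nrow(X))) {
      gi <- groups[i]
      idx <- which(groups == gi)
      if (length(idx) < 2L) next
      gm_i <- gm
      gm_i[gi, ] <- colMeans(X[setdiff(idx, i), , drop = FALSE])
      ctr_i <- colSums(gm_i * w) / sum(w)
      sv_i <- svd(sweep(gm_i, 2, ctr_i) * sqrt(w))
      ax_i <- apply_sign_convention(sv_i$v[, seq_len(ncol(axes)), drop = FALSE])
      # align CV axis signs to the full-fit axes for comparability
      flip <- sign(diag(crossprod(ax_i, axes)))
      flip[flip == 0] <- 1
      ax_i <- sweep(ax_i, 2, flip, `*`)
      scores[i, ] <- sweep(X[i, , drop = FALSE], 2, ctr_i) %*% ax_i
    }
  }
  ev <- sv$d[keep]^2 / max(1L, nlevels(groups) - 1L)
  colnames(axes) <- colnames(scores) <- paste0("bgPC", seq_len(sum(keep)))
  structure(list(axes = axes, scores = scores, eigenvalues = ev,
                 explained = NULL, center = ctr, method = "bgpca",
                 group_means = gm, groups = groups,
                 cross_validated = cross_validate),
            class = "gm_ordination")
}

group_mean_matrix <- function(X, groups) {
  gm <- do.call(rbind, lapply(levels(groups), function(g)
    colMeans(X[groups == g, , drop = FALSE])))
  rownames(gm) <- levels(groups)
  gm
}

#' Canonical variate analysis on leading principal components
#'
#' Maximizes between-group variance relative to pooled within-group
#' variance on the first `n_pcs` principal component scores (the inversion
#' of the within covariance requires this prior dimension reduction: shape
#' coordinates are never of full rank, and with many variables CVA
#' separates even identical distributions). Canonical axes are scaled so CV
#' scores have unit pooled within-group variance, and axes are
#' back-transformed to the original coordinate space for visualization as
#' deformations.
#'
#' @param data an `n x q` matrix.
#' @param groups factor of length `n`.
#' @param n_pcs number of leading PCs to retain before CVA.
#' @return a `gm_ordination` with `axes` (coordinate-space directions, for
#'   visualization), `scores`, `eigenvalues` (between/within variance
#'   ratios), `pc_basis`, `pc_axes_cv` (axes in PC-score space).
#' @export
cva_on_pcs <- function(data, groups, n_pcs) {
  X <- as.matrix(data)
  groups <- factor(groups)
  g <- nlevels(groups)
  if (g < 2L) stop("CVA needs at least 2 groups")
  pc <- pca(X)
  n_pcs <- min(n_pcs, ncol(pc$scores))
  S <- pc$scores[, seq_len(n_pcs), drop = FALSE]
  W <- pooled_within_cov(S, groups)
  ew <- eigen(W, symmetric = TRUE)
  if (min(ew$values) < 1e-10 * max(ew$values))
    stop("pooled within-group covariance is singular; use fewer PCs")
  Wi_h <- ew$vectors %*% diag(1 / sqrt(ew$values), n_pcs) %*% t(ew$vectors)
  gm <- group_mean_matrix(S, groups)
  B <- stats::cov(gm)
  eb <- eigen(Wi_h %*% B %*% Wi_h, symmetric = TRUE)
  m <- min(g - 1L, n_pcs)
  A <- Wi_h %*% eb$vectors[, seq_len(m), drop = FALSE]  # CV axes in PC space
  A <- apply_sign_convention(A)
  scores <- S %*% A
  axes <- pc$axes[, seq_len(n_pcs), drop = FALSE] %*% A
  colnames(axes) <- colnames(scores) <- paste0("CV", seq_len(m))
  structure(list(axes = axes, scores = scores,
                 eigenvalues = eb$values[seq_len(m)],
                 explained = NULL, center = pc$center, method = "cva",
                 groups = groups, pc_basis = n_pcs, pc_axes_cv = A),
            class = "gm_ordination")
}

pooled_within_cov <- function(X, groups) {
  groups <- factor(groups)
  n <- nrow(X)
  g <- nlevels(groups)
  acc <- matrix(0, ncol(X), ncol(X))
  for (lev in levels(groups)) {
    Xi <- X[groups == lev, , drop = FALSE]
    if (nrow(Xi) > 1L)
      acc <- acc + stats::cov(Xi) * (nrow(Xi) - 1L)
  }
  acc / (n - g)
}

#' Mahalanobis distance between two group means
#'
#' Distance between group means relative to the within-group variation
#' along that direction; invariant to any nonsingular linear transform of
#' the basis. Computed on a stated PC basis when the pooled covariance is
#' rank deficient.
#'
#' @param mean_a,mean_b mean vectors.
#' @param pooled_cov pooled within-group covariance on the same basis.
#' @return a nonnegative scalar.
#' @export
mahalanobis_distance <- function(mean_a, mean_b, pooled_cov) {
  d <- as.numeric(mean_a) - as.numeric(mean_b)
  q <- qr(pooled_cov)
  if (q$rank < length(d)) stop("singular covariance; reduce the basis first")
  sqrt(drop(crossprod(d, solve(pooled_cov, d))))
}

#' Leave-one-out cross-validated quadratic classification on PCs
#'
#' Quadratic (per-group Gaussian, equal priors) classification on the first
#' `n_pcs` principal component scores, with the PCA recomputed inside every
#' leave-one-out fold so the held-out case never influences its own basis.
#' Ties go to the lower group index.
#'
#' @param data an `n x q` matrix.
#' @param groups factor of length `n`.
#' @param n_pcs number of leading PCs for the classifier.
#' @return an object of class `gm_classification`: list with `confusion`
#'   (true x predicted), `rates` (per group), `overall` correct rate,
#'   `scheme = "loocv"`.
#' @export
qda_loocv_classify <- function(data, groups, n_pcs) {
  X <- as.matrix(data)
  groups <- factor(groups)
  n <- nrow(X)
  sizes <- table(groups)
  if (any(sizes <= n_pcs + 1L))
    stop("each group needs more than n_pcs + 1 cases for quadratic classification")
  pred <- integer(n)
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]
    gtr <- groups[-i]
    ctr <- colMeans(Xtr)
    sv <- svd(sweep(Xtr, 2, ctr), nu = 0, nv = n_pcs)
    Str <- sweep(Xtr, 2, ctr) %*% sv$v
    ste <- drop(sweep(X[i, , drop = FALSE], 2, ctr) %*% sv$v)
    ll <- vapply(levels(gtr), function(lev) {
      Sg <- Str[gtr == lev, , drop = FALSE]
      mu <- colMeans(Sg)
      Cg <- stats::cov(Sg)
      ch <- tryCatch(chol(Cg), error = function(e)
        stop("singular within-group covariance in a fold; use fewer PCs"))
      z <- backsolve(ch, ste - mu, transpose = TRUE)
      -sum(log(diag(ch))) - 0.5 * sum(z^2)
    }, numeric(1))
    pred[i] <- which.max(ll)  # which.max takes the first (lowest index) on ties
  }
  pred <- factor(levels(groups)[pred], levels = levels(groups))
  confusion <- table(true = groups, predicted = pred)
  rates <- diag(confusion) / rowSums(confusion)
  structure(list(confusion = confusion, rates = rates,
                 overall = sum(diag(confusion)) / n, scheme = "loocv",
                 n_pcs = n_pcs),
            class = "gm_classification")
}

#' @export
print.gm_classification <- function(x, ...) {
  cat("Leave-one-out quadratic classification on", x$n_pcs, "PCs\n")
  print(x$confusion)
  cat("Overall correct:", round(100 * x$overall, 1), "%\n")
  invisible(x)
}

#' Relative eigenanalysis of two covariance matrices
#'
#' Finds linear combinations maximizing (and minimizing) the variance ratio
#' between two groups: the generalized eigendecomposition of `cov_a` with
#' respect to `cov_b`. Eigenvalues are the achievable variance ratios,
#' descending; they are invariant under any common nonsingular linear
#' transform of both matrices, which makes them largely independent of
#' landmark spacing. Requires `cov_b` nonsingular, so shape data must be
#' reduced (e.g. to leading PCs) first.
#'
#' @param cov_a,cov_b symmetric covariance matrices on the same basis.
#' @return an object of class `gm_releigen`: list with `eigenvalues`
#'   (descending), `log_eigenvalues`, `eigenvectors` (columns, in the input
#'   basis).
#' @export
relative_eigenanalysis <- function(cov_a, cov_b) {
  A <- as.matrix(cov_a); B <- as.matrix(cov_b)
  eb <- eigen(B, symmetric = TRUE)
  if (min(eb$values) <= 1e-10 * max(abs(eb$values), 1e-300))
    stop("second covariance matrix is singular; reduce the dimension first")
  Bi_h <- eb$vectors %*% diag(1 / sqrt(eb$values), nrow(B)) %*% t(eb$vectors)
  ea <- eigen(Bi_h %*% A %*% Bi_h, symmetric = TRUE)
  vec <- apply_sign_convention(Bi_h %*% ea$vectors)
  structure(list(eigenvalues = ea$values,
                 log_eigenvalues = log(ea$values),
                 eigenvectors = vec),
            class = "gm_releigen")
}

#' Ratio of generalized variances
#'
#' `det(cov_a) / det(cov_b)`: the ratio of the two groups' generalized
#' variances, equal to the product of the relative eigenvalues, and affine
#' invariant. Only computable on a nonsingular (reduced) basis.
#'
#' @inheritParams relative_eigenanalysis
#' @return a positive scalar.
#' @export
generalized_variance_ratio <- function(cov_a, cov_b) {
  A <- as.matrix(cov_a); B <- as.matrix(cov_b)
  da <- determinant(A, logarithm = TRUE)
  db <- determinant(B, logarithm = TRUE)
  if (!is.finite(da$modulus) || !is.finite(db$modulus) ||
      da$sign <= 0 || db$sign <= 0)
    stop("singular covariance matrix; reduce the dimension first")
  exp(as.numeric(da$modulus - db$modulus))
}

#' Affine-invariant covariance metric
#'
#' The square root of the summed squared log relative eigenvalues: a
#' symmetric, affine-invariant distance between covariance matrices, zero
#' exactly when the matrices are equal.
#'
#' @inheritParams relative_eigenanalysis
#' @return a nonnegative scalar.
#' @export
covariance_metric <- function(cov_a, cov_b) {
  re <- relative_eigenanalysis(cov_a, cov_b)
  sqrt(sum(re$log_eigenvalues^2))
}

#' Total variance of a data matrix
#'
#' Sum of per-column variances = trace of the covariance matrix = sum of
#' the PCA eigenvalues.
#'
#' @param data an `n x q` matrix.
#' @return a nonnegative scalar.
#' @export
total_variance <- function(data) {
  X <- as.matrix(data)
  if (nrow(X) < 2L) stop("total variance needs at least 2 cases")
  sum(apply(X, 2, stats::var))
}
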