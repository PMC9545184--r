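#' Thin-plate spline fit between two configurations
#'
#' Fits the interpolating thin-plate spline mapping `source` landmarks
#' exactly onto `target` landmarks, with the standard biharmonic kernel
#' U(r) = r^2 log r in 2D and the triharmonic kernel U(r) = -r in 3D
#' (the sign makes the bending-energy quadratic form positive
#' semidefinite; any consistent positive scaling of the kernel cancels in
#' every ratio or regression computed from it).
#'
#' @param source,target congruent `p x k` configurations.
#' @return an object of class `gm_tps`: list with `source`, `target`,
#'   `affine` (`(k+1) x k`: intercept row then linear part), `weights`
#'   (`p x k` nonaffine kernel weights), `k`.
#' @export
fit_tps <- function(source, target) {
  S <- as.matrix(unclass(source)); Y <- as.matrix(unclass(target))
  if (!all(dim(S) == dim(Y))) stop("source and target are not congruent in p, k")
  p <- nrow(S); k <- ncol(S)
  if (qr(cbind(1, S))$rank < k + 1L)
    stop("degenerate source: affine rank below k + 1")
  L <- tps_system(S)
  rhs <- rbind(Y, matrix(0, k + 1L, k))
  coefs <- tryCatch(solve(L, rhs), error = function(e)
    stop("singular TPS system (duplicate source landmarks?): ",
         conditionMessage(e)))
  structure(list(source = S, target = Y,
                 weights = coefs[seq_len(p), , drop = FALSE],
                 affine = coefs[p + seq_len(k + 1L), , drop = FALSE],
                 k = k),
            class = "gm_tps")
}

tps_kernel <- function(r, k) {
  if (k == 2L) {
    out <- r^2 * log(r)
    out[r == 0] <- 0
    out
  } else {
    -r
  }
}

# Bordered TPS system [[K, P], [P^T, 0]] for source landmarks.
tps_system <- function(S) {
  p <- nrow(S); k <- ncol(S)
  K <- tps_kernel(as.matrix(stats::dist(S)), k)
  P <- cbind(1, S)
  rbind(cbind(K, P), cbind(t(P), matrix(0, k + 1L, k + 1L)))
}

#' Warp points through a fitted thin-plate spline
#'
#' @param model a `gm_tps` from [fit_tps()].
#' @param pts an `m x k` matrix of points.
#' @return the `m x k` warped points; source landmarks map exactly onto the
#'   targets.
#' @export
warp_points <- function(model, pts) {
  stopifnot(inherits(model, "gm_tps"))
  pts <- matrix(as.numeric(pts), ncol = model$k)
  U <- tps_kernel(cross_dist(pts, model$source), model$k)
  cbind(1, pts) %*% model$affine + U %*% model$weights
}

cross_dist <- function(A, B) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' Bending-energy matrix and partial warps of a reference shape
#'
#' Computes the `p x p` bending-energy matrix of a reference configuration
#' (the upper-left block of the inverse bordered TPS system). It is
#' positive semidefinite with a `k + 1` dimensional null space spanned by
#' the constant vector and the coordinate columns of the reference, so
#' affine deformations carry zero bending energy. Its eigenvectors with
#' positive eigenvalue are the partial warps: a basis for nonaffine shape
#' change ordered by spatial scale; small eigenvalues correspond to
#' large-scale (smooth) deformation, large eigenvalues to localized
#' deformation of closely adjacent landmarks.
#'
#' @param reference a `p x k` configuration (typically a sample consensus).
#' @param cond_limit error out if the bordered system's reciprocal condition
#'   number falls below this limit.
#' @return an object of class `gm_bending_energy`: list with `reference`,
#'   `be_matrix` (`p x p` symmetric PSD), `eigenvalues` (ascending, the
#'   `k + 1` zeros dropped), `partial_warps` (`p x (p - k - 1)` matrix of
#'   eigenvectors, columns ordered as the eigenvalues), `k`.
#' @export
bending_energy_matrix <- function(reference, cond_limit = 1e-12) {
  S <- as.matrix(unclass(reference))
  p <- nrow(S); k <- ncol(S)
  L <- tps_system(S)
  rc <- rcond(L)
  if (rc < cond_limit)
    stop(sprintf("near-singular TPS kernel system (rcond = %.3g)", rc))
  Li <- solve(L)
  B <- Li[seq_len(p), seq_len(p), drop = FALSE]
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  ev <- rev(eig$values)                      # ascending
  vec <- eig$vectors[, rev(seq_len(p)), drop = FALSE]
  if (any(ev < -1e-10))
    stop("bending-energy matrix has a substantially negative eigenvalue: ",
         format(min(ev)))
  ev[ev < 0] <- 0
  nz <- ev > 1e-10 * max(ev)
  if (sum(!nz) != k + 1L)
    warning("expected exactly k + 1 zero eigenvalues, found ", sum(!nz))
  structure(list(reference = S, be_matrix = B,
                 eigenvalues = ev[nz],
                 partial_warps = vec[, nz, drop = FALSE],
                 k = k),
            class = "gm_bending_energy")
}

#' Bending energy of a deformation
#'
#' The thin-plate spline bending energy of deforming the model's reference
#' into `target`: the quadratic form of the target's coordinate columns in
#' the bending-energy matrix, summed over the `k` axes. Zero if and only if
#' the deformation is affine, and invariant under affine transformation of
#' the target.
#'
#' @param model a `gm_bending_energy`.
#' @param target a congruent `p x k` configuration.
#' @return a nonnegative scalar.
#' @export
deformation_bending_energy <- function(model, target) {
  stopifnot(inherits(model, "gm_bending_energy"))
  Y <- as.matrix(unclass(target))
  if (!all(dim(Y) == dim(model$reference)))
    stop("target is not congruent with the model reference")
  sum(vapply(seq_len(ncol(Y)),
             function(c) drop(crossprod(Y[, c], model$be_matrix %*% Y[, c])),
             numeric(1)))
}

# Residuals of an aligned sample about the model reference, n x (p*k).
reference_residuals <- function(model, sup) {
  if (nrow(model$reference) != sup$p || model$k != sup$k)
    stop("reference and sample landmarks do not match")
  sweep(sup$aligned, 2, as.numeric(model$reference))
}

#' Partial-warp scores of an aligned sample
#'
#' Projects each case's residual from the model reference onto every
#' partial-warp eigenvector, separately per coordinate axis. Together with
#' the uniform (affine) component these scores reconstruct the nonaffine
#' plus affine tangent-space content of the residuals.
#'
#' @param model a `gm_bending_energy` (typically of the sample consensus).
#' @param sup a `gm_superimposition` aligned to the model's reference.
#' @return an `n x ((p-k-1)*k)` score matrix; columns `PW<i>_<axis>` are
#'   ordered by ascending bending-energy eigenvalue (largest spatial scale
#'   first).
#' @export
partial_warp_scores <- function(model, sup) {
  stopifnot(inherits(model, "gm_bending_energy"),
            inherits(sup, "gm_superimposition"))
  R <- reference_residuals(model, sup)
  p <- sup$p; k <- sup$k
  W <- model$partial_warps
  scores <- matrix(NA_real_, nrow(R), ncol(W) * k)
  axes <- c("x", "y", "z")[seq_len(k)]
  cn <- character(ncol(W) * k)
  for (i in seq_len(ncol(W))) for (c in seq_len(k)) {
    col <- (i - 1L) * k + c
    scores[, col] <- R[, (c - 1L) * p + seq_len(p), drop = FALSE] %*% W[, i]
    cn[col] <- paste0("PW", i, "_", axes[c])
  }
  colnames(scores) <- cn
  rownames(scores) <- sup$ids
  scores
}

# Orthonormal basis (pk x u) of the uniform (affine minus similarity)
# subspace of tangent space at the model reference. u = 2 in 2D, 5 in 3D.
uniform_basis <- function(model) {
  X <- scale(model$reference, scale = FALSE)
  p <- nrow(X); k <- ncol(X)
  vecs <- function(Es) vapply(Es, function(E) as.numeric(X %*% t(E)),
                              numeric(p * k))
  elem <- list()
  for (i in seq_len(k)) for (j in seq_len(k)) {
    E <- matrix(0, k, k); E[i, j] <- 1
    elem[[length(elem) + 1L]] <- E
  }
  A <- vecs(elem)                                   # full affine span, k^2 dims
  sims <- list(diag(k))                             # scaling
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {   # rotation generators
    E <- matrix(0, k, k); E[i, j] <- 1; E[j, i] <- -1
    sims[[length(sims) + 1L]] <- E
  }
  S <- vecs(sims)
  Qs <- qr.Q(qr(S))
  resid <- A - Qs %*% crossprod(Qs, A)
  sv <- svd(resid)
  u_dim <- if (k == 2L) 2L else 5L
  sv$u[, seq_len(u_dim), drop = FALSE]
}

#' Uniform (affine) component scores of an aligned sample
#'
#' Projects residuals from the model reference onto an orthonormal basis of
#' the uniform shape subspace: the affine deformations of the reference
#' with translation, rotation, and scaling removed (2 dimensions in 2D,
#' 5 in 3D). This subspace is the orthogonal complement of the nonaffine
#' (partial-warp) subspace within centered tangent space.
#'
#' @inheritParams partial_warp_scores
#' @return an `n x u` score matrix (`u` = 2 or 5).
#' @export
uniform_component <- function(model, sup) {
  stopifnot(inherits(model, "gm_bending_energy"),
            inherits(sup, "gm_superimposition"))
  R <- reference_residuals(model, sup)
  U <- uniform_basis(model)
  scores <- R %*% U
  colnames(scores) <- paste0("U", seq_len(ncol(scores)))
  rownames(scores) <- sup$ids
  scores
}

#' Thin-plate spline deformation grid
#'
#' A regular grid over the source bounding box (2D; for 3D models a grid on
#' a caller-chosen coordinate plane through the source centroid) warped
#' through the model, for visualizing a shape deformation.
#'
#' @param model a `gm_tps`.
#' @param resolution number of grid lines per side (at least 2).
#' @param margin fractional expansion of the source bounding box.
#' @param plane for 3D models, the two coordinate axes spanning the grid
#'   plane (default `c(1, 2)`).
#' @return an object of class `gm_deformation_grid`: list of `rows` and
#'   `cols`, each a list of warped polylines (`m x k` matrices), plus the
#'   warped `nodes` and the model.
#' @export
deformation_grid <- function(model, resolution = 20L, margin = 0.05,
                             plane = c(1, 2)) {
  stopifnot(inherits(model, "gm_tps"))
  if (resolution < 2L) stop("resolution must be at least 2")
  k <- model$k
  S <- model$source
  ax <- if (k == 2L) c(1L, 2L) else as.integer(plane)
  rng <- apply(S[, ax, drop = FALSE], 2, range)
  pad <- margin * (rng[2, ] - rng[1, ])
  xs <- seq(rng[1, 1] - pad[1], rng[2, 1] + pad[1], length.out = resolution)
  ys <- seq(rng[1, 2] - pad[2], rng[2, 2] + pad[2], length.out = resolution)
  nodes2 <- as.matrix(expand.grid(xs, ys))
  nodes <- matrix(rep(colMeans(S), each = nrow(nodes2)), ncol = k)
  nodes[, ax] <- nodes2
  warped <- warp_points(model, nodes)
  idx <- matrix(seq_len(nrow(nodes)), resolution, resolution)
  rows <- lapply(seq_len(resolution), function(j) warped[idx[, j], , drop = FALSE])
  cols <- lapply(seq_len(resolution), function(i) warped[idx[i, ], , drop = FALSE])
  structure(list(rows = rows, cols = cols, nodes = warped, model = model),
            class = "gm_deformation_grid")
}

#' @export
plot.gm_deformation_grid <- function(x, axes = c(1, 2), lcol = "grey40",
                                     pcol = "firebrick", ...) {
  all_pts <- do.call(rbind, c(x$rows, x$cols))[, axes, drop = FALSE]
  plot(all_pts, type = "n", asp = 1, xlab = "", ylab = "", ...)
  for (pl in x$rows) graphics::lines(pl[, axes], col = lcol)
  for (pl in x$cols) graphics::lines(pl[, axes], col = lcol)
  graphics::points(x$model$target[, axes, drop = FALSE], pch = 19, col = pcol)
  invisible(x)
}
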