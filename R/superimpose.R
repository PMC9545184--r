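#' Centroid size
#'
#' The root summed squared distance of a configuration's landmarks from
#' their centroid; the standard measure of scale in landmark morphometrics.
#' It scales linearly under uniform scaling of the configuration.
#'
#' @param config a `p x k` matrix or `landmark_configuration`.
#' @return a positive scalar.
#' @export
centroid_size <- function(config) {
  m <- as.matrix(unclass(config))
  cs <- sqrt(sum(scale(m, scale = FALSE)^2))
  if (cs < sqrt(.Machine$double.eps))
    stop("degenerate configuration: all landmarks coincide (centroid size 0)")
  cs
}

# Optimal proper rotation R (det +1) minimizing ||A %*% R - B||_F for
# centered matrices A, B. 2D uses the closed-form angle; 3D the SVD with
# sign correction so no reflection is ever introduced.
optimal_rotation <- function(A, B) {
  k <- ncol(A)
  if (k == 2L) {
    num <- sum(A[, 2] * B[, 1] - A[, 1] * B[, 2])
    den <- sum(A[, 1] * B[, 1] + A[, 2] * B[, 2])
    th <- atan2(num, den)
    matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  } else {
    s <- svd(crossprod(A, B))
    d <- sign(det(s$u %*% t(s$v)))
    s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  }
}

#' Ordinary Procrustes alignment of one configuration onto another
#'
#' Translates (and optionally scales) the moving configuration and rotates
#' it by the proper rotation that minimizes the summed squared differences
#' to the target. Reflections are never used, so a reflected copy keeps a
#' positive residual.
#'
#' @param moving,target congruent `p x k` configurations.
#' @param scale if `TRUE`, both are scaled to unit centroid size before
#'   rotation (partial Procrustes); if `FALSE`, sizes are kept.
#' @return list with `aligned` (moving after alignment, in the target's
#'   centered frame), `rotation`, `residual` (root summed squared
#'   difference), and `target_centered`.
#' @export
opa_align <- function(moving, target, scale = TRUE) {
  A <- as.matrix(unclass(moving)); B <- as.matrix(unclass(target))
  if (!all(dim(A) == dim(B))) stop("configurations are not congruent in p, k")
  A <- scale(A, scale = FALSE); B <- scale(B, scale = FALSE)
  if (scale) {
    A <- A / centroid_size(A)
    B <- B / centroid_size(B)
  }
  if (qr(A)$rank < ncol(A) - 1L || qr(B)$rank < ncol(B) - 1L)
    stop("degenerate configuration: rank below k - 1")
  R <- optimal_rotation(A, B)
  aligned <- A %*% R
  list(aligned = aligned, rotation = R,
       residual = sqrt(sum((aligned - B)^2)), target_centered = B)
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition of a sample to its consensus: all
#' configurations are centered, scaled to unit centroid size (shape mode),
#' and rotated by proper rotations to the running consensus until the total
#' summed squared deviation changes by less than `tol`. The summed squared
#' deviation is non-increasing across iterations. For reproducibility the
#' final consensus is rotated to optimally align with configuration 1.
#'
#' Boas coordinates (form space: location and orientation standardized,
#' scale kept) are produced by re-multiplying each configuration's shape
#' coordinates by its centroid size.
#'
#' @param sample a [landmark_sample()].
#' @param mode `"shape"` (unit centroid size) or `"boas"` (sizes kept).
#' @param subset optional indices of landmarks on which to base the
#'   superimposition; all landmarks are carried along.
#' @param tol convergence tolerance on the change in summed squared deviation.
#' @param max_iter maximum number of iterations.
#' @return an object of class `gm_superimposition`: list with `aligned`
#'   (`n x pk` matrix, coordinates column-stacked per axis: all x, then all
#'   y, then all z), `coords`
#'   (`p x k x n` array), `mean_shape` (`p x k`), `centroid_sizes`, `mode`,
#'   `transforms` (per-case centering, scale and rotation mapping original
#'   to aligned coordinates), `iterations`, `converged`, `objective`
#'   (per-iteration summed squared deviation), `sample` (ids, names,
#'   covariates carried through).
#' @export
gpa <- function(sample, mode = c("shape", "boas"), subset = NULL,
                tol = 1e-10, max_iter = 100L) {
  mode <- match.arg(mode)
  stopifnot(inherits(sample, "landmark_sample"))
  if (sample$n < 2L) stop("GPA needs at least 2 configurations")
  p <- sample$p; k <- sample$k; n <- sample$n
  if (is.null(subset)) subset <- seq_len(p)

  centers <- matrix(0, n, k)
  sizes <- numeric(n)
  conf <- vector("list", n)
  for (i in seq_len(n)) {
    m <- sample$coords[, , i]
    ctr <- colMeans(m[subset, , drop = FALSE])
    m <- sweep(m, 2, ctr)
    cs <- sqrt(sum(m[subset, , drop = FALSE]^2))
    if (cs < sqrt(.Machine$double.eps))
      stop("degenerate configuration at case ", sample$ids[i])
    centers[i, ] <- ctr
    sizes[i] <- cs
    conf[[i]] <- m / cs
  }

  rots <- rep(list(diag(k)), n)
  consensus <- conf[[1]]
  objective <- numeric(0)
  prev <- Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_len(n)) {
      R <- optimal_rotation(conf[[i]][subset, , drop = FALSE],
                            consensus[subset, , drop = FALSE])
      conf[[i]] <- conf[[i]] %*% R
      rots[[i]] <- rots[[i]] %*% R
    }
    consensus <- Reduce(`+`, conf) / n
    consensus <- consensus / sqrt(sum(consensus[subset, , drop = FALSE]^2))
    obj <- sum(vapply(conf, function(m) sum((m - consensus)^2), numeric(1)))
    objective <- c(objective, obj)
    if (abs(prev - obj) < tol) { converged <- TRUE; break }
    prev <- obj
  }
  if (!converged)
    warning("GPA did not converge in ", max_iter,
            " iterations; returning last iterate")

  # orientation tie-break: rotate consensus (and sample) to configuration 1
  R0 <- optimal_rotation(consensus[subset, , drop = FALSE],
                         conf1_target <- {
                           m <- sweep(sample$coords[, , 1], 2, centers[1, ])
                           (m / sizes[1])[subset, , drop = FALSE]
                         })
  consensus <- consensus %*% R0
  for (i in seq_len(n)) {
    conf[[i]] <- conf[[i]] %*% R0
    rots[[i]] <- rots[[i]] %*% R0
  }

  if (mode == "boas") conf <- lapply(seq_len(n), function(i) conf[[i]] * sizes[i])
  coords <- array(unlist(conf), dim = c(p, k, n),
                  dimnames = dimnames(sample$coords))
  mean_shape <- if (mode == "boas") consensus * mean(sizes) else consensus
  structure(list(
    aligned = flatten_sample(coords),
    coords = coords,
    mean_shape = mean_shape,
    consensus = consensus,
    centroid_sizes = sizes,
    mode = mode,
    transforms = list(centers = centers, sizes = sizes, rotations = rots),
    iterations = iter, converged = converged, objective = objective,
    ids = sample$ids, landmark_names = sample$landmark_names,
    p = p, k = k, n = n, covariates = sample$covariates),
    class = "gm_superimposition")
}

#' @export
print.gm_superimposition <- function(x, ...) {
  cat("Procrustes superimposition (", x$mode, " mode): n = ", x$n,
      ", p = ", x$p, ", k = ", x$k, "\n", sep = "")
  cat("Converged:", x$converged, "after", x$iterations, "iterations\n")
  invisible(x)
}

#' Aligned sample from a superimposition
#'
#' @param sup a `gm_superimposition`.
#' @return a [landmark_sample()] of the aligned coordinates.
#' @export
aligned_sample <- function(sup) {
  stopifnot(inherits(sup, "gm_superimposition"))
  s <- landmark_sample(sup$coords, ids = sup$ids,
                       landmark_names = sup$landmark_names)
  s$covariates <- sup$covariates
  s
}

#' Size-shape (form) coordinates
#'
#' Augments the `pk` shape coordinates of a shape-mode superimposition with
#' the natural logarithm of centroid size, yielding `pk + 1` form variables.
#' Reconstructing a form from a point in this space requires re-scaling the
#' shape part by `exp(log cs)`.
#'
#' @param sup a shape-mode `gm_superimposition`.
#' @return list of class `gm_form_coordinates` with `values`
#'   (`n x (pk+1)` matrix, last column `log_cs`), `mean_shape`, `p`, `k`.
#' @export
size_shape_coordinates <- function(sup) {
  stopifnot(inherits(sup, "gm_superimposition"))
  if (sup$mode != "shape")
    stop("size-shape coordinates require a shape-mode superimposition")
  values <- cbind(sup$aligned, log_cs = log(sup$centroid_sizes))
  structure(list(values = values, mean_shape = sup$mean_shape,
                 p = sup$p, k = sup$k, ids = sup$ids,
                 covariates = sup$covariates),
            class = "gm_form_coordinates")
}

#' Reconstruct a form from a size-shape vector
#'
#' @param v a `pk + 1` vector (shape part followed by log centroid size).
#' @param p,k landmark count and dimension.
#' @return a `p x k` configuration scaled to `exp(log_cs)`.
#' @export
form_from_size_shape <- function(v, p, k) {
  stopifnot(length(v) == p * k + 1)
  matrix(v[seq_len(p * k)], p, k) * exp(v[p * k + 1])
}

#' Procrustes distance between two configurations
#'
#' Root summed squared distance between corresponding landmarks after
#' superimposing the two configurations: location, orientation, and (in
#' shape mode) scale are standardized. Symmetric in its arguments.
#'
#' @param a,b congruent configurations.
#' @param mode `"shape"` (scale out) or `"form"` (sizes kept).
#' @return a nonnegative scalar.
#' @export
procrustes_distance <- function(a, b, mode = c("shape", "form")) {
  mode <- match.arg(mode)
  fit <- opa_align(a, b, scale = (mode == "shape"))
  fit$residual
}

#' Tangent-space coordinates and rank report
#'
#' Mean-centered aligned coordinates of a superimposition, orthogonally
#' projected onto the tangent subspace at the consensus (the complement of
#' the translation, rotation, and — in shape mode — scaling directions),
#' with the numerical rank of the result. Centering and the optimal
#' rotations already annihilate the translation and rotation directions
#' exactly; the projection additionally removes the second-order component
#' along the consensus (scale) direction, so that only the `pk - 4` (2D)
#' or `pk - 7` (3D) geometrically independent dimensions of shape tangent
#' space remain — one more in Boas mode, where scale is a real degree of
#' freedom. No stereographic rescaling is applied: for the small shape
#' variation this package targets, the linear projection is the tangent
#' space.
#'
#' @param sup a `gm_superimposition`.
#' @param rank_tol singular values below `rank_tol` times the largest are
#'   treated as zero.
#' @return list with `residuals` (`n x pk` centered, projected matrix),
#'   `rank`, and `max_rank` (the geometric bound), and the `singular_values`.
#' @export
tangent_coordinates <- function(sup, rank_tol = 1e-8) {
  stopifnot(inherits(sup, "gm_superimposition"))
  X <- scale(sup$aligned, scale = FALSE)
  Q <- similarity_basis(sup$consensus, include_scale = sup$mode == "shape")
  X <- X - (X %*% Q) %*% t(Q)
  sv <- svd(X, nu = 0, nv = 0)$d
  rank <- sum(sv > rank_tol * max(sv))
  max_rank <- sup$p * sup$k - (if (sup$k == 2L) 4L else 7L) +
    (if (sup$mode == "boas") 1L else 0L)
  list(residuals = X, rank = rank, max_rank = max_rank,
       singular_values = sv)
}

# Orthonormal basis (pk x d) of the similarity directions at a reference:
# k translations, k(k-1)/2 rotation generators, optionally the scaling
# direction (the reference itself).
similarity_basis <- function(reference, include_scale = TRUE) {
  m <- scale(as.matrix(reference), scale = FALSE)
  p <- nrow(m); k <- ncol(m)
  cols <- list()
  for (c in seq_len(k)) {                    # translations
    v <- matrix(0, p, k); v[, c] <- 1
    cols[[length(cols) + 1L]] <- as.numeric(v)
  }
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {   # rotations
    G <- matrix(0, k, k); G[i, j] <- 1; G[j, i] <- -1
    cols[[length(cols) + 1L]] <- as.numeric(m %*% G)
  }
  if (include_scale) cols[[length(cols) + 1L]] <- as.numeric(m)
  qr.Q(qr(do.call(cbind, cols)))
}
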