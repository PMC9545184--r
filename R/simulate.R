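#' Regular grid template
#'
#' A unit-spaced lattice of landmarks centered at the origin, the standard
#' template for simulation experiments, with cell membership recorded for
#' per-cell analyses of shape variance at different spatial scales.
#'
#' @param rows,cols lattice extent (at least 2 each).
#' @param layers optional third dimension for a 3D lattice.
#' @return an object of class `gm_grid_template`: list with `coords`
#'   (`p x k` configuration), `rows`, `cols`, `layers`, and `cells`
#'   (list of vertex-index sets of the unit cells).
#' @export
grid_template <- function(rows, cols, layers = NULL) {
  if (rows < 2L || cols < 2L) stop("rows and cols must be at least 2")
  k <- if (is.null(layers)) 2L else 3L
  xs <- seq_len(cols) - (cols + 1) / 2
  ys <- seq_len(rows) - (rows + 1) / 2
  if (k == 2L) {
    g <- expand.grid(x = xs, y = ys)
    coords <- as.matrix(g)
    index <- matrix(seq_len(nrow(coords)), cols, rows)  # [col, row]
    cells <- list()
    for (r in seq_len(rows - 1L)) for (c in seq_len(cols - 1L))
      cells[[length(cells) + 1L]] <-
        c(index[c, r], index[c + 1L, r], index[c + 1L, r + 1L], index[c, r + 1L])
  } else {
    if (layers < 2L) stop("layers must be at least 2")
    zs <- seq_len(layers) - (layers + 1) / 2
    g <- expand.grid(x = xs, y = ys, z = zs)
    coords <- as.matrix(g)
    index <- array(seq_len(nrow(coords)), dim = c(cols, rows, layers))
    cells <- list()
    for (l in seq_len(layers - 1L)) for (r in seq_len(rows - 1L))
      for (c in seq_len(cols - 1L))
        cells[[length(cells) + 1L]] <-
          as.integer(index[c:(c + 1L), r:(r + 1L), l:(l + 1L)])
  }
  rownames(coords) <- paste0("L", seq_len(nrow(coords)))
  structure(list(coords = coords, rows = rows, cols = cols,
                 layers = if (k == 3L) layers else NULL, cells = cells, k = k),
            class = "gm_grid_template")
}

as_template_matrix <- function(template) {
  if (inherits(template, "gm_grid_template")) template$coords
  else as.matrix(unclass(template))
}

#' Sample from the Mardia-Dryden (isotropic landmark noise) distribution
#'
#' Independent Gaussian noise with a common standard deviation is added to
#' every landmark coordinate of the template: the standard "pure noise"
#' null model of landmark variation, under which centroid size is
#' uncorrelated with shape and the shape distribution is isotropic.
#'
#' @param template a `gm_grid_template` or `p x k` configuration.
#' @param n number of configurations.
#' @param sigma coordinate standard deviation (template length units).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a [landmark_sample()].
#' @export
sample_mardia_dryden <- function(template, n, sigma, seed = NULL) {
  M <- as_template_matrix(template)
  if (sigma <= 0) stop("sigma must be positive")
  if (!is.null(seed)) set.seed(seed)
  p <- nrow(M); k <- ncol(M)
  noise <- array(stats::rnorm(p * k * n, sd = sigma), dim = c(p, k, n))
  coords <- array(rep(M, n), dim = c(p, k, n)) + noise
  landmark_sample(coords, landmark_names = rownames(M))
}

#' Sample from the self-similar shape distribution
#'
#' Draws independent partial-warp scores with standard deviation
#' proportional to `lambda^(-s/2)` — variance proportional to the inverse
#' bending-energy eigenvalue raised to `s` — so that nonaffine shape
#' variance is the same at every spatial scale. The scale exponent is
#' `s = 1` for 2D and `s = 2` for 3D landmarks, matching the log-log slope
#' of partial-warp variance on inverse bending energy that defines
#' self-similarity in each dimension. Affine (uniform) variation is zero by
#' default. Landmark covariance under this model decays with interlandmark
#' distance, unlike under the Mardia-Dryden model.
#'
#' @param template a `gm_grid_template` or `p x k` configuration.
#' @param n number of configurations.
#' @param sigma standard deviation of the largest-scale partial warp score;
#'   the other warps' SDs scale as `(lambda/lambda_min)^(-s/2)`.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param s scale exponent; defaults to 1 (2D) or 2 (3D).
#' @param be_model optional precomputed [bending_energy_matrix()] of the
#'   template.
#' @return a [landmark_sample()].
#' @export
sample_self_similar <- function(template, n, sigma = 0.05, seed = NULL,
                                s = NULL, be_model = NULL) {
  M <- as_template_matrix(template)
  p <- nrow(M); k <- ncol(M)
  if (is.null(s)) s <- if (k == 2L) 1 else 2
  if (is.null(be_model)) be_model <- bending_energy_matrix(M)
  if (!is.null(seed)) set.seed(seed)
  lam <- be_model$eigenvalues
  sds <- sigma * (lam / min(lam))^(-s / 2)
  q <- length(lam)
  coords <- array(NA_real_, dim = c(p, k, n))
  W <- be_model$partial_warps
  for (i in seq_len(n)) {
    scores <- matrix(stats::rnorm(q * k), q, k) * sds
    coords[, , i] <- M + W %*% scores
  }
  landmark_sample(coords, landmark_names = rownames(M))
}

#' Four-landmark integration demonstration
#'
#' Four 2D landmarks varying isotropically around a mean shape (by default
#' the unit square) make the geometric point that interlandmark distances
#' and Procrustes shape coordinates are necessarily correlated even under
#' pure noise: shape has only four degrees of freedom (form: five), fewer
#' than the six distances or eight shape coordinates. Distance pairs
#' sharing a landmark reach correlations of about 0.35 on the square, and
#' shape coordinates correlations up to about +/-0.5, regardless of the
#' noise amplitude.
#'
#' @param n number of configurations (several thousand recommended for
#'   stable correlations).
#' @param sigma isotropic coordinate SD, in units of the square's side.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param template optional 4 x 2 mean configuration (default unit square).
#' @return list with the `sample`, `distances` (`n x 6` interlandmark
#'   distances), `distance_pairs_sharing` (logical matrix over distance
#'   pairs), `distance_correlations`, `shape_coordinates` (`n x 8`),
#'   `shape_correlations`, `max_shared_distance_correlation`,
#'   `max_shape_correlation`, and the shape/Boas covariance ranks.
#' @export
four_landmark_demo <- function(n, sigma = 0.05, seed = NULL, template = NULL) {
  if (is.null(template))
    template <- cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1))
  template <- as.matrix(template)
  stopifnot(nrow(template) == 4L, ncol(template) == 2L)
  samp <- sample_mardia_dryden(template, n, sigma, seed)

  pairs <- utils::combn(4L, 2L)
  dists <- t(apply(samp$coords, 3, function(m) {
    d <- stats::dist(m)
    as.numeric(d)
  }))
  colnames(dists) <- apply(pairs, 2, function(ij) paste0("d", ij[1], ij[2]))
  shares <- outer(seq_len(6), seq_len(6), Vectorize(function(a, b)
    a != b && length(intersect(pairs[, a], pairs[, b])) > 0))
  dc <- stats::cor(dists)

  sup <- gpa(samp, mode = "shape")
  sc <- stats::cor(sup$aligned)
  boas <- gpa(samp, mode = "boas")

  rank_of <- function(sup_obj) tangent_coordinates(sup_obj)$rank
  list(sample = samp,
       distances = dists,
       distance_pairs_sharing = shares,
       distance_correlations = dc,
       shape_coordinates = sup$aligned,
       shape_correlations = sc,
       max_shared_distance_correlation = max(dc[shares]),
       max_shape_correlation = max(abs(sc[upper.tri(sc)])),
       shape_rank = rank_of(sup),
       boas_rank = rank_of(boas))
}

# Smooth low-bending-energy effect vector: random weights on the
# largest-scale partial warps, so simulated "biological" effects look like
# coherent deformations rather than white noise. Returns a p x k matrix of
# unit Frobenius norm.
smooth_effect_vector <- function(template, n_warps = 3L) {
  M <- as_template_matrix(template)
  k <- ncol(M)
  bem <- bending_energy_matrix(M)
  n_warps <- min(n_warps, length(bem$eigenvalues))
  W <- bem$partial_warps[, seq_len(n_warps), drop = FALSE]
  wts <- matrix(stats::rnorm(n_warps * k), n_warps, k)
  V <- W %*% wts
  V / sqrt(sum(V^2))
}

#' Simulate a two-group study sample with allometry and a covariate effect
#'
#' Emulates the structure of a two-sex landmark study: two groups of equal
#' size whose shapes differ by a mean-difference vector, with allometric
#' shape change along a second vector proportional to the deviation of log
#' centroid size from the group mean, a continuous covariate (for example a
#' body-mass-index-like measure) acting along a third vector, and isotropic
#' Mardia-Dryden landmark noise on top. Sizes are lognormal around
#' group-specific means. Effect vectors default to random smooth
#' (low-bending-energy) patterns.
#'
#' @param template a `gm_grid_template` or `p x k` configuration.
#' @param n_per_group cases per group (default 100, two groups).
#' @param sigma isotropic landmark noise SD.
#' @param group_effect magnitude of the group mean shape difference, or a
#'   `p x k` effect matrix.
#' @param allometry magnitude of the allometric vector per unit log size,
#'   or a `p x k` matrix.
#' @param covariate_effect magnitude of the covariate vector per covariate
#'   SD, or a `p x k` matrix.
#' @param size_log_mean per-group mean of log centroid scale
#'   (length 2; default `c(0, 0.05)`: the second group slightly larger).
#' @param size_log_sd SD of log size within group (0.1: about +/-10% size
#'   variation, typical of within-age-group biological samples).
#' @param covariate_mean,covariate_sd covariate distribution (shared).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list with `sample` (a [landmark_sample()] with covariates
#'   attached: `sex`, `size`, `covariate`), and the true `group_vector`,
#'   `allometry_vector`, `covariate_vector` (`p x k` matrices).
#' @export
sample_group_study <- function(template, n_per_group = 100L, sigma = 0.02,
                               group_effect = 0.1, allometry = 0.3,
                               covariate_effect = 0.08,
                               size_log_mean = c(0, 0.05), size_log_sd = 0.1,
                               covariate_mean = 22, covariate_sd = 3,
                               seed = NULL) {
  M <- as_template_matrix(template)
  p <- nrow(M); k <- ncol(M)
  if (!is.null(seed)) set.seed(seed)
  as_effect <- function(x) {
    if (is.matrix(x)) x else x * smooth_effect_vector(M)
  }
  gv <- as_effect(group_effect)
  av <- as_effect(allometry)
  cv <- as_effect(covariate_effect)
  n <- 2L * n_per_group
  sex <- rep(c("F", "M"), each = n_per_group)
  logsize <- stats::rnorm(n, mean = size_log_mean[as.integer(sex == "M") + 1L],
                          sd = size_log_sd)
  covar <- stats::rnorm(n, covariate_mean, covariate_sd)
  coords <- array(NA_real_, dim = c(p, k, n))
  for (i in seq_len(n)) {
    shape <- M +
      (sex[i] == "M") * gv +
      (logsize[i] - size_log_mean[(sex[i] == "M") + 1L]) * av +
      ((covar[i] - covariate_mean) / covariate_sd) * cv +
      matrix(stats::rnorm(p * k, sd = sigma), p, k)
    coords[, , i] <- shape * exp(logsize[i])
  }
  samp <- landmark_sample(coords, landmark_names = rownames(M))
  samp <- attach_covariates(samp, data.frame(
    id = samp$ids, sex = sex, size = exp(logsize), covariate = covar,
    stringsAsFactors = FALSE))
  list(sample = samp, group_vector = gv, allometry_vector = av,
       covariate_vector = cv)
}

#' Simulate a bilaterally symmetric sample with asymmetry components
#'
#' Per case: symmetric individual variation (isotropic noise projected onto
#' the symmetric subspace of the symmetrized template), a fixed directional
#' asymmetry vector, an individual fluctuating asymmetry deviation
#' (Gaussian in the asymmetric subspace), and, per replicate, independent
#' measurement error on all coordinates.
#'
#' @param template a `p x k` configuration or `gm_grid_template`; it is
#'   symmetrized under `map` before use.
#' @param map a [symmetry_map()].
#' @param n number of individuals.
#' @param sym_sd SD of symmetric individual variation (per coordinate).
#' @param da magnitude of directional asymmetry, or a `p x k` matrix.
#' @param fa_sd SD of fluctuating asymmetry (per coordinate, before
#'   projection onto the asymmetric subspace).
#' @param error_sd measurement error SD per replicate (0 = no error).
#' @param replicates replicate measurements per individual.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list with `sample` (ids `ind<i>_rep<j>`), `individual`,
#'   `replicate` vectors, and the true `da_vector` (`p x k`).
#' @export
sample_bilateral_asymmetry <- function(template, map, n, sym_sd = 0.02,
                                       da = 0.05, fa_sd = 0.01,
                                       error_sd = 0, replicates = 1L,
                                       seed = NULL) {
  M <- as_template_matrix(template)
  p <- nrow(M); k <- ncol(M)
  if (!is.null(seed)) set.seed(seed)
  M <- (M + relabel_reflect_matrix(M, map)) / 2   # symmetric template
  sym_part <- function(V) (V + relabel_reflect_matrix(V, map)) / 2
  # asymmetric tangent component: anti-invariant part with the similarity
  # directions (which superimposition absorbs) projected out
  Qsim <- similarity_basis(M, include_scale = TRUE)
  asym_part <- function(V) {
    A <- (V - relabel_reflect_matrix(V, map)) / 2
    v <- as.numeric(A)
    matrix(v - Qsim %*% crossprod(Qsim, v), p, k)
  }
  dav <- if (is.matrix(da)) asym_part(da) else {
    v <- asym_part(matrix(stats::rnorm(p * k), p, k))
    if (sum(v^2) == 0) stop("symmetry map leaves no asymmetric subspace")
    da * v / sqrt(sum(v^2))
  }
  N <- n * replicates
  coords <- array(NA_real_, dim = c(p, k, N))
  ids <- character(N)
  individual <- integer(N); replicate <- integer(N)
  idx <- 0L
  for (i in seq_len(n)) {
    si <- sym_part(matrix(stats::rnorm(p * k, sd = sym_sd), p, k))
    fi <- asym_part(matrix(stats::rnorm(p * k, sd = fa_sd), p, k))
    base <- M + si + dav + fi
    for (r in seq_len(replicates)) {
      idx <- idx + 1L
      err <- if (error_sd > 0) matrix(stats::rnorm(p * k, sd = error_sd), p, k)
             else matrix(0, p, k)
      coords[, , idx] <- base + err
      ids[idx] <- paste0("ind", i, "_rep", r)
      individual[idx] <- i; replicate[idx] <- r
    }
  }
  samp <- landmark_sample(coords, ids = ids, landmark_names = rownames(M))
  list(sample = samp, individual = individual, replicate = replicate,
       da_vector = dav)
}
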