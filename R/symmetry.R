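#' Bilateral symmetry map
#'
#' Describes the object symmetry of a landmark scheme: pairs of left/right
#' landmarks that exchange under reflection, midline landmarks that map to
#' themselves, and the coordinate axis to negate. Pairs and midline must
#' cover every landmark exactly once.
#'
#' @param pairs two-column matrix (or list of length-2 vectors) of paired
#'   left/right landmark indices.
#' @param midline integer vector of midline landmark indices.
#' @param p total number of landmarks.
#' @param axis coordinate axis negated by the reflection (default 1).
#' @return an object of class `gm_symmetry_map`.
#' @export
symmetry_map <- function(pairs, midline = integer(0), p, axis = 1L) {
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  midline <- as.integer(midline)
  used <- c(as.integer(pairs), midline)
  if (any(pairs[, 1] == pairs[, 2])) stop("pair indices must be distinct")
  if (anyDuplicated(used)) stop("pairs and midline indices overlap")
  if (!setequal(used, seq_len(p)))
    stop("pairs and midline must cover all ", p, " landmarks exactly once")
  perm <- seq_len(p)
  perm[pairs[, 1]] <- pairs[, 2]
  perm[pairs[, 2]] <- pairs[, 1]
  structure(list(pairs = pairs, midline = midline, p = as.integer(p),
                 axis = as.integer(axis), perm = perm),
            class = "gm_symmetry_map")
}

# Relabelled reflection of a p x k matrix: negate the reflection axis, then
# swap paired landmark rows. An exact orthogonal involution on the flat
# coordinate space.
relabel_reflect_matrix <- function(m, map) {
  m2 <- m
  m2[, map$axis] <- -m2[, map$axis]
  m2[map$perm, , drop = FALSE]
}

#' Relabelled reflection of a configuration
#'
#' Negates the reflection axis and swaps paired landmark labels, keeping
#' midline labels in place. Applying it twice restores the input. A
#' perfectly symmetric configuration coincides with its relabelled
#' reflection after Procrustes alignment.
#'
#' @param config a `p x k` configuration.
#' @param map a [symmetry_map()].
#' @return the reflected configuration (same class as input).
#' @export
relabel_reflect <- function(config, map) {
  m <- as.matrix(unclass(config))
  if (nrow(m) != map$p) stop("configuration and symmetry map landmark counts differ")
  out <- relabel_reflect_matrix(m, map)
  if (inherits(config, "landmark_configuration"))
    landmark_configuration(out, id = attr(config, "id"),
                           landmark_names = rownames(m))
  else out
}

# Reflection involution applied to the n x pk flattened matrix.
relabel_reflect_flat <- function(X, map, p, k) {
  arr <- unflatten_sample(X, p, k)
  for (i in seq_len(dim(arr)[3])) arr[, , i] <- relabel_reflect_matrix(arr[, , i], map)
  flatten_sample(arr)
}

#' Joint Procrustes superimposition of a sample and its reflections
#'
#' Runs GPA on the `2n` configurations consisting of the originals and
#' their relabelled reflections. The consensus is exactly symmetrized
#' (projected onto the reflection-invariant subspace) and all copies are
#' aligned to it in a final pass, so the consensus is invariant under the
#' relabelled reflection to machine precision.
#'
#' @param sample a [landmark_sample()].
#' @param map a [symmetry_map()].
#' @return a `gm_superimposition` of `2n` cases (originals first, then
#'   reflections, ids suffixed `_refl`), with `symmetry_map` attached.
#' @export
symmetry_gpa <- function(sample, map) {
  stopifnot(inherits(sample, "landmark_sample"))
  p <- sample$p; k <- sample$k; n <- sample$n
  refl <- sample$coords
  for (i in seq_len(n)) refl[, , i] <- relabel_reflect_matrix(sample$coords[, , i], map)
  both <- landmark_sample(
    array(c(sample$coords, refl), dim = c(p, k, 2L * n)),
    ids = c(sample$ids, paste0(sample$ids, "_refl")),
    landmark_names = sample$landmark_names)
  sup <- gpa(both, mode = "shape")

  # rotate the consensus into its symmetric pose: the orientation that
  # minimizes the distance to its own relabelled reflection. Maximizing
  # tr(J Q' (m'Pm) Q) over rotations Q reduces to taking the reflection
  # axis along the smallest-eigenvalue eigenvector of sym(m'Pm).
  m <- sup$consensus
  Pm <- m[map$perm, , drop = FALSE]
  S <- (crossprod(m, Pm) + crossprod(Pm, m)) / 2
  es <- eigen(S, symmetric = TRUE)
  q1 <- es$vectors[, k]
  if (q1[which.max(abs(q1))] < 0) q1 <- -q1
  comp <- qr.Q(qr(cbind(q1, diag(k))))[, 2:k, drop = FALSE]
  Q <- matrix(0, k, k)
  Q[, map$axis] <- q1
  Q[, setdiff(seq_len(k), map$axis)] <- comp
  if (det(Q) < 0) {
    j <- setdiff(seq_len(k), map$axis)[1]
    Q[, j] <- -Q[, j]
  }
  m <- m %*% Q

  # exact symmetrization of the posed consensus, then a final re-alignment
  ms <- (m + relabel_reflect_matrix(m, map)) / 2
  if (sqrt(sum(ms^2)) < 0.2)
    stop("consensus nearly cancels under reflection; check the symmetry map")
  ms <- sweep(ms, 2, colMeans(ms))
  ms <- ms / sqrt(sum(ms^2))
  # polish the symmetric fixed point: realign, re-average, re-project
  coords <- sup$coords
  for (pass in 1:3) {
    for (i in seq_len(2L * n)) {
      R <- optimal_rotation(coords[, , i], ms)
      coords[, , i] <- coords[, , i] %*% R
    }
    mnew <- apply(coords, c(1, 2), mean)
    mnew <- (mnew + relabel_reflect_matrix(mnew, map)) / 2
    mnew <- sweep(mnew, 2, colMeans(mnew))
    ms <- mnew / sqrt(sum(mnew^2))
  }
  for (i in seq_len(2L * n)) {
    R <- optimal_rotation(coords[, , i], ms)
    coords[, , i] <- coords[, , i] %*% R
  }
  sup$consensus <- sup$mean_shape <- ms
  sup$coords <- coords
  sup$aligned <- flatten_sample(coords)
  sup$symmetry_map <- map
  sup$n_original <- n
  sup
}

#' Decompose a sample into symmetric and asymmetry components
#'
#' After the joint superimposition of originals and relabelled reflections,
#' each aligned original `o` is split exactly into a symmetric component
#' `s = (o + reflect(o)) / 2` (invariant under the relabelled reflection)
#' and an asymmetry vector `a = o - reflect(o)`, so that `o = s + a / 2`.
#' The directional asymmetry is the sample mean of the asymmetry vectors;
#' fluctuating asymmetry the individual deviations from it. Symmetric and
#' asymmetry components occupy exactly orthogonal subspaces of tangent
#' space. The magnitude `|a|` of a case's asymmetry vector equals the
#' Procrustes distance between the case and its relabelled reflection (up
#' to the joint-alignment convention).
#'
#' The sums of squares are reported on the `2n`-copy convention: the total
#' Procrustes sum of squares of originals plus reflections about the
#' symmetric consensus decomposes as
#' `SS_total = SS_symmetric + SS_directional + SS_fluctuating` with
#' `SS_directional = n |mean(a)|^2 / 2` and
#' `SS_fluctuating = sum |a - mean(a)|^2 / 2`. Proportions are reported
#' both of the total and of the asymmetric part only.
#'
#' @param sample a [landmark_sample()].
#' @param map a [symmetry_map()].
#' @return an object of class `gm_asymmetry`: list with `symmetric`
#'   (`n x pk`), `asymmetry` (`n x pk`), `directional` (`pk` vector),
#'   `fluctuating` (`n x pk`, rows summing to zero), `anova` (data frame of
#'   SS and proportions), `consensus`, `map`, `p`, `k`, `n`, `sup`.
#' @export
decompose_asymmetry <- function(sample, map) {
  sup <- symmetry_gpa(sample, map)
  n <- sup$n_original; p <- sup$p; k <- sup$k
  O <- sup$aligned[seq_len(n), , drop = FALSE]
  Orefl <- relabel_reflect_flat(O, map, p, k)
  symmetric <- (O + Orefl) / 2
  asymmetry <- O - Orefl
  directional <- colMeans(asymmetry)
  fluctuating <- sweep(asymmetry, 2, directional)
  mvec <- as.numeric(sup$consensus)
  ss_sym <- 2 * sum(sweep(symmetric, 2, mvec)^2)
  ss_da <- n * sum(directional^2) / 2
  ss_fa <- sum(fluctuating^2) / 2
  ss_tot <- ss_sym + ss_da + ss_fa
  anova <- data.frame(
    component = c("symmetric", "directional", "fluctuating", "total"),
    SS = c(ss_sym, ss_da, ss_fa, ss_tot),
    prop_total = c(ss_sym, ss_da, ss_fa, ss_tot) / ss_tot,
    prop_asymmetric = c(NA, ss_da, ss_fa, NA) / (ss_da + ss_fa))
  structure(list(symmetric = symmetric, asymmetry = asymmetry,
                 directional = directional, fluctuating = fluctuating,
                 anova = anova, consensus = sup$consensus, map = map,
                 p = p, k = k, n = n, sup = sup),
            class = "gm_asymmetry")
}

#' Procrustes ANOVA of symmetric variation, asymmetry, and error
#'
#' Sum-of-squares decomposition of a bilaterally symmetric sample into
#' symmetric individual variation, directional asymmetry, fluctuating
#' asymmetry, and — when balanced replicate measurements are available —
#' measurement error. Sums of squares are additive to the total within
#' numerical precision (`2n`-copy convention as in
#' [decompose_asymmetry()]). Mean squares use degrees of freedom from the
#' usual counting argument on the symmetric/asymmetric tangent subspaces.
#'
#' @param sample a [landmark_sample()] (all replicates included as cases).
#' @param map a [symmetry_map()].
#' @param replicates optional vector (length `n`) of individual labels; if
#'   given, each individual must have the same number of replicates.
#' @return data frame with components, SS, df, MS, and proportions.
#' @export
procrustes_anova_symmetry <- function(sample, map, replicates = NULL) {
  dec <- decompose_asymmetry(sample, map)
  p <- dec$p; k <- dec$k
  # reflection-invariant (+1) and anti-invariant (-1) eigenspace dimensions
  # of the involution, minus the similarity transforms falling in each
  n_pair <- nrow(map$pairs); n_mid <- length(map$midline)
  sym_dim <- n_pair * k + n_mid * (k - 1L) - (if (k == 2L) 2L else 4L)
  asym_dim <- n_pair * k + n_mid - (if (k == 2L) 2L else 3L)
  tangent_dim <- p * k - (if (k == 2L) 4L else 7L)
  if (is.null(replicates)) {
    return(dec$anova)
  }
  replicates <- as.character(replicates)
  if (length(replicates) != dec$n)
    stop("replicates must label every case")
  tab <- table(replicates)
  if (length(unique(tab)) != 1L)
    stop("unbalanced replicates: each individual needs the same number of replicates")
  r <- unname(tab[1]); n_ind <- length(tab)
  if (r < 2L) stop("at least 2 replicates per individual are required")
  ind <- factor(replicates, levels = unique(replicates))

  S <- dec$symmetric; A <- dec$asymmetry
  mvec <- as.numeric(dec$consensus)
  s_bar <- apply(S, 2, function(col) tapply(col, ind, mean))
  a_bar <- apply(A, 2, function(col) tapply(col, ind, mean))
  dirv <- colMeans(A)

  ss_ind <- 2 * r * sum(sweep(s_bar, 2, mvec)^2)
  ss_da <- n_ind * r * sum(dirv^2) / 2
  ss_fa <- r * sum(sweep(a_bar, 2, dirv)^2) / 2
  ss_err_sym <- 2 * sum((S - s_bar[as.integer(ind), , drop = FALSE])^2)
  ss_err_asym <- sum((A - a_bar[as.integer(ind), , drop = FALSE])^2) / 2
  ss_err <- ss_err_sym + ss_err_asym
  ss_tot <- ss_ind + ss_da + ss_fa + ss_err
  df <- c((n_ind - 1L) * sym_dim, asym_dim, (n_ind - 1L) * asym_dim,
          n_ind * (r - 1L) * tangent_dim, NA)
  ss <- c(ss_ind, ss_da, ss_fa, ss_err, ss_tot)
  data.frame(
    component = c("individuals", "directional", "fluctuating", "error", "total"),
    SS = ss, df = df, MS = ss / df,
    prop_total = ss / ss_tot,
    prop_asymmetric = c(NA, ss_da, ss_fa, NA, NA) / (ss_da + ss_fa))
}

#' Principal components of asymmetry about the origin
#'
#' Ordinary PCA of asymmetry vectors maximizes variance about the sample
#' mean and therefore only sees fluctuating asymmetry. Because asymmetry
#' vectors have a natural origin — the zero vector is perfect symmetry —
#' it is more informative to maximize the mean squared deviation from
#' zero, achieved by a singular value decomposition of the uncentered
#' asymmetry matrix. Scores are then read as vectors from the origin, so
#' both the pattern and the magnitude of asymmetry are displayed, and a
#' strong directional component emerges along the leading axes.
#'
#' @param decomp a `gm_asymmetry` from [decompose_asymmetry()], or an
#'   `n x q` asymmetry matrix.
#' @return list with `components` (right singular vectors, columns),
#'   `singular_values`, `scores` (`n x m`), and
#'   `directional_projection` (fraction of the directional vector's squared
#'   norm captured by each component, cumulative).
#' @export
uncentered_asymmetry_pca <- function(decomp) {
  A <- if (inherits(decomp, "gm_asymmetry")) decomp$asymmetry else as.matrix(decomp)
  if (all(abs(A) < .Machine$double.eps))
    stop("asymmetry matrix is all zero")
  sv <- svd(A)
  keep <- sv$d > 1e-12 * max(sv$d)
  comp <- sv$v[, keep, drop = FALSE]
  scores <- A %*% comp
  out <- list(components = comp, singular_values = sv$d[keep], scores = scores)
  if (inherits(decomp, "gm_asymmetry")) {
    d <- decomp$directional
    proj <- as.numeric(crossprod(comp, d))
    out$directional_projection <- cumsum(proj^2) / sum(d^2)
  }
  out
}

#' Symmetrize a sample
#'
#' Replaces each configuration by its symmetric component (the average of
#' the aligned configuration and its relabelled reflection), removing all
#' asymmetric variation. Output configurations are exactly invariant under
#' the relabelled reflection, and total variance cannot exceed the input
#' total variance.
#'
#' @param sample a [landmark_sample()].
#' @param map a [symmetry_map()].
#' @return a [landmark_sample()] of symmetric components (aligned, unit
#'   centroid size scale).
#' @export
symmetrize_sample <- function(sample, map) {
  dec <- decompose_asymmetry(sample, map)
  coords <- unflatten_sample(dec$symmetric, dec$p, dec$k)
  landmark_sample(coords, ids = sample$ids,
                  landmark_names = sample$landmark_names)
}
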