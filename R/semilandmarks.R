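#' Semilandmark scheme
#'
#' Partitions a landmark scheme into fixed anatomical landmarks, ordered
#' curve chains of semilandmarks, and surface semilandmarks. Only the
#' coordinate orthogonal to the curve or surface carries anatomical signal
#' at a semilandmark; the position along the structure is arbitrary and is
#' estimated by sliding. Curve chains are ordered polylines and may include
#' fixed landmarks as anchors (anchors never slide but shape the tangents).
#'
#' @param fixed integer indices of fixed anatomical landmarks.
#' @param curves list of integer vectors, each an ordered chain (length
#'   at least 2) along a curve.
#' @param surface integer indices of surface semilandmarks.
#' @param p total number of landmarks.
#' @return an object of class `gm_semilandmark_scheme`.
#' @export
semilandmark_scheme <- function(fixed = integer(0), curves = list(),
                                surface = integer(0), p) {
  fixed <- as.integer(fixed)
  surface <- as.integer(surface)
  curves <- lapply(curves, as.integer)
  if (any(vapply(curves, length, integer(1)) < 2L))
    stop("every curve chain needs at least 2 points")
  curve_semis <- setdiff(unlist(curves), fixed)
  groups <- c(fixed, curve_semis, surface)
  if (anyDuplicated(groups))
    stop("fixed, curve, and surface index sets must be disjoint")
  if (length(groups) && max(groups) > p) stop("index exceeds p = ", p)
  structure(list(fixed = fixed, curves = curves, surface = surface,
                 curve_semis = curve_semis, p = as.integer(p)),
            class = "gm_semilandmark_scheme")
}

#' Unit tangents along curve chains
#'
#' Central differences of chain neighbors for interior points, one-sided
#' differences at chain endpoints, all normalized to unit length.
#'
#' @param config a `p x k` configuration.
#' @param scheme a [semilandmark_scheme()].
#' @return a `p x k` matrix; rows of curve points hold unit tangents, all
#'   other rows are zero.
#' @export
estimate_curve_tangents <- function(config, scheme) {
  m <- as.matrix(unclass(config))
  k <- ncol(m)
  tang <- matrix(0, nrow(m), k)
  for (chain in scheme$curves) {
    L <- length(chain)
    for (j in seq_len(L)) {
      # central/one-sided difference; widen the window if neighbors coincide
      nd <- 0
      w <- 1L
      while (nd < 1e-12 && w < L) {
        lo <- max(1L, j - w); hi <- min(L, j + w)
        d <- m[chain[hi], ] - m[chain[lo], ]
        nd <- sqrt(sum(d^2))
        w <- w + 1L
      }
      if (nd < 1e-12)
        stop("coincident chain neighbors at landmark index ", chain[j])
      tang[chain[j], ] <- d / nd
    }
  }
  tang
}

#' Orthonormal tangent planes at surface semilandmarks
#'
#' Builds two orthonormal tangent vectors orthogonal to the surface normal
#' at every surface semilandmark. Normals are either supplied directly or
#' taken from the nearest face of a triangulated mesh.
#'
#' @param config a `p x k` configuration (`k` = 3 for meshes).
#' @param scheme a [semilandmark_scheme()].
#' @param mesh optional `gm_mesh` (see [read_obj()]).
#' @param normals optional `p x k` matrix of outward normals.
#' @param far_tol warn when a point is farther from the mesh than this
#'   fraction of the mesh bounding-box diagonal.
#' @return list with `t1`, `t2` (`p x k` matrices; zero rows off-surface)
#'   and `normals`.
#' @export
estimate_surface_tangent_planes <- function(config, scheme, mesh = NULL,
                                            normals = NULL, far_tol = 0.1) {
  m <- as.matrix(unclass(config))
  k <- ncol(m)
  if (is.null(normals)) {
    if (is.null(mesh)) stop("surface semilandmarks need a mesh or supplied normals")
    normals <- matrix(0, nrow(m), k)
    diam <- sqrt(sum((apply(mesh$vertices, 2, max) -
                      apply(mesh$vertices, 2, min))^2))
    for (i in scheme$surface) {
      np <- nearest_on_mesh(m[i, ], mesh)
      if (np$distance > far_tol * diam)
        warning("surface semilandmark ", i, " is far from the mesh (",
                signif(np$distance, 3), ")")
      normals[i, ] <- np$normal
    }
  }
  t1 <- matrix(0, nrow(m), k)
  t2 <- matrix(0, nrow(m), k)
  for (i in scheme$surface) {
    nrm <- normals[i, ]
    nn <- sqrt(sum(nrm^2))
    if (nn < 1e-12) stop("zero normal at surface semilandmark ", i)
    nrm <- nrm / nn
    seed <- if (abs(nrm[1]) < 0.9) c(1, 0, 0)[seq_len(k)] else c(0, 1, 0)[seq_len(k)]
    a <- seed - sum(seed * nrm) * nrm
    a <- a / sqrt(sum(a^2))
    t1[i, ] <- a
    if (k == 3L) {
      b <- c(nrm[2] * a[3] - nrm[3] * a[2],
             nrm[3] * a[1] - nrm[1] * a[3],
             nrm[1] * a[2] - nrm[2] * a[1])
      t2[i, ] <- b / sqrt(sum(b^2))
    }
  }
  list(t1 = t1, t2 = t2, normals = normals)
}

# Sliding design matrix: maps tangent amplitudes to flat (pk) coordinate
# displacements. Curve semilandmarks get one column, surface ones two.
sliding_design <- function(scheme, tangents, surf_tangents, p, k) {
  cols <- list()
  owners <- integer(0)
  for (i in scheme$curve_semis) {
    col <- numeric(p * k)
    for (c in seq_len(k)) col[(c - 1L) * p + i] <- tangents[i, c]
    cols[[length(cols) + 1L]] <- col
    owners <- c(owners, i)
  }
  if (length(scheme$surface)) {
    for (i in scheme$surface) {
      for (tm in list(surf_tangents$t1, surf_tangents$t2)) {
        if (all(tm[i, ] == 0)) next
        col <- numeric(p * k)
        for (c in seq_len(k)) col[(c - 1L) * p + i] <- tm[i, c]
        cols[[length(cols) + 1L]] <- col
        owners <- c(owners, i)
      }
    }
  }
  if (!length(cols)) return(NULL)
  list(D = do.call(cbind, cols), owners = owners)
}

#' One sliding step of a configuration toward a consensus
#'
#' Solves the constrained least-squares problem for the tangent
#' displacements of all semilandmarks at once. Under the `bending`
#' criterion the thin-plate-spline quadratic form of the residual from the
#' consensus (the consensus bending-energy matrix applied per coordinate
#' axis) is minimized; under `d2` the summed squared residual is, which
#' decouples into an independent orthogonal projection of each
#' semilandmark's residual onto its tangent line or plane. Fixed landmarks
#' never move.
#'
#' @param config `p x k` configuration, aligned to the consensus.
#' @param consensus `p x k` consensus configuration.
#' @param scheme a [semilandmark_scheme()].
#' @param criterion `"bending"` or `"d2"`.
#' @param be_model [bending_energy_matrix()] of the consensus (required for
#'   `"bending"`; computed if missing).
#' @param tangents optional precomputed curve tangents.
#' @param surf_tangents optional precomputed surface tangent planes (list
#'   with `t1`, `t2`).
#' @return list with `config` (slid), `amplitudes` (per design column),
#'   `displacement` (`p x k`).
#' @export
slide_step <- function(config, consensus, scheme,
                       criterion = c("bending", "d2"),
                       be_model = NULL, tangents = NULL,
                       surf_tangents = NULL) {
  criterion <- match.arg(criterion)
  m <- as.matrix(unclass(config))
  cons <- as.matrix(unclass(consensus))
  p <- nrow(m); k <- ncol(m)
  if (is.null(tangents)) tangents <- estimate_curve_tangents(m, scheme)
  if (is.null(surf_tangents) && length(scheme$surface))
    stop("surface semilandmarks need precomputed tangent planes")
  des <- sliding_design(scheme, tangents, surf_tangents, p, k)
  if (is.null(des))
    return(list(config = m, amplitudes = numeric(0),
                displacement = matrix(0, p, k)))
  D <- des$D
  r <- as.numeric(m - cons)
  if (criterion == "d2") {
    t_amp <- -drop(crossprod(D, r))   # orthonormal, disjoint columns
  } else {
    if (is.null(be_model)) be_model <- bending_energy_matrix(cons)
    B <- be_model$be_matrix
    BD <- apply(D, 2, function(col) {
      as.numeric(B %*% matrix(col, p, k))
    })
    G <- crossprod(D, BD)
    rhs <- -drop(crossprod(BD, r))
    t_amp <- tryCatch(solve(G, rhs), error = function(e) {
      warning("singular sliding normal equations; using ridge fallback")
      solve(G + 1e-8 * diag(nrow(G)), rhs)
    })
  }
  disp_flat <- drop(D %*% t_amp)
  disp <- matrix(disp_flat, p, k)
  list(config = m + disp, amplitudes = t_amp, displacement = disp)
}

#' Slide semilandmarks across a sample
#'
#' Iterates: GPA of the current sample, optional symmetrization of the
#' consensus (required for asymmetry studies, so an asymmetric initial
#' placement of semilandmarks does not masquerade as shape asymmetry),
#' re-estimation of tangents from the current positions, one
#' [slide_step()] per specimen damped by `step_fraction`, and optional
#' reprojection onto each specimen's own original curve polylines or mesh.
#' Stops when the mean sliding amplitude (relative to specimen size) drops
#' below `tol` or after `max_iter` iterations. Minimizing Procrustes
#' distance (`d2`) converges — the total shape variance is non-increasing
#' — whereas minimizing bending energy need not converge because affine
#' variation carries no penalty; non-convergence is reported, not an error.
#'
#' @param sample a [landmark_sample()].
#' @param scheme a [semilandmark_scheme()].
#' @param criterion `"bending"` or `"d2"`.
#' @param step_fraction fraction of the computed sliding distance applied
#'   per iteration (default 1 for curve-only schemes, 0.5 when surface
#'   semilandmarks are present).
#' @param max_iter maximum sliding iterations.
#' @param tol amplitude tolerance (fraction of centroid size).
#' @param update_mean recompute the consensus each iteration (`TRUE`);
#'   freezing it can stabilize the bending criterion.
#' @param symmetry_map optional [symmetry_map()]: symmetrize the consensus
#'   each iteration.
#' @param meshes optional list (per specimen) of `gm_mesh` for surface
#'   reprojection; surface normals are also taken from them.
#' @param curve_polylines optional reprojection geometry for the curves: a
#'   list with one polyline (`v x k` matrix) per curve chain, shared by all
#'   specimens; defaults to each specimen's own initial chain points.
#' @param normals optional `p x k x n` array of per-specimen surface
#'   normals (alternative to `meshes`).
#' @param reproject reproject curve semilandmarks onto each specimen's
#'   original chain polyline (and surface ones onto its mesh) after every
#'   iteration.
#' @return an object of class `gm_sliding_result`: list with `sample`
#'   (slid), `iterations`, `objective` (per iteration; summed squared
#'   deviation from consensus for `d2`, total bending energy for
#'   `bending`), `mean_amplitude` per iteration, `converged`, `criterion`.
#' @export
slide <- function(sample, scheme, criterion = c("bending", "d2"),
                  step_fraction = NULL, max_iter = 10L, tol = 1e-6,
                  update_mean = TRUE, symmetry_map = NULL,
                  meshes = NULL, normals = NULL, reproject = TRUE,
                  curve_polylines = NULL) {
  criterion <- match.arg(criterion)
  stopifnot(inherits(sample, "landmark_sample"))
  p <- sample$p; k <- sample$k; n <- sample$n
  has_surface <- length(scheme$surface) > 0L
  if (is.null(step_fraction)) step_fraction <- if (has_surface) 0.5 else 1
  orig_chains <- lapply(seq_len(n), function(i) {
    if (!is.null(curve_polylines)) curve_polylines
    else lapply(scheme$curves, function(ch) sample$coords[ch, , i, drop = FALSE])
  })

  cur <- sample
  objective <- numeric(0)
  amplitudes <- numeric(0)
  converged <- FALSE
  frozen_consensus <- NULL
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    sup <- gpa(cur, mode = "shape")
    cons <- if (!update_mean && !is.null(frozen_consensus)) frozen_consensus
            else sup$consensus
    if (!is.null(symmetry_map)) {
      cons <- (cons + relabel_reflect_matrix(cons, symmetry_map)) / 2
      cons <- cons / sqrt(sum(scale(cons, scale = FALSE)^2))
    }
    if (is.null(frozen_consensus)) frozen_consensus <- cons
    be_model <- NULL
    if (criterion == "bending") {
      be_model <- tryCatch(bending_energy_matrix(cons), error = function(e) NULL)
      if (is.null(be_model)) {
        warning("consensus became degenerate for the bending criterion; ",
                "stopping after ", iter - 1L, " iterations")
        iter <- iter - 1L
        break
      }
    }

    obj <- 0
    amps <- numeric(0)
    new_coords <- cur$coords
    for (i in seq_len(n)) {
      sz <- sup$transforms$sizes[i]
      R <- sup$transforms$rotations[[i]]
      ctr <- sup$transforms$centers[i, ]
      # consensus mapped into the specimen's own coordinate frame
      cons_i <- (cons %*% t(R)) * sz + matrix(ctr, p, k, byrow = TRUE)
      m_i <- cur$coords[, , i]
      tang <- estimate_curve_tangents(m_i, scheme)
      st <- if (has_surface)
        estimate_surface_tangent_planes(m_i, scheme,
                                        mesh = if (!is.null(meshes)) meshes[[i]],
                                        normals = if (!is.null(normals)) normals[, , i])
      else NULL
      step <- slide_step(m_i, cons_i, scheme, criterion,
                         be_model = be_model, tangents = tang,
                         surf_tangents = st)
      newm <- m_i + step_fraction * step$displacement
      if (reproject) {
        for (ci in seq_along(scheme$curves)) {
          ch <- scheme$curves[[ci]]
          semis <- ch[!ch %in% scheme$fixed]
          if (length(semis))
            newm[semis, ] <- project_to_curve(newm[semis, , drop = FALSE],
                                              orig_chains[[i]][[ci]])
        }
        if (has_surface && !is.null(meshes))
          newm[scheme$surface, ] <-
            project_to_surface(newm[scheme$surface, , drop = FALSE], meshes[[i]])
      }
      new_coords[, , i] <- newm
      amps <- c(amps, abs(step$amplitudes) * step_fraction / sz)
    }
    cur <- landmark_sample(new_coords, ids = sample$ids,
                           landmark_names = sample$landmark_names)
    sup2 <- gpa(cur, mode = "shape")
    cons2 <- if (update_mean) sup2$consensus else frozen_consensus
    if (criterion == "d2") {
      obj <- sum(sweep(sup2$aligned, 2, as.numeric(cons2))^2)
    } else {
      bem2 <- tryCatch(bending_energy_matrix(cons2), error = function(e) NULL)
      obj <- if (is.null(bem2)) NA_real_ else
        sum(vapply(seq_len(n), function(i)
          deformation_bending_energy(bem2, sup2$coords[, , i] - cons2),
          numeric(1)))
    }
    objective <- c(objective, obj)
    amplitudes <- c(amplitudes, mean(amps))
    if (length(amps) == 0L || mean(amps) < tol) { converged <- TRUE; break }
  }
  structure(list(sample = cur, iterations = iter, objective = objective,
                 mean_amplitude = amplitudes, converged = converged,
                 criterion = criterion),
            class = "gm_sliding_result")
}

#' @export
print.gm_sliding_result <- function(x, ...) {
  cat("Semilandmark sliding (", x$criterion, "): ", x$iterations,
      " iterations, converged: ", x$converged, "\n", sep = "")
  cat("Objective:", paste(signif(x$objective, 5), collapse = " -> "), "\n")
  invisible(x)
}

#' Project points onto a polyline
#'
#' Each point is replaced by its nearest point on the polyline (searched
#' over all segments).
#'
#' @param points `m x k` matrix.
#' @param polyline ordered `v x k` matrix of polyline vertices (at least 2).
#' @return the projected `m x k` matrix.
#' @export
project_to_curve <- function(points, polyline) {
  P <- matrix(as.numeric(points), ncol = ncol(polyline))
  V <- as.matrix(polyline)
  if (nrow(V) < 2L) stop("polyline needs at least 2 vertices")
  out <- P
  for (i in seq_len(nrow(P))) {
    best <- NULL; bestd <- Inf
    for (s in seq_len(nrow(V) - 1L)) {
      a <- V[s, ]; b <- V[s + 1L, ]
      ab <- b - a
      t <- sum((P[i, ] - a) * ab) / sum(ab^2)
      t <- max(0, min(1, t))
      q <- a + t * ab
      d <- sum((P[i, ] - q)^2)
      if (d < bestd) { bestd <- d; best <- q }
    }
    out[i, ] <- best
  }
  out
}

#' Project points onto a triangulated mesh
#'
#' Each point is replaced by its nearest point on the mesh surface
#' (searched over all triangles).
#'
#' @param points `m x 3` matrix.
#' @param mesh a `gm_mesh` with at least one face.
#' @return the projected `m x 3` matrix.
#' @export
project_to_surface <- function(points, mesh) {
  if (is.null(mesh$faces) || nrow(mesh$faces) == 0L)
    stop("mesh has no faces")
  P <- matrix(as.numeric(points), ncol = 3L)
  out <- P
  for (i in seq_len(nrow(P)))
    out[i, ] <- nearest_on_mesh(P[i, ], mesh)$point
  out
}

# Nearest point on a triangle mesh: closest point per triangle, global min.
nearest_on_mesh <- function(x, mesh) {
  best <- NULL; bestd <- Inf; bestn <- NULL
  for (f in seq_len(nrow(mesh$faces))) {
    tri <- mesh$vertices[mesh$faces[f, ], , drop = FALSE]
    q <- closest_point_triangle(x, tri[1, ], tri[2, ], tri[3, ])
    d <- sum((x - q)^2)
    if (d < bestd) {
      bestd <- d; best <- q
      nrm <- cross3(tri[2, ] - tri[1, ], tri[3, ] - tri[1, ])
      bestn <- nrm / sqrt(sum(nrm^2))
    }
  }
  list(point = best, distance = sqrt(bestd), normal = bestn)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Closest point on triangle abc to point x (Ericson, Real-Time Collision
# Detection, ch. 5).
closest_point_triangle <- function(x, a, b, c) {
  ab <- b - a; ac <- c - a; ax <- x - a
  d1 <- sum(ab * ax); d2 <- sum(ac * ax)
  if (d1 <= 0 && d2 <= 0) return(a)
  bx <- x - b
  d3 <- sum(ab * bx); d4 <- sum(ac * bx)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(a + (d1 / (d1 - d3)) * ab)
  cx <- x - c
  d5 <- sum(ab * cx); d6 <- sum(ac * cx)
  if (d6 >= 0 && d5 <= d6) return(c)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(a + (d2 / (d2 - d6)) * ac)
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
    return(b + ((d4 - d3) / ((d4 - d3) + (d5 - d6))) * (c - b))
  denom <- 1 / (va + vb + vc)
  a + ab * (vb * denom) + ac * (vc * denom)
}
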