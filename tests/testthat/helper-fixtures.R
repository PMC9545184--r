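# Shared fixtures for the test suite; everything is generated in code.

unit_square <- function() {
  landmark_configuration(cbind(x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)),
                         id = "square")
}

rotation2 <- function(theta) {
  matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2, byrow = TRUE)
}

random_rotation <- function(k) {
  qrm <- qr(matrix(rnorm(k * k), k, k))
  R <- qr.Q(qrm)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Apply independent random similarity transforms to every configuration.
scramble_sample <- function(sample, rotate = TRUE, translate = TRUE,
                            scale = FALSE) {
  coords <- sample$coords
  k <- sample$k
  for (i in seq_len(sample$n)) {
    m <- coords[, , i]
    if (rotate) m <- m %*% random_rotation(k)
    if (scale) m <- m * exp(rnorm(1, sd = 0.3))
    if (translate) m <- sweep(m, 2, rnorm(k, sd = 2), `+`)
    coords[, , i] <- m
  }
  landmark_sample(coords, ids = sample$ids,
                  landmark_names = sample$landmark_names)
}

# Align superimposition B's output onto A's orientation convention and
# return the maximum coordinate discrepancy.
aligned_discrepancy <- function(sup_a, sup_b) {
  R <- gmkit:::optimal_rotation(sup_b$consensus, sup_a$consensus)
  mx <- 0
  for (i in seq_len(sup_a$n)) {
    mx <- max(mx, max(abs(sup_b$coords[, , i] %*% R - sup_a$coords[, , i])))
  }
  mx
}

# Left/right symmetry map of a 2D grid template (midline = central column).
grid_map <- function(template) gmkit:::grid_symmetry_map(template)

# A small 3D plane mesh (z = 0) over [0, 1]^2.
plane_mesh <- function(n = 4) {
  g <- expand.grid(x = seq(0, 1, length.out = n), y = seq(0, 1, length.out = n))
  verts <- cbind(as.matrix(g), z = 0)
  faces <- NULL
  idx <- matrix(seq_len(n * n), n, n)
  for (i in seq_len(n - 1)) for (j in seq_len(n - 1)) {
    a <- idx[i, j]; b <- idx[i + 1, j]; c <- idx[i + 1, j + 1]; d <- idx[i, j + 1]
    faces <- rbind(faces, c(a, b, c), c(a, c, d))
  }
  structure(list(vertices = verts, faces = faces), class = "gm_mesh")
}

# Icosahedron-based sphere mesh (unit radius), refined `refine` times.
sphere_mesh <- function(refine = 1) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, t, 0), c(1, t, 0), c(-1, -t, 0), c(1, -t, 0),
             c(0, -1, t), c(0, 1, t), c(0, -1, -t), c(0, 1, -t),
             c(t, 0, -1), c(t, 0, 1), c(-t, 0, -1), c(-t, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  verts <- v
  for (pass in seq_len(refine)) {
    faces <- NULL
    midpoint <- function(a, b) {
      m <- (verts[a, ] + verts[b, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      nrow(verts)
    }
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      faces <- rbind(faces, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc),
                     c(ab, bc, ca))
    }
    f <- faces
  }
  structure(list(vertices = verts, faces = f), class = "gm_mesh")
}

# Sample of one shape on a shared semicircle with arbitrary semilandmark
# spacing (fixed endpoints at the diameter).
semicircle_sample <- function(n = 12, n_semi = 7) {
  cfgs <- replicate(n, {
    tt <- c(0, sort(runif(n_semi, 0.15, pi - 0.15)), pi)
    cbind(cos(tt), sin(tt))
  }, simplify = FALSE)
  landmark_sample(cfgs)
}

semicircle_polyline <- function(m = 400) {
  tt <- seq(0, pi, length.out = m)
  cbind(cos(tt), sin(tt))
}

random_spd <- function(q) {
  A <- matrix(rnorm(q * q), q, q)
  crossprod(A) / q + diag(q) * 0.1
}
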