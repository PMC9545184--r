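#' Partial-warp variance spectrum
#'
#' The variance of each partial warp's scores, summed over the `k`
#' coordinate axes, paired with its bending-energy eigenvalue. The inverse
#' eigenvalue is a measure of spatial scale, so the spectrum shows how
#' nonaffine shape variance is distributed across scales: flat under the
#' Mardia-Dryden model, proportional to `1/lambda` (2D) or `1/lambda^2`
#' (3D) under the self-similar model. Affine (uniform) variation is
#' excluded — bending energy is undefined for affine change.
#'
#' @param be_model a [bending_energy_matrix()] of the reference.
#' @param sup a `gm_superimposition` aligned to the reference.
#' @return an object of class `gm_scale_spectrum`: data frame with columns
#'   `warp`, `lambda`, `inv_lambda`, `variance`, plus attribute `k`.
#' @export
partial_warp_variance_spectrum <- function(be_model, sup) {
  scores <- partial_warp_scores(be_model, sup)
  k <- sup$k
  q <- length(be_model$eigenvalues)
  v <- vapply(seq_len(q), function(i) {
    cols <- (i - 1L) * k + seq_len(k)
    sum(apply(scores[, cols, drop = FALSE], 2, stats::var))
  }, numeric(1))
  out <- data.frame(warp = seq_len(q), lambda = be_model$eigenvalues,
                    inv_lambda = 1 / be_model$eigenvalues, variance = v)
  attr(out, "k") <- k
  class(out) <- c("gm_scale_spectrum", "data.frame")
  out
}

#' Log-log slope of partial-warp variance on inverse bending energy
#'
#' Ordinary least squares of `log(variance)` on `log(1/lambda)` across the
#' partial warps (repeated eigenvalues averaged first). A self-similar
#' sample yields a slope of about 1 in 2D and 2 in 3D; a Mardia-Dryden
#' sample a slope of about 0. Slopes above the self-similar value indicate
#' coordinated variation (large-scale features more variable than their
#' parts), smaller slopes compensatory variation.
#'
#' @param spectrum a `gm_scale_spectrum`.
#' @param tie_tol relative tolerance for treating eigenvalues as tied.
#' @return list with `slope`, `se`, `intercept`, `n_points`, and the `fit`.
#' @export
scale_slope <- function(spectrum, tie_tol = 1e-8) {
  sp <- spectrum[spectrum$variance > 0, , drop = FALSE]
  if (nrow(sp) < nrow(spectrum))
    warning("dropped ", nrow(spectrum) - nrow(sp), " zero-variance warps")
  if (nrow(sp) < 3L) stop("need at least 3 spectrum entries")
  # average variances over tied eigenvalues
  key <- round(log(sp$lambda) / tie_tol) * tie_tol
  grp <- match(key, unique(key))
  lam <- tapply(sp$lambda, grp, mean)
  v <- tapply(sp$variance, grp, mean)
  x <- log(1 / lam)
  fit <- stats::lm(log(v) ~ x)
  sm <- suppressWarnings(summary(fit))$coefficients  # exact fits are fine
  list(slope = unname(sm["x", "Estimate"]), se = unname(sm["x", "Std. Error"]),
       intercept = unname(sm["(Intercept)", "Estimate"]),
       n_points = length(x), fit = fit)
}

#' Relative intrinsic warps
#'
#' Relative eigenanalysis of the nonaffine part of shape variation with
#' respect to the variance expected under a self-similar shape
#' distribution: instead of the directions of largest variance (PCA), these
#' are the directions with the largest variance *relative to what their
#' spatial scale predicts*. The reference covariance is diagonal in the
#' partial-warp basis with entries proportional to `lambda^(-s)`
#' (`s` = 1 in 2D, 2 in 3D), so the result is invariant to a uniform
#' rescaling of all bending-energy eigenvalues.
#'
#' @param sup a `gm_superimposition`.
#' @param be_model a [bending_energy_matrix()] of the reference.
#' @param n_warps number of leading (largest-scale) partial warps to retain.
#' @param s self-similar scale exponent; defaults to 1 (2D) or 2 (3D).
#' @return a `gm_releigen` (see [relative_eigenanalysis()]) with an extra
#'   element `warp_basis` giving the retained warp/axis columns.
#' @export
relative_intrinsic_warps <- function(sup, be_model, n_warps = NULL, s = NULL) {
  k <- sup$k
  if (is.null(s)) s <- if (k == 2L) 1 else 2
  scores <- partial_warp_scores(be_model, sup)
  q <- length(be_model$eigenvalues)
  if (is.null(n_warps)) n_warps <- q
  n_warps <- min(n_warps, q)
  cols <- as.vector(vapply(seq_len(n_warps),
                           function(i) (i - 1L) * k + seq_len(k),
                           integer(k)))
  S <- stats::cov(scores[, cols, drop = FALSE])
  ref <- diag(rep(be_model$eigenvalues[seq_len(n_warps)]^(-s), each = k))
  out <- relative_eigenanalysis(S, ref)
  out$warp_basis <- colnames(scores)[cols]
  out
}

#' Per-cell nonaffine shape variance of grid samples
#'
#' For grid-template samples, extracts the landmark subsets of cells of a
#' given linear size, superimposes each cell subsample, and reports its
#' summed nonaffine (partial-warp) shape variance. Comparing cell sizes
#' shows whether shape variance decreases with spatial scale
#' (Mardia-Dryden/compensatory) or stays constant (self-similar).
#'
#' @param sample a [landmark_sample()] on a [grid_template()].
#' @param template the `gm_grid_template` the sample was built on.
#' @param cell_size cell edge length in lattice units (1 = unit cells).
#' @return data frame with one row per cell: `cell`, `nonaffine_variance`.
#' @export
per_cell_nonaffine_variance <- function(sample, template, cell_size = 1L) {
  stopifnot(inherits(template, "gm_grid_template"), template$k == 2L)
  rows <- template$rows; cols <- template$cols
  index <- matrix(seq_len(rows * cols), cols, rows)
  out <- list()
  for (r in seq_len(rows - cell_size)) for (c in seq_len(cols - cell_size)) {
    idx <- as.integer(index[c(c, c + cell_size), c(r, r + cell_size)])
    sub <- landmark_sample(sample$coords[idx, , , drop = FALSE],
                           ids = sample$ids)
    sup <- gpa(sub, mode = "shape")
    bem <- bending_energy_matrix(sup$consensus)
    sp <- partial_warp_variance_spectrum(bem, sup)
    out[[length(out) + 1L]] <- data.frame(
      row = r, col = c, cell_size = cell_size,
      nonaffine_variance = sum(sp$variance))
  }
  do.call(rbind, out)
}
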