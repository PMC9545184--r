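#' Landmark configuration
#'
#' A landmark configuration is a single specimen's set of `p` point locations
#' in `k` dimensions (2 or 3), stored as a `p x k` numeric matrix with an
#' `id` attribute and unique landmark names. All downstream machinery
#' (superimposition, thin-plate splines, symmetry decomposition) consumes
#' these objects or samples of them.
#'
#' @param coords numeric `p x k` matrix of landmark coordinates (`k` = 2 or 3).
#' @param id specimen label.
#' @param landmark_names optional character vector of `p` unique names;
#'   defaults to `L1 ... Lp`.
#' @return an object of class `landmark_configuration` (a `p x k` matrix).
#' @examples
#' sq <- landmark_configuration(cbind(c(-1, 1, 1, -1), c(-1, -1, 1, 1)))
#' centroid_size(sq)
#' @export
landmark_configuration <- function(coords, id = "1", landmark_names = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  p <- nrow(coords)
  k <- ncol(coords)
  if (!k %in% c(2L, 3L)) stop("landmark dimension k must be 2 or 3, got ", k)
  if (p < 3L) stop("a configuration needs at least 3 landmarks, got ", p)
  if (!all(is.finite(coords))) stop("non-finite landmark coordinates")
  if (is.null(landmark_names)) landmark_names <- paste0("L", seq_len(p))
  if (anyDuplicated(landmark_names)) stop("landmark names must be unique")
  dimnames(coords) <- list(landmark_names, c("x", "y", "z")[seq_len(k)])
  structure(coords, id = as.character(id), class = "landmark_configuration")
}

#' @export
print.landmark_configuration <- function(x, ...) {
  cat("Landmark configuration '", attr(x, "id"), "': ",
      nrow(x), " landmarks in ", ncol(x), "D\n", sep = "")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Landmark sample
#'
#' A sample of `n` congruent landmark configurations (same `p`, `k`, and
#' landmark names), stored as a `p x k x n` array. Optionally carries a
#' covariate table aligned to case order (see [attach_covariates()]).
#'
#' @param coords a `p x k x n` array, a list of `landmark_configuration`s or
#'   `p x k` matrices, or a single configuration.
#' @param ids case labels (defaults to array dimnames or `1:n`).
#' @param landmark_names optional landmark names shared by all configurations.
#' @return an object of class `landmark_sample`: a list with elements
#'   `coords` (`p x k x n` array), `ids`, `landmark_names`, `p`, `k`, `n`,
#'   and `covariates` (a data frame or `NULL`).
#' @export
landmark_sample <- function(coords, ids = NULL, landmark_names = NULL) {
  if (is.list(coords)) {
    mats <- lapply(coords, function(m) {
      if (is.null(ids) && !is.null(attr(m, "id"))) attr(m, "id") else NULL
      as.matrix(unclass(m))
    })
    dims <- vapply(mats, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
      stop("all configurations must share the same p and k")
    if (is.null(ids)) {
      ids <- vapply(seq_along(coords), function(i) {
        id <- attr(coords[[i]], "id")
        if (is.null(id)) as.character(i) else id
      }, character(1))
    }
    if (is.null(landmark_names) && !is.null(rownames(mats[[1]])))
      landmark_names <- rownames(mats[[1]])
    coords <- array(unlist(mats), dim = c(dims[1, 1], dims[2, 1], length(mats)))
  } else if (length(dim(coords)) == 2L) {
    coords <- array(as.matrix(coords), dim = c(dim(coords), 1L))
  }
  stopifnot(length(dim(coords)) == 3L)
  storage.mode(coords) <- "double"
  p <- dim(coords)[1]; k <- dim(coords)[2]; n <- dim(coords)[3]
  if (!k %in% c(2L, 3L)) stop("landmark dimension k must be 2 or 3, got ", k)
  if (p < 3L) stop("a configuration needs at least 3 landmarks")
  if (!all(is.finite(coords))) stop("non-finite landmark coordinates")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ids <- as.character(ids)
  if (length(ids) != n) stop("ids length does not match the number of configurations")
  if (is.null(landmark_names)) landmark_names <- paste0("L", seq_len(p))
  if (anyDuplicated(landmark_names)) stop("landmark names must be unique")
  dimnames(coords) <- list(landmark_names, c("x", "y", "z")[seq_len(k)], ids)
  structure(list(coords = coords, ids = ids, landmark_names = landmark_names,
                 p = p, k = k, n = n, covariates = NULL),
            class = "landmark_sample")
}

#' @export
print.landmark_sample <- function(x, ...) {
  cat("Landmark sample: n =", x$n, "configurations of", x$p,
      "landmarks in", paste0(x$k, "D\n"))
  if (!is.null(x$covariates))
    cat("Covariates:", paste(setdiff(names(x$covariates), "id"), collapse = ", "), "\n")
  invisible(x)
}

#' Extract one configuration from a sample
#'
#' @param sample a `landmark_sample`.
#' @param i case index or id.
#' @return a `landmark_configuration`.
#' @export
get_configuration <- function(sample, i) {
  stopifnot(inherits(sample, "landmark_sample"))
  if (is.character(i)) i <- match(i, sample$ids)
  landmark_configuration(sample$coords[, , i], id = sample$ids[i],
                         landmark_names = sample$landmark_names)
}

# Flatten a p x k x n array to an n x (p*k) matrix, column-major per
# configuration (x1..xp, y1..yp[, z1..zp]). The single vectorization
# convention used throughout the package.
flatten_sample <- function(coords) {
  d <- dim(coords)
  out <- t(matrix(coords, d[1] * d[2], d[3]))
  rownames(out) <- dimnames(coords)[[3]]
  ln <- dimnames(coords)[[1]]
  if (!is.null(ln))
    colnames(out) <- paste0(rep(ln, d[2]), "_", rep(dimnames(coords)[[2]], each = d[1]))
  out
}

# Inverse of flatten_sample.
unflatten_sample <- function(mat, p, k) {
  array(t(mat), dim = c(p, k, nrow(mat)))
}
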