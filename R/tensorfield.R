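#' Diffusion tensor fields
#'
#' A `tensor_field` stores one 3x3 symmetric diffusion tensor per voxel of a
#' 2-D or 3-D grid, together with a validity mask. Tensors are kept in the
#' compact upper-triangular component order `(Dxx, Dxy, Dxz, Dyy, Dyz, Dzz)`,
#' the layout used by the NIfTI tensor convention.
#'
#' On construction every tensor is eigen-checked and repaired: eigenvalues in
#' `(-tau, tau]` with `tau = 1e-12 * lambda1` are clamped up to `tau` (noisy
#' least-squares fits routinely produce tiny negative eigenvalues), while any
#' eigenvalue below `-tau` marks the voxel invalid. Valid voxels therefore
#' always carry strictly positive-definite tensors.
#'
#' @param tensors either an `n x 6` matrix of upper-triangular components, or
#'   an `n x 3 x 3` array of full symmetric tensors (checked for symmetry to
#'   `1e-10` relative tolerance).
#' @param dims integer grid dimensions, length 2 or 3; `prod(dims)` must be `n`.
#' @param voxel_size physical spacing per axis (mm); defaults to 1.
#' @param valid additional per-voxel validity to intersect with the repair
#'   policy (e.g. a brain mask); default all `TRUE`.
#' @return An object of class `tensor_field`: a list with elements `dims`,
#'   `tensors` (`n x 6` matrix), `valid` (logical `n`), `voxel_size`.
#' @export
tensor_field <- function(tensors, dims, voxel_size = rep(1, length(dims)),
                         valid = NULL) {
  dims <- as.integer(dims)
  if (!length(dims) %in% c(2L, 3L)) {
    stop("`dims` must have length 2 or 3")
  }
  n <- prod(dims)
  if (is.array(tensors) && length(dim(tensors)) == 3L) {
    tensors <- full_to_ut(tensors)
  }
  tensors <- as.matrix(tensors)
  if (ncol(tensors) != 6L) {
    stop("`tensors` must have 6 components per voxel ",
         "(upper-triangular order Dxx, Dxy, Dxz, Dyy, Dyz, Dzz)")
  }
  if (nrow(tensors) != n) {
    stop("nrow(tensors) (", nrow(tensors), ") != prod(dims) (", n, ")")
  }
  if (is.null(valid)) valid <- rep(TRUE, n)
  valid <- valid & apply(is.finite(tensors), 1L, all)
  ## all-zero tensors (e.g. padded voxels) are invalid, not isotropic-zero
  valid <- valid & rowSums(abs(tensors)) > 0

  field <- structure(
    list(dims = dims, tensors = tensors, valid = valid,
         voxel_size = voxel_size),
    class = "tensor_field")
  repair_spd(field)
}

#' @export
print.tensor_field <- function(x, ...) {
  cat("tensor_field: ", paste(x$dims, collapse = " x "),
      " grid, ", sum(x$valid), "/", length(x$valid), " valid voxels\n",
      sep = "")
  invisible(x)
}

## upper-triangular row -> 3x3 symmetric matrix
ut_to_mat <- function(v) {
  matrix(c(v[1], v[2], v[3],
           v[2], v[4], v[5],
           v[3], v[5], v[6]), 3L, 3L)
}

## 3x3 symmetric matrix -> upper-triangular row
mat_to_ut <- function(m) {
  c(m[1, 1], m[1, 2], m[1, 3], m[2, 2], m[2, 3], m[3, 3])
}

full_to_ut <- function(arr) {
  n <- dim(arr)[1]
  out <- matrix(0, n, 6)
  for (i in seq_len(n)) {
    m <- arr[i, , ]
    rel <- max(abs(m))
    if (rel > 0 && max(abs(m - t(m))) > 1e-10 * rel) {
      stop("tensor at voxel ", i, " is not symmetric within tolerance")
    }
    out[i, ] <- mat_to_ut((m + t(m)) / 2)
  }
  out
}

#' Extract one voxel's tensor as a 3x3 matrix
#' @param field a `tensor_field`
#' @param i linear voxel index
#' @return 3x3 symmetric matrix
#' @export
voxel_tensor <- function(field, i) ut_to_mat(field$tensors[i, ])

## Apply the SPD repair policy in place: clamp eigenvalues in (-tau, tau],
## invalidate anything below -tau. tau = 1e-12 * lambda1.
repair_spd <- function(field) {
  for (i in which(field$valid)) {
    m <- ut_to_mat(field$tensors[i, ])
    e <- eigen(m, symmetric = TRUE)
    lam <- e$values
    tau <- 1e-12 * max(lam[1], 0)
    if (any(lam < -tau) || lam[1] <= 0) {
      field$valid[i] <- FALSE
      next
    }
    if (any(lam <= tau)) {
      lam <- pmax(lam, tau)
      field$tensors[i, ] <- mat_to_ut(e$vectors %*% (lam * t(e$vectors)))
    }
  }
  field
}

#' Eigendecompose every valid tensor of a field
#'
#' Each valid voxel's tensor is decomposed into descending eigenvalues
#' `lambda1 >= lambda2 >= lambda3 > 0` and a unit principal eigenvector (the
#' axis of `lambda1`). When the two leading eigenvalues coincide within
#' `1e-9` relative tolerance the principal axis is degenerate; the
#' decomposition's first eigenvector is kept deterministically and the voxel
#' is flagged in `degenerate`.
#'
#' @param field a `tensor_field`
#' @return A list of class `tensor_eigen` with matrices `values` (`n x 3`),
#'   `vectors` (`n x 3`, principal axis per row), logicals `valid` and
#'   `degenerate`.
#' @export
eigendecompose <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  n <- nrow(field$tensors)
  values <- matrix(NA_real_, n, 3)
  vectors <- matrix(NA_real_, n, 3)
  degenerate <- rep(FALSE, n)
  for (i in which(field$valid)) {
    e <- eigen(ut_to_mat(field$tensors[i, ]), symmetric = TRUE)
    values[i, ] <- e$values
    vectors[i, ] <- e$vectors[, 1] / sqrt(sum(e$vectors[, 1]^2))
    if ((e$values[1] - e$values[2]) <= 1e-9 * e$values[1]) {
      degenerate[i] <- TRUE
    }
  }
  structure(list(values = values, vectors = vectors,
                 valid = field$valid, degenerate = degenerate),
            class = "tensor_eigen")
}

#' Scalar and orientation features of a tensor field
#'
#' Computes, per valid voxel, the three classical eigenvalue features
#' \deqn{MD = (\lambda_1+\lambda_2+\lambda_3)/3,\quad
#'       FA = \sqrt{3/2}\,\frac{\|\lambda - MD\|}{\|\lambda\|},\quad
#'       VR = \frac{\lambda_1\lambda_2\lambda_3}{MD^3},}
#' plus min-max normalized versions (over the valid voxels of this field
#' only) used by the distance vector. A constant feature normalizes to 0.
#' Voxels with `MD == 0` are marked invalid.
#'
#' @param eig a `tensor_eigen` from [eigendecompose()], or a `tensor_field`
#'   (decomposed on the fly)
#' @return A list of class `voxel_features`: vectors `md`, `fa`, `vr`, their
#'   normalized counterparts `md_norm`, `fa_norm`, `vr_norm`, the `n x 3`
#'   principal-axis matrix `axes`, and logicals `valid`, `degenerate`.
#' @export
compute_features <- function(eig) {
  if (inherits(eig, "tensor_field")) eig <- eigendecompose(eig)
  stopifnot(inherits(eig, "tensor_eigen"))
  lam <- eig$values
  md <- rowMeans(lam)
  dev2 <- rowSums((lam - md)^2)
  fa <- sqrt(1.5 * dev2 / rowSums(lam^2))
  vr <- lam[, 1] * lam[, 2] * lam[, 3] / md^3
  valid <- eig$valid & !is.na(md) & md > 0

  minmax <- function(x) {
    x[!valid] <- NA_real_
    rng <- range(x[valid])
    if (diff(rng) == 0) {
      x[valid] <- 0
    } else {
      x <- (x - rng[1]) / diff(rng)
    }
    x
  }
  structure(
    list(md = md, fa = fa, vr = vr,
         md_norm = minmax(md), fa_norm = minmax(fa), vr_norm = minmax(vr),
         axes = eig$vectors, valid = valid, degenerate = eig$degenerate),
    class = "voxel_features")
}
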