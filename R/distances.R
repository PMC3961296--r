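#' Pairwise voxel distances
#'
#' The discriminative distance between two voxels is a 4-vector: the
#' component-wise absolute differences of the normalized (MD, FA, VR)
#' features, plus a normalized orientation distance between the principal
#' axes. All four components lie in `[0, 1]`, which lets a learned 4x4
#' kernel matrix reweight them individually.
#'
#' @name distance-vector
NULL

#' @describeIn distance-vector absolute differences of the normalized
#'   geometry features `(md_norm, fa_norm, vr_norm)`.
#' @param fi,fj numeric 3-vectors of normalized features
#' @export
geometry_distance <- function(fi, fj) {
  stopifnot(length(fi) == 3, length(fj) == 3)
  abs(fi - fj)
}

#' @describeIn distance-vector minimum rotation angle between sign-ambiguous
#'   principal axes, normalized so that orthogonal axes are at distance 1:
#'   `acos(|ei . ej|) / (pi/2)`.
#' @param ei,ej unit 3-vectors (principal diffusion axes)
#' @export
orientation_distance <- function(ei, ej) {
  ni <- sqrt(sum(ei^2)); nj <- sqrt(sum(ej^2))
  if (ni < 1e-12 || nj < 1e-12) stop("zero principal axis")
  ## |dot| clamped to [0, 1] to absorb rounding before acos
  ct <- min(1, abs(sum(ei * ej) / (ni * nj)))
  acos(ct) / (pi / 2)
}

#' @describeIn distance-vector full 4-component distance vector between two
#'   voxels of a feature set.
#' @param features a `voxel_features` object from [compute_features()]
#' @param i,j linear voxel indices
#' @export
original_distance <- function(features, i, j) {
  if (!features$valid[i] || !features$valid[j]) {
    stop("invalid voxel in pair (", i, ", ", j, ")")
  }
  fi <- c(features$md_norm[i], features$fa_norm[i], features$vr_norm[i])
  fj <- c(features$md_norm[j], features$fa_norm[j], features$vr_norm[j])
  c(geometry_distance(fi, fj),
    orientation_distance(features$axes[i, ], features$axes[j, ]))
}

#' Classical tensor metrics
#'
#' The three predefined distances between diffusion tensors used as
#' baselines: the Euclidean (Frobenius) distance, the J-divergence
#' (symmetrized Kullback-Leibler between the zero-mean Gaussians the tensors
#' define), and the geodesic distance on the SPD manifold.
#'
#' @param D1,D2 3x3 symmetric (SPD for J-divergence / geodesic) matrices
#' @return a nonnegative scalar; zero iff `D1 == D2`
#' @name tensor-metrics
NULL

#' @describeIn tensor-metrics Frobenius norm of the difference,
#'   `sqrt(trace((D1 - D2)^2))`.
#' @export
euclidean_metric <- function(D1, D2) {
  sqrt(sum((D1 - D2)^2))
}

#' @describeIn tensor-metrics `(1/2) sqrt(trace(D1^-1 D2 + D2^-1 D1) - 6)`.
#' @export
jdivergence_metric <- function(D1, D2) {
  check_spd(D1); check_spd(D2)
  tr <- sum(diag(solve(D1, D2))) + sum(diag(solve(D2, D1)))
  0.5 * sqrt(max(tr - 6, 0))
}

#' @describeIn tensor-metrics affine-invariant Riemannian distance
#'   `sqrt(sum(log(lambda_k(D1^-1 D2))^2))`; `variant = "logeuclidean"`
#'   uses `||logm(D1) - logm(D2)||_F` instead (the two agree on commuting
#'   tensors).
#' @param variant `"affine"` (default) or `"logeuclidean"`
#' @export
geodesic_metric <- function(D1, D2, variant = c("affine", "logeuclidean")) {
  variant <- match.arg(variant)
  check_spd(D1); check_spd(D2)
  if (variant == "affine") {
    ## eigenvalues of D1^-1 D2 == eigenvalues of R^-T D2 R^-1, D1 = R'R
    R <- chol(D1)
    S <- forwardsolve(t(R), D2)          # R^-T D2
    S <- t(forwardsolve(t(R), t(S)))     # (R^-T D2) R^-1, symmetric
    lam <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    sqrt(sum(log(lam)^2))
  } else {
    sqrt(sum((logm_spd(D1) - logm_spd(D2))^2))
  }
}

check_spd <- function(D) {
  lam <- eigen((D + t(D)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(lam) <= 0) stop("tensor is not positive definite (singular metric)")
  invisible(TRUE)
}

logm_spd <- function(D) {
  e <- eigen((D + t(D)) / 2, symmetric = TRUE)
  e$vectors %*% (log(e$values) * t(e$vectors))
}

## classical metric dispatch used by graph weighting
classical_metric_fun <- function(metric = c("euclidean", "jdivergence", "geodesic")) {
  metric <- match.arg(metric)
  switch(metric,
         euclidean = euclidean_metric,
         jdivergence = jdivergence_metric,
         geodesic = geodesic_metric)
}
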