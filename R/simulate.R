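#' Synthetic tensor-lattice phantoms and DWI simulation
#'
#' The validation protocol: a 15x15 lattice of diffusion tensors whose
#' region of interest (ROI) shares one eigenvalue triple (geometry) but is
#' split across several principal orientations, on a geometry-distinct
#' background; diffusion-weighted images are synthesized from the tensors
#' with the Stejskal-Tanner equation (12 directions at b = 1000 s/mm^2 plus
#' one b = 0 baseline), corrupted with Rician noise at a fixed SNR, and the
#' tensors re-estimated by linear least squares.
#'
#' @name simulate-phantom
NULL

## 12 diffusion gradient axes, electrostatic-repulsion layout (antipodally
## symmetrized energy, minimized once and frozen). Rows are unit vectors.
DTSEG_BVECS_12 <- matrix(c(
  -0.7730247689, 0.6337377050, 0.0284469311,
   0.9376018620, 0.3391217713, 0.0768060715,
  -0.1714354871, 0.9810019087, 0.0908026919,
   0.4842400197, 0.8680762926, 0.1093396250,
  -0.8777889569, 0.0977561493, 0.4689672509,
   0.8328383879, -0.1968585956, 0.5173266985,
  -0.5053511186, -0.6458287428, 0.5722984203,
   0.2281937040, -0.7721630295, 0.5930361619,
  -0.2876622731, 0.6410175325, 0.7115805925,
   0.4458824997, 0.5146825946, 0.7323186624,
  -0.3705638430, -0.0377638357, 0.9280389706,
   0.2851121932, -0.1506867181, 0.9465751688),
  nrow = 12, ncol = 3, byrow = TRUE)

#' Default diffusion gradient table
#'
#' @return the frozen 12 x 3 matrix of unit gradient directions
#' @export
default_bvecs <- function() DTSEG_BVECS_12

## in-plane tensor with principal axis at `angle` degrees from +x
tensor_at_angle <- function(eigenvalues, angle) {
  th <- angle * pi / 180
  R <- matrix(c(cos(th), sin(th), 0,
                -sin(th), cos(th), 0,
                0, 0, 1), 3, 3)
  mat_to_ut(R %*% (eigenvalues * t(R)))
}

#' Specification of a synthetic lattice phantom
#'
#' Defaults reconstruct the validation phantom: a 15x15 grid whose 9x9
#' central ROI carries white-matter-like eigenvalues `(1.7, 0.3, 0.3)e-3`
#' mm^2/s split into three vertical orientation bands at 0, 90 and 0
#' degrees, over an isotropic background `(1.0, 1.0, 1.0)e-3`. Seed
#' strokes: one horizontal foreground bar crossing the first two orientation
#' bands, and two horizontal background bars above and below the ROI
#' (one red / two green bars of the protocol).
#'
#' @param grid lattice dimensions (default `c(15, 15)`)
#' @param roi_rows,roi_cols index ranges of the rectangular ROI
#' @param roi_eigenvalues,bg_eigenvalues eigenvalue triples (descending)
#' @param roi_orientations in-plane principal-axis angles (degrees in
#'   `[0, 180)`), one per vertical band of equal width within the ROI
#' @param bg_orientations angles for the background bands (ignored for an
#'   isotropic background tensor, where the axis is degenerate)
#' @return object of class `phantom_spec`
#' @export
phantom_spec <- function(grid = c(15, 15),
                         roi_rows = 4:12, roi_cols = 4:12,
                         roi_eigenvalues = c(1.7e-3, 0.3e-3, 0.3e-3),
                         bg_eigenvalues = c(1.0e-3, 1.0e-3, 1.0e-3),
                         roi_orientations = c(0, 90, 0),
                         bg_orientations = 0) {
  stopifnot(all(roi_eigenvalues > 0), all(bg_eigenvalues > 0),
            all(roi_orientations >= 0 & roi_orientations < 180),
            all(bg_orientations >= 0 & bg_orientations < 180),
            length(grid) == 2)
  if (!length(roi_rows) || !length(roi_cols)) stop("ROI is empty")
  structure(list(grid = as.integer(grid), roi_rows = roi_rows,
                 roi_cols = roi_cols,
                 roi_eigenvalues = sort(roi_eigenvalues, decreasing = TRUE),
                 bg_eigenvalues = sort(bg_eigenvalues, decreasing = TRUE),
                 roi_orientations = roi_orientations,
                 bg_orientations = bg_orientations),
            class = "phantom_spec")
}

#' Generate the synthetic tensor lattice, ground truth and seed strokes
#'
#' Deterministic given the spec (the lattice itself has no randomness; noise
#' enters later through [add_rician_noise()]).
#'
#' @param spec a [phantom_spec()]
#' @return list with `field` (a [tensor_field()]), `truth` (full-grid 1/0
#'   ROI mask), `labels` (full-grid seeds: 1 = foreground stroke,
#'   2 = background strokes, 0 = unlabeled), and `bands` (per-voxel ROI band
#'   index, 0 outside)
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$grid[1]; nc <- spec$grid[2]
  n <- nr * nc
  coord <- arrayInd(seq_len(n), .dim = spec$grid)
  in_roi <- coord[, 1] %in% spec$roi_rows & coord[, 2] %in% spec$roi_cols
  if (!any(in_roi)) stop("ROI is empty")

  band_of <- function(cols, angles, colv) {
    ## split the column range into length(angles) contiguous equal bands
    k <- length(angles)
    edges <- floor(seq(0, k, length.out = k + 1) / k * length(cols))
    b <- findInterval(match(colv, cols) - 1, edges[-(k + 1)])
    b
  }
  tensors <- matrix(0, n, 6)
  bands <- integer(n)
  roi_idx <- which(in_roi)
  bands[roi_idx] <- band_of(spec$roi_cols, spec$roi_orientations,
                            coord[roi_idx, 2])
  for (i in roi_idx) {
    tensors[i, ] <- tensor_at_angle(spec$roi_eigenvalues,
                                    spec$roi_orientations[bands[i]])
  }
  bg_idx <- which(!in_roi)
  bg_band <- band_of(seq_len(nc), spec$bg_orientations, coord[bg_idx, 2])
  for (k in seq_along(bg_idx)) {
    tensors[bg_idx[k], ] <- tensor_at_angle(spec$bg_eigenvalues,
                                            spec$bg_orientations[bg_band[k]])
  }

  labels <- integer(n)
  ## one foreground stroke crossing the first two orientation bands
  mid_row <- spec$roi_rows[ceiling(length(spec$roi_rows) / 2)]
  k <- length(spec$roi_orientations)
  ncols_fg <- if (k >= 2) {
    ceiling(length(spec$roi_cols) * 2 / k)
  } else {
    length(spec$roi_cols)
  }
  fg_cols <- spec$roi_cols[seq_len(ncols_fg)]
  labels[(coord[, 1] == mid_row) & coord[, 2] %in% fg_cols] <- 1L
  ## two background strokes above and below the ROI
  row_above <- max(min(spec$roi_rows) - 2, 1)
  row_below <- min(max(spec$roi_rows) + 2, nr)
  bg_stroke <- coord[, 1] %in% c(row_above, row_below) &
    coord[, 2] %in% spec$roi_cols & !in_roi
  labels[bg_stroke] <- 2L

  list(field = tensor_field(tensors, dims = spec$grid),
       truth = as.integer(in_roi), labels = labels, bands = bands)
}

#' Stejskal-Tanner diffusion-weighted signal synthesis
#'
#' `S_k(x) = S0 * exp(-b * g_k' D(x) g_k)` per voxel and gradient direction.
#'
#' @param field a [tensor_field()]
#' @param bvecs `k x 3` matrix of unit gradient directions (default the
#'   frozen 12-direction table)
#' @param bval diffusion weighting (s/mm^2), default 1000
#' @param S0 baseline signal, default 100
#' @return object of class `dwi_set`: `S0` (baseline image, vector),
#'   `signals` (`n x k` matrix), `bvals`, `bvecs`, `dims`, `valid`
#' @export
stejskal_tanner <- function(field, bvecs = default_bvecs(), bval = 1000,
                            S0 = 100) {
  stopifnot(bval >= 0, S0 > 0)
  bvecs <- as.matrix(bvecs)
  stopifnot(ncol(bvecs) == 3)
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(abs(nrm - 1) > 1e-8)) stop("gradient directions must be unit norm")
  ## g' D g for all voxels x directions via the 6-component design
  X <- st_design(bvecs)                     # k x 6
  q <- field$tensors %*% t(X)               # n x k quadratic forms
  signals <- S0 * exp(-bval * q)
  signals[!field$valid, ] <- 0
  structure(list(S0 = rep(S0, nrow(field$tensors)), signals = signals,
                 bvals = rep(bval, nrow(bvecs)), bvecs = bvecs,
                 dims = field$dims, valid = field$valid),
            class = "dwi_set")
}

## design row per direction against upper-triangular components:
## g' D g = gx^2 Dxx + 2 gx gy Dxy + 2 gx gz Dxz + gy^2 Dyy + 2 gy gz Dyz
##          + gz^2 Dzz
st_design <- function(bvecs) {
  cbind(bvecs[, 1]^2, 2 * bvecs[, 1] * bvecs[, 2], 2 * bvecs[, 1] * bvecs[, 3],
        bvecs[, 2]^2, 2 * bvecs[, 2] * bvecs[, 3], bvecs[, 3]^2)
}

#' Add Rician noise to a DWI set
#'
#' Magnitude-MR noise: `S~ = sqrt((S + n1)^2 + n2^2)` with independent
#' `n1, n2 ~ N(0, sigma^2)` and `sigma = S0 / snr` (noise level referenced
#' to the baseline signal on each complex channel). By default only the
#' diffusion-weighted images are corrupted — the baseline is generated
#' separately in the protocol and kept clean; set `noise_baseline = TRUE`
#' to corrupt it as well.
#'
#' @param dwi a `dwi_set` from [stejskal_tanner()]
#' @param snr nominal signal-to-noise ratio, `> 0`
#' @param seed RNG seed for reproducibility
#' @param noise_baseline also corrupt the b = 0 image (default `FALSE`)
#' @return a `dwi_set` with noisy `signals` (and `S0` if requested)
#' @export
add_rician_noise <- function(dwi, snr, seed = NULL, noise_baseline = FALSE) {
  stopifnot(inherits(dwi, "dwi_set"))
  if (snr <= 0) stop("snr must be > 0")
  if (!is.null(seed)) set.seed(seed)
  sigma <- dwi$S0[1] / snr
  rician <- function(S) {
    sqrt((S + stats::rnorm(length(S), 0, sigma))^2 +
           stats::rnorm(length(S), 0, sigma)^2)
  }
  noisy <- dwi
  noisy$signals <- matrix(rician(dwi$signals), nrow = nrow(dwi$signals))
  if (noise_baseline) noisy$S0 <- rician(dwi$S0)
  noisy$snr <- snr
  noisy
}

#' Linear least-squares tensor estimation from DWI signals
#'
#' Per voxel, regresses `log(S0 / S_k) / b_k` on the six tensor design
#' components. Nonpositive signals are clamped to `1e-6 * S0` (the number of
#' clamped values is reported in the `n_clamped` attribute); the estimated
#' field then passes through the standard SPD repair policy.
#'
#' @param dwi a `dwi_set` (at least 6 non-collinear directions)
#' @return a [tensor_field()] with an `n_clamped` attribute
#' @export
fit_tensors_lls <- function(dwi) {
  stopifnot(inherits(dwi, "dwi_set"))
  bvecs <- dwi$bvecs
  if (nrow(bvecs) < 6) {
    stop("need at least 6 gradient directions for tensor estimation, got ",
         nrow(bvecs))
  }
  X <- st_design(bvecs)
  if (qr(X)$rank < 6) stop("gradient directions are rank-deficient")
  XtXinv_Xt <- solve(crossprod(X), t(X))

  S <- dwi$signals
  S0 <- dwi$S0
  floor_val <- 1e-6 * S0
  n_clamped <- sum(S[dwi$valid, ] <= matrix(floor_val[dwi$valid],
                                            sum(dwi$valid), ncol(S)))
  S <- pmax(S, matrix(floor_val, nrow(S), ncol(S)))
  if (n_clamped > 0) {
    warning(n_clamped, " nonpositive signal(s) clamped to 1e-6 * S0")
  }
  ## y_k = log(S0/S_k)/b_k = g_k' D g_k
  Y <- (log(S0) - log(S)) / matrix(dwi$bvals, nrow(S), ncol(S), byrow = TRUE)
  tensors <- Y %*% t(XtXinv_Xt)
  tensors[!dwi$valid, ] <- 0
  out <- tensor_field(tensors, dims = dwi$dims, valid = dwi$valid)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Generate a noisy re-estimated tensor field from a clean phantom
#'
#' Convenience pipeline: Stejskal-Tanner synthesis, Rician noise at `snr`,
#' linear least-squares re-estimation. `snr = Inf` returns the clean field
#' unchanged (the noise-free pipeline is the identity to within round-off).
#'
#' @param field clean [tensor_field()]
#' @param snr signal-to-noise ratio (10 / 15 / 20 in the protocol), or `Inf`
#' @param seed RNG seed
#' @param bvecs,bval,S0 forwarded to [stejskal_tanner()]
#' @return a [tensor_field()]
#' @export
noisy_field <- function(field, snr, seed = NULL, bvecs = default_bvecs(),
                        bval = 1000, S0 = 100) {
  if (is.infinite(snr)) return(field)
  dwi <- stejskal_tanner(field, bvecs = bvecs, bval = bval, S0 = S0)
  suppressWarnings(fit_tensors_lls(add_rician_noise(dwi, snr, seed = seed)))
}
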