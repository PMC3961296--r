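test_that("eigendecomposition handles isotropic, diagonal and rotated tensors", {
  ## isotropic: eigenvalues (1,1,1), degenerate axis flagged, unit norm
  fld <- tensor_field(matrix(c(1, 0, 0, 1, 0, 1), 1), dims = c(1, 1))
  eig <- eigendecompose(fld)
  expect_equal(eig$values[1, ], c(1, 1, 1))
  expect_true(eig$degenerate[1])
  expect_equal(sum(eig$vectors[1, ]^2), 1, tolerance = 1e-10)

  ## diagonal: sorted eigenvalues, principal axis +-x
  fld <- tensor_field(matrix(c(3, 0, 0, 2, 0, 1), 1), dims = c(1, 1))
  eig <- eigendecompose(fld)
  expect_equal(eig$values[1, ], c(3, 2, 1))
  expect_equal(abs(eig$vectors[1, ]), c(1, 0, 0), tolerance = 1e-10)
  expect_false(eig$degenerate[1])

  ## construct-then-decompose round trip under random rotations
  set.seed(11)
  for (k in 1:10) {
    R <- random_rotation()
    D <- R %*% diag(c(3, 2, 1)) %*% t(R)
    fld <- tensor_field(array(D, c(1, 3, 3)), dims = c(1, 1))
    eig <- eigendecompose(fld)
    expect_equal(eig$values[1, ], c(3, 2, 1), tolerance = 1e-8)
    expect_equal(abs(sum(eig$vectors[1, ] * R[, 1])), 1, tolerance = 1e-8)
  }
})

test_that("non-symmetric tensors error with the voxel named", {
  arr <- array(0, c(2, 3, 3))
  arr[1, , ] <- diag(3)
  arr[2, , ] <- matrix(c(1, 0.5, 0, 0, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  expect_error(tensor_field(arr, dims = c(2, 1)), "voxel 2.*not symmetric")
})

test_that("MD/FA/VR match the closed forms", {
  mk <- function(lam) tensor_field(array(diag(lam), c(1, 3, 3)), dims = c(1, 1))
  fe <- compute_features(mk(c(1, 1, 1)))
  expect_equal(fe$md[1], 1)
  expect_equal(fe$fa[1], 0)
  expect_equal(fe$vr[1], 1)

  ## prolate limit: FA -> 1, VR -> 0
  fe <- compute_features(mk(c(1, 1e-9, 1e-9)))
  expect_equal(fe$fa[1], 1, tolerance = 1e-6)
  expect_equal(fe$vr[1], 0, tolerance = 1e-6)

  ## hand-evaluated case lambda = (2, 1, 1)
  fe <- compute_features(mk(c(2, 1, 1)))
  expect_equal(fe$md[1], 4 / 3)
  expect_equal(fe$fa[1], sqrt(1 / 6), tolerance = 1e-12)  # ~0.4082
  expect_equal(fe$vr[1], 54 / 64)
})

test_that("features are rotation invariant and scale as expected", {
  set.seed(21)
  for (k in 1:8) {
    D <- random_spd3()
    R <- random_rotation()
    c_pos <- runif(1, 0.5, 3)
    arr <- array(0, c(3, 3, 3))
    arr[1, , ] <- D
    arr[2, , ] <- R %*% D %*% t(R)
    arr[3, , ] <- c_pos * D
    fld <- tensor_field(arr, dims = c(3, 1))
    eig <- eigendecompose(fld)
    fe <- compute_features(eig)
    expect_equal(fe$md[2], fe$md[1], tolerance = 1e-8)
    expect_equal(fe$fa[2], fe$fa[1], tolerance = 1e-8)
    expect_equal(fe$vr[2], fe$vr[1], tolerance = 1e-8)
    ## FA and VR scale-invariant, MD linear in the scale
    expect_equal(fe$fa[3], fe$fa[1], tolerance = 1e-8)
    expect_equal(fe$vr[3], fe$vr[1], tolerance = 1e-8)
    expect_equal(fe$md[3], c_pos * fe$md[1], tolerance = 1e-8)
    ## reconstruct from the decomposition: identity on SPD tensors
    V <- eigen(D, symmetric = TRUE)
    expect_equal(V$vectors %*% diag(V$values) %*% t(V$vectors), D,
                 tolerance = 1e-8)
  }
})

test_that("min-max normalization is monotone, [0,1], and constant -> 0", {
  set.seed(31)
  fld <- random_field(c(4, 4))
  fe <- compute_features(fld)
  for (nm in c("md_norm", "fa_norm", "vr_norm")) {
    x <- fe[[nm]][fe$valid]
    expect_true(all(x >= 0 & x <= 1))
  }
  expect_equal(order(fe$md[fe$valid]), order(fe$md_norm[fe$valid]))

  ## constant field: all features identical -> normalized to 0, not 0/0
  tens <- matrix(rep(c(1, 0, 0, 1, 0, 1), each = 4), 4, 6)
  fe2 <- compute_features(tensor_field(tens * 1e-3, dims = c(2, 2)))
  expect_true(all(fe2$md_norm == 0 & fe2$fa_norm == 0 & fe2$vr_norm == 0))
})

test_that("SPD repair clamps tiny negatives and invalidates real ones", {
  ## slightly negative third eigenvalue within tolerance -> clamped valid
  D_ok <- diag(c(1, 0.5, 1e-14)) - diag(c(0, 0, 2e-14))
  ## genuinely indefinite tensor -> invalid, not silently zeroed
  D_bad <- diag(c(1, 0.5, -0.2))
  arr <- array(0, c(2, 3, 3))
  arr[1, , ] <- D_ok; arr[2, , ] <- D_bad
  fld <- tensor_field(arr, dims = c(2, 1))
  expect_true(fld$valid[1])
  expect_false(fld$valid[2])
  eig <- eigendecompose(fld)
  expect_true(all(eig$values[1, ] > 0))
  expect_true(all(is.na(eig$values[2, ])))
})

test_that("NIfTI tensor volumes round-trip bit-exactly in both dialects", {
  set.seed(41)
  fld <- random_field(c(3, 4))
  for (ext in c(".nii", ".nii.gz")) {
    path <- tempfile(fileext = ext)
    write_tensor_nifti(fld, path)
    back <- read_tensor_nifti(path)
    expect_identical(back$tensors, fld$tensors)
    expect_identical(back$dims, fld$dims)
    unlink(path)
  }
  ## lower-triangular dialect stores permuted components but reads back equal
  p_up <- tempfile(fileext = ".nii"); p_lo <- tempfile(fileext = ".nii")
  write_tensor_nifti(fld, p_up, dialect = "upper")
  write_tensor_nifti(fld, p_lo, dialect = "lower")
  expect_identical(read_tensor_nifti(p_lo, dialect = "lower")$tensors,
                   read_tensor_nifti(p_up, dialect = "upper")$tensors)
  ## reading the lower-dialect file as upper must NOT match (real permutation)
  expect_false(identical(read_tensor_nifti(p_lo, dialect = "upper")$tensors,
                         fld$tensors))
  unlink(c(p_up, p_lo))
})

test_that("all-zero voxels read back as invalid; wrong layout errors", {
  tens <- matrix(1e-3 * c(1, 0, 0, 1, 0, 1), 4, 6, byrow = TRUE)
  fld <- tensor_field(tens, dims = c(2, 2), valid = c(TRUE, TRUE, FALSE, TRUE))
  path <- tempfile(fileext = ".nii")
  write_tensor_nifti(fld, path)
  back <- read_tensor_nifti(path)
  expect_identical(back$valid, c(TRUE, TRUE, FALSE, TRUE))
  unlink(path)

  ## a 3-D scalar mask is not a 6-component tensor volume
  mpath <- tempfile(fileext = ".nii")
  write_mask_nifti(c(1, 0, 2, 0), mpath, dims = c(2, 2))
  expect_error(read_tensor_nifti(mpath), "6 tensor components")
  expect_identical(read_mask_nifti(mpath)$labels, c(1L, 0L, 2L, 0L))
  unlink(mpath)
})

test_that("raw binary lattice format round-trips", {
  set.seed(43)
  fld <- random_field(c(5, 3))
  path <- tempfile(fileext = ".bin")
  write_tensor_raw(fld, path)
  back <- read_tensor_raw(path)
  expect_identical(back$tensors, fld$tensors)
  expect_identical(back$dims, fld$dims)
  unlink(path)
})
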