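## Minimal NIfTI-1 I/O.
##
## No NIfTI package ships with the supported R stack, so a small reader and
## writer for the subset this package needs is implemented here: single-file
## .nii / .nii.gz, little-endian, no extensions, datatypes uint8 / int16 /
## int32 / float32 / float64, scl_slope/scl_inter honoured on read.
## Tensor volumes are stored as 6 components in the 5th dimension
## (dim = [5, nx, ny, nz, 1, 6, ...]); masks as 3-D integer volumes.

nii_con <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

nii_pad <- function(s, n) {
  raw_s <- charToRaw(s)
  c(raw_s[seq_len(min(length(raw_s), n))],
    raw(n - min(length(raw_s), n)))
}

write_nii <- function(path, data, dims, datatype, pixdim) {
  ## dims: full grid dims (length <= 5: x, y, z, t, comp)
  dim8 <- rep(1L, 8)
  dim8[1] <- length(dims)
  dim8[seq_along(dims) + 1] <- as.integer(dims)
  bitpix <- c(`2` = 8L, `4` = 16L, `8` = 32L, `16` = 32L, `64` = 64L)[
    as.character(datatype)]
  pd8 <- rep(1, 8)
  pd8[1] <- 1
  pd8[seq_along(pixdim) + 1] <- pixdim

  con <- nii_con(path, "wb")
  on.exit(close(con))
  w_int <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  w_short <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w_float <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  w_raw <- function(x) writeBin(x, con)

  w_int(348)                          # sizeof_hdr
  w_raw(raw(10))                      # data_type (unused)
  w_raw(raw(18))                      # db_name
  w_int(0); w_short(0); w_raw(as.raw(c(114L, 0L)))  # extents, session_error, regular='r', dim_info
  w_short(dim8)                       # dim[8]
  w_float(c(0, 0, 0))                 # intent_p1..3
  w_short(0)                          # intent_code
  w_short(datatype)                   # datatype
  w_short(bitpix)                     # bitpix
  w_short(0)                          # slice_start
  w_float(pd8)                        # pixdim[8]
  w_float(352)                        # vox_offset
  w_float(1); w_float(0)              # scl_slope, scl_inter
  w_short(0); w_raw(raw(2))           # slice_end, slice_code, xyzt_units
  w_float(c(0, 0, 0, 0))              # cal_max, cal_min, slice_duration, toffset
  w_int(c(0, 0))                      # glmax, glmin
  w_raw(nii_pad("dtseg", 80))         # descrip
  w_raw(raw(24))                      # aux_file
  w_short(c(0, 1))                    # qform_code, sform_code
  w_float(rep(0, 6))                  # quatern_b..d, qoffset_x..z
  w_float(c(pd8[2], 0, 0, 0))         # srow_x
  w_float(c(0, pd8[3], 0, 0))         # srow_y
  w_float(c(0, 0, pd8[4], 0))         # srow_z
  w_raw(raw(16))                      # intent_name
  w_raw(c(charToRaw("n+1"), raw(1)))  # magic
  w_raw(raw(4))                       # extension indicator

  if (datatype == 64) {
    writeBin(as.numeric(data), con, size = 8, endian = "little")
  } else if (datatype == 16) {
    writeBin(as.numeric(data), con, size = 4, endian = "little")
  } else {
    size <- bitpix / 8
    writeBin(as.integer(data), con, size = size, endian = "little")
  }
  invisible(path)
}

read_nii <- function(path) {
  con <- nii_con(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348)
  endian <- "little"
  sz <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
  if (sz != 348) {
    endian <- "big"
    sz <- readBin(hdr_raw[1:4], "integer", size = 4, endian = endian)
    if (sz != 348) stop("not a NIfTI-1 file: ", path)
  }
  r_short <- function(off, n = 1)
    readBin(hdr_raw[(off + 1):(off + 2 * n)], "integer", n = n, size = 2,
            endian = endian)
  r_float <- function(off, n = 1)
    readBin(hdr_raw[(off + 1):(off + 4 * n)], "numeric", n = n, size = 4,
            endian = endian)
  dim8 <- r_short(40, 8)
  datatype <- r_short(70)
  pixdim <- r_float(76, 8)
  vox_offset <- r_float(108)
  scl_slope <- r_float(112)
  scl_inter <- r_float(116)
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("unrecognized NIfTI magic: ", magic)

  ndim <- dim8[1]
  dims <- dim8[2:(1 + ndim)]
  n <- prod(dims)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  data <- switch(as.character(datatype),
    "2" = as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE)),
    "4" = as.numeric(readBin(con, "integer", n = n, size = 2, endian = endian)),
    "8" = as.numeric(readBin(con, "integer", n = n, size = 4, endian = endian)),
    "16" = readBin(con, "numeric", n = n, size = 4, endian = endian),
    "64" = readBin(con, "numeric", n = n, size = 8, endian = endian),
    stop("unsupported NIfTI datatype: ", datatype))
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    data <- data * scl_slope + scl_inter
  }
  list(data = data, dims = dims, pixdim = pixdim[2:(1 + ndim)])
}

## permutation between upper-triangular (Dxx,Dxy,Dxz,Dyy,Dyz,Dzz) and
## NIfTI lower-triangular row-major (Dxx,Dxy,Dyy,Dxz,Dyz,Dzz); involution
UT_LT_PERM <- c(1L, 2L, 4L, 3L, 5L, 6L)

#' Write a tensor field as a 6-component NIfTI-1 volume
#'
#' Components are stored along the 5th NIfTI dimension, by default in
#' upper-triangular order `(Dxx, Dxy, Dxz, Dyy, Dyz, Dzz)`; `dialect =
#' "lower"` writes the NIfTI symmetric-matrix order `(Dxx, Dxy, Dyy, Dxz,
#' Dyz, Dzz)` instead. Data are float64, so a write/read round trip is
#' bit-exact. Invalid voxels are written as all-zero tensors.
#'
#' @param field a [tensor_field()]
#' @param path output `.nii` or `.nii.gz` path
#' @param dialect component order on disk, `"upper"` (default) or `"lower"`
#' @export
write_tensor_nifti <- function(field, path, dialect = c("upper", "lower")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(field, "tensor_field"))
  d3 <- c(field$dims, rep(1L, 3 - length(field$dims)))
  tens <- field$tensors
  tens[!field$valid, ] <- 0
  if (dialect == "lower") tens <- tens[, UT_LT_PERM, drop = FALSE]
  ## column-major over (x, y, z, t=1, comp)
  write_nii(path, as.numeric(tens), dims = c(d3, 1L, 6L), datatype = 64,
            pixdim = c(field$voxel_size, rep(1, 5 - length(field$voxel_size))))
}

#' Read a 6-component NIfTI-1 tensor volume
#'
#' @param path `.nii` or `.nii.gz` file storing 6 tensor components per voxel
#' @param dialect component order on disk (see [write_tensor_nifti()])
#' @return a [tensor_field()]; all-zero voxels come back with `valid = FALSE`
#' @export
read_tensor_nifti <- function(path, dialect = c("upper", "lower")) {
  dialect <- match.arg(dialect)
  nii <- read_nii(path)
  dims <- nii$dims
  ncomp <- prod(dims) / prod(dims[seq_len(min(3, length(dims)))])
  if (ncomp != 6) {
    stop("expected 6 tensor components per voxel ",
         "(dim = [5, nx, ny, nz, 1, 6]), found ", ncomp)
  }
  d3 <- dims[1:min(3, length(dims))]
  nvox <- prod(d3)
  tens <- matrix(nii$data, nrow = nvox, ncol = 6)
  if (dialect == "lower") tens <- tens[, UT_LT_PERM, drop = FALSE]
  if (length(d3) == 3 && d3[3] == 1) d3 <- d3[1:2]
  tensor_field(tens, dims = d3, voxel_size = nii$pixdim[seq_along(d3)])
}

#' Write / read integer label or mask volumes as NIfTI-1
#'
#' Label coding follows the package convention: 1 = foreground seed,
#' 2 = background seed, 0 = unlabeled; segmentations are 1/0.
#'
#' @param labels integer vector (length = grid size) or array
#' @param dims grid dimensions (write only; inferred from array input)
#' @param path file path (`.nii` or `.nii.gz`)
#' @return `read_mask_nifti` returns a list with `labels` (integer vector)
#'   and `dims`.
#' @export
write_mask_nifti <- function(labels, path, dims = NULL) {
  if (is.array(labels) && is.null(dims)) dims <- dim(labels)
  stopifnot(!is.null(dims))
  d3 <- c(as.integer(dims), rep(1L, 3 - length(dims)))
  write_nii(path, as.integer(labels), dims = d3, datatype = 8,
            pixdim = rep(1, 3))
}

#' @rdname write_mask_nifti
#' @export
read_mask_nifti <- function(path) {
  nii <- read_nii(path)
  d <- nii$dims
  if (length(d) == 3 && d[3] == 1) d <- d[1:2]
  list(labels = as.integer(nii$data), dims = as.integer(d))
}

#' Raw binary array format for 2-D tensor lattices
#'
#' A trivial fallback format: int32 header `(ndim, dims...)` followed by the
#' `n x 6` upper-triangular tensor components as little-endian float64,
#' column-major.
#'
#' @param field a [tensor_field()]
#' @param path file path
#' @export
write_tensor_raw <- function(field, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(length(field$dims), field$dims), con, size = 4, endian = "little")
  tens <- field$tensors
  tens[!field$valid, ] <- 0
  writeBin(as.numeric(tens), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_tensor_raw
#' @export
read_tensor_raw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ndim <- readBin(con, "integer", n = 1, size = 4, endian = "little")
  dims <- readBin(con, "integer", n = ndim, size = 4, endian = "little")
  tens <- matrix(readBin(con, "numeric", n = prod(dims) * 6, size = 8,
                         endian = "little"),
                 nrow = prod(dims), ncol = 6)
  tensor_field(tens, dims = dims)
}
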