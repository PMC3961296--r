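#' Semi-supervised label propagation on the voxel graph
#'
#' Seeds carry hard labels `y = +1` (foreground) / `-1` (background); all
#' other voxels are `y = 0` (unlabeled). The score field `f` minimizes the
#' Laplacian smoothness `f' L f` subject to `f = y` on the seeds; the binary
#' segmentation thresholds `f` at zero.
#'
#' @name label-propagation
NULL

## connected components of the sparsity pattern of a symmetric sparse matrix
pattern_components <- function(A) {
  n <- nrow(A)
  Ap <- methods::as(A, "CsparseMatrix")
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      nb <- Ap@i[(Ap@p[v] + 1):Ap@p[v + 1]] + 1L
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Hard-constrained label solve
#'
#' Minimizes `f' L f` subject to `f_i = y_i` on labeled voxels, by solving
#' the reduced linear system `L_uu f_u = -L_ul y_l` — the exact minimizer of
#' the equality-constrained quadratic program.
#'
#' @param L normalized Laplacian (sparse symmetric)
#' @param y per-voxel constraints in `{+1, -1, 0}`; both classes must occur
#' @return numeric score vector `f` with `f = y` on labeled voxels
#' @export
solve_labels <- function(L, y) {
  n <- nrow(L)
  stopifnot(length(y) == n)
  if (!any(y > 0) || !any(y < 0)) {
    stop("need at least one foreground (+1) and one background (-1) seed")
  }
  lab <- which(y != 0)
  unl <- which(y == 0)
  f <- as.numeric(y)
  if (!length(unl)) return(f)

  ## every unlabeled component must contain a labeled voxel, else singular
  comp <- pattern_components(L)
  bad <- setdiff(unique(comp[unl]), unique(comp[lab]))
  if (length(bad)) {
    stop("unlabeled connected component with no seed (component containing ",
         "voxel ", which(comp == bad[1])[1], ")")
  }
  Luu <- L[unl, unl, drop = FALSE]
  rhs <- -L[unl, lab, drop = FALSE] %*% y[lab]
  f[unl] <- as.numeric(Matrix::solve(Luu, rhs))
  if (!all(is.finite(f))) stop("label solve produced non-finite scores")
  f
}

#' Soft-constrained label solve
#'
#' Minimizes `f' L f + mu * sum_labeled (f_i - y_i)^2`, the regularized cost
#' whose closed-form minimizer is `f = (L + mu J)^-1 (mu J y)` with `J` the
#' diagonal indicator of labeled voxels. Unlabeled voxels whose row of
#' `L + mu J` is identically zero (no smoothness, no fit) get `f = 0`, the
#' minimum-norm solution.
#'
#' @param L graph Laplacian (sparse symmetric PSD)
#' @param y per-voxel constraints in `{+1, -1, 0}`
#' @param mu trade-off between smoothness and fit, `> 0` (default 10)
#' @return numeric score vector `f`
#' @export
solve_labels_soft <- function(L, y, mu = 10) {
  if (mu <= 0) stop("mu must be > 0")
  n <- nrow(L)
  stopifnot(length(y) == n)
  J <- Matrix::Diagonal(n, as.numeric(y != 0))
  A <- L + mu * J
  f <- numeric(n)
  live <- which(Matrix::rowSums(abs(A)) > 0)
  if (length(live)) {
    f[live] <- as.numeric(Matrix::solve(A[live, live, drop = FALSE],
                                        (mu * (y != 0) * y)[live]))
  }
  f
}

#' Threshold scores into a binary segmentation
#'
#' Foreground iff `f > 0`; an exact zero is assigned to background (the
#' conservative choice for the structure of interest).
#'
#' @param f numeric score vector
#' @return integer vector, 1 = foreground, 0 = background
#' @export
decide <- function(f) {
  stopifnot(all(is.finite(f)))
  as.integer(f > 0)
}

## labels coded 1 = foreground, 2 = background, 0 = unlabeled -> y in {+1,-1,0}
labels_to_y <- function(labels) {
  y <- numeric(length(labels))
  y[labels == 1] <- 1
  y[labels == 2] <- -1
  y
}
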