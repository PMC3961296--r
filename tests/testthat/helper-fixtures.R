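## shared fixture builders; all randomness goes through the caller's RNG

random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

random_spd3 <- function(scale = 1) {
  A <- matrix(rnorm(9), 3, 3)
  scale * (crossprod(A) + diag(3) * 0.1)
}

random_psd4 <- function() {
  A <- matrix(rnorm(16), 4, 4)
  crossprod(A) / 4
}

## connected random weighted graph: spanning path + Bernoulli(p) extras
random_graph <- function(n, p = 0.3, wmin = 0.1, wmax = 1) {
  path <- cbind(seq_len(n - 1), 2:n)
  extra <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pick <- extra[runif(nrow(extra)) < p, , drop = FALSE]
  edges <- unique(rbind(path, pick))
  w <- runif(nrow(edges), wmin, wmax)
  W <- Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]),
                            j = c(edges[, 2], edges[, 1]),
                            x = c(w, w), dims = c(n, n))
  list(n = n, edges = edges, w = w, W = W, L = normalized_laplacian(W))
}

## random +1/-1 seed assignment with both classes present
random_seeds <- function(n, nlab = sample(2:5, 1)) {
  y <- numeric(n)
  lab <- sample(n, nlab)
  y[lab] <- c(1, -1, sample(c(-1, 1), nlab - 2, replace = TRUE))
  y
}

## small all-valid SPD field on a grid, tensors drawn by the caller's RNG
random_field <- function(dims) {
  n <- prod(dims)
  tens <- t(vapply(seq_len(n), function(i) {
    m <- random_spd3(1e-3)
    c(m[1, 1], m[1, 2], m[1, 3], m[2, 2], m[2, 3], m[3, 3])
  }, numeric(6)))
  tensor_field(tens, dims = dims)
}

## dense, base-R reference for the smoothness cost under a learned kernel:
## independent of the package's sparse-matrix path
dense_cost <- function(f, edges, dvecs, M, n) {
  w <- exp(-rowSums((dvecs %*% M) * dvecs))
  W <- matrix(0, n, n)
  W[edges] <- w
  W <- W + t(W)
  deg <- rowSums(W)
  L <- diag(n) - diag(1 / sqrt(deg)) %*% W %*% diag(1 / sqrt(deg))
  as.numeric(t(f) %*% L %*% f)
}
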