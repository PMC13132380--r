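# Non-negative matrix factorization engine: deterministic NNDSVD-style
# initialization (positive/negative parts of the truncated SVD, zeros filled
# with a small seeded perturbation around the matrix mean) plus Frobenius
# multiplicative updates. Written for the modest problem sizes of per-sample
# meta-program discovery (hundreds of genes x hundreds of cells, k <= ~10).

# NNDSVD initialization (Boutsidis & Gallopoulos): for each singular triplet
# keep the dominant sign-consistent (positive) parts of u and v.
nndsvd_init <- function(V, k, seed = 1L) {
  s <- svd(V, nu = k, nv = k)
  m <- nrow(V); n <- ncol(V)
  W <- matrix(0, m, k); H <- matrix(0, k, n)
  W[, 1L] <- sqrt(s$d[1L]) * abs(s$u[, 1L])
  H[1L, ] <- sqrt(s$d[1L]) * abs(s$v[, 1L])
  for (j in seq_len(k)[-1L]) {
    u <- s$u[, j]; v <- s$v[, j]
    up <- pmax(u, 0); un <- pmax(-u, 0)
    vp <- pmax(v, 0); vn <- pmax(-v, 0)
    nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
    nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
    if (nup * nvp >= nun * nvn) {
      scale <- sqrt(s$d[j] * nup * nvp)
      if (nup > 0 && nvp > 0) {
        W[, j] <- scale * up / nup
        H[j, ] <- scale * vp / nvp
      }
    } else {
      scale <- sqrt(s$d[j] * nun * nvn)
      if (nun > 0 && nvn > 0) {
        W[, j] <- scale * un / nun
        H[j, ] <- scale * vn / nvn
      }
    }
  }
  # fill exact zeros with a small seeded perturbation so multiplicative
  # updates cannot lock them at zero
  base <- mean(V) / 100
  if (base <= 0) base <- 1e-8
  fill <- function(X) {
    z <- X == 0
    if (any(z)) X[z] <- base * (1 + 0.01 * stats::runif(sum(z)))
    X
  }
  with_seed(seed, {
    W <- fill(W); H <- fill(H)
  })
  list(W = W, H = H)
}

#' Non-negative matrix factorization (Frobenius, multiplicative updates)
#'
#' Deterministic given the input and seed: NNDSVD initialization with a
#' seeded fill of structural zeros, then standard multiplicative updates
#' minimizing `||V - W H||_F`, at most `max_iter` iterations with a relative
#' objective-change stop.
#'
#' @param V Non-negative numeric matrix (genes x cells).
#' @param k Factorization rank; must satisfy `k <= min(dim(V))`.
#' @param max_iter Maximum iterations (default 500).
#' @param tol Relative Frobenius-objective change tolerance (default 1e-6),
#'   checked every 10 iterations.
#' @param seed Seed for the initialization fill.
#' @return List with `W` (genes x k), `H` (k x cells), `iterations`,
#'   `objective`.
#' @export
nmf_factorize <- function(V, k, max_iter = 500L, tol = 1e-6, seed = 1L) {
  if (any(V < 0) || any(!is.finite(V)))
    stop("NMF input must be non-negative and finite")
  if (k < 1L || k > min(dim(V)))
    stop("k must be between 1 and min(dim(V))")
  init <- nndsvd_init(V, k, seed)
  W <- init$W; H <- init$H
  eps <- .Machine$double.eps
  obj_old <- Inf
  it <- 0L
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, V)) / (crossprod(W) %*% H + eps)
    W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (it %% 10L == 0L) {
      obj <- sum((V - W %*% H)^2)
      if (is.finite(obj_old) && (obj_old - obj) <= tol * obj_old) break
      obj_old <- obj
    }
  }
  list(W = W, H = H, iterations = it, objective = sum((V - W %*% H)^2))
}
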