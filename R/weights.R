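# Local weight machinery for MLLE: per-point Gram spectra, regularized
# barycentric weights, and the multiple Householder-rotated weight vectors.

#' Local Gram matrix and singular spectrum
#'
#' For point i with neighborhood J_i, forms the centered neighbor matrix
#' C (k x D, rows x_j - x_i) and its Gram matrix G_i = C C'. The singular
#' values of C are the square roots of G_i's eigenvalues; their decay
#' determines how many reconstruction weight vectors the point contributes.
#'
#' @param X numeric n x D data matrix.
#' @param i point index (1-based).
#' @param J integer vector of neighbor indices (length k >= 2, excluding i).
#' @return List with `G` (k x k Gram matrix), `singvals` (descending),
#'   `evals` (squared singular values, descending, negatives clipped to 0)
#'   and `V` (k x k eigenvector matrix of G, columns matching `evals`).
#' @export
local_gram <- function(X, i, J) {
  C <- sweep(X[J, , drop = FALSE], 2, X[i, ])
  G <- tcrossprod(C)
  e <- eigen(G, symmetric = TRUE)
  evals <- pmax(e$values, 0)
  # eigenvalues beyond rank(C) <= D are exact zeros contaminated by
  # round-off; zero them so downstream ratio tests see the true spectrum
  nev <- min(ncol(C), length(evals))
  if (nev < length(evals)) evals[(nev + 1L):length(evals)] <- 0
  list(G = G, singvals = sqrt(evals), evals = evals, V = e$vectors)
}

#' Split a local spectrum into large and small parts
#'
#' Decides s_i, the number of trailing "small" singular values of the local
#' Gram matrix, which equals the number of independent weight vectors the
#' point contributes. s_i is the largest t such that the energy ratio
#' sum(evals[k-t+1..k]) / sum(evals[1..k-t]) stays below `eta`, clamped to
#' `[1, max(1, k - d)]`. A spectrum whose values are all equal (including
#' the all-zero degenerate neighborhood) carries no split information and
#' takes the upper clamp.
#'
#' @param singvals singular values of the centered neighbor matrix,
#'   descending, length k.
#' @param d embedding dimension.
#' @param eta relative energy threshold (default 1e-3).
#' @return List with `r` (count of large values) and `s` (= k - r).
#' @export
split_rank <- function(singvals, d, eta = 1e-3) {
  k <- length(singvals)
  evals <- singvals^2
  hi <- max(1L, k - as.integer(d))
  if (diff(range(evals)) <= 1e-12 * max(evals, 1e-300)) {
    s <- hi  # non-discriminating spectrum: no meaningful large/small split
  } else {
    tot <- cumsum(evals)
    s <- 0L
    for (t in seq_len(k - 1L)) {
      lead <- tot[k - t]
      trail <- tot[k] - lead
      # the ratio is nondecreasing in t, so the first failure is final
      if (lead > 0 && trail / lead < eta) s <- t else break
    }
    s <- min(max(s, 1L), hi)
  }
  list(r = k - s, s = s)
}

#' Regularized barycentric reconstruction weights
#'
#' Solves the sum-to-one least-squares reconstruction of x_i from its
#' neighbors: (G_i + gamma I) w = 1 followed by normalization to sum 1,
#' with gamma = `gamma_scale * trace(G_i)` (or `gamma_scale` itself when
#' the trace vanishes, i.e. all neighbors coincide with x_i). This is the
#' single regularized weight vector w_i(gamma) that anchors the multiple
#' weight construction.
#'
#' @param G k x k local Gram matrix (symmetric PSD).
#' @param gamma_scale relative ridge scale (default 1e-3).
#' @return Numeric weight vector of length k summing to 1.
#' @export
regularized_weights <- function(G, gamma_scale = 1e-3) {
  k <- nrow(G)
  tr <- sum(diag(G))
  reg <- if (tr > 0) gamma_scale * tr else gamma_scale
  w <- solve(G + diag(reg, k), rep(1, k))
  w / sum(w)
}

#' Multiple weight vectors via a Householder rotation
#'
#' Builds the s_i linearly independent weight columns
#' `w^(l) = (1 - alpha) w_reg + V H[, l]` from the orthonormal basis V of
#' the small-singular-value subspace: with `v = V' 1` and
#' `alpha = ||v|| / sqrt(s)`, H is the Householder reflection mapping v to
#' `alpha * 1`, so every column inherits the sum-to-one constraint
#' (`1'VH[,l] = (Hv)[l] = alpha`). When `||alpha*1 - v||` is negligible, H
#' is the identity.
#'
#' @param w_reg length-k regularized weight vector (sums to 1).
#' @param V k x s matrix with orthonormal columns spanning the small
#'   subspace of the local Gram matrix.
#' @param tol reflection degeneracy tolerance (default 1e-12).
#' @return List with `W` (k x s weight columns, each summing to 1), `H`
#'   (s x s symmetric orthogonal), `alpha` and `v`.
#' @export
householder_weights <- function(w_reg, V, tol = 1e-12) {
  V <- as.matrix(V)
  s <- ncol(V)
  v <- colSums(V)                      # V' 1_k
  alpha <- sqrt(sum(v^2)) / sqrt(s)
  h <- alpha - v
  nh <- sqrt(sum(h^2))
  if (nh < tol) {
    H <- diag(s)
    W <- V + (1 - alpha) * w_reg
  } else {
    h <- h / nh
    H <- diag(s) - 2 * tcrossprod(h)
    W <- V %*% H + (1 - alpha) * w_reg  # column recycling adds w_reg to each
  }
  list(W = W, H = H, alpha = alpha, v = v)
}

#' Assemble the MLLE alignment matrix
#'
#' The embedding cost E(Y) = sum_i sum_l || y_i - sum_j W_i[j,l] y_j ||^2
#' is the quadratic form y' Phi y of a symmetric PSD matrix Phi, built by
#' scattering each point's weight columns into the full index space.
#' Because every column sums to one, Phi annihilates the constant vector
#' (Phi 1 = 0), which is why the constant eigenvector is discarded at
#' embedding time.
#'
#' @param weights list of length n; element i is a list with `J` (neighbor
#'   indices) and `W` (k x s_i weight columns).
#' @param n number of training points.
#' @return Dense symmetric n x n matrix Phi.
#' @export
alignment_matrix <- function(weights, n) {
  if (length(weights) != n || any(vapply(weights, is.null, logical(1))))
    stop("weights must be a complete list of length n")
  Phi <- matrix(0, n, n)
  for (i in seq_len(n)) {
    J <- weights[[i]]$J
    W <- weights[[i]]$W
    Phi[J, J] <- Phi[J, J] + tcrossprod(W)
    rs <- rowSums(W)
    Phi[i, J] <- Phi[i, J] - rs
    Phi[J, i] <- Phi[J, i] - rs
    Phi[i, i] <- Phi[i, i] + ncol(W)
  }
  Phi
}

#' Embed from the alignment matrix
#'
#' The embedding minimizing E(Y) under the unit-covariance normalization is
#' given by the eigenvectors of Phi for the d smallest nonzero eigenvalues;
#' the near-zero constant eigenvector is discarded. A deterministic sign
#' convention (largest-magnitude entry of each column positive) makes runs
#' reproducible.
#'
#' @param Phi symmetric n x n alignment matrix.
#' @param d embedding dimension, `d <= n - 2`.
#' @return List with `Y` (n x d coordinates, columns orthonormal) and
#'   `eigvals` (the d + 1 smallest eigenvalues, ascending; the first is the
#'   discarded near-zero one).
#' @export
embed_alignment <- function(Phi, d) {
  n <- nrow(Phi)
  d <- as.integer(d)
  if (d > n - 2L)
    stop("embedding dimension d = ", d, " needs at least n = d + 2 = ",
         d + 2L, " training points (have ", n, ")")
  e <- eigen(Phi, symmetric = TRUE)
  vals <- rev(e$values)
  vecs <- e$vectors[, n:1, drop = FALSE]
  Y <- vecs[, 2:(d + 1L), drop = FALSE]
  for (j in seq_len(d)) {
    m <- which.max(abs(Y[, j]))
    if (Y[m, j] < 0) Y[, j] <- -Y[, j]
  }
  list(Y = Y, eigvals = vals[seq_len(d + 1L)])
}
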