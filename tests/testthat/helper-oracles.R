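# Independent oracles used across tests. These deliberately avoid the
# package's vectorized code paths: plain loops, brute-force enumerations,
# or an external reference implementation.

# Brute-force embedding cost: term-by-term sum over points and weight
# columns, never touching the alignment matrix.
brute_energy <- function(weights, Y) {
  tot <- 0
  for (i in seq_along(weights)) {
    J <- weights[[i]]$J
    W <- weights[[i]]$W
    for (l in seq_len(ncol(W))) {
      recon <- rep(0, ncol(Y))
      for (jj in seq_along(J))
        recon <- recon + W[jj, l] * Y[J[jj], ]
      tot <- tot + sum((Y[i, ] - recon)^2)
    }
  }
  tot
}

# Brute-force kNN sets from an all-pairs loop.
brute_knn <- function(X, k) {
  n <- nrow(X)
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    d <- rep(Inf, n)
    for (j in seq_len(n))
      if (j != i) d[j] <- sqrt(sum((X[i, ] - X[j, ])^2))
    out[i, ] <- order(d)[seq_len(k)]
  }
  out
}

# Reference MLLE embedding via the installed scikit-learn, run as a
# subprocess on a temporary CSV. Euclidean neighborhoods, dense solver.
reference_mlle <- function(X, k, d) {
  xin <- tempfile(fileext = ".csv")
  yout <- tempfile(fileext = ".csv")
  utils::write.table(X, xin, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "import numpy as np",
    "from sklearn.manifold import LocallyLinearEmbedding",
    sprintf("X = np.loadtxt(%s, delimiter=',')", shQuote(xin)),
    sprintf(paste0("m = LocallyLinearEmbedding(n_neighbors=%d, ",
                   "n_components=%d, method='modified', ",
                   "eigen_solver='dense')"), k, d),
    "Y = m.fit_transform(X)",
    sprintf("np.savetxt(%s, Y, delimiter=',')", shQuote(yout))),
    script)
  status <- system2("python", script, stdout = FALSE, stderr = FALSE)
  if (status != 0) stop("reference MLLE subprocess failed")
  as.matrix(utils::read.csv(yout, header = FALSE))
}

# Random orthonormal k x s matrix.
random_orthonormal <- function(k, s) {
  qr.Q(qr(matrix(stats::rnorm(k * s), k)))[, seq_len(s), drop = FALSE]
}

# Small random embedding set.
random_embeddings <- function(n, d, seed = 1) {
  set.seed(seed)
  word_embeddings(sprintf("tok%03d", seq_len(n)),
                  matrix(stats::rnorm(n * d), n))
}
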