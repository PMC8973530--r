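#' Fit a Modified Locally Linear Embedding model
#'
#' Fits MLLE on a set of training vectors: neighborhoods come from a
#' normalized geodesic metric on a Euclidean kNN graph (or plain Euclidean
#' kNN), each point gets s_i linearly independent sum-to-one reconstruction
#' weight vectors built from the small-singular-value subspace of its local
#' Gram matrix via a Householder rotation, and the embedding is read off
#' the bottom nontrivial eigenvectors of the assembled alignment matrix.
#'
#' The intended use for word vectors is to fit on a frequency window of the
#' vocabulary (see [select_window()]; sizes around 1001-2001 words with
#' k = 500 neighbours and `d` equal to the input dimension are the settings
#' explored in the accompanying parameter studies) and then re-embed the
#' whole vocabulary with [reembed()] / [predict.mlle()].
#'
#' @param x a `training_window` from [select_window()], a
#'   [word_embeddings] object, or a plain numeric matrix (rows = points).
#' @param k neighborhood size for the local weights (default 500, capped
#'   at n - 1). `k > d` is the well-posed regime; `k <= d` proceeds with a
#'   warning and a single weight vector per point.
#' @param d embedding dimension; default the input dimension D (re-embed
#'   between two equally-dimensional coordinate systems, no reduction).
#' @param neighbor_metric `"geodesic"` (normalized geodesic, default) or
#'   `"euclidean"`; see [neighbor_graph()].
#' @param k_graph neighbours used to build the geodesic support graph
#'   (default `k`).
#' @param gamma_scale ridge scale for the regularized weights, relative to
#'   trace(G_i) (default 1e-3).
#' @param eta relative energy threshold splitting each local spectrum into
#'   large/small parts (default 1e-3), or `"auto"` for the adaptive rule
#'   eta = median over points of rho_i, where rho_i is the energy ratio of
#'   the spectrum beyond the first d values (the rule used by reference
#'   MLLE implementations).
#' @return An object of class `mlle`; a list with (among others) `X_train`,
#'   `Y` (n x d embedded coordinates), `eigvals` (d + 1 smallest alignment
#'   eigenvalues), `weights` (per-point `J`, `W`, `w_reg`, `s`, `alpha`),
#'   `graph` (the `neighbor_graph`), `words`, `window` and the
#'   hyperparameters.
#' @examples
#' sim <- simulate_manifold_embeddings(120, ambient_dim = 5,
#'                                     manifold = "s_curve", seed = 7)
#' fit <- mlle(sim$embeddings, k = 10, d = 2)
#' fit
#' @export
mlle <- function(x, k = 500L, d = NULL,
                 neighbor_metric = c("geodesic", "euclidean"),
                 k_graph = k, gamma_scale = 1e-3, eta = 1e-3) {
  neighbor_metric <- match.arg(neighbor_metric)
  cl <- match.call()
  window <- NULL; words <- NULL
  if (inherits(x, "training_window")) {
    window <- list(start = x$start, size = x$size, indices = x$indices)
    words <- x$words
    X <- x$X
  } else if (inherits(x, "word_embeddings")) {
    words <- x$vocab
    X <- x$vectors
  } else {
    X <- as.matrix(x)
  }
  storage.mode(X) <- "double"
  n <- nrow(X); D <- ncol(X)
  if (is.null(d)) d <- D
  d <- as.integer(d); k <- as.integer(k)
  if (n < k + 1L) stop("training window must hold more than k points")
  if (d > n - 2L)
    stop("embedding dimension d = ", d, " requires at least d + 2 = ",
         d + 2L, " training points, have ", n)
  if (k <= d)
    warning("k = ", k, " <= d = ", d,
            ": a single weight vector per point will be used")

  graph <- neighbor_graph(X, k = k, k_graph = min(k_graph, n - 1L),
                          metric = neighbor_metric)
  J <- graph$neighborhoods

  # pass 1: local spectra and regularized weights
  loc <- vector("list", n)
  evals_mat <- matrix(0, n, k)
  for (i in seq_len(n)) {
    loc[[i]] <- local_gram(X, i, J[i, ])
    evals_mat[i, ] <- loc[[i]]$evals
  }

  # split rule: fixed relative eta, or the adaptive median-rho rule
  if (identical(eta, "auto")) {
    s_all <- auto_split(evals_mat, d, k, D)
  } else {
    s_all <- vapply(seq_len(n), function(i)
      split_rank(loc[[i]]$singvals, d, eta)$s, integer(1))
  }

  weights <- vector("list", n)
  for (i in seq_len(n)) {
    s_i <- s_all[i]
    w_reg <- regularized_weights(loc[[i]]$G, gamma_scale)
    V_s <- loc[[i]]$V[, (k - s_i + 1L):k, drop = FALSE]
    hw <- householder_weights(w_reg, V_s)
    weights[[i]] <- list(J = J[i, ], W = hw$W, w_reg = w_reg,
                         s = s_i, r = k - s_i, alpha = hw$alpha)
  }

  Phi <- alignment_matrix(weights, n)
  emb <- embed_alignment(Phi, d)

  structure(list(X_train = X, Y = emb$Y, eigvals = emb$eigvals,
                 weights = weights, graph = graph, words = words,
                 window = window, n = n, D = D, k = k, d = d,
                 gamma_scale = gamma_scale, eta = eta,
                 neighbor_metric = neighbor_metric, call = cl),
            class = "mlle")
}

# Adaptive split rule: eta is the median over points of the energy ratio
# rho_i beyond the first d spectrum values; s_i counts the trailing ratios
# below it (computed over the top nev = min(D, k) values, plus the k - nev
# structural zeros), clamped to [1, k - 1].
auto_split <- function(evals_mat, d, k, D) {
  n <- nrow(evals_mat)
  nev <- min(D, k)
  lead <- rowSums(evals_mat[, seq_len(min(d, nev)), drop = FALSE])
  trail <- rowSums(evals_mat[, seq_len(nev), drop = FALSE]) - lead
  rho <- ifelse(lead > 0, trail / lead, 0)
  eta <- stats::median(rho)
  s_all <- integer(n)
  for (i in seq_len(n)) {
    tot <- cumsum(evals_mat[i, seq_len(nev)])
    cnt <- 0L
    for (t in seq_len(nev - 1L)) {
      lead_t <- tot[nev - t]
      if (lead_t > 0 && (tot[nev] - lead_t) / lead_t < eta) cnt <- t
      else break
    }
    s_all[i] <- min(max(cnt + (k - nev), 1L), k - 1L)
  }
  s_all
}

#' Training reconstruction energy (brute force over weight columns)
#'
#' Evaluates E(Y) = sum_i sum_l || y_i - sum_j W_i[j,l] y_j ||^2 for an
#' arbitrary coordinate matrix. On the fitted coordinates this equals the
#' sum of the d nontrivial alignment eigenvalues.
#'
#' @param object a fitted `mlle` model.
#' @param Y n x d coordinate matrix (default the fitted coordinates).
#' @return The scalar energy.
#' @export
reconstruction_energy <- function(object, Y = object$Y) {
  stopifnot(inherits(object, "mlle"))
  Y <- as.matrix(Y)
  tot <- 0
  for (i in seq_len(object$n)) {
    w <- object$weights[[i]]
    YJ <- Y[w$J, , drop = FALSE]
    for (l in seq_len(ncol(w$W))) {
      r <- Y[i, ] - crossprod(YJ, w$W[, l])[, 1]
      tot <- tot + sum(r^2)
    }
  }
  tot
}

#' @export
print.mlle <- function(x, ...) {
  cat("Modified Locally Linear Embedding fit\n")
  cat("  n = ", x$n, " training points, D = ", x$D, " -> d = ", x$d, "\n",
      sep = "")
  cat("  k = ", x$k, " neighbours (", x$neighbor_metric, " metric), ",
      "gamma_scale = ", x$gamma_scale, ", eta = ",
      if (identical(x$eta, "auto")) "auto" else format(x$eta), "\n",
      sep = "")
  if (!is.null(x$window))
    cat("  vocabulary window: ranks [", x$window$start, ", ",
        x$window$start + x$window$size, ")\n", sep = "")
  cat("  embedding energy (sum of nontrivial eigenvalues): ",
      format(sum(x$eigvals[-1]), digits = 6), "\n", sep = "")
  invisible(x)
}

#' @export
summary.mlle <- function(object, ...) {
  s_vec <- vapply(object$weights, function(w) w$s, integer(1))
  structure(list(n = object$n, D = object$D, d = object$d, k = object$k,
                 metric = object$neighbor_metric,
                 s_table = table(s_vec),
                 eigvals = object$eigvals,
                 energy = sum(object$eigvals[-1]),
                 resid = summary(residuals.mlle(object)),
                 n_disconnected = object$graph$n_disconnected),
            class = "summary.mlle")
}

#' @export
print.summary.mlle <- function(x, ...) {
  cat("MLLE fit: n = ", x$n, ", D = ", x$D, " -> d = ", x$d, ", k = ",
      x$k, " (", x$metric, " neighbours)\n", sep = "")
  cat("  weight vectors per point (s_i):\n")
  print(x$s_table)
  cat("  smallest eigenvalues (first is the discarded constant mode):\n")
  print(signif(utils::head(x$eigvals, 6), 4))
  cat("  training reconstruction residuals (input space):\n")
  print(x$resid)
  invisible(x)
}

#' @describeIn mlle fitted embedded coordinates (n x d matrix, rownames =
#'   training words when known).
#' @param object,... method arguments.
#' @export
fitted.mlle <- function(object, ...) {
  Y <- object$Y
  if (!is.null(object$words)) rownames(Y) <- object$words
  Y
}

#' @describeIn mlle per-point input-space reconstruction error
#'   sqrt(sum_l ||x_i - sum_j W_i[j,l] x_j||^2), a diagnostic of how well
#'   each neighborhood supports the locally linear model.
#' @export
residuals.mlle <- function(object, ...) {
  X <- object$X_train
  vapply(seq_len(object$n), function(i) {
    w <- object$weights[[i]]
    XJ <- X[w$J, , drop = FALSE]
    sq <- 0
    for (l in seq_len(ncol(w$W)))
      sq <- sq + sum((X[i, ] - crossprod(XJ, w$W[, l])[, 1])^2)
    sqrt(sq)
  }, numeric(1))
}

#' @describeIn mlle scatter plot of two embedded coordinates.
#' @param dims which two embedding dimensions to plot.
#' @export
plot.mlle <- function(x, dims = c(1, 2), ...) {
  Y <- fitted.mlle(x)
  if (x$d < 2L) {
    graphics::plot(Y[, 1], rep(0, x$n), xlab = "dim 1", ylab = "",
                   main = "MLLE embedding", ...)
  } else {
    graphics::plot(Y[, dims[1]], Y[, dims[2]],
                   xlab = paste("dim", dims[1]),
                   ylab = paste("dim", dims[2]),
                   main = "MLLE embedding", ...)
  }
  invisible(x)
}

#' Save / load a fitted MLLE model archive
#'
#' The archive is a versioned RDS container holding the full fitted state
#' (training window, weights, embedded coordinates and hyperparameters), so
#' `predict`/`reembed` work after reloading. Serialization is
#' deterministic: refitting with the same inputs yields a byte-identical
#' archive.
#'
#' @param object a fitted `mlle` model.
#' @param path file path for the archive.
#' @return `save_mlle` returns `path` invisibly; `load_mlle` returns the
#'   `mlle` object.
#' @export
save_mlle <- function(object, path) {
  stopifnot(inherits(object, "mlle"))
  obj <- object
  obj$call <- NULL  # calls capture environments; drop for reproducibility
  saveRDS(list(format = "wordmlle-model", version = 1L, model = obj), path)
  invisible(path)
}

#' @rdname save_mlle
#' @export
load_mlle <- function(path) {
  arch <- readRDS(path)
  if (!is.list(arch) || !identical(arch$format, "wordmlle-model"))
    stop("not a wordmlle model archive: ", path)
  if (arch$version > 1L)
    stop("model archive version ", arch$version, " is newer than this package")
  arch$model
}
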