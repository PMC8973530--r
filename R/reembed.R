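#' Out-of-sample transform through a fitted MLLE model
#'
#' Embeds new points not seen at fit time: each point is expressed as a
#' regularized sum-to-one barycentric combination of its `k_oos` nearest
#' training points (weights of non-neighbours are zero), and the same
#' combination of the fitted coordinates is the closed-form minimizer of
#' the single-point embedding cost, y = sum_j w_j y_j. The transform is
#' therefore exactly linear in the training coordinates and equivariant
#' under their translation.
#'
#' Neighbours are ranked by Euclidean distance to the training window: a
#' novel point is outside the geodesic graph, and attaching it would use a
#' Euclidean hop anyway.
#'
#' @param object a fitted [mlle] model.
#' @param newdata numeric matrix (rows = points) or single vector of
#'   length D; a [word_embeddings] object is also accepted.
#' @param k_oos out-of-sample neighborhood size (default the model's k).
#' @param return_weights also return the sparse weight assignments as
#'   attributes `neighbors` and `weights`.
#' @param ... unused.
#' @return Numeric matrix (n_new x d) of embedded coordinates.
#' @export
predict.mlle <- function(object, newdata, k_oos = object$k,
                         return_weights = FALSE, ...) {
  if (inherits(newdata, "word_embeddings")) newdata <- newdata$vectors
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  storage.mode(newdata) <- "double"
  if (ncol(newdata) != object$D)
    stop("newdata has dimension ", ncol(newdata),
         " but the model was fitted on D = ", object$D)
  if (!all(is.finite(newdata))) stop("non-finite values in newdata")
  k_oos <- as.integer(k_oos)
  if (k_oos < 1L || k_oos > object$n)
    stop("k_oos must be in 1..n_train (= ", object$n, ")")

  X <- object$X_train
  Y <- object$Y
  # cross Euclidean distances, one shot
  d2 <- outer(rowSums(newdata^2), rep(1, object$n)) +
    outer(rep(1, nrow(newdata)), rowSums(X^2)) -
    2 * tcrossprod(newdata, X)
  d2[d2 < 0] <- 0
  m <- nrow(newdata)
  out <- matrix(0, m, object$d)
  Jmat <- matrix(0L, m, k_oos)
  Wmat <- matrix(0, m, k_oos)
  for (i in seq_len(m)) {
    J <- order(d2[i, ])[seq_len(k_oos)]
    C <- sweep(X[J, , drop = FALSE], 2, newdata[i, ])
    G <- tcrossprod(C)
    w <- regularized_weights(G, object$gamma_scale)
    out[i, ] <- crossprod(Y[J, , drop = FALSE], w)[, 1]
    Jmat[i, ] <- J
    Wmat[i, ] <- w
  }
  rownames(out) <- rownames(newdata)
  if (return_weights) {
    attr(out, "neighbors") <- Jmat
    attr(out, "weights") <- Wmat
  }
  out
}

#' Re-embed a whole vocabulary through a fitted model
#'
#' Maps every word of an embedding set into the manifold coordinate
#' system. Words that belong to the training window pass through to their
#' fitted coordinates by default (exact idempotence on the window); all
#' other words go through the out-of-sample extension of [predict.mlle()].
#'
#' @param model a fitted [mlle] model (fitted on a `training_window` or
#'   [word_embeddings] so that training words are known).
#' @param emb the [word_embeddings] to re-embed; its dimension must equal
#'   the model's input dimension.
#' @param k_oos out-of-sample neighborhood size (default the model's k).
#' @param training `"passthrough"` (default) reuses fitted coordinates for
#'   training-window words; `"transform"` re-transforms them like any
#'   other word.
#' @return A [word_embeddings] object with the same vocabulary and ranks,
#'   `dim = model$d`, and an attribute `"provenance"` recording the model
#'   parameters.
#' @export
reembed <- function(model, emb, k_oos = model$k,
                    training = c("passthrough", "transform")) {
  training <- match.arg(training)
  stopifnot(inherits(model, "mlle"), inherits(emb, "word_embeddings"))
  if (emb$dim != model$D)
    stop("embedding dimension ", emb$dim, " does not match model D = ",
         model$D)
  n <- length(emb$vocab)
  out <- matrix(NA_real_, n, model$d)
  hit <- rep(FALSE, n)
  if (training == "passthrough" && !is.null(model$words)) {
    pos <- match(emb$vocab, model$words)
    hit <- !is.na(pos)
    if (any(hit)) out[hit, ] <- model$Y[pos[hit], , drop = FALSE]
  }
  if (any(!hit))
    out[!hit, ] <- predict.mlle(model, emb$vectors[!hit, , drop = FALSE],
                                k_oos = k_oos)
  res <- word_embeddings(emb$vocab, out, emb$rank)
  attr(res, "provenance") <- list(
    d = model$d, k = model$k, k_oos = k_oos,
    neighbor_metric = model$neighbor_metric,
    gamma_scale = model$gamma_scale,
    window = model$window, training = training,
    n_passthrough = sum(hit))
  res
}

#' Deterministic random vector for an out-of-vocabulary word
#'
#' Out-of-vocabulary words are initialized at random according to the
#' dimension size: components i.i.d. uniform on [-0.5/dim, 0.5/dim], with
#' the RNG stream derived from the word itself plus a base seed, so the
#' same word always receives the same vector.
#'
#' @param word the word (used to derive the stream; different words get
#'   different vectors).
#' @param dim vector dimension.
#' @param seed base integer seed.
#' @return Numeric vector of length `dim`.
#' @export
oov_vector <- function(word, dim, seed = 1L) {
  stopifnot(dim > 0)
  h <- 0
  for (cp in utf8ToInt(word)) h <- (h * 31 + cp) %% 2147480017
  with_seed(as.integer((h + as.numeric(seed)) %% 2147480017), {
    stats::runif(dim, min = -0.5 / dim, max = 0.5 / dim)
  })
}
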