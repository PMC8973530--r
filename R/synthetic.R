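# Synthetic data with the statistical structure the re-embedding method
# assumes: vectors near a curved low-dimensional manifold lifted into a
# high-dimensional ambient space, a Zipf-ranked vocabulary, and gold
# similarity ratings that decay monotonically with latent proximity.

#' Generate word vectors lying near a low-dimensional manifold
#'
#' Samples latent coordinates on a chosen surface (swiss roll, S-curve, or
#' a linear subspace), lifts them into `ambient_dim` through a seeded
#' random orthogonal map (norm-preserving, so `noise_sigma` keeps its
#' meaning across ambient dimensions), and adds isotropic Gaussian noise.
#' Words are named `w00000`, `w00001`, ... with frequency rank equal to
#' generation order, emulating a frequency-sorted release.
#'
#' The returned latent coordinates are isometric surface coordinates
#' (arc-length along the roll for `swiss_roll`), so Euclidean distance in
#' latent space equals geodesic distance along the noiseless manifold —
#' the ground truth that re-embedding is meant to recover.
#'
#' @param n_words number of words (>= 10).
#' @param ambient_dim ambient dimension D (> intrinsic dimension).
#' @param manifold `"swiss_roll"`, `"s_curve"` or `"linear_subspace"`.
#' @param latent_dim intrinsic dimension (only for `linear_subspace`; the
#'   curved surfaces are 2-dimensional).
#' @param noise_sigma standard deviation of the ambient Gaussian noise.
#' @param seed RNG seed; same spec + seed reproduces the output exactly.
#' @return List with `embeddings` (a [word_embeddings]) and `latent`
#'   (n x d_true matrix of ground-truth coordinates).
#' @export
simulate_manifold_embeddings <- function(n_words, ambient_dim,
                                         manifold = c("swiss_roll",
                                                      "s_curve",
                                                      "linear_subspace"),
                                         latent_dim = 2L, noise_sigma = 0,
                                         seed = 1L) {
  manifold <- match.arg(manifold)
  stopifnot(n_words >= 10, noise_sigma >= 0)
  with_seed(seed, {
    if (manifold == "swiss_roll") {
      t <- 1.5 * pi * (1 + 2 * stats::runif(n_words))
      h <- stats::runif(n_words, 0, 21)
      coords <- cbind(t * cos(t), h, t * sin(t))
      arc <- (t * sqrt(1 + t^2) + asinh(t)) / 2  # unrolled arc length
      latent <- cbind(arc, h)
    } else if (manifold == "s_curve") {
      t <- stats::runif(n_words, -1.5 * pi, 1.5 * pi)
      h <- stats::runif(n_words, 0, 2)
      coords <- cbind(sin(t), h, sign(t) * (cos(t) - 1))
      latent <- cbind(t, h)  # unit-speed curve: t is arc length
    } else {
      latent <- matrix(stats::rnorm(n_words * latent_dim), n_words)
      coords <- latent
    }
    d0 <- ncol(coords)
    if (ambient_dim < d0)
      stop("ambient_dim must be at least ", d0, " for manifold '",
           manifold, "'")
    Q <- qr.Q(qr(matrix(stats::rnorm(ambient_dim^2), ambient_dim)))
    X <- coords %*% t(Q[, seq_len(d0), drop = FALSE])
    if (noise_sigma > 0)
      X <- X + matrix(stats::rnorm(length(X), sd = noise_sigma), nrow(X))
    vocab <- sprintf("w%05d", seq_len(n_words) - 1L)
    rownames(latent) <- vocab
    list(embeddings = word_embeddings(vocab, X), latent = latent)
  })
}

#' Generate a gold similarity dataset from latent coordinates
#'
#' Samples distinct word pairs and rates each as
#' `max_rating * exp(-dist / tau)` where `dist` is the latent (geodesic)
#' distance and `tau` the median sampled distance — a bounded score that is
#' strictly monotone-decreasing in latent distance, which is all a
#' rank-correlation evaluation needs.
#'
#' @param latent n x d matrix of latent coordinates with word rownames.
#' @param n_pairs number of pairs (at most n(n-1)/2).
#' @param seed RNG seed.
#' @param max_rating rating of an identical pair (default 10, MayoSRS-like
#'   1-10 scale).
#' @return A `similarity_dataset` of `n_pairs` pairs.
#' @export
generate_similarity_gold <- function(latent, n_pairs, seed = 1L,
                                     max_rating = 10) {
  latent <- as.matrix(latent)
  n <- nrow(latent)
  if (is.null(rownames(latent)))
    rownames(latent) <- sprintf("w%05d", seq_len(n) - 1L)
  if (n_pairs > n * (n - 1) / 2)
    stop("n_pairs exceeds the number of distinct pairs")
  with_seed(seed, {
    code <- sample.int(n * (n - 1L) / 2L, n_pairs)  # pair id, no repeats
    # decode the lower-triangle linear index; guard sqrt round-off
    i <- as.integer(ceiling((sqrt(8 * code + 1) - 1) / 2)) + 1L
    j <- code - (i - 1L) * (i - 2L) / 2L
    lo <- j < 1L
    i[lo] <- i[lo] - 1L
    j[lo] <- code[lo] - (i[lo] - 1L) * (i[lo] - 2L) / 2L
    hi <- j > i - 1L
    i[hi] <- i[hi] + 1L
    j[hi] <- code[hi] - (i[hi] - 1L) * (i[hi] - 2L) / 2L
    d <- sqrt(rowSums((latent[i, , drop = FALSE] -
                         latent[j, , drop = FALSE])^2))
    tau <- stats::median(d)
    if (tau == 0) tau <- 1
    similarity_dataset(rownames(latent)[i], rownames(latent)[j],
                       max_rating * exp(-d / tau),
                       name = "synthetic-gold")
  })
}

#' Zipf-distributed word frequencies
#'
#' Counts proportional to `rank^(-exponent)`, integerized with a large
#' constant so that the non-increasing order survives rounding, floored at
#' one occurrence.
#'
#' @param n_words vocabulary size.
#' @param exponent Zipf exponent (> 0, default 1.05 — typical for natural
#'   language).
#' @param top_count count of the most frequent word (default 1e7).
#' @return Integer vector of length `n_words`, non-increasing.
#' @export
generate_zipf_frequencies <- function(n_words, exponent = 1.05,
                                      top_count = 1e7) {
  stopifnot(exponent > 0)
  pmax(1L, as.integer(floor(top_count * seq_len(n_words)^(-exponent))))
}
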