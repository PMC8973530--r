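# Intrinsic evaluation: word-pair similarity datasets, cosine scores, and
# Pearson/Spearman agreement with human ratings.

#' Read a word-pair similarity dataset
#'
#' CSV with columns term1, term2, rating (header auto-detected from a
#' non-numeric third field on the first line), in the style of the medical
#' relatedness benchmarks (UMNSRS-Sim/Rel with 566/587 pairs, MayoSRS with
#' 101 pairs). Terms are whitespace-trimmed; duplicate pairs are an error.
#'
#' @param path CSV path.
#' @param name dataset identifier (default the file name).
#' @return A data.frame of class `similarity_dataset` with columns `term1`,
#'   `term2`, `rating`, and attributes `name` and `scale` (rating range).
#' @export
read_similarity <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty similarity file: ", path)
  first <- strsplit(lines[1], ",")[[1]]
  has_header <- length(first) >= 3 &&
    is.na(suppressWarnings(as.numeric(trimws(first[3]))))
  start <- if (has_header) 2L else 1L
  if (start > length(lines)) stop("no data rows in ", path)
  rows <- strsplit(lines[start:length(lines)], ",")
  term1 <- character(length(rows)); term2 <- character(length(rows))
  rating <- numeric(length(rows))
  for (i in seq_along(rows)) {
    f <- trimws(rows[[i]])
    if (length(f) < 3)
      stop("malformed line ", start + i - 1L, " in ", path,
           ": need term1,term2,rating")
    r <- suppressWarnings(as.numeric(f[3]))
    if (is.na(r))
      stop("non-numeric rating on line ", start + i - 1L, " in ", path,
           ": \"", f[3], "\"")
    term1[i] <- f[1]; term2[i] <- f[2]; rating[i] <- r
  }
  key <- paste(term1, term2, sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1]
    stop("duplicate pair in ", path, ": (", term1[d], ", ", term2[d], ")")
  }
  similarity_dataset(term1, term2, rating, name = name)
}

#' @rdname read_similarity
#' @param term1,term2 character vectors of paired terms.
#' @param rating numeric human ratings on the dataset's native scale.
#' @export
similarity_dataset <- function(term1, term2, rating, name = "dataset") {
  ds <- data.frame(term1 = as.character(term1),
                   term2 = as.character(term2),
                   rating = as.numeric(rating),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(paste(ds$term1, ds$term2, sep = "\r")))
    stop("duplicate (term1, term2) pairs")
  attr(ds, "name") <- name
  attr(ds, "scale") <- range(ds$rating)
  class(ds) <- c("similarity_dataset", "data.frame")
  ds
}

#' Write a similarity dataset as CSV
#' @param ds a `similarity_dataset`.
#' @param path output path.
#' @export
write_similarity <- function(ds, path) {
  utils::write.csv(as.data.frame(ds)[, c("term1", "term2", "rating")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Look up (or compose) the vector for a term
#'
#' Single-token terms map to their stored vector. Multiword medical terms
#' ("pulmonary edema") map to the mean of their in-vocabulary token
#' vectors. When every token is out of vocabulary the result depends on
#' the policy: `"skip"` returns NULL, `"random"` substitutes the seeded
#' deterministic random vectors of [oov_vector()] for the missing tokens.
#'
#' @param emb a [word_embeddings] object.
#' @param term the term (possibly multiword, space-separated).
#' @param oov_policy `"skip"` or `"random"`.
#' @param seed base seed for `"random"`.
#' @return A length-D vector, or NULL when skipped.
#' @export
term_vector <- function(emb, term, oov_policy = c("skip", "random"),
                        seed = 1L) {
  oov_policy <- match.arg(oov_policy)
  stopifnot(nzchar(term))
  tokens <- strsplit(trimws(term), "[[:space:]]+")[[1]]
  idx <- match(tokens, emb$vocab)
  if (all(is.na(idx)) && oov_policy == "skip") return(NULL)
  vecs <- matrix(NA_real_, length(tokens), emb$dim)
  vecs[!is.na(idx), ] <- emb$vectors[idx[!is.na(idx)], , drop = FALSE]
  if (any(is.na(idx))) {
    if (oov_policy == "skip") {
      vecs <- vecs[!is.na(idx), , drop = FALSE]
    } else {
      for (t in which(is.na(idx)))
        vecs[t, ] <- oov_vector(tokens[t], emb$dim, seed)
    }
  }
  colMeans(vecs)
}

#' Cosine similarity of two vectors
#' @param u,v numeric vectors of equal length, neither all-zero.
#' @return `u . v / (||u|| ||v||)`, in [-1, 1].
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Pearson and Spearman correlation, from first principles
#'
#' `pearson_cor` is the sample product-moment correlation computed from
#' centered sums; `spearman_cor` is the Pearson correlation of mid-ranks
#' (ties receive average ranks). Both require at least 3 observations and
#' nonzero variance.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return Correlation in [-1, 1].
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3) stop("need at least 3 observations")
  xc <- x - mean(x); yc <- y - mean(y)
  sx <- sum(xc^2); sy <- sum(yc^2)
  if (sx == 0 || sy == 0) stop("correlation undefined: zero variance")
  sum(xc * yc) / sqrt(sx * sy)
}

#' @rdname pearson_cor
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  pearson_cor(rx, ry)
}

#' Evaluate an embedding against a similarity dataset
#'
#' Scores every scorable pair by cosine similarity and reports the Pearson
#' and Spearman correlation of the scores with the human ratings. With the
#' default `"skip"` policy, pairs whose terms cannot be resolved are
#' dropped and counted in `n_skipped` (never scored with fabricated
#' vectors).
#'
#' @param emb a [word_embeddings] object.
#' @param ds a `similarity_dataset`.
#' @param oov_policy `"skip"` (default) or `"random"`; see [term_vector()].
#' @param seed base seed for the `"random"` policy.
#' @return An object of class `embedding_eval`: list with `name`,
#'   `pearson`, `spearman`, `n_scored`, `n_skipped`, `scores`, `ratings`.
#' @export
evaluate_embeddings <- function(emb, ds, oov_policy = c("skip", "random"),
                                seed = 1L) {
  oov_policy <- match.arg(oov_policy)
  stopifnot(inherits(emb, "word_embeddings"),
            inherits(ds, "similarity_dataset"))
  scores <- numeric(0); ratings <- numeric(0)
  n_skipped <- 0L
  for (i in seq_len(nrow(ds))) {
    v1 <- term_vector(emb, ds$term1[i], oov_policy, seed)
    v2 <- term_vector(emb, ds$term2[i], oov_policy, seed)
    if (is.null(v1) || is.null(v2) || sum(v1^2) == 0 || sum(v2^2) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    scores <- c(scores, cosine_similarity(v1, v2))
    ratings <- c(ratings, ds$rating[i])
  }
  if (length(scores) < 3)
    stop("fewer than 3 scorable pairs (", length(scores), " scored, ",
         n_skipped, " skipped): vocabulary overlap too small")
  structure(list(name = attr(ds, "name"),
                 pearson = pearson_cor(scores, ratings),
                 spearman = spearman_cor(scores, ratings),
                 n_scored = length(scores), n_skipped = n_skipped,
                 scores = scores, ratings = ratings),
            class = "embedding_eval")
}

#' @export
print.embedding_eval <- function(x, ...) {
  cat(sprintf("%s\tn_scored=%d\tn_skipped=%d\tpearson=%.4f\tspearman=%.4f\n",
              x$name, x$n_scored, x$n_skipped, x$pearson, x$spearman))
  invisible(x)
}
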