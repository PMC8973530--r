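#' Construct a word embedding set
#'
#' Bundles an ordered vocabulary with its dense vector matrix and a per-word
#' frequency rank. Rank 0 is the most frequent word; standard word2vec and
#' GloVe releases are frequency-sorted, so rank defaults to row order.
#'
#' @param vocab character vector of unique words.
#' @param vectors numeric matrix, one row per word, all entries finite.
#' @param rank integer vector, a permutation of `0:(N-1)`; rank 0 = most
#'   frequent word. Defaults to file/row order.
#' @return An object of class `word_embeddings`: a list with elements
#'   `vocab`, `vectors` (rownames set to `vocab`), `rank` and `dim`.
#' @examples
#' emb <- word_embeddings(c("a", "b"), rbind(c(1, 0), c(0, 1)))
#' emb$dim
#' @export
word_embeddings <- function(vocab, vectors,
                            rank = seq_along(vocab) - 1L) {
  vocab <- as.character(vocab)
  if (!is.matrix(vectors)) vectors <- matrix(vectors, nrow = length(vocab))
  storage.mode(vectors) <- "double"
  n <- length(vocab)
  if (n == 0L) stop("empty vocabulary")
  if (nrow(vectors) != n)
    stop("vocab has ", n, " words but vectors has ", nrow(vectors), " rows")
  dup <- vocab[duplicated(vocab)]
  if (length(dup))
    stop("duplicate word(s) in vocabulary: ", paste(utils::head(dup, 3), collapse = ", "))
  if (!all(is.finite(vectors)))
    stop("non-finite entries in embedding vectors")
  rank <- as.integer(rank)
  if (length(rank) != n || !setequal(rank, 0:(n - 1L)))
    stop("rank must be a permutation of 0..N-1")
  rownames(vectors) <- vocab
  structure(list(vocab = vocab, vectors = vectors, rank = rank,
                 dim = ncol(vectors)),
            class = "word_embeddings")
}

#' @export
print.word_embeddings <- function(x, ...) {
  cat("Word embedding set: ", length(x$vocab), " words x ", x$dim,
      " dimensions\n", sep = "")
  cat("  head of vocabulary (frequency order): ",
      paste(utils::head(x$vocab[order(x$rank)], 5), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.word_embeddings <- function(x) dim(x$vectors)

parse_vector_lines <- function(lines, path, first_data_line = 1L) {
  fields <- strsplit(lines, " +")
  d <- length(fields[[1]]) - 1L
  if (d < 1L)
    stop("malformed line ", first_data_line, " in ", path,
         ": no vector components")
  words <- character(length(fields))
  vecs <- matrix(NA_real_, length(fields), d)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) != d + 1L)
      stop("malformed line ", first_data_line + i - 1L, " in ", path,
           ": expected ", d + 1L, " fields, found ", length(f))
    words[i] <- f[1]
    v <- suppressWarnings(as.numeric(f[-1]))
    if (anyNA(v))
      stop("malformed line ", first_data_line + i - 1L, " in ", path,
           ": non-numeric vector component")
    vecs[i, ] <- v
  }
  list(words = words, vectors = vecs)
}

#' Read a word embedding file
#'
#' Reads word2vec text (first line a `"N D"` header), GloVe text (no header)
#' or word2vec binary files into a [word_embeddings] object. Frequency rank
#' defaults to row order, matching the frequency-sorted convention of
#' standard releases; an optional `word<TAB>count` side file overrides it.
#'
#' @param path path to the embedding file.
#' @param format one of `"word2vec"` (text with header), `"glove"` (text,
#'   no header), `"word2vec_bin"` (binary, little-endian float32).
#' @param lowercase lowercase all words at load time (duplicates created by
#'   case-folding are an error).
#' @param counts optional path to a two-column `word<TAB>count` file; words
#'   are then ranked by decreasing count (ties keep file order).
#' @return A [word_embeddings] object whose row order equals file order.
#' @export
read_embeddings <- function(path,
                            format = c("word2vec", "glove", "word2vec_bin"),
                            lowercase = FALSE, counts = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "word2vec_bin") {
    out <- read_word2vec_bin(path)
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) stop("empty embedding file: ", path)
    if (format == "word2vec") {
      hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), " +")[[1]]))
      if (length(hdr) != 2L || anyNA(hdr))
        stop("malformed word2vec header in ", path, ": expected \"N D\"")
      body <- lines[-1]
      if (length(body) != hdr[1])
        stop("word2vec header in ", path, " declares ", hdr[1],
             " rows but file has ", length(body))
      out <- parse_vector_lines(body, path, first_data_line = 2L)
      if (ncol(out$vectors) != hdr[2])
        stop("word2vec header in ", path, " declares dimension ", hdr[2],
             " but rows have ", ncol(out$vectors))
    } else {
      out <- parse_vector_lines(lines, path)
    }
  }
  words <- out$words
  if (lowercase) words <- tolower(words)
  rank <- seq_along(words) - 1L
  if (!is.null(counts)) rank <- rank_from_counts(words, counts)
  word_embeddings(words, out$vectors, rank)
}

rank_from_counts <- function(words, counts_path) {
  if (!file.exists(counts_path)) stop("no such counts file: ", counts_path)
  tab <- utils::read.table(counts_path, sep = "\t", header = FALSE,
                           quote = "", comment.char = "",
                           col.names = c("word", "count"),
                           colClasses = c("character", "numeric"))
  cnt <- tab$count[match(words, tab$word)]
  cnt[is.na(cnt)] <- -Inf  # words absent from the side file rank last
  ord <- order(-cnt, seq_along(words))
  rank <- integer(length(words))
  rank[ord] <- seq_along(words) - 1L
  rank
}

read_word2vec_bin <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (!length(ch) || ch == "\n") break
    hdr <- c(hdr, ch)
  }
  hdr <- as.integer(strsplit(trimws(paste(hdr, collapse = "")), " +")[[1]])
  if (length(hdr) != 2L || anyNA(hdr))
    stop("malformed word2vec binary header in ", path)
  n <- hdr[1]; d <- hdr[2]
  words <- character(n)
  vecs <- matrix(NA_real_, n, d)
  for (i in seq_len(n)) {
    w <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch)) stop("truncated word2vec binary file: ", path)
      if (ch == " ") break
      if (ch != "\n") w <- c(w, ch)
    }
    words[i] <- paste(w, collapse = "")
    v <- readBin(con, "numeric", n = d, size = 4L, endian = "little")
    if (length(v) != d) stop("truncated word2vec binary file: ", path)
    vecs[i, ] <- v
  }
  list(words = words, vectors = vecs)
}

#' Write a word embedding file
#'
#' Inverse of [read_embeddings()]: word2vec text gets exactly one `"N D"`
#' header line, GloVe text none, word2vec binary stores float32. Word order
#' is preserved. Text output keeps 8 significant digits, so a text
#' round-trip reproduces vectors to well within 1e-6 relative error.
#'
#' @param emb a [word_embeddings] object.
#' @param path output path.
#' @param format see [read_embeddings()].
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(emb, path,
                             format = c("word2vec", "glove", "word2vec_bin")) {
  format <- match.arg(format)
  stopifnot(inherits(emb, "word_embeddings"))
  if (length(emb$vocab) == 0L) stop("refusing to write an empty vocabulary")
  if (format == "word2vec_bin") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(paste0(length(emb$vocab), " ", emb$dim, "\n"), con,
              eos = NULL, useBytes = TRUE)
    for (i in seq_along(emb$vocab)) {
      writeChar(paste0(emb$vocab[i], " "), con, eos = NULL, useBytes = TRUE)
      writeBin(as.numeric(emb$vectors[i, ]), con, size = 4L,
               endian = "little")
    }
    return(invisible(path))
  }
  rows <- vapply(seq_along(emb$vocab), function(i) {
    paste(emb$vocab[i],
          paste(formatC(emb$vectors[i, ], format = "g", digits = 8),
                collapse = " "))
  }, character(1))
  if (format == "word2vec")
    rows <- c(paste(length(emb$vocab), emb$dim), rows)
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' Select a frequency-window of the vocabulary for training
#'
#' Window sampling picks a contiguous block of the frequency-ranked
#' vocabulary as the manifold-learning training set: frequent words sample
#' the underlying semantic manifold densely, and a window keeps the O(n^2)
#' neighbor computations tractable. Typical settings from the tuning studies
#' are sizes 1001/1501/2001 with start offsets in 0..1000.
#'
#' @param emb a [word_embeddings] object.
#' @param start first frequency rank included (0-based; default 0 = most
#'   frequent word).
#' @param size number of words in the window.
#' @return An object of class `training_window`: list with `start`, `size`,
#'   `indices` (row indices into `emb`, in rank order), `words`, `X`
#'   (`size` x D matrix) and `parent_n`.
#' @export
select_window <- function(emb, start = 0L, size) {
  stopifnot(inherits(emb, "word_embeddings"))
  start <- as.integer(start); size <- as.integer(size)
  n <- length(emb$vocab)
  if (size <= 0L) stop("window size must be positive")
  if (start < 0L) stop("window start must be >= 0")
  if (start + size > n)
    stop("window [", start, ", ", start + size, ") exceeds vocabulary of ",
         n, " words")
  want <- start:(start + size - 1L)
  idx <- order(emb$rank)[want + 1L]
  structure(list(start = start, size = size, indices = idx,
                 words = emb$vocab[idx],
                 X = emb$vectors[idx, , drop = FALSE],
                 parent_n = n),
            class = "training_window")
}

#' @export
print.training_window <- function(x, ...) {
  cat("Training window: ranks [", x$start, ", ", x$start + x$size,
      ") -> ", x$size, " words x ", ncol(x$X), " dims\n", sep = "")
  invisible(x)
}
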