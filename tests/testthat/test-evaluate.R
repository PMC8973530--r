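test_that("similarity CSV parsing handles headers, trimming and errors", {
  f <- withr::local_tempfile(lines = c("renal failure, kidney failure ,8.1",
                                       "heart,lung,2.0",
                                       "fever,cough,3.5"))
  ds <- read_similarity(f)
  expect_s3_class(ds, "similarity_dataset")
  expect_equal(nrow(ds), 3L)
  expect_identical(ds$term2[1], "kidney failure")
  expect_equal(attr(ds, "scale"), c(2.0, 8.1))
  # header detected from a non-numeric third field, MayoSRS-sized body
  set.seed(71)
  body <- sprintf("t%03da,t%03db,%.2f", 1:101, 1:101, runif(101, 1, 10))
  fh <- withr::local_tempfile(lines = c("Term1,Term2,Mean", body))
  expect_equal(nrow(read_similarity(fh)), 101L)
  fbad <- withr::local_tempfile(lines = c("a,b,1.0", "c,d,oops"))
  expect_error(read_similarity(fbad), "line 2")
  fdup <- withr::local_tempfile(lines = c("a,b,1.0", "a,b,2.0"))
  expect_error(read_similarity(fdup), "duplicate pair")
})

test_that("term vectors average tokens and honour the OOV policy", {
  emb <- word_embeddings(c("pulmonary", "edema", "renal"),
                         rbind(c(1, 0), c(0, 1), c(2, 2)))
  expect_equal(term_vector(emb, "renal"), c(2, 2))
  expect_equal(term_vector(emb, "pulmonary edema"), c(0.5, 0.5))
  # partially OOV multiword: mean of the present tokens under skip
  expect_equal(term_vector(emb, "pulmonary xyz"), c(1, 0))
  expect_null(term_vector(emb, "xyz abc"))
  r <- term_vector(emb, "xyz abc", oov_policy = "random", seed = 3)
  expect_length(r, 2)
  expect_identical(r, term_vector(emb, "xyz abc", "random", seed = 3))
})

test_that("cosine similarity matches hand values and rejects zeros", {
  expect_equal(cosine_similarity(c(2, 1), c(2, 1)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  expect_error(cosine_similarity(1:2, 1:3), "length")
})

test_that("correlations agree with an independent statistics routine", {
  expect_equal(pearson_cor(1:10, 2 * (1:10) + 3), 1)
  expect_equal(pearson_cor(1:10, -(1:10)), -1)
  expect_equal(spearman_cor(1:10, exp(1:10)), 1)
  expect_equal(spearman_cor(1:10, 10:1), -1)
  set.seed(72)
  for (rep in 1:100) {
    n <- sample(5:60, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    if (rep %% 2 == 0) { x <- round(x, 1); y <- round(y, 1) }  # ties
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    expect_equal(pearson_cor(x, y), stats::cor(x, y), tolerance = 1e-12)
    expect_equal(spearman_cor(x, y),
                 stats::cor(x, y, method = "spearman"),
                 tolerance = 1e-12)
  }
  expect_error(pearson_cor(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_cor(1:2, 1:2), "at least 3")
})

test_that("correlations are symmetric and transform-invariant", {
  set.seed(73)
  x <- rnorm(40); y <- rnorm(40)
  expect_equal(pearson_cor(x, y), pearson_cor(y, x))
  expect_equal(pearson_cor(3 * x + 1, y), pearson_cor(x, y),
               tolerance = 1e-12)
  expect_equal(spearman_cor(exp(x), y), spearman_cor(x, y))
})

test_that("evaluation scores pairs, skips OOV and enforces overlap", {
  set.seed(74)
  emb <- random_embeddings(30, 8, seed = 74)
  # a dataset whose ratings are an exact monotone function of cosine
  i <- sample(30, 40, replace = TRUE); j <- sample(30, 40, replace = TRUE)
  keep <- !duplicated(cbind(i, j)) & i != j
  i <- i[keep]; j <- j[keep]
  cs <- vapply(seq_along(i), function(p)
    cosine_similarity(emb$vectors[i[p], ], emb$vectors[j[p], ]),
    numeric(1))
  ds <- similarity_dataset(emb$vocab[i], emb$vocab[j], 10 * exp(cs))
  ev <- evaluate_embeddings(emb, ds)
  expect_equal(ev$spearman, 1)
  expect_equal(ev$n_skipped, 0L)
  # unknown terms are skipped and counted, never fabricated
  ds2 <- similarity_dataset(c(emb$vocab[1:3], "nope1", "nope2"),
                            c(emb$vocab[4:6], "nope3", emb$vocab[7]),
                            c(1, 2, 3, 4, 5))
  ev2 <- evaluate_embeddings(emb, ds2)
  expect_equal(ev2$n_scored, 3L)
  expect_equal(ev2$n_skipped, 2L)
  expect_equal(ev2$n_scored + ev2$n_skipped, nrow(ds2))
  # no vocabulary overlap at all
  ds3 <- similarity_dataset(c("q1", "q2", "q3"), c("q4", "q5", "q6"), 1:3)
  expect_error(evaluate_embeddings(emb, ds3), "fewer than 3")
  expect_output(print(ev2), "n_scored=3")
})
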