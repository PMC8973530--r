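fit_roll <- local({
  sim <- simulate_manifold_embeddings(300, ambient_dim = 5,
                                      manifold = "swiss_roll",
                                      noise_sigma = 0.02, seed = 61)
  list(sim = sim, fit = mlle(sim$embeddings, k = 10, d = 2))
})

test_that("training points reconstruct themselves through their neighborhoods", {
  fit <- fit_roll$fit
  Yhat <- predict(fit, fit$X_train)
  err <- sqrt(rowSums((Yhat - fit$Y)^2))
  rms <- sqrt(mean(rowSums(fit$Y^2)))
  expect_lt(median(err) / rms, 0.05)
})

test_that("a symmetric query splits its weight evenly between two neighbors", {
  # planar training grid so the two nearest neighbors of an edge midpoint
  # are its endpoints
  g <- as.matrix(expand.grid(x = 0:4, y = 0:4))
  fit <- mlle(g, k = 6, d = 2, neighbor_metric = "euclidean")
  x <- colMeans(g[1:2, ])               # midpoint of (0,0) and (1,0)
  y <- predict(fit, x, k_oos = 2, return_weights = TRUE)
  w <- attr(y, "weights")
  expect_setequal(as.vector(attr(y, "neighbors")), 1:2)
  expect_equal(as.vector(w), c(0.5, 0.5), tolerance = 1e-10)
  expect_equal(as.vector(y), colMeans(fit$Y[1:2, ]), tolerance = 1e-10)
})

test_that("out-of-sample weights sum to one and vanish off-neighborhood", {
  fit <- fit_roll$fit
  set.seed(62)
  q <- fit$X_train[1:8, ] + matrix(rnorm(8 * 5, sd = 0.05), 8)
  y <- predict(fit, q, k_oos = 7, return_weights = TRUE)
  W <- attr(y, "weights")
  expect_equal(rowSums(W), rep(1, 8), tolerance = 1e-10)
  expect_equal(ncol(W), 7L)             # all other training weights are 0
  expect_error(predict(fit, q[, 1:3]), "dimension")
  expect_error(predict(fit, q * NaN), "non-finite")
  expect_error(predict(fit, q, k_oos = 0), "k_oos")
})

test_that("transform is linear in Y and translation-equivariant", {
  fit <- fit_roll$fit
  set.seed(63)
  q <- fit$X_train[5, ] + rnorm(5, sd = 0.03)
  y <- predict(fit, q)
  fit2 <- fit; fit2$Y <- 2 * fit$Y
  expect_equal(predict(fit2, q), 2 * y, tolerance = 1e-10)
  fit3 <- fit; fit3$Y <- sweep(fit$Y, 2, c(-1.5, 4), "+")
  expect_equal(as.vector(predict(fit3, q)),
               as.vector(y) + c(-1.5, 4), tolerance = 1e-10)
})

test_that("self-reconstruction degrades monotonically with query noise", {
  fit <- fit_roll$fit
  med <- vapply(c(0, 0.01, 0.05), function(s) {
    set.seed(64)
    q <- fit$X_train + matrix(rnorm(length(fit$X_train), sd = s),
                              nrow(fit$X_train))
    median(sqrt(rowSums((predict(fit, q) - fit$Y)^2)))
  }, numeric(1))
  expect_true(all(diff(med) > 0))
})

test_that("re-embedding the training window passes through exactly", {
  fit <- fit_roll$fit
  sim <- fit_roll$sim
  res <- reembed(fit, sim$embeddings)
  expect_identical(res$vocab, sim$embeddings$vocab)
  expect_equal(res$dim, fit$d)
  expect_identical(unname(res$vectors), unname(fit$Y))  # all words trained
  prov <- attr(res, "provenance")
  expect_equal(prov$n_passthrough, 300L)
  expect_equal(prov$k_oos, fit$k)
})

test_that("re-embedding a larger vocabulary transforms the rest", {
  sim <- simulate_manifold_embeddings(200, ambient_dim = 5,
                                      manifold = "swiss_roll",
                                      noise_sigma = 0.02, seed = 65)
  win <- select_window(sim$embeddings, 0, 120)
  fit <- mlle(win, k = 10, d = 2)
  res <- reembed(fit, sim$embeddings, k_oos = 10)
  expect_equal(nrow(res$vectors), 200L)
  expect_equal(attr(res, "provenance")$n_passthrough, 120L)
  expect_equal(attr(res, "provenance")$window$size, 120L)
  # transform mode re-computes even window words
  res2 <- reembed(fit, sim$embeddings, training = "transform")
  expect_false(identical(res2$vectors[1, ], res$vectors[1, ]))
  bad <- sim$embeddings; bad$vectors <- bad$vectors[, 1:3]; bad$dim <- 3L
  expect_error(reembed(fit, bad), "dimension")
})

test_that("re-embedding tracks latent geometry better than the ambient space", {
  # a well-sampled regime: k > d, sparse geodesic support graph, window
  # dense enough that 10-NN balls stay within one winding of the roll
  sim <- simulate_manifold_embeddings(900, ambient_dim = 20,
                                      manifold = "swiss_roll",
                                      noise_sigma = 0.05, seed = 66)
  win <- select_window(sim$embeddings, 0, 600)
  fit <- suppressMessages(mlle(win, k = 20, d = 5, k_graph = 10))
  res <- reembed(fit, sim$embeddings)
  set.seed(67)
  i <- sample(900, 400, replace = TRUE)
  j <- sample(900, 400, replace = TRUE)
  keep <- i != j
  i <- i[keep]; j <- j[keep]
  dl <- sqrt(rowSums((sim$latent[i, ] - sim$latent[j, ])^2))
  damb <- sqrt(rowSums((sim$embeddings$vectors[i, ] -
                          sim$embeddings$vectors[j, ])^2))
  demb <- sqrt(rowSums((res$vectors[i, ] - res$vectors[j, ])^2))
  expect_gte(spearman_cor(dl, demb), spearman_cor(dl, damb))
  # and the intrinsic evaluation against gold ratings improves too
  gold <- generate_similarity_gold(sim$latent, 300, seed = 66)
  expect_gte(evaluate_embeddings(res, gold)$spearman,
             evaluate_embeddings(sim$embeddings, gold)$spearman)
})

test_that("OOV vectors are word-deterministic and bounded", {
  v1 <- oov_vector("angiogram", 50, seed = 9)
  v2 <- oov_vector("angiogram", 50, seed = 9)
  v3 <- oov_vector("angioplasty", 50, seed = 9)
  v4 <- oov_vector("angiogram", 50, seed = 10)
  expect_identical(v1, v2)
  expect_false(identical(v1, v3))
  expect_false(identical(v1, v4))
  set.seed(68)
  words <- replicate(1000, paste(sample(letters, 6), collapse = ""))
  draws <- vapply(words, oov_vector, numeric(20), dim = 20, seed = 1)
  expect_true(all(abs(draws) <= 0.5 / 20))
})
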