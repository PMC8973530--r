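Package: wordmlle
Title: Manifold Re-Embedding of Word Vectors via Modified Locally Linear
    Embedding
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processes pre-trained word embeddings (word2vec, GloVe) by
    fitting a Modified Locally Linear Embedding (MLLE) model on a
    frequency-ranked window of the vocabulary, using a normalized geodesic
    neighbor metric on a k-nearest-neighbour graph, and re-embedding the
    full vocabulary through an out-of-sample barycentric extension.
    Includes intrinsic evaluation of embeddings against word-pair
    similarity ratings (cosine similarity scored with Pearson and Spearman
    correlation), synthetic manifold data generators for validation, and a
    command-line interface covering the simulate/fit/transform/evaluate
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
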