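test_that("char_ngrams matches the boundary-marked sliding definition", {
  expect_identical(char_ngrams("fever", subword_config(3, 3)),
                   c("<fe", "fev", "eve", "ver", "er>"))
  expect_identical(char_ngrams("a", subword_config(3, 3)), "<a>")
  # n = 1 equals a direct character split of the marked word
  for (w in c("fever", "bp", "x")) {
    expect_identical(char_ngrams(w, subword_config(1, 1)),
                     strsplit(paste0("<", w, ">"), "")[[1]])
  }
  # range 3..4 emits order-3 grams then order-4 grams
  got <- char_ngrams("abcd", subword_config(3, 4))
  expect_identical(got, c("<ab", "abc", "bcd", "cd>", "<abc", "abcd", "bcd>"))
})

test_that("cosine similarity behaves at its fixed points and rejects zero vectors", {
  x <- c(1, 2, 3)
  expect_equal(cosine_similarity(x, x), 1)
  expect_equal(cosine_similarity(x, -x), -1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  expect_error(cosine_similarity(c(1, 2), c(1, 2, 3)), "dimension")
})

test_that("nearest_neighbors equals a brute-force cosine ranking", {
  tab <- toy_vector_table()
  hits <- nearest_neighbors("fever", tab, k = 10, threshold = -1)
  expect_false(hits$oov)
  oracle <- oracle_cosine_ranking(tab$vectors["fever", ],
                                  tab$vectors[rownames(tab$vectors) !=
                                                "fever", ])
  expect_identical(hits$matches$token, names(oracle))
  expect_equal(hits$matches$similarity, unname(oracle), tolerance = 1e-12)

  expect_identical(nrow(nearest_neighbors("fever", tab, k = 0)$matches), 0L)
  expect_identical(
    nrow(nearest_neighbors("fever", tab, k = 5, threshold = 1.01)$matches),
    0L)

  oov <- nearest_neighbors("unknown", tab, k = 5)
  expect_true(oov$oov)
  expect_identical(nrow(oov$matches), 0L)
})

test_that("exact similarity ties break lexicographically", {
  m <- rbind(q = c(1, 0), bb = c(0.5, 0.5), aa = c(0.5, 0.5))
  tab <- structure(list(dimension = 2L, vectors = m, subword = NULL),
                   class = "vector_table")
  hits <- nearest_neighbors("q", tab, k = 2, threshold = -1)
  expect_identical(hits$matches$token, c("aa", "bb"))
})

test_that("expand_synonyms strips special characters and defaults to top-10 at 0.5", {
  expect_identical(formals(expand_synonyms)$k, 10L)
  expect_identical(formals(expand_synonyms)$threshold, 0.5)
  tab <- toy_vector_table()
  with_marks <- expand_synonyms("fever!?", tab, k = 3, threshold = 0.1)
  plain <- expand_synonyms("fever", tab, k = 3, threshold = 0.1)
  expect_identical(with_marks$matches, plain$matches)
})

test_that("vector files round-trip and malformed files are named errors", {
  tab <- toy_vector_table()
  path <- withr::local_tempfile(fileext = ".vec")
  write_vectors(tab, path)
  back <- read_vectors(path)
  expect_identical(rownames(back$vectors), rownames(tab$vectors))
  expect_equal(back$vectors, tab$vectors, tolerance = 1e-6)

  lines <- readLines(path)
  writeLines(lines[-2], path)  # header now overstates the row count
  expect_error(read_vectors(path), "declares")

  writeLines(c("2 3", "a 1 2 3", "b 1 2"), path)
  expect_error(read_vectors(path), "line 3")

  writeLines(c("2 2", "tok 1 2", "tok 3 4"), path)
  expect_warning(dup <- read_vectors(path), "duplicate")
  expect_equal(unname(dup$vectors["tok", ]), c(3, 4))
})

test_that("skip-gram learns closer vectors for interchangeable tokens", {
  sents <- interchangeable_corpus()
  wins <- 0L
  for (seed in 1:5) {
    vt <- train_skipgram(sents, train_config(dimension = 16L, window = 3L,
                                             epochs = 30L, min_count = 2L,
                                             downsample = 0, seed = seed))
    pair <- cosine_similarity(vt$vectors["aspirin", ],
                              vt$vectors["ibuprofen", ])
    cross <- cosine_similarity(vt$vectors["aspirin", ],
                               vt$vectors["weather", ])
    if (pair > cross) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})

test_that("training is reproducible per seed and echoes its dimension", {
  sents <- interchangeable_corpus(reps = 5L)
  cfg <- train_config(epochs = 3L, min_count = 2L, seed = 42L)
  expect_identical(cfg$dimension, 32L)
  a <- train_skipgram(sents, cfg)
  b <- train_skipgram(sents, cfg)
  expect_identical(a$vectors, b$vectors)
  expect_identical(ncol(a$vectors), 32L)
  sa <- train_subword(sents, cfg)
  sb <- train_subword(sents, cfg)
  expect_identical(sa$vectors, sb$vectors)
  expect_error(train_skipgram(sents, train_config(min_count = 10000L)),
               "empty vocabulary")
})

test_that("subword word vectors equal the sum of their n-gram vectors", {
  sents <- interchangeable_corpus(reps = 10L)
  cfg <- train_config(dimension = 8L, epochs = 5L, min_count = 2L, seed = 3L)
  sw <- subword_config(3, 6)
  vt <- train_subword(sents, cfg, sw)
  for (word in rownames(vt$vectors)) {
    grams <- char_ngrams(word, sw)
    composed <- colSums(vt$subword$ngram_vectors[grams, , drop = FALSE])
    expect_equal(unname(vt$vectors[word, ]), unname(composed),
                 tolerance = 1e-6)
  }
})

test_that("out-of-vocabulary words compose from shared n-grams", {
  # with 1-grams, "dose" and "odse" share the same character multiset,
  # so their composed vectors are identical
  sents <- interchangeable_corpus(reps = 10L)
  cfg <- train_config(dimension = 8L, epochs = 5L, min_count = 2L, seed = 3L)
  vt <- train_subword(sents, cfg, subword_config(1, 1))
  expect_false("odse" %in% rownames(vt$vectors))
  expect_equal(unname(word_vector(vt, "odse")),
               unname(word_vector(vt, "dose")), tolerance = 1e-6)
  # OOV neighbor ranking equals brute force over the stored vocabulary
  vt2 <- train_subword(sents, cfg, subword_config(2, 4))
  qv <- word_vector(vt2, "dosing")
  expect_false(is.null(qv))
  hits <- nearest_neighbors("dosing", vt2, k = 3, threshold = -1)
  oracle <- oracle_cosine_ranking(qv, vt2$vectors)
  expect_identical(hits$matches$token, names(oracle)[1:3])
})
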