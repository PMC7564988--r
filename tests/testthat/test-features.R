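test_that("word-level preprocessing follows the fixed pipeline order", {
  t <- preprocess_word_level("add pressure with 103 systolic blood pressure")
  expect_identical(t$tokens,
                   c("add", "pressure", "103", "systolic", "blood",
                     "pressure"))
  expect_true("with" %in% t$dropped$token)
  expect_identical(
    t$dropped$reason[t$dropped$token == "with"], "stopword")

  # contractions expand before tokenization, then stopwords drop
  t2 <- preprocess_word_level("I'm cleaning dentures")
  expect_false(any(c("i'm", "im") %in% t2$tokens))
  expect_identical(t2$tokens, c("clean", "denture"))

  # zero-token reduction is flagged, not raised
  t3 <- preprocess_word_level("I am the")
  expect_length(t3$tokens, 0L)
  expect_gte(nrow(t3$dropped), 3L)
})

test_that("lemmatization maps inflected forms to their base", {
  expect_identical(lemmatize_token("closest"), "close")
  expect_identical(lemmatize_token("dentures"), "denture")
  expect_identical(lemmatize_token("brushes"), "brush")
  expect_identical(lemmatize_token("nappies"), "nappy")
  expect_identical(lemmatize_token("cleaned"), "clean")
  expect_identical(lemmatize_token("helping"), "help")
  expect_identical(lemmatize_token("made"), "make")
  # unknown words pass through
  expect_identical(lemmatize_token("qwerty"), "qwerty")
  expect_identical(lemmatize_token("103"), "103")
})

test_that("sentence-level preprocessing only strips non-ASCII", {
  expect_identical(preprocess_sentence_level("Add 103 mmHg, please!"),
                   "Add 103 mmHg, please!")
  txt <- "temp 39° high"
  out <- preprocess_sentence_level(txt)
  expect_identical(nchar(out), nchar(txt) - 1L)
  expect_identical(out, "temp 39 high")
  expect_identical(preprocess_sentence_level("closer"), "closer")
})

test_that("word_feature is the arithmetic mean and order-invariant", {
  m <- rbind(a = c(0, 2), b = c(2, 0), c = c(4, 4))
  tab <- structure(list(dimension = 2L, vectors = m, subword = NULL),
                   class = "vector_table")
  expect_equal(unname(word_feature(c("a"), tab)), c(0, 2))
  expect_equal(unname(word_feature(c("a", "b"), tab)), c(1, 1))
  expect_equal(word_feature(c("a", "b", "c"), tab),
               word_feature(c("c", "a", "b"), tab))
  # unknown tokens are skipped from the mean, not zero-imputed
  expect_equal(unname(word_feature(c("a", "zzz"), tab)), c(0, 2))
  expect_error(word_feature(c("zzz"), tab), "missing feature")
})

test_that("the default sentence encoder mean-pools without lemma/stopword stages", {
  m <- rbind(the = c(10, 0), denture = c(0, 4), dentures = c(2, 2))
  tab <- structure(list(dimension = 2L, vectors = m, subword = NULL),
                   class = "vector_table")
  enc <- word_mean_encoder(tab)
  # "the" and the inflected form contribute directly
  expect_equal(unname(sentence_feature("the dentures", enc)), c(6, 1))
  expect_identical(sentence_feature("the dentures", enc),
                   sentence_feature("the dentures", enc))
  expect_error(sentence_feature("", enc), "empty")
  expect_error(sentence_feature("x", structure(list(), class = "list")),
               "capability error")
})

test_that("the rule-based chunker finds object and prepositional noun phrases", {
  cand <- extract_entity_candidates("add pressure with 114 mmhg")
  expect_true("pressure" %in% cand$phrase)
  expect_identical(cand$tag[cand$phrase == "pressure"], "dobj")
  expect_true("114 mmhg" %in% cand$phrase)
  expect_identical(cand$tag[cand$phrase == "114 mmhg"], "pobj")

  expect_identical(nrow(extract_entity_candidates("add")), 0L)

  cand2 <- extract_entity_candidates("clean dentures with water")
  expect_setequal(cand2$phrase, c("dentures", "water"))

  # spans index into the original text, non-overlapping
  txt <- "can you clean the dentures with dental floss?"
  cand3 <- extract_entity_candidates(txt)
  for (i in seq_len(nrow(cand3))) {
    expect_identical(substr(txt, cand3$start[i] + 1, cand3$end[i]),
                     cand3$phrase[i])
  }
  o <- order(cand3$start)
  expect_true(all(cand3$start[o][-1] >= cand3$end[o][-nrow(cand3)]))
})

test_that("a failing external parser falls back to the rule-based chunker", {
  boom <- function(text) stop("no model")
  expect_message(
    cand <- extract_entity_candidates("clean dentures with water",
                                      parser = boom),
    "falling back"
  )
  expect_setequal(cand$phrase, c("dentures", "water"))
})

test_that("feature matrices carry ids and drop unrepresentable rows", {
  m <- rbind(add = c(1, 0), pressure = c(0, 1))
  tab <- structure(list(dimension = 2L, vectors = m, subword = NULL),
                   class = "vector_table")
  X <- word_feature_matrix(c("add pressure", "zzz qqq", "add"), tab)
  expect_identical(rownames(X), c("u00001", "u00003"))
  expect_identical(attr(X, "dropped"), "u00002")
  expect_equal(unname(X["u00001", ]), c(0.5, 0.5))
})
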