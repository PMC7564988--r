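test_that("pair confusion matches hand counts on small partitions", {
  pc <- pair_confusion(c(1, 1, 2), c("a", "a", "b"))
  expect_identical(unlist(pc[c("tp", "fp", "tn", "fn")]),
                   c(tp = 1, fp = 0, tn = 2, fn = 0))
  # everything in one cluster, all classes distinct (n = 4)
  pc2 <- pair_confusion(rep(1, 4), letters[1:4])
  expect_identical(unlist(pc2[c("tp", "fp", "tn", "fn")]),
                   c(tp = 0, fp = 6, tn = 0, fn = 0))
  expect_error(pair_confusion(1:3, c("a", "b")), "mismatch")
})

test_that("pair counts always partition all n(n-1)/2 pairs", {
  set.seed(2)
  for (rep in 1:50) {
    n <- sample(3:8, 1)
    pred <- sample(1:3, n, replace = TRUE)
    gold <- sample(letters[1:3], n, replace = TRUE)
    pc <- pair_confusion(pred, gold)
    expect_equal(pc$tp + pc$fp + pc$tn + pc$fn, choose(n, 2))
    oc <- oracle_pair_confusion(pred, gold)
    expect_equal(pc[c("tp", "fp", "tn", "fn")], oc)
  }
})

test_that("pair metrics are invariant to index and label permutations", {
  set.seed(3)
  pred <- sample(1:3, 12, replace = TRUE)
  gold <- sample(letters[1:3], 12, replace = TRUE)
  f <- pair_prf(pair_confusion(pred, gold))
  perm <- c(2L, 3L, 1L)
  relab <- c(a = "z", b = "y", c = "x")
  f2 <- pair_prf(pair_confusion(perm[pred], unname(relab[gold])))
  expect_equal(f, f2)
})

test_that("precision/recall/F1 follow the printed formulas with 0-conventions", {
  r <- pair_prf(structure(list(tp = 1, fp = 0, tn = 2, fn = 0),
                          class = "pair_confusion"))
  expect_equal(unlist(r), c(precision = 1, recall = 1, f1 = 1))
  r2 <- pair_prf(structure(list(tp = 2, fp = 2, tn = 0, fn = 2),
                           class = "pair_confusion"))
  expect_equal(unlist(r2), c(precision = 0.5, recall = 0.5, f1 = 0.5))
  r3 <- pair_prf(structure(list(tp = 0, fp = 0, tn = 3, fn = 0),
                           class = "pair_confusion"))
  expect_equal(unlist(r3), c(precision = 0, recall = 0, f1 = 0))
})

test_that("silhouette agrees with direct hand computation", {
  X <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  good <- silhouette_score(X, c(1, 1, 2, 2))
  # point 1: a = 0.1, b = mean(10, 10.1) = 10.05
  expect_equal(good$values[1], (10.05 - 0.1) / 10.05)
  expect_gt(good$mean, 0.98)
  bad <- silhouette_score(X, c(1, 2, 1, 2))
  expect_lt(bad$mean, 0)
  expect_error(silhouette_score(X, rep(1, 4)), "at least 2")
  # singleton cluster scores 0 by convention
  sing <- silhouette_score(X, c(1, 2, 2, 2))
  expect_equal(sing$values[1], 0)
})

test_that("silhouette matches the brute-force oracle on random instances", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    a <- sample(1:3, n, replace = TRUE)
    if (length(unique(a)) < 2) a[1:2] <- c(1L, 2L)
    got <- silhouette_score(X, a)
    want <- oracle_silhouette(X, a)
    expect_equal(got$values, want$values, tolerance = 1e-9)
    expect_equal(got$mean, want$mean, tolerance = 1e-9)
    expect_true(all(got$values >= -1 & got$values <= 1))
  }
})

test_that("BLEU hits its fixed points and a hand-computed value", {
  expect_equal(bleu("add blood pressure to record",
                    "add blood pressure to record"), 1)
  expect_equal(bleu("alpha beta gamma", "delta epsilon zeta"), 0)
  expect_warning(z <- bleu("", "reference text"), "empty")
  expect_equal(z, 0)

  # hand-computed: candidate 5 tokens vs reference 6 tokens
  # p1 = 4/5 (unsmoothed); add-one on higher orders:
  # p2 = (1+1)/(4+1); p3 = (0+1)/(3+1); p4 = (0+1)/(2+1)
  # BP = exp(1 - 6/5)
  hand <- exp(1 - 6 / 5) *
    (4 / 5 * 2 / 5 * 1 / 4 * 1 / 3)^(1 / 4)
  expect_equal(bleu("the cat sat on mat", "the cat is on the mat"),
               hand, tolerance = 1e-12)

  # without smoothing a zero higher-order precision annihilates the score
  expect_equal(bleu("the cat sat on mat", "the cat is on the mat",
                    smoothing = "none"), 0)

  # best-match corpus scoring
  res <- bleu_corpus(c("add pressure now", "totally unrelated words"),
                     c("add pressure now", "clean mouth"))
  expect_equal(res$scores[1], 1)
  expect_equal(res$scores[2], 0)
  expect_equal(res$mean, 0.5)
})

test_that("corpus statistics count words and truncate averages", {
  u <- list(
    labeled_utterance("a b c", "x"),
    labeled_utterance("d e", "x"),
    labeled_utterance("f g h i", "y")
  )
  corp <- structure(list(utterances = u, ontology_version = "t", seed = 0L),
                    class = "corpus")
  st <- corpus_stats(corp)
  expect_identical(st$class, c("x", "y", "Total"))
  expect_identical(st$utterances, c(2L, 1L, 3L))
  expect_identical(st$words, c(5L, 4L, 9L))
  expect_equal(st$avg_length_3, c(2.5, 4, 3))
  # one utterance "a b c" -> (1, 3, 3.000)
  one <- corpus_stats(structure(list(utterances = u[1]), class = "corpus"))
  expect_equal(one[one$class == "x", c("utterances", "words")],
               data.frame(utterances = 1L, words = 3L), ignore_attr = TRUE)
  # truncation, not rounding
  tab <- data.frame(class = "k", utterances = 606L, words = 4163L)
  expect_equal(corpus_stats(tab)$avg_length_3[1], 6.869)
})

test_that("rating aggregation is the unweighted 2-decimal mean", {
  expect_equal(aggregate_ratings(c(4.2, 4.2)), 4.2)
  expect_equal(aggregate_ratings(c(1, 2)), 1.5)
  expect_equal(aggregate_ratings(3.333333), 3.33)
})

test_that("evaluate_clustering reports maxima for the gold partition", {
  X <- rbind(matrix(rnorm(10, 0, 0.1), 5, 2),
             matrix(rnorm(10, 5, 0.1), 5, 2))
  gold <- rep(c("a", "b"), each = 5)
  rep_good <- evaluate_clustering(rep(1:2, each = 5), gold, X)
  expect_equal(rep_good$f1, 1)
  rep_bad <- evaluate_clustering(rep(1:2, times = 5), gold, X)
  expect_lt(rep_bad$f1, 1)
  expect_gt(rep_good$silhouette, rep_bad$silhouette)
})
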