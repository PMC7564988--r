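test_that("enumerate_orderings keeps the verb head first and covers all permutations", {
  for (m in 0:3) {
    o <- tiny_ontology(n_record = m)
    templates <- enumerate_orderings(o$intents[[1]])
    expect_length(templates, factorial(m))
    keys <- vapply(templates, function(t) {
      paste(vapply(t$ordered_phrases, `[[`, "", "slot"), collapse = "|")
    }, "")
    expect_false(anyDuplicated(keys) > 0)
    # a second verb doubles the template count
    o2 <- tiny_ontology(n_record = m, verbs = c("add", "set"))
    expect_length(enumerate_orderings(o2$intents[[1]]), 2L * factorial(m))
  }
})

test_that("templates reject duplicate slot references", {
  ph <- phrase_template("with", "rec-1")
  expect_error(
    utterance_template("x", "add", "thing-type", list(ph, ph)),
    "more than once"
  )
})

test_that("fill_slots enumerates the Cartesian product under budget", {
  o <- tiny_ontology(n_record = 2L, activity_values = "pressure")
  t <- enumerate_orderings(o$intents[[1]])[[1]]
  # activity 1 x rec-1 2 x rec-2 2 = 4; then widen rec-2 to 3 values
  o$slots[[3]]$values <- c("x", "y", "z")
  utts <- fill_slots(t, o, budget = 100)
  expect_length(utts, 1L * 2L * 3L)
  expect_false(anyDuplicated(vapply(utts, `[[`, "", "text")) > 0)
})

test_that("fill_slots samples reproducibly when the budget binds", {
  o <- tiny_ontology(n_record = 2L)  # product = 2*2*2 = 8
  t <- enumerate_orderings(o$intents[[1]])[[1]]
  a <- fill_slots(t, o, budget = 4, seed = 5)
  b <- fill_slots(t, o, budget = 4, seed = 5)
  expect_length(a, 4L)
  expect_identical(a, b)
  expect_false(anyDuplicated(vapply(a, `[[`, "", "text")) > 0)
})

test_that("filled utterances carry exact entity spans including modifiers", {
  o <- builtin_fixture()
  spec <- Filter(function(i) i$name == "add-vital", o$intents)[[1]]
  t <- enumerate_orderings(spec)[[1]]
  utts <- fill_slots(t, o, budget = 5000)
  texts <- vapply(utts, `[[`, "", "text")
  hit <- utts[[grep("^add pressure with 103 systolic bp", texts)[1]]]
  vv <- hit$entities[hit$entities$slot == "vital-value", ]
  expect_identical(vv$surface, "103 systolic bp")
  for (u in utts[seq(1, length(utts), by = 37)]) {
    e <- u$entities
    expect_identical(substr(rep(u$text, nrow(e)), e$start + 1, e$end),
                     e$surface)
  }
})

test_that("paraphrase rules transform text while keeping spans valid", {
  o <- builtin_fixture()
  spec <- Filter(function(i) i$name == "clean-oral", o$intents)[[1]]
  u <- fill_slots(enumerate_orderings(spec)[[1]], o, budget = 1)[[1]]

  vars <- paraphrase(u, rules = "question", seed = 2)
  expect_length(vars, 1L)
  expect_match(vars[[1]]$text, "^(can|could|when did|where did) you ")
  expect_match(vars[[1]]$text, "\\?$")
  expect_identical(vars[[1]]$intent, u$intent)

  vars <- paraphrase(u, rules = "politeness", seed = 2)
  expect_match(vars[[1]]$text, "^(please, |i )")
  expect_identical(sub("^(please, |i )", "", vars[[1]]$text), u$text)

  vars <- paraphrase(u, rules = "synonym", seed = 2)
  expect_length(vars, 1L)
  expect_match(vars[[1]]$text, "^(wash|scrub|wipe|sponge) ")

  for (rule in c("question", "politeness", "passive", "synonym")) {
    for (v in paraphrase(u, rules = rule, seed = 9)) {
      e <- v$entities
      expect_identical(substr(rep(v$text, nrow(e)), e$start + 1, e$end),
                       e$surface)
    }
  }

  expect_identical(paraphrase(u, rules = character()), list())
})

test_that("passive voice fronts the activity object", {
  u <- labeled_utterance(
    "clean dentures with detergent", "clean-oral",
    data.frame(slot = c("oral-type", "oral-material"),
               start = c(6L, 20L), end = c(14L, 29L),
               surface = c("dentures", "detergent"),
               stringsAsFactors = FALSE)
  )
  v <- paraphrase(u, rules = "passive", seed = 1)[[1]]
  expect_identical(v$text, "dentures are cleaned with detergent")
  expect_identical(v$entities$surface, c("dentures", "detergent"))
  # singular activity object takes "is"
  u2 <- labeled_utterance(
    "clean mouth with water", "clean-oral",
    data.frame(slot = c("oral-type", "oral-material"),
               start = c(6L, 17L), end = c(11L, 22L),
               surface = c("mouth", "water"), stringsAsFactors = FALSE)
  )
  expect_identical(paraphrase(u2, rules = "passive")[[1]]$text,
                   "mouth is cleaned with water")
  # unknown verb: variant skipped with a warning
  u3 <- labeled_utterance(
    "defenestrate mouth with water", "clean-oral",
    data.frame(slot = "oral-type", start = 13L, end = 18L,
               surface = "mouth", stringsAsFactors = FALSE)
  )
  expect_warning(out <- paraphrase(u3, rules = "passive"), "inventory")
  expect_length(out, 0L)
})

test_that("generate_corpus meets budgets with unique texts, deterministically", {
  o <- builtin_fixture()
  budgets <- setNames(rep(3L, 6), names(fixture_budgets()))
  cfg <- generation_config(budgets = budgets)
  corp <- generate_corpus(o, cfg, seed = 7)
  counts <- table(corpus_intents(corp))
  expect_true(all(counts == 3L))
  texts <- corpus_texts(corp)
  expect_false(anyDuplicated(texts) > 0)

  corp2 <- generate_corpus(o, cfg, seed = 7)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_corpus_jsonl(corp, f1); write_corpus_jsonl(corp2, f2)
  expect_identical(readLines(f1), readLines(f2))

  corp3 <- generate_corpus(o, cfg, seed = 8)
  expect_false(identical(corpus_texts(corp3), texts))

  one <- generate_corpus(o, generation_config(budgets = setNames(
    rep(1L, 6), names(fixture_budgets()))), seed = 1)
  expect_length(one$utterances, 6L)
  expect_setequal(unique(corpus_intents(one)), names(fixture_budgets()))
})

test_that("unattainable budgets emit the attainable maximum with a shortfall report", {
  o <- tiny_ontology(n_record = 1L)  # tiny variant space
  cfg <- generation_config(budgets = c("add-thing" = 5000L),
                           rules = "question")
  expect_warning(corp <- generate_corpus(o, cfg, seed = 1), "shortfall")
  expect_lt(length(corp$utterances), 5000L)
  expect_gt(length(corp$utterances), 0L)
  expect_true(attr(corp, "shortfall")[["add-thing"]] > 0)
})

test_that("corpora round-trip through JSON lines", {
  corp <- tiny_corpus()
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus_jsonl(corp, path)
  back <- read_corpus_jsonl(path)
  expect_length(back$utterances, length(corp$utterances))
  for (i in seq_along(corp$utterances)) {
    expect_identical(back$utterances[[i]]$text, corp$utterances[[i]]$text)
    expect_identical(back$utterances[[i]]$entities,
                     corp$utterances[[i]]$entities)
  }
  tpath <- withr::local_tempfile(fileext = ".txt")
  write_corpus_text(corp, tpath)
  expect_identical(readLines(tpath), corpus_texts(corp))
})
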