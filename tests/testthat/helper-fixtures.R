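# Hand-built miniature fixtures used across the suite.

# Minimal ontology with one intent, a single verb, and a configurable
# number of record phrases (each over its own two-value slot).
tiny_ontology <- function(n_record = 2L, verbs = "add",
                          activity_values = c("pressure", "temperature")) {
  record_slots <- lapply(seq_len(n_record), function(i) {
    entity_slot(paste0("rec-", i), kind = "record",
                values = paste0("val", i, c("a", "b")))
  })
  templates <- lapply(seq_len(n_record), function(i) {
    phrase_template(preposition = c("with", "for", "at", "to", "on",
                                    "from")[i],
                    slot = paste0("rec-", i))
  })
  ontology(
    intents = list(intent_spec("add-thing", verbs = verbs,
                               activity_slot = "thing-type",
                               record_templates = templates)),
    slots = c(list(entity_slot("thing-type", kind = "activity",
                               values = activity_values)),
              record_slots),
    version = "test"
  )
}

# A deterministic hand-set vector table over a few tokens.
toy_vector_table <- function() {
  m <- rbind(
    fever = c(1, 0, 0),
    chills = c(0.9, 0.1, 0),
    pressure = c(0, 1, 0),
    pulse = c(0, 0.9, 0.2),
    banana = c(0, 0, 1)
  )
  structure(list(dimension = 3L, vectors = m, subword = NULL),
            class = "vector_table")
}

# Corpus with two interchangeable tokens ("aspirin"/"ibuprofen" appear in
# identical contexts) and an unrelated token in disjoint contexts.
interchangeable_corpus <- function(reps = 40L) {
  pair <- c("aspirin", "ibuprofen")
  sents <- list()
  for (r in seq_len(reps)) {
    for (w in pair) {
      sents[[length(sents) + 1L]] <-
        c("give", "the", w, "dose", "now")
      sents[[length(sents) + 1L]] <-
        c("take", w, "tablet")
    }
    sents[[length(sents) + 1L]] <- c("weather", "report", "rain", "today")
    sents[[length(sents) + 1L]] <- c("weather", "rain", "cold", "today")
  }
  sents
}

# Ten short distinct-prefix utterances for char-LM memorization checks.
memorize_utterances <- function() {
  c("add blood pressure now",
    "clean mouth with water",
    "help to use urinals",
    "prepare noodles for lunch",
    "wash dentures with soap",
    "change wet diaper",
    "set body temperature",
    "make soup for dinner",
    "record pulse beats",
    "bring towels to room three")
}

# Training stream for memorization checks: the ten utterances repeated in
# shuffled order so every utterance boundary is seen at many window offsets.
memorize_stream <- function(reps = 12L, seed = 1L) {
  utts <- memorize_utterances()
  set.seed(seed)
  stream <- unlist(lapply(seq_len(reps), function(i) sample(utts)))
  paste0(paste(stream, collapse = "\n"), "\n")
}

# small labeled corpus without going through the generator
tiny_corpus <- function() {
  o <- builtin_fixture()
  cfg <- generation_config(budgets = setNames(rep(4L, 6),
                                              names(fixture_budgets())))
  generate_corpus(o, cfg, seed = 11)
}
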