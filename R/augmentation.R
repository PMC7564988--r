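#' Construct a labeled utterance
#'
#' @param text Utterance text.
#' @param intent Intent identifier.
#' @param entities Data frame with columns `slot`, `start`, `end`, `surface`.
#'   Offsets are 0-based, half-open: `substr(text, start + 1, end)` must
#'   equal `surface`, and spans must not overlap.
#' @param provenance Character vector describing the operations that
#'   produced this utterance (ordering index, paraphrase rule ids,
#'   synonym substitutions).
#' @return An object of class `labeled_utterance`.
#' @export
labeled_utterance <- function(text, intent, entities = empty_entities(),
                              provenance = character()) {
  u <- structure(
    list(text = text, intent = intent, entities = entities,
         provenance = provenance),
    class = "labeled_utterance"
  )
  check_spans(u)
  u
}

empty_entities <- function() {
  data.frame(slot = character(), start = integer(), end = integer(),
             surface = character(), stringsAsFactors = FALSE)
}

check_spans <- function(u) {
  e <- u$entities
  if (!nrow(e)) return(invisible(u))
  n <- nchar(u$text)
  if (any(e$start < 0L) || any(e$end > n) || any(e$start >= e$end)) {
    stop("invalid entity span in utterance '", u$text, "'")
  }
  got <- substr(rep(u$text, nrow(e)), e$start + 1L, e$end)
  if (!all(got == e$surface)) {
    bad <- which(got != e$surface)[1L]
    stop("entity surface mismatch in '", u$text, "': span [", e$start[bad],
         ",", e$end[bad], ") reads '", got[bad], "', recorded '",
         e$surface[bad], "'")
  }
  o <- order(e$start)
  if (any(e$start[o][-1L] < e$end[o][-length(o)])) {
    stop("overlapping entity spans in utterance '", u$text, "'")
  }
  invisible(u)
}

#' @export
print.labeled_utterance <- function(x, ...) {
  cat("<utterance> #", x$intent, ": \"", x$text, "\"\n", sep = "")
  if (nrow(x$entities)) {
    for (i in seq_len(nrow(x$entities))) {
      cat("  @", x$entities$slot[i], " = \"", x$entities$surface[i],
          "\" [", x$entities$start[i], ",", x$entities$end[i], ")\n",
          sep = "")
    }
  }
  invisible(x)
}

#' Construct an utterance template
#'
#' A rendering plan for one intent: a single action verb, the activity
#' slot providing the verb's object, and an ordered list of record phrase
#' templates. The verb + activity head always renders first
#' (subject-verb-object order); record phrases render in `ordered_phrases`
#' order.
#'
#' @param intent Intent identifier.
#' @param verb Action verb (may be multi-word).
#' @param activity_value_slot Name of the activity slot.
#' @param ordered_phrases List of [phrase_template()] objects; duplicate
#'   slot references are rejected.
#' @return An object of class `utterance_template`.
#' @export
utterance_template <- function(intent, verb, activity_value_slot,
                               ordered_phrases = list()) {
  slots <- vapply(ordered_phrases, `[[`, "", "slot")
  if (anyDuplicated(slots)) {
    stop("utterance template for intent '", intent,
         "' references slot '", slots[duplicated(slots)][1L],
         "' more than once")
  }
  structure(
    list(intent = intent, verb = verb,
         activity_value_slot = activity_value_slot,
         ordered_phrases = ordered_phrases),
    class = "utterance_template"
  )
}

permutations <- function(n) {
  if (n <= 0L) return(list(integer()))
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- permutations(n - 1L)
    for (p in rest) {
      idx <- seq_len(n)[-i]
      out[[length(out) + 1L]] <- c(i, idx[p])
    }
  }
  out
}

#' Enumerate phrase-order variants of an intent
#'
#' Produces every utterance template obtainable by permuting the intent's
#' record phrases while keeping the verb + activity head first, crossed
#' with the intent's verbs: `length(verbs) * factorial(m)` distinct
#' templates for `m` record phrases, in deterministic order (verbs in
#' declaration order, permutations in lexicographic order).
#'
#' @param spec An [intent_spec()].
#' @return List of [utterance_template()] objects, no duplicates.
#' @export
enumerate_orderings <- function(spec) {
  m <- length(spec$record_templates)
  perms <- permutations(m)
  out <- vector("list", length(spec$verbs) * length(perms))
  i <- 0L
  for (verb in spec$verbs) {
    for (p in perms) {
      i <- i + 1L
      out[[i]] <- utterance_template(
        intent = spec$name, verb = verb,
        activity_value_slot = spec$activity_slot,
        ordered_phrases = spec$record_templates[p]
      )
    }
  }
  out
}

# One choice dimension per template part: the activity value, then for each
# phrase either the slot option (pattern 1) or modifier x option (pattern 2).
template_dimensions <- function(t, o) {
  act <- ontology_slot(o, t$activity_value_slot)
  if (is.null(act)) {
    stop("template references undeclared activity slot '",
         t$activity_value_slot, "'")
  }
  if (!length(act$values)) {
    stop("configuration error: slot '", act$name, "' has no values")
  }
  dims <- list(list(kind = "activity", slot = act$name,
                    options = tolower(slot_options(act))))
  for (ph in t$ordered_phrases) {
    s <- ontology_slot(o, ph$slot)
    if (is.null(s)) stop("template references undeclared slot '", ph$slot, "'")
    opts <- tolower(slot_options(s))
    if (!length(opts)) {
      stop("configuration error: slot '", s$name, "' has no values")
    }
    if (ph$pattern == 2L) {
      grid <- expand.grid(modifier = tolower(ph$modifiers), value = opts,
                          stringsAsFactors = FALSE)
      opts <- paste(grid$modifier, grid$value)
    }
    dims[[length(dims) + 1L]] <- list(kind = "record", slot = s$name,
                                      preposition = ph$preposition,
                                      options = opts)
  }
  dims
}

render_choice <- function(t, dims, idx) {
  pieces <- character()
  entities <- list()
  pos <- 0L  # 0-based cursor
  push <- function(str) {
    pieces[[length(pieces) + 1L]] <<- str
    pos <<- pos + nchar(str) + 1L  # +1 for the joining space
  }
  push(t$verb)
  for (d in seq_along(dims)) {
    dim <- dims[[d]]
    surface <- dim$options[idx[d]]
    if (dim$kind == "record" && nzchar(dim$preposition)) {
      push(dim$preposition)
    }
    entities[[length(entities) + 1L]] <- data.frame(
      slot = dim$slot, start = pos, end = pos + nchar(surface),
      surface = surface, stringsAsFactors = FALSE
    )
    push(surface)
  }
  labeled_utterance(
    text = paste(pieces, collapse = " "),
    intent = t$intent,
    entities = do.call(rbind, entities),
    provenance = paste0("fill:", paste(idx, collapse = "."))
  )
}

#' Fill the placeholders of an utterance template
#'
#' Replaces the activity placeholder and every record-phrase placeholder
#' with concrete slot values (declared values and their synonyms). If the
#' full Cartesian product of choices fits within `budget`, it is emitted
#' exhaustively in deterministic order; otherwise `budget` distinct
#' combinations are sampled uniformly without replacement under `seed`.
#' Every emitted utterance carries a character span for each filled slot;
#' pattern-2 spans cover modifier + value (e.g. "103 systolic bp").
#'
#' @param t An [utterance_template()].
#' @param o The [ontology()] declaring the referenced slots.
#' @param budget Maximum number of utterances to emit (>= 1).
#' @param seed Integer seed controlling sampling when the product exceeds
#'   the budget.
#' @return List of [labeled_utterance()] objects.
#' @export
fill_slots <- function(t, o, budget, seed = 0L) {
  stopifnot(budget >= 1)
  dims <- template_dimensions(t, o)
  sizes <- vapply(dims, function(d) length(d$options), 0L)
  total <- prod(sizes)
  picks <- if (total <= budget) {
    seq_len(total)
  } else {
    sort(with_seed(derive_seed(seed, paste0("fill", t$intent, t$verb)),
                   sample.int(total, budget)))
  }
  lapply(picks, function(flat) {
    idx <- integer(length(sizes))
    rem <- flat - 1L
    for (d in seq_along(sizes)) {
      idx[d] <- rem %% sizes[d] + 1L
      rem <- rem %/% sizes[d]
    }
    render_choice(t, dims, idx)
  })
}

# --- paraphrase transformations ---------------------------------------------

# Closed verb inventory: base form -> past participle. Multi-word verbs are
# inflected on their first token.
VERB_FORMS <- c(
  add = "added", set = "set", put = "put", record = "recorded",
  clean = "cleaned", wash = "washed", brush = "brushed", scrub = "scrubbed",
  wipe = "wiped", sponge = "sponged", attach = "attached",
  help = "helped", assist = "assisted", prepare = "prepared",
  make = "made", cook = "cooked", fix = "fixed",
  change = "changed", replace = "replaced", swap = "swapped",
  rinse = "rinsed"
)

verb_participle <- function(verb) {
  first <- strsplit(verb, " ", fixed = TRUE)[[1]][1]
  if (!first %in% names(VERB_FORMS)) return(NULL)
  sub(first, VERB_FORMS[[first]], verb, fixed = TRUE)
}

#' Default synonym lexicon
#'
#' The packaged static keyword-to-synonyms map used by the `synonym`
#' paraphrase rule when no trained vector table is supplied.
#'
#' @return Named list mapping a keyword to a character vector of synonyms.
#' @export
default_synonym_lexicon <- function() {
  path <- system.file("extdata", "synonyms.yaml", package = "dialogforge",
                      mustWork = TRUE)
  lapply(yaml::read_yaml(path), function(v) as.character(unlist(v)))
}

shift_entities <- function(entities, delta) {
  entities$start <- entities$start + as.integer(delta)
  entities$end <- entities$end + as.integer(delta)
  entities
}

para_question <- function(u, seed) {
  forms <- c("can you", "could you", "when did you", "where did you")
  prefix <- forms[with_seed(derive_seed(seed, paste0("q", u$text)),
                            sample.int(length(forms), 1L))]
  labeled_utterance(
    text = paste0(prefix, " ", u$text, "?"),
    intent = u$intent,
    entities = shift_entities(u$entities, nchar(prefix) + 1L),
    provenance = c(u$provenance, "rule:question")
  )
}

para_politeness <- function(u, seed) {
  forms <- c("please, ", "i ")
  prefix <- forms[with_seed(derive_seed(seed, paste0("p", u$text)),
                            sample.int(length(forms), 1L))]
  labeled_utterance(
    text = paste0(prefix, u$text),
    intent = u$intent,
    entities = shift_entities(u$entities, nchar(prefix)),
    provenance = c(u$provenance, "rule:politeness")
  )
}

para_passive <- function(u, seed) {
  if (!nrow(u$entities)) return(NULL)
  act <- u$entities[1L, ]
  verb <- trimws(substr(u$text, 1L, act$start))
  if (act$start == 0L || !nzchar(verb)) return(NULL)
  part <- verb_participle(verb)
  if (is.null(part)) {
    warning("passive rule skipped: verb '", verb,
            "' is not in the verb inventory", call. = FALSE)
    return(NULL)
  }
  be <- if (grepl("(?<!s)s$", act$surface, perl = TRUE)) "are" else "is"
  prefix <- paste(act$surface, be, part)
  tail_txt <- substr(u$text, act$end + 1L, nchar(u$text))
  rest <- u$entities[-1L, , drop = FALSE]
  rest <- shift_entities(rest, nchar(prefix) - act$end)
  act_new <- data.frame(slot = act$slot, start = 0L,
                        end = nchar(act$surface), surface = act$surface,
                        stringsAsFactors = FALSE)
  labeled_utterance(
    text = paste0(prefix, tail_txt),
    intent = u$intent,
    entities = rbind(act_new, rest),
    provenance = c(u$provenance, "rule:passive")
  )
}

para_synonym <- function(u, lexicon, seed) {
  tokens <- strsplit(u$text, " ", fixed = TRUE)[[1]]
  offs <- cumsum(c(0L, nchar(tokens) + 1L))[seq_along(tokens)]
  inside <- function(pos, len) {
    any(u$entities$start < pos + len & pos < u$entities$end)
  }
  for (i in seq_along(tokens)) {
    tok <- tokens[i]
    if (!tok %in% names(lexicon)) next
    if (nrow(u$entities) && inside(offs[i], nchar(tok))) next
    alts <- lexicon[[tok]]
    if (!length(alts)) next
    alt <- alts[with_seed(derive_seed(seed, paste0("s", u$text)),
                          sample.int(length(alts), 1L))]
    delta <- nchar(alt) - nchar(tok)
    ent <- u$entities
    after <- ent$start >= offs[i] + nchar(tok)
    ent$start[after] <- ent$start[after] + delta
    ent$end[after] <- ent$end[after] + delta
    new_text <- paste0(
      substr(u$text, 1L, offs[i]), alt,
      substr(u$text, offs[i] + nchar(tok) + 1L, nchar(u$text))
    )
    return(labeled_utterance(
      text = new_text, intent = u$intent, entities = ent,
      provenance = c(u$provenance, paste0("rule:synonym:", tok, ">", alt))
    ))
  }
  NULL
}

#' Paraphrase a labeled utterance
#'
#' Applies each requested syntactic transformation rule independently to
#' `u` and returns the resulting variants. Entity spans are recomputed so
#' they remain valid in the transformed text and the intent label is
#' preserved. Rules:
#' * `question` - modal yes/no ("can you ...?") or Wh- form, chosen by a
#'   seeded draw;
#' * `politeness` - prefix "please, " or "i ", remainder unchanged;
#' * `passive` - "clean dentures with water" becomes "dentures are cleaned
#'   with water"; skipped with a warning when the verb is outside the
#'   closed inventory;
#' * `synonym` - replaces the first keyword found in `lexicon` (outside
#'   any entity span) with a seeded choice among its synonyms.
#'
#' @param u A [labeled_utterance()].
#' @param rules Subset of `c("question", "politeness", "passive", "synonym")`.
#' @param lexicon Synonym map for the `synonym` rule; defaults to the
#'   packaged lexicon.
#' @param seed Integer seed for the per-rule draws.
#' @return List of [labeled_utterance()] variants (possibly shorter than
#'   `rules` when a rule does not apply).
#' @export
paraphrase <- function(u, rules = c("question", "politeness", "passive",
                                    "synonym"),
                       lexicon = default_synonym_lexicon(), seed = 0L) {
  if (!length(rules)) return(list())
  rules <- match.arg(rules, several.ok = TRUE)
  out <- list()
  for (rule in rules) {
    v <- switch(rule,
      question = para_question(u, seed),
      politeness = para_politeness(u, seed),
      passive = para_passive(u, seed),
      synonym = para_synonym(u, lexicon, seed)
    )
    if (!is.null(v)) out[[length(out) + 1L]] <- v
  }
  out
}

# --- corpus ------------------------------------------------------------------

#' Construct a generation configuration
#'
#' @param budgets Named integer vector: utterances requested per intent.
#' @param rules Paraphrase rules to apply during generation.
#' @param lexicon Synonym lexicon for the `synonym` rule.
#' @return A list of class `generation_config`.
#' @export
generation_config <- function(budgets,
                              rules = c("question", "politeness", "passive",
                                        "synonym"),
                              lexicon = default_synonym_lexicon()) {
  stopifnot(length(budgets) >= 1, !is.null(names(budgets)),
            all(budgets >= 1))
  structure(list(budgets = budgets, rules = rules, lexicon = lexicon),
            class = "generation_config")
}

#' Study-scale generation budgets for the fixture ontology
#'
#' The per-intent utterance counts of the reference corpus profile
#' (876, 606, 408, 756, 560, 340 across the six fixture intents; 3546 in
#' total).
#'
#' @return Named integer vector of per-intent budgets.
#' @export
fixture_budgets <- function() {
  c("add-vital" = 876L, "clean-oral" = 606L, "assist-toilet" = 408L,
    "prepare-meal" = 756L, "assist-bath" = 560L, "change-diaper" = 340L)
}

#' Generate a gold-labeled corpus
#'
#' Composes the full augmentation pipeline per intent: enumerate phrase
#' orderings, fill slot placeholders (word shuffling + word replacing),
#' apply the paraphrase rules, de-duplicate texts, and sample down to the
#' per-intent budget. The result is a pure function of
#' (ontology, config, seed).
#'
#' @param o An [ontology()].
#' @param cfg A [generation_config()]; budgets must name every intent to
#'   generate.
#' @param seed Integer seed.
#' @return An object of class `corpus`: list with `utterances` (list of
#'   [labeled_utterance()]), `ontology_version` and `seed`. When a budget
#'   exceeds the attainable number of unique texts, the attainable maximum
#'   is emitted and the shortfall reported in `attr(corpus, "shortfall")`
#'   and a warning.
#' @export
generate_corpus <- function(o, cfg, seed = 0L) {
  stopifnot(inherits(o, "ontology"), inherits(cfg, "generation_config"))
  missing_intents <- setdiff(names(cfg$budgets),
                             vapply(o$intents, `[[`, "", "name"))
  if (length(missing_intents)) {
    stop("budgets name undeclared intents: ",
         paste(missing_intents, collapse = ", "))
  }
  all_utts <- list()
  shortfall <- list()
  for (intent_name in names(cfg$budgets)) {
    spec <- ontology_intent(o, intent_name)
    budget <- as.integer(cfg$budgets[[intent_name]])
    templates <- enumerate_orderings(spec)
    per_template <- max(1L, ceiling(4L * budget / length(templates)))
    base <- list()
    for (ti in seq_along(templates)) {
      got <- fill_slots(templates[[ti]], o, budget = per_template,
                        seed = derive_seed(seed, paste0(intent_name, ti)))
      got <- lapply(got, function(u) {
        u$provenance <- c(paste0("ordering:", ti), u$provenance)
        u
      })
      base <- c(base, got)
    }
    pool <- base
    texts <- vapply(pool, `[[`, "", "text")
    want_pool <- 3L * budget
    for (bi in seq_along(base)) {
      if (length(pool) >= want_pool) break
      vars <- paraphrase(base[[bi]], rules = cfg$rules,
                         lexicon = cfg$lexicon,
                         seed = derive_seed(seed, paste0("pp", intent_name, bi)))
      for (v in vars) {
        if (!v$text %in% texts) {
          pool[[length(pool) + 1L]] <- v
          texts <- c(texts, v$text)
        }
      }
    }
    keep <- !duplicated(texts)
    pool <- pool[keep]
    if (length(pool) > budget) {
      idx <- sort(with_seed(derive_seed(seed, paste0("pick", intent_name)),
                            sample.int(length(pool), budget)))
      pool <- pool[idx]
    } else if (length(pool) < budget) {
      shortfall[[intent_name]] <- budget - length(pool)
    }
    all_utts <- c(all_utts, pool)
  }
  texts <- vapply(all_utts, `[[`, "", "text")
  all_utts <- all_utts[!duplicated(texts)]
  corp <- structure(
    list(utterances = all_utts, ontology_version = o$version,
         seed = as.integer(seed)),
    class = "corpus"
  )
  if (length(shortfall)) {
    attr(corp, "shortfall") <- unlist(shortfall)
    warning("budget shortfall for intent(s): ",
            paste(names(shortfall), unlist(shortfall), sep = "=",
                  collapse = ", "), call. = FALSE)
  }
  corp
}

#' @export
print.corpus <- function(x, ...) {
  tab <- table(corpus_intents(x))
  cat("<corpus>", length(x$utterances), "utterances,",
      length(tab), "intents (ontology", x$ontology_version,
      "- seed", x$seed, ")\n")
  print(tab)
  invisible(x)
}

#' @export
#' @rdname generate_corpus
corpus_texts <- function(corpus) vapply(corpus$utterances, `[[`, "", "text")

#' @export
#' @rdname generate_corpus
corpus_intents <- function(corpus) vapply(corpus$utterances, `[[`, "", "intent")

#' @export
as.data.frame.corpus <- function(x, ...) {
  data.frame(
    id = sprintf("u%05d", seq_along(x$utterances)),
    text = corpus_texts(x),
    intent = corpus_intents(x),
    stringsAsFactors = FALSE
  )
}

#' Corpus I/O
#'
#' `write_corpus_jsonl()` writes one JSON object per line with fields
#' `id`, `text`, `intent`, `entities` and `provenance`;
#' `read_corpus_jsonl()` is its inverse. `write_corpus_text()` writes the
#' plain texts, one utterance per line.
#'
#' @param corpus A `corpus` object.
#' @param path Output file.
#' @return `path` invisibly; `read_corpus_jsonl()` returns a `corpus`.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(seq_along(corpus$utterances), function(i) {
    u <- corpus$utterances[[i]]
    jsonlite::toJSON(
      list(id = sprintf("u%05d", i), text = u$text, intent = u$intent,
           entities = u$entities, provenance = u$provenance),
      auto_unbox = TRUE, digits = NA
    )
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  utts <- lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln)
    ents <- if (length(x$entities)) {
      data.frame(slot = x$entities$slot, start = as.integer(x$entities$start),
                 end = as.integer(x$entities$end),
                 surface = x$entities$surface, stringsAsFactors = FALSE)
    } else {
      empty_entities()
    }
    labeled_utterance(x$text, x$intent, ents, as.character(x$provenance))
  })
  structure(list(utterances = utts, ontology_version = NA_character_,
                 seed = NA_integer_),
            class = "corpus")
}

#' @rdname write_corpus_jsonl
#' @export
write_corpus_text <- function(corpus, path) {
  writeLines(corpus_texts(corpus), path, useBytes = TRUE)
  invisible(path)
}

#' Concatenate a corpus into language-model training text
#'
#' Each utterance is terminated by a newline so a character-level model can
#' learn where utterances end.
#'
#' @param corpus A `corpus` object.
#' @return A single string.
#' @export
corpus_text <- function(corpus) {
  paste0(paste(corpus_texts(corpus), collapse = "\n"), "\n")
}
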