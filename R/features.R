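# Packaged lexical resources, cached per session.
the <- new.env(parent = emptyenv())

resource_lines <- function(file) {
  path <- system.file("extdata", file, package = "dialogforge",
                      mustWork = TRUE)
  readLines(path, encoding = "UTF-8")
}

stopword_list <- function() {
  if (is.null(the$stopwords)) the$stopwords <- resource_lines("stopwords.txt")
  the$stopwords
}

contraction_table <- function() {
  if (is.null(the$contractions)) {
    rows <- strsplit(resource_lines("contractions.tsv"), "\t", fixed = TRUE)
    the$contractions <- setNames(vapply(rows, `[[`, "", 2L),
                                 vapply(rows, `[[`, "", 1L))
  }
  the$contractions
}

lemma_exceptions <- function() {
  if (is.null(the$lemmas)) {
    rows <- strsplit(resource_lines("lemmas.tsv"), "\t", fixed = TRUE)
    the$lemmas <- setNames(vapply(rows, `[[`, "", 2L),
                           vapply(rows, `[[`, "", 1L))
  }
  the$lemmas
}

expand_contractions <- function(text) {
  tab <- contraction_table()
  for (key in names(tab)) {
    text <- gsub(paste0("\\b", key, "\\b"), tab[[key]], text,
                 ignore.case = TRUE)
  }
  text
}

#' Lemmatize a token
#'
#' Lexicon-backed rule lemmatizer: irregular and domain forms come from the
#' packaged exception table; regular plurals (`-ies`, `-es`, `-s`) and
#' verbal `-ing`/`-ed` endings are stripped by rule; unknown words pass
#' through unchanged.
#'
#' @param token Lower-case token.
#' @return The lemma.
#' @export
lemmatize_token <- function(token) {
  exc <- lemma_exceptions()
  if (token %in% names(exc)) return(exc[[token]])
  if (grepl("^[0-9]", token) || nchar(token) < 4L) return(token)
  if (grepl("ies$", token)) return(sub("ies$", "y", token))
  if (grepl("(ses|xes|zes|ches|shes)$", token)) return(sub("es$", "", token))
  if (grepl("[^su]s$", token) && !grepl("ss$", token)) {
    return(sub("s$", "", token))
  }
  if (nchar(token) > 5L && grepl("ing$", token)) {
    stem <- sub("ing$", "", token)
    if (grepl("([bcdfgklmnprstvz])\\1$", stem)) {
      stem <- substr(stem, 1L, nchar(stem) - 1L)
    }
    return(stem)
  }
  if (nchar(token) > 4L && grepl("ed$", token)) {
    stem <- sub("ed$", "", token)
    if (grepl("([bcdfgklmnprstvz])\\1$", stem)) {
      stem <- substr(stem, 1L, nchar(stem) - 1L)
    }
    return(stem)
  }
  token
}

simple_tokenize <- function(text) {
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Word-level preprocessing
#'
#' Normalization pipeline for word-level features, in fixed order:
#' contraction expansion, lower-casing, tokenization, stopword removal,
#' lemmatization, and removal of non-ASCII and pure-punctuation tokens
#' (punctuation is stripped from token edges first). Deterministic; a text
#' reducing to zero tokens is flagged via the `dropped` log, not raised.
#'
#' @param text Input utterance.
#' @return Object of class `tokenized_utterance`: list with `original`,
#'   `tokens` and a `dropped` data frame of (token, reason).
#' @export
preprocess_word_level <- function(text) {
  dropped <- list()
  drop <- function(tok, reason) {
    dropped[[length(dropped) + 1L]] <<- data.frame(
      token = tok, reason = reason, stringsAsFactors = FALSE
    )
  }
  lowered <- tolower(expand_contractions(text))
  raw <- simple_tokenize(lowered)
  tokens <- character()
  for (tok in raw) {
    if (tok %in% stopword_list()) { drop(tok, "stopword"); next }
    tok <- lemmatize_token(tok)
    clean <- gsub("[^a-z0-9]", "", iconv(tok, to = "ASCII", sub = ""))
    if (!nzchar(clean)) { drop(tok, "non-ascii/punctuation"); next }
    tokens <- c(tokens, clean)
  }
  structure(
    list(original = text, tokens = tokens,
         dropped = if (length(dropped)) do.call(rbind, dropped) else
           data.frame(token = character(), reason = character())),
    class = "tokenized_utterance"
  )
}

#' Sentence-level preprocessing
#'
#' Removes non-ASCII characters only; case, inflection and stopwords are
#' preserved because lemmatization can cut semantic distinctions at the
#' sentence level ("close" / "closer" / "closest").
#'
#' @param text Input utterance.
#' @return The cleaned string.
#' @export
preprocess_sentence_level <- function(text) {
  iconv(text, to = "ASCII", sub = "")
}

#' Mean-pooled word-level feature vector
#'
#' Arithmetic mean of the vectors of the utterance's representable tokens:
#' `Fw = (1/N) sum(v_wn)`. Tokens absent from a non-subword table are
#' skipped (not zero-imputed); subword tables compose out-of-vocabulary
#' tokens from their character n-grams.
#'
#' @param t A [preprocess_word_level()] result (or a character vector of
#'   tokens).
#' @param table A `vector_table`.
#' @return Numeric vector of length `table$dimension`.
#' @export
word_feature <- function(t, table) {
  tokens <- if (inherits(t, "tokenized_utterance")) t$tokens else
    as.character(t)
  vecs <- lapply(tokens, function(tok) word_vector(table, tok))
  vecs <- vecs[!vapply(vecs, is.null, TRUE)]
  if (!length(vecs)) {
    id <- if (inherits(t, "tokenized_utterance")) t$original else
      paste(tokens, collapse = " ")
    stop("missing feature: no representable tokens in utterance '", id, "'")
  }
  colMeans(do.call(rbind, vecs))
}

#' Build a feature matrix for a set of utterances
#'
#' @param texts Character vector of utterances.
#' @param table A `vector_table`.
#' @param ids Row identifiers (defaults to `u00001`-style ids).
#' @return Object of class `feature_matrix`: numeric matrix with one row
#'   per representable utterance; utterances with no representable token
#'   are dropped and recorded in `attr(, "dropped")`.
#' @export
word_feature_matrix <- function(texts, table, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("u%05d", seq_along(texts))
  rows <- vector("list", length(texts))
  ok <- logical(length(texts))
  for (i in seq_along(texts)) {
    t <- preprocess_word_level(texts[i])
    rows[i] <- list(tryCatch(word_feature(t, table),
                             error = function(e) NULL))
    ok[i] <- !is.null(rows[[i]])
  }
  m <- do.call(rbind, rows[ok])
  rownames(m) <- ids[ok]
  structure(m, class = c("feature_matrix", class(m)),
            level = "word", dropped = ids[!ok])
}

#' Sentence encoders
#'
#' A sentence encoder is a list with fields `name`, `dimension` and
#' `encode(texts) -> matrix`; any conforming object (e.g. an adapter over
#' an external contextual encoder) can stand behind the sentence-level
#' feature interface. `word_mean_encoder()` is the packaged default: it
#' mean-pools trained word vectors over sentence-level-preprocessed text
#' (no stopword removal, no lemmatization).
#'
#' @param table A `vector_table`.
#' @return An object of class `sentence_encoder`.
#' @export
word_mean_encoder <- function(table) {
  structure(
    list(
      name = "word-mean",
      dimension = table$dimension,
      encode = function(texts) {
        rows <- lapply(texts, function(txt) {
          toks <- simple_tokenize(tolower(preprocess_sentence_level(txt)))
          vecs <- lapply(toks, function(tok) word_vector(table, tok))
          vecs <- vecs[!vapply(vecs, is.null, TRUE)]
          if (!length(vecs)) return(rep(NA_real_, table$dimension))
          colMeans(do.call(rbind, vecs))
        })
        do.call(rbind, rows)
      }
    ),
    class = "sentence_encoder"
  )
}

#' Sentence-level feature vector
#'
#' @param text Input utterance (non-empty).
#' @param encoder A `sentence_encoder` (see [word_mean_encoder()]).
#' @return Numeric vector of length `encoder$dimension`.
#' @export
sentence_feature <- function(text, encoder) {
  if (!inherits(encoder, "sentence_encoder")) {
    stop("capability error: no sentence encoder available; ",
         "use the word-level route (word_feature) or supply an encoder")
  }
  if (!nzchar(trimws(text))) stop("empty text has no sentence feature")
  v <- encoder$encode(text)[1L, ]
  if (anyNA(v)) stop("encoder produced no representation for '", text, "'")
  v
}

# Closed function-word inventories for the rule-based chunker.
CHUNK_PREPOSITIONS <- c("with", "for", "at", "to", "on", "in", "from",
                        "until", "by", "of", "since")
CHUNK_DETERMINERS <- c("a", "an", "the", "this", "that", "my", "his", "her",
                       "their", "your", "its", "some")
CHUNK_AUX <- c("can", "could", "will", "would", "you", "please", "please,",
               "i", "have", "has", "did", "do", "are", "is", "when", "where",
               "who", "what", "how")

chunk_verbs <- function() names(VERB_FORMS)

# Deterministic noun-phrase chunker over the corpus's sentence shapes:
# leading auxiliaries/verbs are consumed, the tokens after the verb up to
# the first preposition form the direct-object phrase (dobj), and each
# prepositional phrase contributes its object (pobj; nummod when it starts
# with a number and no preposition precedes it).
rule_chunk <- function(text) {
  clean <- tolower(gsub("[?.!,]", "", text))
  toks <- simple_tokenize(clean)
  # map each cleaned token back to a char offset in the original text
  offs <- integer(length(toks))
  pos <- 0L
  low <- tolower(text)
  for (i in seq_along(toks)) {
    hit <- regexpr(toks[i], substr(low, pos + 1L, nchar(low)),
                   fixed = TRUE)[1L]
    offs[i] <- pos + hit - 1L
    pos <- offs[i] + nchar(toks[i])
  }
  verbs <- c(chunk_verbs(), VERB_FORMS)
  i <- 1L
  while (i <= length(toks) &&
         (toks[i] %in% CHUNK_AUX || toks[i] %in% verbs ||
          toks[i] %in% c("use"))) {
    i <- i + 1L
  }
  spans <- list()
  add_span <- function(from, to, tag) {
    while (from <= to && toks[from] %in% CHUNK_DETERMINERS) from <- from + 1L
    if (from > to) return()
    start <- offs[from]
    end <- offs[to] + nchar(toks[to])
    spans[[length(spans) + 1L]] <<- data.frame(
      phrase = substr(text, start + 1L, end), start = start, end = end,
      tag = tag, stringsAsFactors = FALSE
    )
  }
  tag <- "dobj"
  from <- i
  while (i <= length(toks) + 1L) {
    boundary <- i > length(toks) || toks[i] %in% CHUNK_PREPOSITIONS
    if (boundary) {
      if (from <= i - 1L) {
        actual <- tag
        if (tag == "dobj" && grepl("^[0-9]", toks[from])) actual <- "nummod"
        add_span(from, i - 1L, actual)
      }
      tag <- "pobj"
      from <- i + 1L
    }
    i <- i + 1L
  }
  if (length(spans)) do.call(rbind, spans) else
    data.frame(phrase = character(), start = integer(), end = integer(),
               tag = character(), stringsAsFactors = FALSE)
}

#' Extract noun-phrase entity candidates
#'
#' Splits an utterance into candidate entity phrases with head dependency
#' tags. By default a deterministic rule-based chunker tuned to the
#' corpus's sentence shapes is used (verb-object phrase tagged `dobj`,
#' prepositional objects tagged `pobj`, leading number phrases `nummod`);
#' a full dependency parser can be plugged in as `parser`, a function
#' `text -> data.frame(phrase, start, end, tag)`. If the supplied parser
#' fails, the rule-based chunker takes over with a notice.
#'
#' @param text Input utterance.
#' @param parser Optional parser function.
#' @return Data frame of class `entity_candidates` with columns `phrase`,
#'   `start`, `end` (0-based half-open spans into `text`) and `tag`;
#'   spans are non-overlapping.
#' @export
extract_entity_candidates <- function(text, parser = NULL) {
  out <- if (is.null(parser)) {
    rule_chunk(text)
  } else {
    tryCatch(parser(text), error = function(e) {
      message("parser failed (", conditionMessage(e),
              "); falling back to the rule-based chunker")
      rule_chunk(text)
    })
  }
  structure(out, class = c("entity_candidates", class(out)))
}
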