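#' Training configuration for word embeddings
#'
#' Defaults are the tuned values used throughout the package: 32 features,
#' minimum word count 3, context window 6, downsampling threshold 1e-3 for
#' frequent words, 50 epochs of the skip-gram objective. Negative-sampling
#' count and initial learning rate default to 5 and 0.025 with linear
#' decay. Training is single-threaded so runs are bit-reproducible per
#' seed.
#'
#' @param dimension Embedding dimension.
#' @param min_count Minimum token frequency to enter the vocabulary.
#' @param window Maximum context window (a reduced window is drawn per
#'   position, as in standard skip-gram training).
#' @param downsample Frequent-word downsampling threshold (0 disables).
#' @param epochs Training epochs.
#' @param negative Negative samples per positive pair.
#' @param alpha Initial learning rate (linear decay to `alpha/1e4`).
#' @param seed Integer seed.
#' @return A list of class `train_config`.
#' @export
train_config <- function(dimension = 32L, min_count = 3L, window = 6L,
                         downsample = 1e-3, epochs = 50L, negative = 5L,
                         alpha = 0.025, seed = 1L) {
  stopifnot(dimension > 0, min_count > 0, window > 0, epochs > 0,
            negative >= 0, alpha > 0)
  structure(
    list(dimension = as.integer(dimension), min_count = as.integer(min_count),
         window = as.integer(window), downsample = downsample,
         epochs = as.integer(epochs), negative = as.integer(negative),
         alpha = alpha, algorithm = "skipgram", seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Subword (character n-gram) configuration
#'
#' @param n_min,n_max Inclusive n-gram length range (default 3..6).
#' @param boundary_start,boundary_end Word boundary markers.
#' @return A list of class `subword_config`.
#' @export
subword_config <- function(n_min = 3L, n_max = 6L,
                           boundary_start = "<", boundary_end = ">") {
  stopifnot(n_min >= 1, n_min <= n_max)
  structure(
    list(n_min = as.integer(n_min), n_max = as.integer(n_max),
         boundary_start = boundary_start, boundary_end = boundary_end),
    class = "subword_config"
  )
}

#' Character n-grams of a boundary-marked word
#'
#' The word is wrapped in boundary markers (`<fever>`) and sliding
#' character n-grams are emitted for each order `n_min..n_max` in
#' left-to-right order, duplicates preserved. A word shorter than every
#' requested order collapses to the marked whole word.
#'
#' @param word Non-empty string.
#' @param cfg A [subword_config()].
#' @return Character vector of n-grams.
#' @examples
#' char_ngrams("fever", subword_config(3, 3))
#' # "<fe" "fev" "eve" "ver" "er>"
#' @export
char_ngrams <- function(word, cfg = subword_config()) {
  stopifnot(nzchar(word))
  marked <- paste0(cfg$boundary_start, word, cfg$boundary_end)
  len <- nchar(marked)
  out <- character()
  for (n in cfg$n_min:cfg$n_max) {
    if (len < n) next
    for (i in seq_len(len - n + 1L)) {
      out <- c(out, substr(marked, i, i + n - 1L))
    }
  }
  if (!length(out)) out <- marked
  out
}

# Normalize the many accepted corpus shapes to a list of token vectors.
as_token_sentences <- function(corpus) {
  if (inherits(corpus, "corpus")) {
    corpus <- corpus_texts(corpus)
  }
  if (is.character(corpus)) {
    return(lapply(tolower(corpus), simple_tokenize))
  }
  if (is.list(corpus)) {
    return(lapply(corpus, function(s) tolower(as.character(s))))
  }
  stop("unsupported corpus type: supply a corpus object, a character ",
       "vector of texts, or a list of token vectors")
}

build_vocab_counts <- function(sentences, min_count) {
  counts <- table(unlist(sentences))
  counts <- counts[counts >= min_count]
  if (!length(counts)) {
    stop("configuration error: empty vocabulary after min_count filtering")
  }
  counts <- counts[order(-as.integer(counts), names(counts))]
  counts
}

new_vector_table <- function(vectors, subword = NULL) {
  structure(
    list(dimension = ncol(vectors), vectors = vectors, subword = subword),
    class = "vector_table"
  )
}

#' @export
print.vector_table <- function(x, ...) {
  cat("<vector table>", nrow(x$vectors), "tokens, dimension",
      x$dimension, if (!is.null(x$subword)) "(subword)" else "", "\n")
  invisible(x)
}

#' Train skip-gram word embeddings
#'
#' Skip-gram with negative sampling over the tokenized corpus. Tokens with
#' frequency below `min_count` are excluded from the vocabulary.
#' Single-threaded and reproducible per `cfg$seed`.
#'
#' @param corpus A `corpus` object, character vector of texts, or list of
#'   token vectors.
#' @param cfg A [train_config()].
#' @return A `vector_table`: list with `dimension`, `vectors` (matrix with
#'   token rownames) and `subword = NULL`.
#' @export
train_skipgram <- function(corpus, cfg = train_config()) {
  sentences <- as_token_sentences(corpus)
  counts <- build_vocab_counts(sentences, cfg$min_count)
  vocab <- names(counts)
  ids <- lapply(sentences, function(s) {
    m <- match(s, vocab)
    as.integer(m[!is.na(m)]) - 1L
  })
  res <- .sg_train_cpp(ids, length(vocab), as.numeric(counts), list(),
                       length(vocab), cfg$dimension, cfg$window,
                       cfg$negative, cfg$epochs, cfg$alpha, cfg$downsample,
                       cfg$seed)
  m <- res$input_vectors
  rownames(m) <- vocab
  new_vector_table(m)
}

#' Train subword character n-gram embeddings
#'
#' Each vocabulary word is represented as the bag of its boundary-marked
#' character n-grams; the word vector is the sum of its n-gram vectors, so
#' out-of-vocabulary words can still be composed from shared n-grams.
#' Trained with the same skip-gram/negative-sampling objective as
#' [train_skipgram()], with gradients distributed over the center word's
#' n-grams.
#'
#' @param corpus A `corpus` object, character vector of texts, or list of
#'   token vectors.
#' @param cfg A [train_config()].
#' @param subword A [subword_config()].
#' @return A `vector_table` whose `vectors` hold the composed (summed)
#'   word vectors and whose `subword` field carries the n-gram vectors and
#'   configuration.
#' @export
train_subword <- function(corpus, cfg = train_config(),
                          subword = subword_config()) {
  sentences <- as_token_sentences(corpus)
  counts <- build_vocab_counts(sentences, cfg$min_count)
  vocab <- names(counts)
  grams_per_word <- lapply(vocab, char_ngrams, cfg = subword)
  gram_vocab <- sort(unique(unlist(grams_per_word)))
  input_map <- lapply(grams_per_word, function(g) {
    match(g, gram_vocab) - 1L
  })
  ids <- lapply(sentences, function(s) {
    m <- match(s, vocab)
    as.integer(m[!is.na(m)]) - 1L
  })
  res <- .sg_train_cpp(ids, length(vocab), as.numeric(counts), input_map,
                       length(gram_vocab), cfg$dimension, cfg$window,
                       cfg$negative, cfg$epochs, cfg$alpha, cfg$downsample,
                       cfg$seed)
  grams <- res$input_vectors
  rownames(grams) <- gram_vocab
  words <- t(vapply(grams_per_word, function(g) {
    colSums(grams[match(g, gram_vocab), , drop = FALSE])
  }, numeric(cfg$dimension)))
  rownames(words) <- vocab
  new_vector_table(words, subword = list(config = subword,
                                         ngram_vectors = grams))
}

#' Look up (or compose) the vector for a token
#'
#' In-vocabulary tokens return their stored row. For subword tables,
#' out-of-vocabulary tokens are composed as the sum of the vectors of
#' their known character n-grams.
#'
#' @param table A `vector_table`.
#' @param word Token to look up.
#' @return Numeric vector, or `NULL` when the token is not representable.
#' @export
word_vector <- function(table, word) {
  i <- match(word, rownames(table$vectors))
  if (!is.na(i)) return(table$vectors[i, ])
  if (is.null(table$subword)) return(NULL)
  grams <- char_ngrams(word, table$subword$config)
  idx <- match(grams, rownames(table$subword$ngram_vectors))
  idx <- idx[!is.na(idx)]
  if (!length(idx)) return(NULL)
  colSums(table$subword$ngram_vectors[idx, , drop = FALSE])
}

#' Cosine similarity of two vectors
#'
#' @param u,v Non-zero numeric vectors of equal length.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors differ in dimension")
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for zero vector")
  sum(u * v) / (nu * nv)
}

#' Nearest neighbors of a token by cosine similarity
#'
#' Ranks the whole vocabulary by cosine similarity to the query (the query
#' token itself excluded), keeps entries with similarity at or above
#' `threshold`, and returns at most `k`. Exact ties are broken by
#' lexicographic token order. Out-of-vocabulary queries on subword tables
#' are composed from their n-grams.
#'
#' @param word Query token.
#' @param table A `vector_table`.
#' @param k Maximum neighbors (k = 0 gives an empty result).
#' @param threshold Minimum similarity in `[-1, 1]` (or above 1 for an
#'   unreachable threshold).
#' @return Object of class `synonym_hits`: list with `matches` (data frame
#'   of `token`, `similarity`) and `oov` (TRUE when the query could not be
#'   represented at all).
#' @export
nearest_neighbors <- function(word, table, k = 10L, threshold = 0.5) {
  stopifnot(k >= 0)
  empty <- data.frame(token = character(), similarity = numeric(),
                      stringsAsFactors = FALSE)
  qv <- word_vector(table, word)
  if (is.null(qv)) {
    return(structure(list(matches = empty, oov = TRUE),
                     class = "synonym_hits"))
  }
  vocab <- rownames(table$vectors)
  keep <- vocab != word
  m <- table$vectors[keep, , drop = FALSE]
  norms <- sqrt(rowSums(m^2))
  qn <- sqrt(sum(qv^2))
  sims <- as.numeric(m %*% qv) / (norms * qn)
  df <- data.frame(token = vocab[keep], similarity = sims,
                   stringsAsFactors = FALSE)
  df <- df[df$similarity >= threshold, , drop = FALSE]
  df <- df[order(-df$similarity, df$token), , drop = FALSE]
  df <- head(df, k)
  rownames(df) <- NULL
  structure(list(matches = df, oov = FALSE), class = "synonym_hits")
}

#' @export
print.synonym_hits <- function(x, ...) {
  if (x$oov) cat("<synonym hits> query out of vocabulary\n")
  else {
    cat("<synonym hits>", nrow(x$matches), "match(es)\n")
    if (nrow(x$matches)) print(x$matches)
  }
  invisible(x)
}

#' Expand a word into embedding-space synonyms
#'
#' Looks up the top `k` vocabulary words whose cosine similarity to the
#' query is at least `threshold` (defaults 10 and 0.5). Special characters
#' are stripped from the query before lookup, so unit-like surface forms
#' ("mmHg," with punctuation) resolve to their clean token.
#'
#' @param word Query word.
#' @param vectors A `vector_table`.
#' @param k Maximum synonyms to return.
#' @param threshold Minimum cosine similarity.
#' @return A `synonym_hits` object; `oov = TRUE` distinguishes an
#'   out-of-vocabulary query from an in-vocabulary query with no hit.
#' @export
expand_synonyms <- function(word, vectors, k = 10L, threshold = 0.5) {
  cleaned <- tolower(gsub("[^[:alnum:]]", "", word))
  if (!nzchar(cleaned)) {
    return(structure(list(matches = data.frame(token = character(),
                                               similarity = numeric()),
                          oov = TRUE),
                     class = "synonym_hits"))
  }
  nearest_neighbors(cleaned, vectors, k = k, threshold = threshold)
}

#' Read and write word2vec text vector files
#'
#' The format is a header line `"vocab_size dimension"` followed by one
#' `token v1 ... vd` line per token. Writing uses 6 significant digits, so
#' a write/read round trip preserves vectors to that precision. On read,
#' a duplicated token keeps its last occurrence (with a warning), and a
#' row whose value count does not match the header dimension is a format
#' error naming the line.
#'
#' @param path File path.
#' @return `read_vectors()` returns a `vector_table`.
#' @export
read_vectors <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  if (!length(lines)) stop("empty vector file: ", path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(header) != 2) {
    stop("format error at line 1: expected 'vocab_size dimension' header")
  }
  n <- as.integer(header[1])
  dim <- as.integer(header[2])
  body <- lines[-1]
  if (length(body) != n) {
    stop("format error: header declares ", n, " rows but file has ",
         length(body))
  }
  tokens <- character(n)
  m <- matrix(0, n, dim)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(body[i]), "\\s+")[[1]]
    if (length(parts) != dim + 1L) {
      stop("format error at line ", i + 1L, ": expected ", dim + 1L,
           " fields, found ", length(parts))
    }
    tokens[i] <- parts[1]
    vals <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(vals)) {
      stop("format error at line ", i + 1L, ": non-numeric vector entry")
    }
    m[i, ] <- vals
  }
  if (anyDuplicated(tokens)) {
    dup <- unique(tokens[duplicated(tokens)])
    warning("duplicate token(s) in vector file (last occurrence kept): ",
            paste(dup, collapse = ", "), call. = FALSE)
    keep <- !duplicated(tokens, fromLast = TRUE)
    tokens <- tokens[keep]
    m <- m[keep, , drop = FALSE]
  }
  rownames(m) <- tokens
  new_vector_table(m)
}

#' @rdname read_vectors
#' @param table A `vector_table`.
#' @export
write_vectors <- function(table, path) {
  m <- table$vectors
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(rownames(m)[i], paste(sprintf("%.6g", m[i, ]), collapse = " "))
  }, "")
  writeLines(c(paste(nrow(m), ncol(m)), rows), path, useBytes = TRUE)
  invisible(path)
}
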