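#' Build a character vocabulary
#'
#' Maps every character of the training text to a unique integer id
#' (0-based). The newline character, which terminates utterances, always
#' gets id 0; the remaining characters are ordered by descending frequency
#' and then by codepoint, so the mapping is deterministic.
#'
#' @param text Non-empty training text.
#' @return Object of class `char_vocab`: list with `chars` (character
#'   vector; `chars[i]` has id `i - 1`), `size` and `newline_id` (0 when
#'   the text contains a newline).
#' @export
build_vocab <- function(text) {
  stopifnot(nzchar(text))
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  counts <- table(chars)
  has_nl <- "\n" %in% names(counts)
  counts <- counts[names(counts) != "\n"]
  ord <- names(counts)[order(-as.integer(counts),
                             vapply(names(counts), utf8ToInt, 0L))]
  chars_out <- if (has_nl) c("\n", ord) else ord
  structure(
    list(chars = chars_out, size = length(chars_out),
         newline_id = if (has_nl) 0L else NA_integer_),
    class = "char_vocab"
  )
}

#' @export
print.char_vocab <- function(x, ...) {
  cat("<char vocab>", x$size, "characters\n")
  invisible(x)
}

#' Encode/decode text with a character vocabulary
#'
#' @param text Input string (every character must be in the vocabulary).
#' @param vocab A [build_vocab()] result.
#' @return `encode_chars()`: integer vector of 0-based ids;
#'   `decode_chars()`: the string.
#' @export
encode_chars <- function(text, vocab) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  ids <- match(chars, vocab$chars)
  if (anyNA(ids)) {
    bad <- unique(chars[is.na(ids)])
    stop("characters not in vocabulary: ",
         paste(sprintf("'%s'", bad), collapse = ", "))
  }
  ids - 1L
}

#' @rdname encode_chars
#' @param ids Integer vector of 0-based character ids.
#' @export
decode_chars <- function(ids, vocab) {
  paste(vocab$chars[ids + 1L], collapse = "")
}

#' Split text into fixed-length training windows
#'
#' Splits the encoded text into non-overlapping windows of `L` characters;
#' each window's target sequence is its input shifted by one character
#' (input characters `t` predict characters `t + 1`). The final partial
#' window is dropped.
#'
#' @param text Training text of more than `L` characters (utterances
#'   terminated by newlines; see [corpus_text()]).
#' @param vocab A [build_vocab()] covering `text`.
#' @param L Window length (default 100).
#' @return Object of class `windowed_dataset`: list with integer matrices
#'   `inputs` and `targets` (rows = windows, 0-based ids), `L` and
#'   `vocab_size`.
#' @export
make_windows <- function(text, vocab, L = 100L) {
  ids <- encode_chars(text, vocab)
  n <- length(ids)
  if (n <= L) {
    stop("text of ", n, " characters is too short for windows of length ", L)
  }
  starts <- seq(1L, n - L, by = L)
  inputs <- t(vapply(starts, function(s) ids[s:(s + L - 1L)],
                     integer(L)))
  targets <- t(vapply(starts, function(s) ids[(s + 1L):(s + L)],
                      integer(L)))
  structure(
    list(inputs = inputs, targets = targets, L = as.integer(L),
         vocab_size = vocab$size),
    class = "windowed_dataset"
  )
}

#' Character language model configuration
#'
#' The default profile mirrors the full-scale setup: a 256-dimensional
#' character lookup table, a single recurrent LSTM layer of 1024 memory
#' units with dropout 0.2, categorical cross-entropy, mini-batches of 64
#' over 30 epochs on length-100 windows. `charlm_desk_profile()` is the
#' same architecture at 256 units, sized so a full training run stays in
#' the minutes range on one CPU.
#'
#' @param embed_dim Character embedding dimension.
#' @param hidden Recurrent memory units.
#' @param dropout Dropout probability on the recurrent layer output.
#' @param batch Mini-batch size.
#' @param epochs Training epochs.
#' @param window Window length L.
#' @param lr Adam learning rate.
#' @param seed Integer seed.
#' @return A list of class `charlm_config`.
#' @export
charlm_config <- function(embed_dim = 256L, hidden = 1024L, dropout = 0.2,
                          batch = 64L, epochs = 30L, window = 100L,
                          lr = 1e-3, seed = 1L) {
  stopifnot(embed_dim > 0, hidden > 0, dropout >= 0, dropout < 1,
            batch > 0, epochs > 0, window > 0)
  structure(
    list(embed_dim = as.integer(embed_dim), hidden = as.integer(hidden),
         dropout = dropout, batch = as.integer(batch),
         epochs = as.integer(epochs), window = as.integer(window),
         lr = lr, cell = "lstm", loss = "categorical-crossentropy",
         seed = as.integer(seed)),
    class = "charlm_config"
  )
}

#' @rdname charlm_config
#' @param ... Overrides passed to [charlm_config()].
#' @export
charlm_desk_profile <- function(...) {
  cfg <- charlm_config(hidden = 256L)
  modifyList(cfg, list(...))
}

#' Train the character-level LSTM language model
#'
#' Architecture: character embedding layer, one LSTM layer with dropout on
#' its output, and a dense softmax over the vocabulary, trained with Adam
#' on categorical cross-entropy for one-step-ahead character prediction.
#' Reports the running training loss and next-character accuracy for every
#' epoch (averaged over the epoch's mini-batches, with dropout active, as
#' training frameworks conventionally log them), the pre-training loss
#' over the whole dataset (which is close to `log(vocab_size)` under the
#' near-uniform initial softmax), and `final_loss`/`final_accuracy`: the
#' trained model's loss and next-character accuracy over the full training
#' set with dropout off — the training accuracy of the model itself.
#' Runs and draws are reproducible per `cfg$seed`.
#'
#' @param dataset A [make_windows()] result.
#' @param cfg A [charlm_config()].
#' @param vocab The [build_vocab()] used to encode the dataset.
#' @return Object of class `charlm_model`: list with the weight matrices,
#'   `vocab`, `config`, `history` (data frame `epoch`, `loss`,
#'   `accuracy`) and `initial_loss`.
#' @export
train_charlm <- function(dataset, cfg = charlm_desk_profile(), vocab) {
  stopifnot(inherits(dataset, "windowed_dataset"),
            inherits(cfg, "charlm_config"))
  if (max(dataset$inputs) >= vocab$size || max(dataset$targets) >= vocab$size) {
    stop("integrity error: dataset ids exceed vocabulary size ", vocab$size)
  }
  if (!nrow(dataset$inputs)) stop("empty dataset")
  res <- .charlm_train_cpp(dataset$inputs, dataset$targets, vocab$size,
                           cfg$embed_dim, cfg$hidden, cfg$dropout,
                           cfg$batch, cfg$epochs, cfg$seed, cfg$lr)
  structure(
    list(E = res$E, Wx = res$Wx, Wh = res$Wh, b = res$b, Wy = res$Wy,
         by = res$by, vocab = vocab, config = cfg,
         history = data.frame(epoch = seq_len(cfg$epochs),
                              loss = res$loss, accuracy = res$accuracy),
         initial_loss = res$initial_loss,
         final_loss = res$final_loss,
         final_accuracy = res$final_accuracy),
    class = "charlm_model"
  )
}

#' @export
print.charlm_model <- function(x, ...) {
  cat("<char-LM>", x$config$hidden, "LSTM units, vocab", x$vocab$size,
      sprintf("- training loss %.4f, accuracy %.4f\n", x$final_loss,
              x$final_accuracy))
  invisible(x)
}

lstm_step <- function(model, h, c, id) {
  H <- model$config$hidden
  g <- model$E[id + 1L, , drop = FALSE] %*% model$Wx + h %*% model$Wh
  g <- g + model$b
  gi <- 1 / (1 + exp(-g[, 1:H, drop = FALSE]))
  gf <- 1 / (1 + exp(-g[, (H + 1):(2 * H), drop = FALSE]))
  gg <- tanh(g[, (2 * H + 1):(3 * H), drop = FALSE])
  go <- 1 / (1 + exp(-g[, (3 * H + 1):(4 * H), drop = FALSE]))
  c <- gf * c + gi * gg
  h <- go * tanh(c)
  logits <- h %*% model$Wy + model$by
  list(h = h, c = c, logits = as.numeric(logits))
}

#' Sample an utterance from a trained character model
#'
#' Feeds `seed_text` through the network, then samples autoregressively
#' from the temperature-scaled softmax, feeding each drawn character back
#' in, until a newline is produced or `max_len` characters have been
#' generated. `temperature = 0` performs greedy argmax decoding (the
#' limiting distribution as temperature approaches 0). Reproducible per
#' `seed`.
#'
#' @param model A [train_charlm()] result.
#' @param seed_text Priming text; every character must be in the model's
#'   vocabulary.
#' @param temperature Softmax temperature (>= 0; 1.0 samples from the
#'   model's own distribution).
#' @param max_len Maximum generated characters.
#' @param seed Integer RNG seed.
#' @return The generated continuation (not including `seed_text`, without
#'   the terminating newline).
#' @export
sample_charlm <- function(model, seed_text, temperature = 1.0,
                          max_len = 200L, seed = 1L) {
  stopifnot(temperature >= 0)
  vocab <- model$vocab
  ids <- encode_chars(seed_text, vocab)
  H <- model$config$hidden
  h <- matrix(0, 1, H)
  c <- matrix(0, 1, H)
  logits <- NULL
  for (id in ids) {
    st <- lstm_step(model, h, c, id)
    h <- st$h; c <- st$c; logits <- st$logits
  }
  out <- integer()
  with_seed(seed, {
    for (i in seq_len(max_len)) {
      nxt <- if (temperature == 0) {
        which.max(logits) - 1L
      } else {
        z <- logits / temperature
        z <- z - max(z)
        p <- exp(z) / sum(exp(z))
        sample.int(length(p), 1L, prob = p) - 1L
      }
      if (!is.na(vocab$newline_id) && nxt == vocab$newline_id) break
      out <- c(out, nxt)
      st <- lstm_step(model, h, c, nxt)
      h <- st$h; c <- st$c; logits <- st$logits
    }
  })
  decode_chars(out, vocab)
}

#' Generate multiple utterances from a trained character model
#'
#' Samples `n` utterances, each primed with a newline (the
#' utterance-boundary character), with per-utterance derived seeds.
#'
#' @inheritParams sample_charlm
#' @param n Number of utterances.
#' @return Character vector of generated utterances (empty samples
#'   dropped).
#' @export
generate_utterances <- function(model, n, temperature = 1.0,
                                max_len = 200L, seed = 1L) {
  if (is.na(model$vocab$newline_id)) {
    stop("model vocabulary has no newline: train on corpus_text() output")
  }
  out <- vapply(seq_len(n), function(i) {
    sample_charlm(model, "\n", temperature = temperature,
                  max_len = max_len, seed = derive_seed(seed, paste0("g", i)))
  }, "")
  out[nzchar(out)]
}
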