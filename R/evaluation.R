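#' Pair-counting confusion for a clustering
#'
#' Counts all unordered item pairs `i < j` by same-cluster vs same-class
#' agreement: TP pairs share cluster and class, FP share only the cluster,
#' FN share only the class, TN share neither. The four counts always sum
#' to `n(n-1)/2`.
#'
#' @param pred Vector of predicted cluster indices, one per item. If named,
#'   names are matched against `gold`.
#' @param gold Vector of gold class labels, same items as `pred`.
#' @return Object of class `pair_confusion`: list with `tp`, `fp`, `tn`,
#'   `fn`, `n`.
#' @export
pair_confusion <- function(pred, gold) {
  if (length(pred) != length(gold)) {
    stop("item-set mismatch: ", length(pred), " predictions vs ",
         length(gold), " gold labels")
  }
  if (!is.null(names(pred)) && !is.null(names(gold))) {
    if (!setequal(names(pred), names(gold))) {
      stop("item-set mismatch: prediction and gold item names differ")
    }
    gold <- gold[names(pred)]
  }
  n <- length(pred)
  choose2 <- function(x) sum(choose(x, 2))
  cont <- table(pred, gold)
  tp <- choose2(cont)
  fp <- choose2(rowSums(cont)) - tp
  fn <- choose2(colSums(cont)) - tp
  tn <- choose(n, 2) - tp - fp - fn
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, n = n),
            class = "pair_confusion")
}

#' @export
print.pair_confusion <- function(x, ...) {
  cat("<pair confusion> n =", x$n, "items,", choose(x$n, 2), "pairs\n")
  cat("  TP =", x$tp, " FP =", x$fp, " TN =", x$tn, " FN =", x$fn, "\n")
  invisible(x)
}

#' Pair-counting precision, recall and F1
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`, `F1 = 2PR / (P + R)`;
#' each is 0 by convention when its denominator is 0.
#'
#' @param c A [pair_confusion()].
#' @return List with `precision`, `recall`, `f1`.
#' @export
pair_prf <- function(c) {
  p <- if (c$tp + c$fp > 0) c$tp / (c$tp + c$fp) else 0
  r <- if (c$tp + c$fn > 0) c$tp / (c$tp + c$fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f1 = f1)
}

#' Silhouette coefficient
#'
#' Per point, `a(i)` is the mean Euclidean distance to the other members of
#' its own cluster, `b(i)` the smallest mean distance to any other cluster,
#' and `S(i) = (b - a) / max(a, b)`. Points in singleton clusters get
#' `S(i) = 0` by convention. Distances are Euclidean, matching the
#' clustering metric.
#'
#' @param X Numeric matrix, one row per item.
#' @param assignment Cluster index per row.
#' @return List with `mean` and the per-point `values`.
#' @export
silhouette_score <- function(X, assignment) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(assignment) != n) stop("assignment length must match nrow(X)")
  clusters <- sort(unique(assignment))
  if (length(clusters) < 2) {
    stop("silhouette requires at least 2 clusters, got ", length(clusters))
  }
  d <- as.matrix(stats::dist(X))
  sizes <- table(factor(assignment, levels = clusters))
  s <- numeric(n)
  # mean distance from every point to every cluster, in one pass
  mean_to <- sapply(clusters, function(cl) {
    members <- assignment == cl
    rowSums(d[, members, drop = FALSE]) / sum(members)
  })
  colnames(mean_to) <- as.character(clusters)
  for (i in seq_len(n)) {
    cl <- as.character(assignment[i])
    m <- sizes[[cl]]
    if (m == 1L) { s[i] <- 0; next }
    a <- mean_to[i, cl] * m / (m - 1)  # exclude the point itself
    b <- min(mean_to[i, setdiff(colnames(mean_to), cl)])
    s[i] <- (b - a) / max(a, b)
  }
  list(mean = mean(s), values = s)
}

ngram_counts <- function(tokens, n) {
  if (length(tokens) < n) return(integer())
  grams <- vapply(seq_len(length(tokens) - n + 1L), function(i) {
    paste(tokens[i:(i + n - 1L)], collapse = "\u0001")
  }, "")
  table(grams)
}

#' BLEU score of a candidate against reference utterances
#'
#' Geometric mean of modified n-gram precisions (orders 1..`max_n`) times
#' a brevity penalty; clipping uses the maximum reference count per n-gram
#' and the brevity penalty uses the reference length closest to the
#' candidate length. For short utterances, add-one smoothing is applied to
#' higher-order precisions (n >= 2) so a single zero count does not
#' annihilate the score; orders longer than the candidate are skipped.
#' A perfect match scores 1.0; zero unigram overlap scores 0.0.
#'
#' @param candidate Candidate utterance (whitespace-tokenized).
#' @param references Character vector of reference utterances.
#' @param max_n Maximum n-gram order (default 4).
#' @param smoothing `"add1"` (default) or `"none"`.
#' @return BLEU score in `[0, 1]`.
#' @export
bleu <- function(candidate, references, max_n = 4L,
                 smoothing = c("add1", "none")) {
  smoothing <- match.arg(smoothing)
  stopifnot(length(references) >= 1)
  cand <- strsplit(trimws(candidate), "\\s+")[[1]]
  cand <- cand[nzchar(cand)]
  if (!length(cand)) {
    warning("empty candidate scored 0", call. = FALSE)
    return(0)
  }
  refs <- lapply(references, function(r) {
    toks <- strsplit(trimws(r), "\\s+")[[1]]
    toks[nzchar(toks)]
  })
  log_precisions <- numeric()
  for (n in seq_len(max_n)) {
    cc <- ngram_counts(cand, n)
    if (!length(cc)) break  # candidate shorter than n
    clipped <- 0
    for (g in names(cc)) {
      best_ref <- max(vapply(refs, function(rt) {
        rc <- ngram_counts(rt, n)
        if (g %in% names(rc)) rc[[g]] else 0L
      }, 0L))
      clipped <- clipped + min(cc[[g]], best_ref)
    }
    total <- sum(cc)
    p <- if (smoothing == "add1" && n >= 2L) {
      (clipped + 1) / (total + 1)
    } else {
      clipped / total
    }
    if (p == 0) return(0)
    log_precisions <- c(log_precisions, log(p))
  }
  ref_lens <- vapply(refs, length, 0L)
  r <- ref_lens[which.min(abs(ref_lens - length(cand)))]
  bp <- if (length(cand) >= r) 1 else exp(1 - r / length(cand))
  bp * exp(mean(log_precisions))
}

#' Mean best-match BLEU over a set of generated utterances
#'
#' Scores each candidate against every reference and keeps the maximum
#' sentence-level BLEU, then averages over candidates.
#'
#' @param candidates Character vector of generated utterances.
#' @param references Character vector of reference utterances (e.g. the
#'   original corpus texts for the candidate's intent).
#' @param ... Passed to [bleu()].
#' @return List with `mean` and per-candidate `scores`.
#' @export
bleu_corpus <- function(candidates, references, ...) {
  scores <- vapply(candidates, function(cand) {
    max(vapply(references, function(r) bleu(cand, r, ...), 0))
  }, 0, USE.NAMES = FALSE)
  list(mean = mean(scores), scores = scores)
}

trunc3 <- function(x) trunc(x * 1000) / 1000

#' Per-class corpus statistics
#'
#' Counts utterances and whitespace-tokenized words per class and reports
#' the average utterance length both at full precision and truncated (not
#' rounded) to 3 decimals, plus a `Total` row.
#'
#' @param x A `corpus` object, or a data frame with columns `class`,
#'   `utterances` and `words` (pre-counted inputs).
#' @return Data frame with columns `class`, `utterances`, `words`,
#'   `avg_length` (full precision) and `avg_length_3` (truncated).
#' @export
corpus_stats <- function(x) {
  if (inherits(x, "corpus")) {
    texts <- corpus_texts(x)
    intents <- corpus_intents(x)
    words <- vapply(strsplit(trimws(texts), "\\s+"), length, 0L)
    agg <- stats::aggregate(
      cbind(utterances = rep(1L, length(texts)), words = words),
      by = list(class = intents), FUN = sum
    )
  } else {
    agg <- as.data.frame(x)
    stopifnot(all(c("class", "utterances", "words") %in% names(agg)))
    agg <- agg[, c("class", "utterances", "words")]
  }
  agg <- agg[order(match(agg$class, unique(agg$class))), ]
  total <- data.frame(class = "Total",
                      utterances = sum(agg$utterances),
                      words = sum(agg$words))
  out <- rbind(agg, total)
  out$avg_length <- out$words / out$utterances
  out$avg_length_3 <- trunc3(out$avg_length)
  rownames(out) <- NULL
  out
}

#' Aggregate per-group rating means
#'
#' Unweighted arithmetic mean of group means, reported to 2 decimals.
#'
#' @param group_means Numeric vector of per-group means.
#' @return The overall mean, rounded to 2 decimals.
#' @export
aggregate_ratings <- function(group_means) {
  stopifnot(length(group_means) >= 1)
  round(mean(group_means), 2)
}

#' Full clustering evaluation report
#'
#' Bundles the pair-counting metrics, optional silhouette, and per-cluster
#' sizes into one report.
#'
#' @param pred Predicted cluster indices per item.
#' @param gold Gold class labels per item.
#' @param X Optional feature matrix for the silhouette (requires >= 2
#'   clusters).
#' @return Object of class `eval_report`.
#' @export
evaluate_clustering <- function(pred, gold, X = NULL) {
  pc <- pair_confusion(pred, gold)
  prf <- pair_prf(pc)
  sil <- if (!is.null(X) && length(unique(pred)) >= 2) {
    silhouette_score(X, pred)$mean
  } else {
    NA_real_
  }
  structure(
    list(pairs = pc, precision = prf$precision, recall = prf$recall,
         f1 = prf$f1, silhouette = sil,
         cluster_sizes = as.integer(table(pred))),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<clustering evaluation>\n")
  cat(sprintf("  pair P = %.3f  R = %.3f  F1 = %.3f\n",
              x$precision, x$recall, x$f1))
  if (!is.na(x$silhouette)) {
    cat(sprintf("  mean silhouette = %.3f\n", x$silhouette))
  }
  cat("  cluster sizes:", paste(x$cluster_sizes, collapse = ", "), "\n")
  invisible(x)
}
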