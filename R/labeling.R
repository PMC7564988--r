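sq_dist_to <- function(X, C) {
  # n x k matrix of squared Euclidean distances
  D <- -2 * X %*% t(C)
  D <- sweep(D, 2, rowSums(C^2), "+")
  D <- sweep(D, 1, rowSums(X^2), "+")
  pmax(D, 0)
}

kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(X, 2, X[centers[1], ], "-")^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (sum(d2) <= 0) {
      # all remaining mass at chosen points: pick uniformly among the rest
      centers[j] <- sample.int(n, 1L)
    } else {
      centers[j] <- sample.int(n, 1L, prob = d2 / sum(d2))
    }
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[centers[j], ], "-")^2))
  }
  X[centers, , drop = FALSE]
}

lloyd_run <- function(X, k, max_iter, tol) {
  C <- kmeanspp_init(X, k)
  trace <- numeric()
  assign_vec <- NULL
  for (iter in seq_len(max_iter)) {
    D <- sq_dist_to(X, C)
    new_assign <- max.col(-D, ties.method = "first")
    # empty-cluster policy: re-seed at the point farthest from its centroid
    repeat {
      sizes <- tabulate(new_assign, nbins = k)
      if (all(sizes > 0L)) break
      j <- which(sizes == 0L)[1L]
      nearest <- D[cbind(seq_len(nrow(X)), new_assign)]
      far <- which.max(nearest)
      C[j, ] <- X[far, ]
      D <- sq_dist_to(X, C)
      new_assign <- max.col(-D, ties.method = "first")
    }
    trace <- c(trace, sum(D[cbind(seq_len(nrow(X)), new_assign)]))
    converged <- !is.null(assign_vec) && all(new_assign == assign_vec)
    assign_vec <- new_assign
    newC <- t(vapply(seq_len(k), function(j) {
      colMeans(X[assign_vec == j, , drop = FALSE])
    }, numeric(ncol(X))))
    shift <- max(rowSums((newC - C)^2))
    C <- newC
    if (converged || shift < tol) break
  }
  D <- sq_dist_to(X, C)
  assign_vec <- max.col(-D, ties.method = "first")
  J <- sum(D[cbind(seq_len(nrow(X)), assign_vec)])
  trace <- c(trace, J)
  list(centroids = C, assignment = assign_vec, objective = J,
       iterations = iter, trace = trace)
}

#' Fit k-means with k-means++ initialization
#'
#' Lloyd iterations from k-means++ seeds, minimizing the within-cluster
#' sum of squared Euclidean distances
#' `J = sum_j sum_{i in cluster j} || x_i - c_j ||^2`. The recorded
#' objective trace is non-increasing. Ten restarts are run by default and
#' the solution with the lowest objective is kept. An empty cluster
#' arising during iteration is re-seeded at the point farthest from its
#' current centroid. Equidistant points go to the lowest-index centroid.
#' Deterministic per `seed`.
#'
#' @param X Numeric feature matrix (rows = items); row names are carried
#'   into the assignment.
#' @param k Number of clusters, `1 <= k <= nrow(X)`.
#' @param seed Integer seed.
#' @param max_iter Maximum Lloyd iterations per restart.
#' @param tol Convergence threshold on the squared centroid shift.
#' @param nstart Number of k-means++ restarts.
#' @param normalize If TRUE, L2-normalize rows before clustering (off by
#'   default).
#' @return List with `model` (class `cluster_model`: `k`, `centroids`,
#'   `seed`, `objective`, `iterations_run`, `trace`) and `assignment`
#'   (named integer vector of 1-based cluster indices).
#' @export
kmeans_fit <- function(X, k, seed = 1L, max_iter = 100L, tol = 1e-8,
                       nstart = 10L, normalize = FALSE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!all(is.finite(X))) stop("feature matrix contains non-finite entries")
  if (k < 1L || k > nrow(X)) {
    stop("k must be between 1 and the number of items (", nrow(X), "), got ",
         k)
  }
  if (normalize) {
    nr <- sqrt(rowSums(X^2))
    nr[nr == 0] <- 1
    X <- X / nr
  }
  best <- NULL
  for (r in seq_len(nstart)) {
    run <- with_seed(derive_seed(seed, paste0("kmeans", r)),
                     lloyd_run(X, k, max_iter, tol))
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  assignment <- setNames(best$assignment, rownames(X))
  model <- structure(
    list(k = as.integer(k), centroids = best$centroids,
         seed = as.integer(seed), objective = best$objective,
         iterations_run = best$iterations, trace = best$trace),
    class = "cluster_model"
  )
  list(model = model, assignment = assignment)
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<k-means model> k =", x$k, " J =", format(x$objective),
      " (", x$iterations_run, "iterations )\n")
  invisible(x)
}

#' Majority-vote labels for clusters
#'
#' Assigns each cluster the most frequent gold label among its members
#' (exact ties broken by lexicographically smallest label) and reports the
#' resulting labeling accuracy: the fraction of items whose cluster label
#' matches their own gold label.
#'
#' @param assignment Cluster index per item (named or positional, matching
#'   `gold`).
#' @param gold Gold label per item.
#' @return Object of class `labeled_clusters`: list with `labels`
#'   (cluster -> label map), `histogram` (cluster x label counts) and
#'   `accuracy`.
#' @export
majority_labels <- function(assignment, gold) {
  if (length(assignment) != length(gold)) {
    stop("gold labels must cover all items: ", length(assignment),
         " items vs ", length(gold), " labels")
  }
  if (!is.null(names(assignment)) && !is.null(names(gold))) {
    gold <- gold[names(assignment)]
  }
  hist <- table(cluster = assignment, label = gold)
  labels <- apply(hist, 1L, function(row) {
    winners <- names(row)[row == max(row)]
    sort(winners)[1L]
  })
  predicted <- labels[as.character(assignment)]
  structure(
    list(labels = labels, histogram = hist,
         accuracy = mean(predicted == gold)),
    class = "labeled_clusters"
  )
}

#' @export
print.labeled_clusters <- function(x, ...) {
  cat("<labeled clusters> accuracy =", sprintf("%.3f", x$accuracy), "\n")
  for (cl in names(x$labels)) {
    cat("  cluster", cl, "->", x$labels[[cl]], "\n")
  }
  invisible(x)
}

entity_items <- function(corpus, parser = NULL) {
  rows <- list()
  for (i in seq_along(corpus$utterances)) {
    u <- corpus$utterances[[i]]
    cand <- extract_entity_candidates(u$text, parser = parser)
    if (!nrow(cand)) next
    for (ci in seq_len(nrow(cand))) {
      ov <- pmin(u$entities$end, cand$end[ci]) -
        pmax(u$entities$start, cand$start[ci])
      if (!length(ov) || max(ov) <= 0) next  # no gold span: drop candidate
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("u%05d.e%d", i, ci),
        phrase = cand$phrase[ci],
        gold = u$entities$slot[which.max(ov)],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) stop("no entity candidates matched a gold span")
  do.call(rbind, rows)
}

#' Cluster-and-label a corpus
#'
#' End-to-end labeling: featurize the corpus, cluster with k-means at the
#' gold k, and name each cluster by majority vote. For `target =
#' "intent"` the items are utterances, featurized either at word level
#' (mean-pooled word vectors over normalized tokens) or at sentence level
#' through `encoder`. For `target = "entity"` the items are noun-phrase
#' entity candidates matched to gold spans, always featurized at word
#' level, and the gold k is the number of distinct slot names among the
#' matched candidates.
#'
#' @param corpus A `corpus` with gold labels.
#' @param vectors A `vector_table` trained on (or applicable to) the
#'   corpus.
#' @param target `"intent"` or `"entity"`.
#' @param level `"word"` or `"sentence"` (intents only; entities always
#'   use word-level features).
#' @param k `"gold"` (default: the number of distinct gold labels) or an
#'   integer.
#' @param seed Integer seed for clustering.
#' @param encoder Optional `sentence_encoder` for `level = "sentence"`;
#'   defaults to [word_mean_encoder()] over `vectors`.
#' @param parser Optional parser for entity candidate extraction.
#' @param ... Passed to [kmeans_fit()].
#' @return List with `predictions` (data frame `id`, `cluster`,
#'   `predicted_label`, `gold_label`), `clusters`
#'   (a [majority_labels()] result), `model`, `features`.
#' @export
label_corpus <- function(corpus, vectors, target = c("intent", "entity"),
                         level = c("word", "sentence"), k = "gold",
                         seed = 1L, encoder = NULL, parser = NULL, ...) {
  target <- match.arg(target)
  level <- match.arg(level)
  if (target == "entity" && level == "sentence") {
    stop("labeling stage: entity clustering uses word-level features only")
  }
  if (target == "intent") {
    texts <- corpus_texts(corpus)
    ids <- sprintf("u%05d", seq_along(texts))
    gold <- setNames(corpus_intents(corpus), ids)
    X <- tryCatch({
      if (level == "word") {
        word_feature_matrix(texts, vectors, ids = ids)
      } else {
        enc <- if (is.null(encoder)) word_mean_encoder(vectors) else encoder
        m <- enc$encode(preprocess_sentence_level(texts))
        rownames(m) <- ids
        m <- m[stats::complete.cases(m), , drop = FALSE]
        m
      }
    }, error = function(e) {
      stop("featurize stage failed: ", conditionMessage(e), call. = FALSE)
    })
    gold <- gold[rownames(X)]
  } else {
    items <- entity_items(corpus, parser = parser)
    X <- tryCatch(
      word_feature_matrix(items$phrase, vectors, ids = items$id),
      error = function(e) {
        stop("featurize stage failed: ", conditionMessage(e), call. = FALSE)
      }
    )
    gold <- setNames(items$gold, items$id)[rownames(X)]
  }
  if (identical(k, "gold")) k <- length(unique(gold))
  fit <- tryCatch(
    kmeans_fit(X, k = k, seed = seed, ...),
    error = function(e) {
      stop("cluster stage failed: ", conditionMessage(e), call. = FALSE)
    }
  )
  lab <- majority_labels(fit$assignment, gold)
  predictions <- data.frame(
    id = names(fit$assignment),
    cluster = as.integer(fit$assignment),
    predicted_label = unname(lab$labels[as.character(fit$assignment)]),
    gold_label = unname(gold),
    stringsAsFactors = FALSE
  )
  list(predictions = predictions, clusters = lab, model = fit$model,
       features = X)
}
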