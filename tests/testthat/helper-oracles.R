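# Independent brute-force oracles, deliberately written as plain double
# loops over definitions so they share no code with the implementation.

oracle_pair_confusion <- function(pred, gold) {
  n <- length(pred)
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      same_cluster <- pred[i] == pred[j]
      same_class <- gold[i] == gold[j]
      if (same_cluster && same_class) tp <- tp + 1L
      else if (same_cluster && !same_class) fp <- fp + 1L
      else if (!same_cluster && !same_class) tn <- tn + 1L
      else fn <- fn + 1L
    }
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

oracle_silhouette <- function(X, a) {
  X <- as.matrix(X)
  n <- nrow(X)
  euc <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(a == a[i]), i)
    if (!length(own)) { s[i] <- 0; next }
    ai <- mean(vapply(own, function(j) euc(i, j), 0))
    bi <- Inf
    for (cl in setdiff(unique(a), a[i])) {
      members <- which(a == cl)
      bi <- min(bi, mean(vapply(members, function(j) euc(i, j), 0)))
    }
    s[i] <- (bi - ai) / max(ai, bi)
  }
  list(mean = mean(s), values = s)
}

# minimum within-cluster sum of squares over all 2-partitions (both
# clusters non-empty)
oracle_best_two_partition <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  wss <- function(rows) {
    if (!length(rows)) return(0)
    ctr <- colMeans(X[rows, , drop = FALSE])
    sum(sweep(X[rows, , drop = FALSE], 2, ctr, "-")^2)
  }
  best <- Inf
  for (mask in 1:(2^n - 2)) {
    g1 <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    g2 <- setdiff(seq_len(n), g1)
    best <- min(best, wss(g1) + wss(g2))
  }
  best
}

oracle_cosine_ranking <- function(query_vec, vectors) {
  sims <- vapply(rownames(vectors), function(tok) {
    v <- vectors[tok, ]
    sum(query_vec * v) / sqrt(sum(query_vec^2) * sum(v^2))
  }, 0)
  sims[order(-sims, names(sims))]
}
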