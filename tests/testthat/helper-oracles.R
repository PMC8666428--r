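# Independent brute-force oracles used to check the fast implementations.

# Greedy max-min selection with explicit loops over the full distance
# matrix: farthest pair first, then repeatedly the row whose minimum
# distance to the selected set is largest (lowest index on ties).
ks_oracle <- function(x, n_select) {
  d <- as.matrix(stats::dist(x))
  n <- nrow(d)
  if (n_select == n) return(seq_len(n))
  if (n_select == 1) return(which.max(colMeans(d)))
  best_pair <- c(1L, 2L); best_d <- -Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (d[i, j] > best_d) { best_d <- d[i, j]; best_pair <- c(i, j) }
    }
  }
  sel <- best_pair
  while (length(sel) < n_select) {
    cand <- setdiff(seq_len(n), sel)
    mind <- sapply(cand, function(r) min(d[r, sel]))
    sel <- c(sel, cand[which.max(mind)])
  }
  sel
}

# Pairwise-concordance AUROC by exhaustive enumeration.
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Youden cut-point by exhaustive threshold scan (predict positive at
# score >= t over all observed scores).
youden_oracle <- function(scores, labels) {
  ths <- sort(unique(scores))
  best <- -Inf; out <- NULL
  for (t in ths) {
    pred <- as.integer(scores >= t)
    sens <- sum(pred == 1 & labels == 1) / sum(labels == 1)
    spec <- sum(pred == 0 & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    if (j > best) { best <- j; out <- list(threshold = t, j = j) }
  }
  out
}

# Small planted cohort shared by several tests.
tiny_cohort <- function(n = 60, seed = 5, effects = default_effect_sizes()) {
  generate_cohort(synth_config(n_patients = n, seed = seed,
                               effect_sizes = effects))
}
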