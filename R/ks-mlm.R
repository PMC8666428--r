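#' Configuration for representative data splitting
#'
#' @param fractions Numeric triple (train, tune, validation) of positive
#'   fractions summing to 1. Default \code{c(0.70, 0.15, 0.15)}.
#' @param mutation_rate Fraction of Kennard-Stone-selected training rows
#'   exchanged with held-out rows in the Morais-Lima-Martin mutation step,
#'   in [0, 0.5). Default 0.10.
#' @param seed Integer seed driving the mutation step.
#' @param init Kennard-Stone seeding rule: \code{"farthest_pair"} (classic;
#'   start from the two mutually farthest samples) or \code{"max_mean"}
#'   (single seed with the largest mean distance to all others).
#' @param pool_method How the non-training remainder is carved into tuning
#'   and validation: \code{"ks"} (a second Kennard-Stone pass on the pool,
#'   so both held-out sets are representative) or \code{"random"}.
#' @return An object of class \code{split_config}.
#' @export
split_config <- function(fractions = c(0.70, 0.15, 0.15),
                         mutation_rate = 0.10,
                         seed = 1,
                         init = c("farthest_pair", "max_mean"),
                         pool_method = c("ks", "random")) {
  if (!is.numeric(fractions) || length(fractions) != 3 ||
      any(fractions <= 0) || abs(sum(fractions) - 1) > 1e-9) {
    stop_config("fractions",
                "must be three positive fractions summing to 1")
  }
  if (!is.numeric(mutation_rate) || length(mutation_rate) != 1 ||
      mutation_rate < 0 || mutation_rate >= 0.5) {
    stop_config("mutation_rate", "must lie in [0, 0.5)")
  }
  structure(
    list(fractions = fractions,
         mutation_rate = mutation_rate,
         seed = as.integer(seed),
         init = match.arg(init),
         pool_method = match.arg(pool_method)),
    class = "split_config"
  )
}

#' Standardize a feature matrix
#'
#' Centres each column to mean 0 and scales to unit standard deviation
#' (sample convention, denominator n - 1). Zero-variance columns are
#' centred but scaled by 1 and flagged.
#'
#' @param x Numeric matrix with at least 2 rows.
#' @param center,scale Optional pre-computed per-column centre/scale (e.g.
#'   from training rows) to apply instead of estimating from \code{x}.
#' @return List with \code{x} (standardized matrix), \code{center},
#'   \code{scale}, and \code{constant} (logical flag per column).
#' @examples
#' s <- standardize_features(cbind(a = c(1, 2, 3), b = c(5, 5, 5)))
#' colMeans(s$x)
#' s$constant
#' @export
standardize_features <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("matrix must have at least 2 rows")
  if (any(apply(x, 2, function(col) all(is.na(col))))) {
    stop("matrix has an all-missing column")
  }
  if (is.null(center)) center <- colMeans(x, na.rm = TRUE)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd, na.rm = TRUE)
  }
  constant <- !is.finite(scale) | scale == 0
  scale[constant] <- 1
  z <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  list(x = z, center = center, scale = scale, constant = constant)
}

# Full pairwise Euclidean distance matrix.
distance_matrix <- function(x) {
  as.matrix(stats::dist(as.matrix(x), method = "euclidean"))
}

#' Kennard-Stone representative sample selection
#'
#' Greedy max-min selection: after seeding, each pick maximizes the minimum
#' Euclidean distance to all already-selected samples, so the selection
#' covers the sample space uniformly. Deterministic; ties are broken by the
#' lowest row index. With the classic \code{"farthest_pair"} seeding the
#' first two picks are the two mutually farthest samples (for
#' \code{n_select = 1} the sample with the largest mean distance is used).
#'
#' @param x Numeric matrix (typically standardized features); ignored when
#'   \code{dist} is supplied.
#' @param n_select Number of samples to select, in [1, nrow].
#' @param dist Optional pre-computed full distance matrix.
#' @param init Seeding rule, see \code{\link{split_config}}.
#' @return Integer vector of selected row indices, in selection order.
#' @examples
#' kennard_stone(cbind(c(0, 1, 10)), 2)
#' @export
kennard_stone <- function(x = NULL, n_select, dist = NULL,
                          init = c("farthest_pair", "max_mean")) {
  init <- match.arg(init)
  if (is.null(dist)) {
    if (is.null(x)) stop("either x or dist must be supplied")
    dist <- distance_matrix(x)
  }
  n <- nrow(dist)
  if (!is.numeric(n_select) || length(n_select) != 1 ||
      n_select < 1 || n_select > n) {
    stop("n_select must lie in [1, ", n, "]")
  }
  n_select <- as.integer(n_select)
  if (n_select == n) return(seq_len(n))

  selected <- integer(0)
  if (init == "farthest_pair" && n_select >= 2) {
    # two mutually farthest samples; ties -> smallest (i, j)
    best <- which(dist == max(dist), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    selected <- as.integer(best[1, ])
  } else {
    selected <- as.integer(unname(which.max(colMeans(dist))))
  }
  # min distance from every row to the selected set
  mind <- unname(do.call(pmin, lapply(selected, function(i) dist[, i])))
  mind[selected] <- -Inf
  while (length(selected) < n_select) {
    nxt <- which.max(mind)  # which.max takes the first (lowest-index) tie
    selected <- c(selected, nxt)
    mind <- pmin(mind, unname(dist[, nxt]))
    mind[nxt] <- -Inf
  }
  as.integer(unname(selected))
}

#' Morais-Lima-Martin representative 70/15/15 split
#'
#' Kennard-Stone selects the training rows (round(train fraction x n));
#' then m = round(mutation rate x train size) training rows, chosen
#' uniformly at random, are swapped one-for-one with m uniformly chosen
#' held-out rows, injecting randomness while preserving the set sizes.
#' The remaining pool is carved into tuning and validation (by a second
#' Kennard-Stone pass on the pool by default, so both held-out sets are
#' representative too). Fully reproducible from the seed.
#'
#' @param x Numeric feature matrix (rows = samples); standardized
#'   internally for the distance computation.
#' @param config A \code{\link{split_config}}.
#' @param dist Optional pre-computed distance matrix on standardized
#'   features (saves recomputation across repeats).
#' @return List of class \code{split_assignment} with integer index sets
#'   \code{train_idx}, \code{tune_idx}, \code{valid_idx} (disjoint,
#'   exhaustive) and the sizes and seed used.
#' @examples
#' x <- matrix(rnorm(200 * 3), 200)
#' sp <- mlm_split(x, split_config(seed = 1))
#' lengths(sp[c("train_idx", "tune_idx", "valid_idx")])
#' @export
mlm_split <- function(x, config = split_config(), dist = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 10) stop("mlm_split requires at least 10 rows")
  f <- config$fractions
  n_train <- round(f[1] * n)
  n_tune <- round(f[2] * n)
  n_valid <- n - n_train - n_tune
  if (n_train < 1 || n_tune < 1 || n_valid < 1) {
    stop("fractions are infeasible for n = ", n)
  }
  if (is.null(dist)) dist <- distance_matrix(standardize_features(x)$x)

  ks_train <- kennard_stone(dist = dist, n_select = n_train,
                            init = config$init)
  train <- ks_train
  pool <- setdiff(seq_len(n), train)

  m <- round(config$mutation_rate * n_train)
  with_local_seed(config$seed, {
    if (m > 0) {
      out_rows <- sample(train, m)
      in_rows <- sample(pool, m)
      train <- c(setdiff(train, out_rows), in_rows)
      pool <- setdiff(seq_len(n), train)
    }
    if (config$pool_method == "ks") {
      tune_local <- kennard_stone(dist = dist[pool, pool, drop = FALSE],
                                  n_select = n_tune, init = config$init)
      tune <- pool[tune_local]
    } else {
      tune <- sample(pool, n_tune)
    }
  })
  valid <- setdiff(pool, tune)

  structure(
    list(train_idx = sort(train), tune_idx = sort(tune),
         valid_idx = sort(valid),
         n = n, n_mutated = m, seed = config$seed,
         ks_train = sort(ks_train)),
    class = "split_assignment"
  )
}

#' @export
print.split_assignment <- function(x, ...) {
  cat(sprintf(
    "MLM split of %d rows: train %d / tune %d / valid %d (%d mutated, seed %d)\n",
    x$n, length(x$train_idx), length(x$tune_idx), length(x$valid_idx),
    x$n_mutated, x$seed))
  invisible(x)
}
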