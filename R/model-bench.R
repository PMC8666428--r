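#' Default hyperparameter search grids
#'
#' One data frame per model kind, rows ordered from least to most complex
#' so that tuning-set ties resolve toward the simpler configuration. The
#' ridge/lasso penalty spans a 7-point log grid on [1e-3, 1e3]; gradient
#' boosting searches trees x depth x learning rate; the random forest
#' searches trees x depth (0 = unlimited); the two-layer (one hidden
#' layer) neural network searches hidden units x weight decay, the decay
#' playing the regularization role of early stopping.
#'
#' @return Named list of data frames (logistic regression has no grid).
#' @export
default_grids <- function() {
  gb <- expand.grid(eta = c(0.05, 0.1), max_depth = c(2, 3),
                    nrounds = c(50, 200))
  gb <- gb[order(gb$nrounds, gb$max_depth, gb$eta), , drop = FALSE]
  rf <- expand.grid(num_trees = c(200, 500), max_depth = c(3, 0))
  rf <- rf[order(rf$max_depth == 0, rf$num_trees), , drop = FALSE]
  nn <- expand.grid(decay = c(0.1, 0.01), size = c(8, 16, 32))
  nn <- nn[order(nn$size, -nn$decay), , drop = FALSE]
  list(
    logistic = data.frame(),
    ridge = data.frame(lambda = 10^seq(3, -3)),  # largest penalty first
    lasso = data.frame(lambda = 10^seq(3, -3)),
    gboost = gb,
    rforest = rf,
    nn2 = nn
  )
}

model_kind_names <- function() {
  c("logistic", "ridge", "lasso", "gboost", "rforest", "nn2")
}

# Model kinds / feature sets that skip univariate feature selection.
selection_free_kinds <- function() c("lasso", "nn2")
selection_free_sets <- function() c("tumor_clinical", "clinical")

#' Benchmark configuration
#'
#' @param n_repeats Number of split/fit/evaluate repeats (>= 2). The full
#'   study profile uses 1000; the desk default is 100.
#' @param model_kinds Subset of \code{"logistic"}, \code{"ridge"},
#'   \code{"lasso"}, \code{"gboost"}, \code{"rforest"}, \code{"nn2"}.
#'   Desk default: ridge and logistic regression.
#' @param feature_sets Subset of \code{feature_set_names()}.
#' @param selection_p P-value threshold for univariate feature selection
#'   (Mann-Whitney U for continuous, chi-squared for categorical features,
#'   training rows only), in (0, 1). Default 0.1.
#' @param master_seed Integer master seed; per-repeat seeds are derived
#'   from it by a counter scheme, so results are reproducible end to end.
#' @param grids Hyperparameter grids, see \code{\link{default_grids}}.
#' @param split A \code{\link{split_config}} template (its seed is
#'   replaced per repeat).
#' @param permute_labels Null-calibration mode: when TRUE every repeat
#'   randomly re-permutes the response labels (seeded), the standard
#'   permutation null in which labels are independent of all features;
#'   useful for verifying that the harness is unbiased. Default FALSE.
#' @return Object of class \code{bench_config}.
#' @export
bench_config <- function(n_repeats = 100,
                         model_kinds = c("logistic", "ridge"),
                         feature_sets = feature_set_names(),
                         selection_p = 0.1,
                         master_seed = 1,
                         grids = default_grids(),
                         split = split_config(),
                         permute_labels = FALSE) {
  if (!is.numeric(n_repeats) || length(n_repeats) != 1 || n_repeats < 2) {
    stop_config("n_repeats", "must be an integer >= 2")
  }
  model_kinds <- match.arg(model_kinds, model_kind_names(),
                           several.ok = TRUE)
  feature_sets <- match.arg(feature_sets, feature_set_names(),
                            several.ok = TRUE)
  if (!is.numeric(selection_p) || selection_p <= 0 || selection_p >= 1) {
    stop_config("selection_p", "must lie in (0, 1)")
  }
  structure(
    list(n_repeats = as.integer(n_repeats), model_kinds = model_kinds,
         feature_sets = feature_sets, selection_p = selection_p,
         master_seed = as.integer(master_seed), grids = grids,
         split = split, permute_labels = isTRUE(permute_labels)),
    class = "bench_config"
  )
}

#' Univariate feature selection on training rows
#'
#' Continuous features are tested by the Mann-Whitney U test between the
#' label groups, categorical features by the chi-squared test on the
#' label-by-category contingency table; features with P below the
#' threshold are retained in their original order. Constant features get
#' P = 1 and are dropped.
#'
#' @param x Training feature matrix (named columns).
#' @param y 0/1 labels for the training rows.
#' @param threshold Retention threshold on P.
#' @param types Optional named character vector (\code{"continuous"} /
#'   \code{"categorical"}) per column; looked up from the cohort schema
#'   when omitted.
#' @return Character vector of retained feature names (possibly empty).
#' @export
select_features <- function(x, y, threshold = 0.1, types = NULL) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (min(table(factor(y, levels = 0:1))) < 10) {
    warning("fewer than 10 training rows in a class; ",
            "selection P-values are unstable")
  }
  if (is.null(types)) types <- feature_types(colnames(x))
  p <- vapply(colnames(x), function(f) {
    v <- x[, f]
    tryCatch({
      if (length(unique(v[!is.na(v)])) < 2) return(1)
      if (types[[f]] == "categorical") {
        chi_squared(table(y, v))$p
      } else {
        mann_whitney_u(v[y == 1], v[y == 0])$p
      }
    }, error = function(e) 1)
  }, numeric(1))
  colnames(x)[p < threshold]
}

# glmnet needs >= 2 columns; pad with an all-zero dummy when necessary.
pad_matrix <- function(z) {
  if (ncol(z) >= 2) return(z)
  cbind(z, ".pad" = 0)
}

#' Fit one model with tuning-set hyperparameter search
#'
#' Features are standardized with the training-set centre/scale; the grid
#' is searched by tuning-set AUROC with ties resolved toward the simpler
#' configuration (earlier grid row). For the linear kinds the coefficients
#' are back-transformed to raw feature units (beta_raw = beta_std / scale)
#' and stored. The fitted object predicts a continuous risk score for the
#' poor-responder class.
#'
#' @param kind One of \code{model_kind_names()}.
#' @param x_train,y_train,x_tune,y_tune Training and tuning features
#'   (matrices with named columns) and 0/1 labels.
#' @param grid Hyperparameter grid (data frame); defaults to
#'   \code{default_grids()[[kind]]}.
#' @param seed Integer seed for stochastic learners.
#' @return Object of class \code{rps_model} with elements \code{kind},
#'   \code{features}, \code{center}, \code{scale}, \code{hyper},
#'   \code{coef_std}, \code{coef_raw} (linear kinds only) and \code{fit}.
#' @export
fit_model <- function(kind, x_train, y_train, x_tune, y_tune,
                      grid = NULL, seed = 1) {
  kind <- match.arg(kind, model_kind_names())
  if (is.null(grid)) grid <- default_grids()[[kind]]
  x_train <- as.matrix(x_train); x_tune <- as.matrix(x_tune)
  y_train <- as.integer(y_train); y_tune <- as.integer(y_tune)
  if (length(unique(y_train)) < 2) {
    stop("degenerate training labels: only one class present")
  }
  std <- standardize_features(x_train)
  zt <- std$x
  ztu <- standardize_features(x_tune, center = std$center,
                              scale = std$scale)$x

  coef_std <- NULL
  if (kind == "logistic") {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(`(Intercept)` = 1, zt), y_train,
                     family = stats::binomial()))
    coef_std <- fit$coefficients[-1]
    coef_std[is.na(coef_std)] <- 0
    hyper <- data.frame()
    model <- list(beta = coef_std)
  } else if (kind %in% c("ridge", "lasso")) {
    alpha <- if (kind == "ridge") 0 else 1
    gfit <- glmnet::glmnet(pad_matrix(zt), y_train, family = "binomial",
                           alpha = alpha, lambda = grid$lambda,
                           standardize = FALSE)
    pred_tu <- stats::predict(gfit, pad_matrix(ztu), s = grid$lambda,
                              type = "link")
    tune_auc <- apply(pred_tu, 2, auroc, labels = y_tune)
    best <- which(tune_auc == max(tune_auc))[1]
    hyper <- grid[best, , drop = FALSE]
    cf <- as.numeric(stats::coef(gfit, s = grid$lambda[best]))[-1]
    coef_std <- stats::setNames(cf[seq_len(ncol(zt))], colnames(zt))
    model <- list(beta = coef_std)
  } else {
    ## non-linear kinds: explicit grid search
    fits <- vector("list", nrow(grid))
    tune_auc <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      fits[[g]] <- fit_nonlinear(kind, zt, y_train, grid[g, , drop = FALSE],
                                 seed)
      tune_auc[g] <- auroc(predict_nonlinear(kind, fits[[g]], ztu), y_tune)
    }
    best <- which(tune_auc == max(tune_auc))[1]
    hyper <- grid[best, , drop = FALSE]
    model <- fits[[best]]
  }

  out <- list(kind = kind, features = colnames(x_train),
              center = std$center, scale = std$scale,
              hyper = hyper, fit = model, coef_std = coef_std)
  if (!is.null(coef_std)) out$coef_raw <- coef_std / std$scale
  class(out) <- "rps_model"
  out
}

fit_nonlinear <- function(kind, z, y, pars, seed) {
  set.seed(seed)
  if (kind == "gboost") {
    dtr <- xgboost::xgb.DMatrix(z, label = y)
    xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = pars$max_depth, eta = pars$eta,
                    nthread = 1, seed = seed),
      data = dtr, nrounds = pars$nrounds, verbose = 0)
  } else if (kind == "rforest") {
    ranger::ranger(x = as.data.frame(z), y = factor(y, levels = 0:1),
                   num.trees = pars$num_trees, max.depth = pars$max_depth,
                   probability = TRUE, seed = seed, num.threads = 1)
  } else {  # nn2
    nnet::nnet(x = z, y = y, size = pars$size, decay = pars$decay,
               maxit = 300, entropy = TRUE, trace = FALSE, MaxNWts = 5000)
  }
}

predict_nonlinear <- function(kind, fit, z) {
  if (kind == "gboost") {
    stats::predict(fit, xgboost::xgb.DMatrix(z))
  } else if (kind == "rforest") {
    stats::predict(fit, data = as.data.frame(z),
                   num.threads = 1)$predictions[, "1"]
  } else {
    as.numeric(stats::predict(fit, z))
  }
}

#' Predict continuous risk scores from a fitted benchmark model
#'
#' @param object An \code{rps_model}.
#' @param newx Feature matrix on raw units with the model's feature
#'   columns.
#' @param ... Unused.
#' @return Numeric risk score for the poor-responder class (linear
#'   predictor for the linear kinds, probability for the others).
#' @export
predict.rps_model <- function(object, newx, ...) {
  newx <- as.matrix(newx)[, object$features, drop = FALSE]
  z <- standardize_features(rbind(newx, newx),  # >=2 rows for the helper
                            center = object$center,
                            scale = object$scale)$x
  z <- z[seq_len(nrow(newx)), , drop = FALSE]
  if (!is.null(object$coef_std)) {
    as.numeric(z %*% object$coef_std)
  } else {
    predict_nonlinear(object$kind, object$fit, z)
  }
}

# Median imputation: medians from the training rows only.
impute_by_train <- function(x, train_idx) {
  if (!anyNA(x)) return(x)
  med <- apply(x[train_idx, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(x))) {
    nas <- is.na(x[, j])
    if (any(nas)) x[nas, j] <- med[j]
  }
  x
}

#' Run the repeated splitting / fitting / evaluation benchmark
#'
#' For each repeat a fresh seed is derived from the master seed, an MLM
#' split is drawn on the full standardized feature space, and every
#' requested (feature set, model kind) cell is run through selection,
#' tuning-set hyperparameter search, and evaluation (AUROC/AUPRC on the
#' training, tuning and validation rows; Youden cut-point on validation).
#' Univariate selection is computed once per (repeat, feature set) and
#' shared by the kinds that use it; lasso and the neural network skip
#' selection, as do the two clinical-only feature sets. Failed repeats are
#' recorded and excluded; more than 10\% failures aborts.
#'
#' @param cohort Cohort data frame with both responder classes.
#' @param config A \code{\link{bench_config}}.
#' @return Object of class \code{benchmark_result}: \code{table} (the
#'   mean +/- sd AUROC/AUPRC per model, feature set and split),
#'   \code{results} (per-repeat \code{ModelRunResult} records),
#'   \code{failures}, and the config.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(synth_config(n_patients = 120, seed = 3))
#' bench <- run_benchmark(cohort, bench_config(
#'   n_repeats = 5, model_kinds = "ridge", feature_sets = "clinical_early"))
#' bench$table
#' }
#' @export
run_benchmark <- function(cohort, config = bench_config()) {
  y <- derive_label(cohort$trg)
  if (length(unique(y)) < 2) stop("cohort must contain both classes")
  x_full <- assemble_features(cohort, "clinical_pre_early")
  ## distance matrix for splitting, computed once; any missing cells are
  ## median-imputed for the distance computation only
  x_dist <- impute_by_train(x_full, seq_len(nrow(x_full)))
  dmat <- distance_matrix(standardize_features(x_dist)$x)

  set_members <- lapply(stats::setNames(nm = config$feature_sets),
                        feature_set_members)
  types_all <- feature_types(colnames(x_full))

  results <- vector("list", config$n_repeats)
  failures <- list()
  for (i in seq_len(config$n_repeats)) {
    seed_i <- derive_seed(config$master_seed, i)
    rep_res <- tryCatch({
      sp_cfg <- config$split
      sp_cfg$seed <- seed_i
      sp <- mlm_split(x_full, sp_cfg, dist = dmat)
      y_i <- y
      if (config$permute_labels) {
        with_local_seed(derive_seed(seed_i, 999),
                        y_i <- y[sample(length(y))])
      }
      run_one_repeat(i, x_full, y_i, sp, config, set_members, types_all,
                     seed_i)
    }, error = function(e) e)
    if (inherits(rep_res, "error")) {
      failures[[length(failures) + 1]] <-
        list(repeat_id = i, message = conditionMessage(rep_res))
    } else {
      results[[i]] <- rep_res
    }
  }
  if (length(failures) > 0.1 * config$n_repeats) {
    stop(sprintf("benchmark aborted: %d of %d repeats failed (first: %s)",
                 length(failures), config$n_repeats,
                 failures[[1]]$message))
  }
  results <- do.call(c, results[!vapply(results, is.null, TRUE)])
  structure(
    list(table = aggregate_benchmark(results),
         results = results, failures = failures, config = config),
    class = "benchmark_result"
  )
}

run_one_repeat <- function(repeat_id, x_full, y, sp, config, set_members,
                           types_all, seed_i) {
  out <- list()
  for (set_name in names(set_members)) {
    members <- set_members[[set_name]]
    xs <- impute_by_train(x_full[, members, drop = FALSE], sp$train_idx)
    use_selection <- !(set_name %in% selection_free_sets())
    sel <- NULL
    if (use_selection) {
      sel <- select_features_quiet(xs[sp$train_idx, , drop = FALSE],
                                   y[sp$train_idx], config$selection_p,
                                   types_all[members])
    }
    for (kind in config$model_kinds) {
      feats <- members
      if (use_selection && !(kind %in% selection_free_kinds())) {
        feats <- if (length(sel)) sel else members  # fallback: all features
      }
      fit <- fit_model(kind,
                       xs[sp$train_idx, feats, drop = FALSE],
                       y[sp$train_idx],
                       xs[sp$tune_idx, feats, drop = FALSE],
                       y[sp$tune_idx],
                       grid = config$grids[[kind]], seed = seed_i)
      metrics <- lapply(
        list(train = sp$train_idx, tune = sp$tune_idx,
             valid = sp$valid_idx),
        function(idx) {
          s <- stats::predict(fit, xs[idx, , drop = FALSE])
          c(auroc = auroc(s, y[idx]), auprc = auprc(s, y[idx]))
        })
      cut <- youden_cutpoint(
        stats::predict(fit, xs[sp$valid_idx, , drop = FALSE]),
        y[sp$valid_idx])
      res <- list(repeat_id = repeat_id, model_kind = kind,
                  feature_set = set_name, selected_features = feats,
                  metrics = metrics, cutpoint = cut)
      if (!is.null(fit$coef_raw)) {
        full <- stats::setNames(numeric(length(members)), members)
        full[feats] <- fit$coef_raw[feats]
        res$coef_raw <- full
        full_std <- stats::setNames(numeric(length(members)), members)
        full_std[feats] <- fit$coef_std[feats]
        res$coef_std <- full_std
      }
      out[[length(out) + 1]] <- structure(res, class = "model_run_result")
    }
  }
  out
}

select_features_quiet <- function(...) {
  suppressWarnings(select_features(...))
}

aggregate_benchmark <- function(results) {
  keys <- unique(data.frame(
    model_kind = vapply(results, `[[`, "", "model_kind"),
    feature_set = vapply(results, `[[`, "", "feature_set"),
    stringsAsFactors = FALSE))
  rows <- list()
  for (r in seq_len(nrow(keys))) {
    sub <- Filter(function(x) x$model_kind == keys$model_kind[r] &&
                    x$feature_set == keys$feature_set[r], results)
    for (split in c("train", "tune", "valid")) {
      au <- vapply(sub, function(x) x$metrics[[split]][["auroc"]], 0)
      ap <- vapply(sub, function(x) x$metrics[[split]][["auprc"]], 0)
      rows[[length(rows) + 1]] <- data.frame(
        model_kind = keys$model_kind[r], feature_set = keys$feature_set[r],
        split = split, n_repeats = length(sub),
        auroc_mean = mean(au), auroc_sd = stats::sd(au),
        auprc_mean = mean(ap), auprc_sd = stats::sd(ap),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("Benchmark: %d repeats, %d model kind(s) x %d feature set(s)",
              x$config$n_repeats, length(x$config$model_kinds),
              length(x$config$feature_sets)), "\n")
  if (length(x$failures)) {
    cat(sprintf("  %d failed repeat(s) excluded\n", length(x$failures)))
  }
  tab <- x$table[x$table$split == "valid", ]
  tab <- tab[order(-tab$auroc_mean), ]
  cat("Validation-set performance (mean +/- sd over repeats):\n")
  for (r in seq_len(nrow(tab))) {
    cat(sprintf("  %-8s %-18s AUROC %.4f +/- %.4f  AUPRC %.4f +/- %.4f\n",
                tab$model_kind[r], tab$feature_set[r],
                tab$auroc_mean[r], tab$auroc_sd[r],
                tab$auprc_mean[r], tab$auprc_sd[r]))
  }
  invisible(x)
}
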