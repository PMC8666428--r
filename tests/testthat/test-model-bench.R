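make_toy <- function(n = 120, seed = 8, shift = 1.5) {
  set.seed(seed)
  y <- rep_len(0:1, n)
  x <- cbind(signal = rnorm(n) + shift * y,
             noise1 = rnorm(n), noise2 = rnorm(n),
             grade = sample(1:3, n, replace = TRUE))
  list(x = x, y = y)
}

test_that("univariate selection keeps shifted features and drops constants", {
  toy <- make_toy(180, seed = 20)
  types <- c(signal = "continuous", noise1 = "continuous",
             noise2 = "continuous", grade = "categorical",
             flat = "continuous")
  x <- cbind(toy$x, flat = 1)
  sel <- select_features(x, toy$y, 0.1, types)
  expect_true("signal" %in% sel)
  expect_false("flat" %in% sel)
  # original column order preserved
  expect_identical(sel, colnames(x)[colnames(x) %in% sel])
  # a permissive threshold keeps every non-degenerate feature
  sel_all <- select_features(toy$x, toy$y, 0.999999, types[1:4])
  expect_identical(sel_all, colnames(toy$x))
  # planted shift recovered across seeds
  hits <- 0
  for (s in 1:20) {
    toy_s <- make_toy(180, seed = 100 + s)
    hits <- hits + ("signal" %in% select_features(toy_s$x, toy_s$y, 0.1,
                                                  types[1:4]))
  }
  expect_gte(hits, 20 * 0.99)
})

test_that("logistic regression separates separable toy data", {
  set.seed(21)
  y <- rep(0:1, each = 20)
  x <- cbind(f = y * 4 + runif(40), g = rnorm(40))
  fit <- fit_model("logistic", x, y, x, y)
  expect_equal(auroc(predict(fit, x), y), 1.0)
})

test_that("tuning-set AUROC picks the better ridge penalty", {
  toy <- make_toy(200, seed = 22, shift = 2)
  idx <- seq_len(100)
  grid <- data.frame(lambda = c(1e6, 0.1))  # absurd vs sensible penalty
  fit <- fit_model("ridge", toy$x[idx, ], toy$y[idx],
                   toy$x[-idx, ], toy$y[-idx], grid = grid)
  expect_equal(fit$hyper$lambda, 0.1)
})

test_that("raw-scale coefficients transform correctly under unit changes", {
  toy <- make_toy(200, seed = 23)
  idx <- seq_len(100)
  fit1 <- fit_model("ridge", toy$x[idx, ], toy$y[idx],
                    toy$x[-idx, ], toy$y[-idx])
  x10 <- toy$x
  x10[, "signal"] <- x10[, "signal"] * 10
  fit2 <- fit_model("ridge", x10[idx, ], toy$y[idx],
                    x10[-idx, ], toy$y[-idx])
  expect_equal(fit2$coef_raw[["signal"]], fit1$coef_raw[["signal"]] / 10,
               tolerance = 1e-6)
  # the risk score itself is invariant to the unit change
  expect_equal(predict(fit2, x10[-idx, ]), predict(fit1, toy$x[-idx, ]),
               tolerance = 1e-6)
})

test_that("standardization parameters come from the training rows only", {
  toy <- make_toy(100, seed = 24)
  idx <- seq_len(60)
  fit <- fit_model("ridge", toy$x[idx, ], toy$y[idx],
                   toy$x[-idx, ], toy$y[-idx])
  expect_equal(fit$center, colMeans(toy$x[idx, ]))
  expect_equal(fit$scale, apply(toy$x[idx, ], 2, sd))
})

test_that("degenerate single-class training labels are refused", {
  toy <- make_toy(40, seed = 25)
  expect_error(fit_model("ridge", toy$x, rep(1, 40), toy$x, toy$y),
               "one class")
})

test_that("all six model kinds fit and produce valid metrics", {
  co <- generate_cohort(synth_config(n_patients = 150, seed = 30))
  bc <- bench_config(n_repeats = 2, model_kinds = model_kinds <-
                       c("logistic", "ridge", "lasso", "gboost",
                         "rforest", "nn2"),
                     feature_sets = "clinical_early", master_seed = 7)
  b <- run_benchmark(co, bc)
  expect_equal(nrow(b$table), 6 * 3)
  expect_true(all(b$table$auroc_mean >= 0 & b$table$auroc_mean <= 1))
  expect_true(all(b$table$auprc_mean >= 0 & b$table$auprc_mean <= 1))
  # lasso skips univariate selection: it sees the full feature set
  lasso_runs <- Filter(function(r) r$model_kind == "lasso", b$results)
  expect_identical(lasso_runs[[1]]$selected_features,
                   feature_set_members("clinical_early"))
  # linear kinds carry coefficients, tree/NN kinds do not
  ridge_runs <- Filter(function(r) r$model_kind == "ridge", b$results)
  expect_length(ridge_runs[[1]]$coef_raw, 24)
  rf_runs <- Filter(function(r) r$model_kind == "rforest", b$results)
  expect_null(rf_runs[[1]]$coef_raw)
})

test_that("the benchmark is deterministic in its master seed", {
  co <- generate_cohort(synth_config(n_patients = 100, seed = 31))
  bc <- bench_config(n_repeats = 3, model_kinds = "ridge",
                     feature_sets = c("tumor_clinical", "clinical_early"),
                     master_seed = 99)
  a <- run_benchmark(co, bc)
  b <- run_benchmark(co, bc)
  expect_identical(a$table, b$table)
  c <- run_benchmark(co, bench_config(n_repeats = 3, model_kinds = "ridge",
                                      feature_sets = "clinical_early",
                                      master_seed = 100))
  expect_false(isTRUE(all.equal(
    a$table[a$table$feature_set == "clinical_early", ]$auroc_mean,
    c$table$auroc_mean)))
})

test_that("tree ensembles overfit null data while validation stays near chance", {
  co <- generate_cohort(synth_config(n_patients = 150, seed = 32,
                                     effect_sizes = numeric(0)))
  b <- run_benchmark(co, bench_config(
    n_repeats = 8, model_kinds = c("gboost", "rforest"),
    feature_sets = "clinical_early", master_seed = 5,
    permute_labels = TRUE))
  tr <- b$table[b$table$split == "train", ]
  va <- b$table[b$table$split == "valid", ]
  expect_true(all(tr$auroc_mean > 0.85))
  expect_true(all(va$auroc_mean > 0.3 & va$auroc_mean < 0.7))
})
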