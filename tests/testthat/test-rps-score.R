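# Minimal hand-built per-repeat records for importance arithmetic.
fake_run <- function(coef_raw, coef_std = coef_raw, selected = NULL,
                     kind = "ridge", set = "clinical_early") {
  structure(
    list(repeat_id = 1, model_kind = kind, feature_set = set,
         selected_features = if (is.null(selected)) names(coef_raw)
                             else selected,
         coef_raw = coef_raw, coef_std = coef_std,
         metrics = list(), cutpoint = list()),
    class = "model_run_result")
}

test_that("generalized importance is the zero-imputed across-repeat mean", {
  f <- c(a = 1.0, b = 0.5)
  runs <- list(fake_run(c(a = 1.0, b = 0.5)),
               fake_run(c(a = 3.0, b = -0.5)))
  imp <- generalized_importance(runs)
  expect_equal(imp$beta[imp$feature == "a"], 2.0)
  expect_equal(imp$selection_count[imp$feature == "a"], 2)
  expect_equal(imp$sign_consistency[imp$feature == "a"], 1.0)
  expect_equal(imp$sign_consistency[imp$feature == "b"], 0.5)

  # selected once with coefficient 4 -> zero-imputed mean 2, count 1
  runs2 <- list(fake_run(c(a = 4.0, b = 1.0), selected = c("a", "b")),
                fake_run(c(a = 0.0, b = 1.0), selected = "b"))
  imp2 <- generalized_importance(runs2)
  expect_equal(imp2$beta[imp2$feature == "a"], 2.0)
  expect_equal(imp2$selection_count[imp2$feature == "a"], 1)
})

test_that("importance is linear in the per-repeat coefficients", {
  set.seed(40)
  cf <- replicate(5, stats::setNames(rnorm(3), c("a", "b", "c")),
                  simplify = FALSE)
  runs <- lapply(cf, fake_run)
  runs2 <- lapply(cf, function(v) fake_run(2 * v))
  i1 <- generalized_importance(runs)
  i2 <- generalized_importance(runs2)
  expect_equal(i2$beta[match(i1$feature, i2$feature)], 2 * i1$beta)
  expect_identical(i1$feature, i2$feature)  # ranking unchanged
})

test_that("importance ranks by standardized magnitude, ties by name", {
  runs <- list(
    fake_run(c(big_raw = 100, big_std = 0.01),
             coef_std = c(big_raw = 0.1, big_std = 0.5)),
    fake_run(c(big_raw = 100, big_std = 0.01),
             coef_std = c(big_raw = 0.1, big_std = 0.5)))
  imp <- generalized_importance(runs)
  expect_identical(imp$feature[1], "big_std")
})

test_that("importance refuses non-linear kinds and tiny N", {
  runs <- list(fake_run(c(a = 1)), fake_run(c(a = 1)))
  expect_error(generalized_importance(runs, model_kind = "rforest"))
  nl <- lapply(runs, function(r) { r$coef_raw <- NULL; r })
  expect_error(generalized_importance(nl), "coefficient")
  expect_error(generalized_importance(runs[1]), "2 repeats")
})

test_that("the significance curve finds a single dominant feature", {
  set.seed(41)
  n <- 300
  y <- rbinom(n, 1, 0.5)
  x <- cbind(strong = y * 3 + rnorm(n),
             dud1 = rnorm(n), dud2 = rnorm(n))
  imp <- data.frame(feature = c("strong", "dud1", "dud2"),
                    beta = c(1.0, 0.6, 0.5))
  sel <- select_score_size(imp, x, y, k_max = 3)
  expect_equal(sel$k_o, 1)
  expect_equal(nrow(sel$curve), 3)
  expect_identical(sel$curve$feature, imp$feature)
})

test_that("null features leave the significance curve flat and insignificant", {
  hits <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    n <- 272
    y <- rbinom(n, 1, 0.45)
    x <- matrix(rnorm(n * 10), n,
                dimnames = list(NULL, paste0("f", 1:10)))
    b <- rnorm(10)
    b <- b[order(-abs(b))]  # importance tables are ranked by magnitude
    imp <- data.frame(feature = paste0("f", 1:10), beta = b)
    sel <- select_score_size(imp, x, y, k_max = 10)
    if (min(sel$curve$p) > 0.01) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("the published score reproduces its printed weights exactly", {
  rps <- published_rps()
  zero <- data.frame(early_monocyte = 0, distance_anal_verge = 0,
                     early_plt = 0, early_neutrophil = 0,
                     early_eosinophil = 0)
  expect_equal(evaluate_score(rps, zero), 0)
  unit <- function(f) { u <- zero; u[[f]] <- 1; u }
  expect_equal(evaluate_score(rps, unit("early_monocyte")), 0.000559)
  expect_equal(evaluate_score(rps, unit("distance_anal_verge")), 0.026172)
  expect_equal(evaluate_score(rps, unit("early_plt")), 0.001021)
  expect_equal(evaluate_score(rps, unit("early_neutrophil")), 0.000049)
  expect_equal(evaluate_score(rps, unit("early_eosinophil")), -0.000433)
})

test_that("score evaluation is an exact linear form", {
  rps <- published_rps()
  pt <- data.frame(early_monocyte = 300, distance_anal_verge = 5,
                   early_plt = 200, early_neutrophil = 2500,
                   early_eosinophil = 100)
  expect_equal(evaluate_score(rps, pt), 0.58196)
  expect_equal(evaluate_score(rps, pt * 3), 3 * evaluate_score(rps, pt))
  expect_error(evaluate_score(rps, pt[, -1]), "distance_anal_verge|missing")
  pt_na <- pt; pt_na$early_plt <- NA
  expect_error(evaluate_score(rps, pt_na), "early_plt")
})

test_that("typical reference-range patients score inside the quartile envelope", {
  co <- generate_cohort(synth_config(n_patients = 2000, seed = 44))
  sc <- evaluate_score(published_rps(), co)
  expect_gt(mean(sc > 0.3 & sc < 1.0), 0.5)
  expect_gt(min(sc), 0)
})

test_that("sign-consistency audit reports fractions and undefined features", {
  runs <- list(
    fake_run(c(a = 1, b = 2), selected = c("a", "b")),
    fake_run(c(a = -1, b = 1), selected = c("a", "b")),
    fake_run(c(a = 1, b = 3), selected = c("a", "b")),
    fake_run(c(a = -1, b = 1), selected = c("a", "b")))
  aud <- sign_consistency_audit(runs, c("a", "b"))
  expect_equal(aud$sign_consistency[aud$feature == "b"], 1.0)
  expect_equal(aud$sign_consistency[aud$feature == "a"], 0.5)
  never <- list(fake_run(c(a = 0, b = 1), selected = "b"),
                fake_run(c(a = 0, b = 1), selected = "b"))
  aud2 <- sign_consistency_audit(never, "a")
  expect_true(is.na(aud2$sign_consistency))
  expect_error(sign_consistency_audit(runs, "zz"), "zz")
})

test_that("predictor comparison ranks the composite score above single features", {
  co <- generate_cohort(synth_config(n_patients = 2000, seed = 45))
  cmp <- compare_predictors(co, published_rps())
  expect_identical(cmp$predictor[1], "RPS")
  expect_true(all(diff(cmp$auroc) <= 0))           # sorted
  expect_true(all(cmp$auroc >= 0.5 - 1e-12))       # negation applied
  expect_true(any(grepl("^-", cmp$predictor)))     # some inverse markers
  # an indicator negatively correlated with poor response flips sign
  expect_true(any(grepl("LMR", cmp$predictor)))
})

test_that("a score and its negation have complementary AUROCs", {
  co <- generate_cohort(synth_config(n_patients = 500, seed = 46))
  y <- derive_label(co$trg)
  sc <- evaluate_score(published_rps(), co)
  expect_equal(auroc(sc, y) + auroc(-sc, y), 1)
})

test_that("quartile stratification groups and tables are consistent", {
  co <- tiny_cohort(80, seed = 6)
  sc <- seq_len(80) / 10
  strat <- stratify_quartiles(sc, co)
  expect_identical(strat$group_sizes, rep(20L, 4))
  expect_equal(unname(strat$thresholds),
               unname(quantile(sc, c(0.25, 0.5, 0.75))))
  expect_equal(sum(strat$trg_table), 80)
  expect_equal(sum(strat$downstaging$n), 80)
  small <- stratify_quartiles(1:8, co[1:8, ])
  expect_identical(small$group_sizes, rep(2L, 4))
  expect_error(stratify_quartiles(1:4, co[1:4, ]), "n >= 8")
})

test_that("null scores stratify outcomes flat; planted scores monotone", {
  co <- generate_cohort(synth_config(n_patients = 2000, seed = 47))
  lab <- derive_label(co$trg)
  set.seed(48)
  null_rep <- stratify_quartiles(runif(2000), co)
  overall <- mean(lab == 0)
  expect_true(all(abs(null_rep$downstaging$good_response_rate - overall)
                  <= 0.10))
  planted <- stratify_quartiles(evaluate_score(published_rps(), co), co)
  expect_true(all(diff(planted$downstaging$good_response_rate) < 0))
})
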