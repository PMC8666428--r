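test_that("identical seeds produce byte-identical cohorts", {
  a <- generate_cohort(synth_config(seed = 7))
  b <- generate_cohort(synth_config(seed = 7))
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_cohort(synth_config(seed = 8))
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("generated cohorts respect physical and outcome invariants", {
  co <- generate_cohort(synth_config(seed = 3))
  sch <- cohort_schema()
  counts <- sch$name[sch$epoch %in% c("pre_cbc", "pre_chem", "early_cbc")]
  for (f in counts) expect_true(all(co[[f]] > 0), label = f)
  expect_true(all(co$pre_hct > 0 & co$pre_hct < 100))
  expect_true(all(co$early_hct > 0 & co$early_hct < 100))
  expect_true(all(co$trg %in% 0:3))
  cr <- co[co$trg == 0, ]
  expect_true(all(cr$ypt == 0 & cr$ypn == 0))
  expect_true(all(derive_downstaging(cr)$overall))
})

test_that("default config hits the configured responder prevalence", {
  co <- generate_cohort(synth_config(seed = 11))
  frac_good <- mean(derive_label(co$trg) == 0)
  expect_gt(frac_good, 0.43 - 0.06)
  expect_lt(frac_good, 0.43 + 0.06)
})

test_that("good responders downstage more often than poor responders", {
  co <- generate_cohort(synth_config(n_patients = 1000, seed = 2))
  ds <- derive_downstaging(co)
  lab <- derive_label(co$trg)
  expect_gt(mean(ds$overall[lab == 0]), mean(ds$overall[lab == 1]) + 0.2)
})

test_that("zero effect sizes leave all features balanced between groups", {
  co <- generate_cohort(synth_config(n_patients = 5000, seed = 4,
                                     effect_sizes = numeric(0)))
  lab <- derive_label(co$trg)
  sch <- cohort_schema()
  feats <- sch$name[sch$type == "continuous"]
  smd <- vapply(feats, function(f) {
    (mean(co[[f]][lab == 1]) - mean(co[[f]][lab == 0])) /
      stats::sd(co[[f]])
  }, numeric(1))
  expect_true(all(abs(smd) <= 0.1),
              info = paste(names(which(abs(smd) > 0.1)), collapse = ", "))
})

test_that("planted early-CRT signal is strong and pre-CRT chemistry is null", {
  hits <- 0
  chem <- paste0("pre_", c("calcium", "phosphorus", "glucose", "uric_acid",
                           "cholesterol", "total_protein", "albumin",
                           "total_bilirubin", "ast", "alt", "alp",
                           "creatinine"))
  chem_null <- matrix(NA, 10, length(chem), dimnames = list(NULL, chem))
  for (s in 1:10) {
    co <- generate_cohort(synth_config(n_patients = 2000, seed = s))
    lab <- derive_label(co$trg)
    p_mono <- mann_whitney_u(co$early_monocyte[lab == 1],
                             co$early_monocyte[lab == 0])$p
    if (p_mono < 0.001) hits <- hits + 1
    for (f in chem) {
      chem_null[s, f] <- mann_whitney_u(co[[f]][lab == 1],
                                        co[[f]][lab == 0])$p > 0.01
    }
  }
  expect_equal(hits, 10)
  expect_true(all(colMeans(chem_null) >= 0.9),
              info = paste(colnames(chem_null)[colMeans(chem_null) < 0.9],
                           collapse = ", "))
})

test_that("invalid generator configurations name the offending field", {
  expect_error(synth_config(n_patients = 10), "n_patients")
  expect_error(synth_config(prevalence_good = 1), "prevalence_good")
  expect_error(synth_config(effect_sizes = c(not_a_feature = 1)),
               "effect_sizes")
  expect_error(synth_config(missing_rate = 0.5), "missing_rate")
  expect_error(synth_config(noise_sd = -1), "noise_sd")
})

test_that("cohort CSV round-trips losslessly, missing cells as empty fields", {
  co <- generate_cohort(synth_config(n_patients = 40, seed = 9,
                                     missing_rate = 0.1))
  expect_true(anyNA(co$pre_albumin) || anyNA(co$early_monocyte) ||
                anyNA(as.matrix(co[paste0("pre_",
                                          c("glucose", "ast", "alt"))])))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  lines <- readLines(path)
  expect_length(lines, 41)  # header + one row per patient
  back <- read_cohort(path)
  expect_equal(as.data.frame(co), back, tolerance = 1e-12,
               ignore_attr = TRUE)

  one <- co[1, ]
  one$pre_albumin <- NA_real_
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(one, path2)
  row <- strsplit(readLines(path2)[2], ",")[[1]]
  alb_pos <- match("pre_albumin", names(co))
  expect_identical(row[alb_pos], "")
  expect_length(readLines(path2), 2)
})
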