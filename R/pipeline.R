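#' End-to-end pipeline configuration
#'
#' @param outdir Directory for the run artifacts (created if needed).
#' @param cohort_path Optional existing cohort CSV; when NULL a synthetic
#'   cohort is generated from \code{synth}.
#' @param synth A \code{\link{synth_config}}.
#' @param bench A \code{\link{bench_config}} (desk profile by default:
#'   100 repeats, ridge + logistic regression).
#' @param score_model_kind,score_feature_set Which benchmark cell feeds
#'   the score derivation.
#' @param k_max Largest score size considered.
#' @param use_published_rps When TRUE the derivation stage is skipped and
#'   the published score constants are used downstream.
#' @param seed Master seed; fans out to the synthesis and benchmark
#'   stages by a counter-based derivation.
#' @return Object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(outdir = "rps_run",
                            cohort_path = NULL,
                            synth = synth_config(),
                            bench = bench_config(),
                            score_model_kind = "ridge",
                            score_feature_set = "clinical_early",
                            k_max = 10,
                            use_published_rps = FALSE,
                            seed = 1) {
  structure(
    list(outdir = outdir, cohort_path = cohort_path, synth = synth,
         bench = bench, score_model_kind = score_model_kind,
         score_feature_set = score_feature_set, k_max = k_max,
         use_published_rps = use_published_rps, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(
    config, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Synthesize (or load) the cohort, run the repeated benchmark, derive the
#' score (unless the published constants are requested), compare it
#' against single features and indicators, and stratify outcomes by score
#' quartiles. Writes eight artifacts to \code{outdir}: the cohort CSV, the
#' benchmark table, the importance table, the score JSON, the comparison
#' CSV, the stratification CSV, the significance-curve CSV and a JSON run
#' manifest (config hash, seed, package version). Reruns with the same
#' configuration and seed reproduce identical numeric artifacts.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @return The manifest, invisibly (list with artifact paths and the
#'   in-memory stage results as attribute \code{"results"}).
#' @examples
#' \donttest{
#' cfg <- pipeline_config(outdir = tempfile(),
#'                        synth = synth_config(n_patients = 80),
#'                        bench = bench_config(n_repeats = 5,
#'                                             model_kinds = "ridge",
#'                                             feature_sets = "clinical_early"),
#'                        use_published_rps = TRUE)
#' run_pipeline(cfg)
#' }
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(config$outdir, f)
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  cohort <- stage("cohort", {
    if (!is.null(config$cohort_path)) {
      read_cohort(config$cohort_path)
    } else {
      sc <- config$synth
      sc$seed <- derive_seed(config$seed, 1)
      generate_cohort(sc)
    }
  })
  write_cohort(cohort, pth("cohort.csv"))

  bench <- stage("benchmark", {
    bc <- config$bench
    bc$master_seed <- derive_seed(config$seed, 2)
    run_benchmark(cohort, bc)
  })
  utils::write.csv(bench$table, pth("benchmark_table.csv"),
                   row.names = FALSE)

  derived <- stage("score", {
    if (config$use_published_rps) {
      imp <- generalized_importance(bench$results,
                                    config$score_model_kind,
                                    config$score_feature_set)
      x <- assemble_features(cohort, config$score_feature_set)
      curve <- select_score_size(imp, x, derive_label(cohort$trg),
                                 config$k_max)$curve
      list(score = published_rps(), importance = imp, k_o = NA_integer_,
           curve = curve)
    } else {
      derive_score_definition(bench$results, cohort,
                              config$score_model_kind,
                              config$score_feature_set, config$k_max)
    }
  })
  utils::write.csv(derived$importance, pth("importance_table.csv"),
                   row.names = FALSE)
  utils::write.csv(derived$curve, pth("significance_curve.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(features = derived$score$features,
         weights = derived$score$weights,
         provenance = derived$score$provenance,
         k_o = derived$score$k_o),
    pth("score.json"), auto_unbox = TRUE, digits = NA)

  comparison <- stage("comparison",
                      compare_predictors(cohort, derived$score))
  utils::write.csv(comparison, pth("comparison.csv"), row.names = FALSE)

  strat <- stage("stratification", {
    complete <- stats::complete.cases(
      as.data.frame(cohort)[derived$score$features])
    stratify_quartiles(evaluate_score(derived$score, cohort[complete, ]),
                       cohort[complete, ])
  })
  strat_df <- cbind(strat$downstaging,
                    as.data.frame.matrix(strat$trg_table))
  utils::write.csv(strat_df, pth("stratification.csv"), row.names = FALSE)

  manifest <- list(
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("rpscore")),
    artifacts = list(
      cohort = pth("cohort.csv"),
      benchmark_table = pth("benchmark_table.csv"),
      importance_table = pth("importance_table.csv"),
      significance_curve = pth("significance_curve.csv"),
      score = pth("score.json"),
      comparison = pth("comparison.csv"),
      stratification = pth("stratification.csv"),
      manifest = pth("manifest.json")
    )
  )
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  attr(manifest, "results") <- list(cohort = cohort, bench = bench,
                                    derived = derived,
                                    comparison = comparison,
                                    stratification = strat)
  invisible(manifest)
}
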