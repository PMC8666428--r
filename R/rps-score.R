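#' Generalized feature importance from repeated linear fits
#'
#' Averages the per-repeat coefficients over all N repeats, entering 0 for
#' repeats in which a feature was not selected, so the average encodes
#' both effect magnitude and selection frequency. Importance is ranked on
#' the standardized-coefficient scale (per-SD effects, comparable across
#' units); the companion raw-scale average is carried as the weight a
#' derived score uses. Ties rank alphabetically.
#'
#' @param results List of per-repeat model run records (from
#'   \code{\link{run_benchmark}}), or a \code{benchmark_result}.
#' @param model_kind Linear model kind to aggregate (\code{"ridge"},
#'   \code{"lasso"} or \code{"logistic"}).
#' @param feature_set Feature set to aggregate.
#' @return Data frame of class \code{importance_table}, sorted by
#'   decreasing |standardized importance|: \code{feature}, \code{beta}
#'   (mean raw-scale coefficient), \code{beta_std} (mean standardized
#'   coefficient), \code{selection_count}, \code{n_repeats},
#'   \code{sign_consistency} (fraction of selecting repeats whose
#'   coefficient sign matches the sign of the mean; NA if never selected).
#' @export
generalized_importance <- function(results, model_kind = "ridge",
                                   feature_set = "clinical_early") {
  if (inherits(results, "benchmark_result")) results <- results$results
  model_kind <- match.arg(model_kind, c("ridge", "lasso", "logistic"))
  sub <- Filter(function(x) x$model_kind == model_kind &&
                  x$feature_set == feature_set, results)
  if (length(sub) < 2) {
    stop("importance requires at least 2 repeats of a linear model kind")
  }
  if (any(vapply(sub, function(x) is.null(x$coef_raw), TRUE))) {
    stop("unsupported model kind: importance is defined only for ",
         "coefficient models")
  }
  raw <- do.call(rbind, lapply(sub, `[[`, "coef_raw"))
  std <- do.call(rbind, lapply(sub, `[[`, "coef_std"))
  n <- nrow(raw)
  beta <- colMeans(raw)
  beta_std <- colMeans(std)
  selected <- do.call(rbind, lapply(sub, function(x) {
    colnames(raw) %in% x$selected_features
  }))
  sel_count <- colSums(selected)
  sign_cons <- vapply(seq_along(beta), function(k) {
    sel <- selected[, k]
    if (!any(sel)) return(NA_real_)
    s <- sign(std[sel, k])
    target <- sign(beta_std[k])
    # an exactly balanced mean has no sign; report the modal-sign fraction
    if (target == 0) return(max(mean(s > 0), mean(s < 0)))
    mean(s == target)
  }, numeric(1))
  out <- data.frame(
    feature = colnames(raw), beta = unname(beta),
    beta_std = unname(beta_std),
    selection_count = unname(sel_count), n_repeats = n,
    sign_consistency = sign_cons,
    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$beta_std), out$feature), ]
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Choose the score size from the significance curve
#'
#' Adds features in decreasing order of importance and, for each candidate
#' size K, evaluates the candidate linear score on the whole cohort and
#' tests it between the responder groups with the Mann-Whitney U test.
#' The chosen size K_o is the global arg-min of the P-value curve (ties
#' toward the smallest K); degenerate candidate scores record P = 1.
#'
#' @param importance An \code{importance_table}.
#' @param x Raw-unit feature matrix covering the importance features.
#' @param labels 0/1 response labels (1 = poor responder).
#' @param k_max Largest score size to consider (default 10, capped at the
#'   number of features).
#' @return List with \code{k_o} and \code{curve} (data frame of K,
#'   P-value, and the feature added at each K).
#' @export
select_score_size <- function(importance, x, labels, k_max = 10) {
  if (length(unique(labels)) < 2) stop("labels must contain both classes")
  k_max <- min(k_max, nrow(importance))
  x <- as.matrix(x)
  p_curve <- numeric(k_max)
  score <- numeric(nrow(x))
  for (k in seq_len(k_max)) {
    f <- importance$feature[k]
    score <- score + importance$beta[k] * x[, f]
    p_curve[k] <- if (length(unique(score)) < 2) 1 else
      mann_whitney_u(score[labels == 1], score[labels == 0])$p
  }
  k_o <- which.min(p_curve)  # first minimum = smallest K on ties
  list(k_o = k_o,
       curve = data.frame(k = seq_len(k_max), p = p_curve,
                          feature = importance$feature[seq_len(k_max)],
                          stringsAsFactors = FALSE))
}

#' Construct a linear score definition
#'
#' @param features Character vector of feature names (unique).
#' @param weights Numeric weights (non-zero), same length.
#' @param provenance \code{"published"} or \code{"derived"}.
#' @param units Optional named character vector of feature units.
#' @return Object of class \code{score_definition}.
#' @export
score_definition <- function(features, weights,
                             provenance = c("derived", "published"),
                             units = NULL) {
  provenance <- match.arg(provenance)
  if (length(features) != length(weights)) {
    stop("features and weights must have equal length")
  }
  if (anyDuplicated(features)) stop("score features must be unique")
  if (any(weights == 0)) stop("score weights must be non-zero")
  structure(
    list(features = as.character(features), weights = as.numeric(weights),
         k_o = length(features), provenance = provenance, units = units),
    class = "score_definition"
  )
}

#' The published Response Prediction Score (RPS)
#'
#' The fixed five-term linear score: +0.000559 per early-CRT monocyte
#' (cells/uL), +0.026172 per cm of distance from the anal verge, +0.001021
#' per early-CRT platelet (10^3/uL), +0.000049 per early-CRT neutrophil
#' (cells/uL), -0.000433 per early-CRT eosinophil (cells/uL). Higher
#' values predict poor response (TRG 2-3) to preoperative CRT.
#'
#' @return A \code{score_definition} with provenance \code{"published"}.
#' @examples
#' published_rps()
#' @export
published_rps <- function() {
  score_definition(
    features = c("early_monocyte", "distance_anal_verge", "early_plt",
                 "early_neutrophil", "early_eosinophil"),
    weights = c(0.000559, 0.026172, 0.001021, 0.000049, -0.000433),
    provenance = "published",
    units = c(early_monocyte = "/uL", distance_anal_verge = "cm",
              early_plt = "10^3/uL", early_neutrophil = "/uL",
              early_eosinophil = "/uL")
  )
}

#' @export
print.score_definition <- function(x, ...) {
  cat(sprintf("Linear response score (%s, %d terms):\n",
              x$provenance, x$k_o))
  for (i in seq_along(x$features)) {
    u <- if (!is.null(x$units)) sprintf(" per %s", x$units[[x$features[i]]])
         else ""
    cat(sprintf("  %+.6f x %s%s\n", x$weights[i], x$features[i], u))
  }
  invisible(x)
}

#' Evaluate a linear score
#'
#' The exact weighted sum of the score features: no intercept, no
#' clipping.
#'
#' @param defn A \code{\link{score_definition}}.
#' @param data Data frame or matrix carrying all score feature columns.
#' @return Numeric vector of scores, one per row.
#' @examples
#' evaluate_score(published_rps(),
#'                data.frame(early_monocyte = 300, distance_anal_verge = 5,
#'                           early_plt = 200, early_neutrophil = 2500,
#'                           early_eosinophil = 100))
#' @export
evaluate_score <- function(defn, data) {
  data <- as.data.frame(data)
  missing_f <- setdiff(defn$features, names(data))
  if (length(missing_f)) {
    stop("missing score feature(s): ", paste(missing_f, collapse = ", "))
  }
  m <- as.matrix(data[defn$features])
  if (anyNA(m)) {
    bad <- defn$features[colSums(is.na(m)) > 0]
    stop("missing values in score feature(s): ",
         paste(bad, collapse = ", "))
  }
  as.numeric(m %*% defn$weights)
}

#' Derive a score definition from a benchmark run
#'
#' Convenience wrapper: generalized importance, significance-curve size
#' selection, and assembly of the resulting score (raw-scale weights of
#' the top K_o features).
#'
#' @inheritParams generalized_importance
#' @param cohort Cohort the benchmark was run on.
#' @param k_max Largest score size to consider.
#' @return List with \code{score} (a \code{score_definition}),
#'   \code{importance}, \code{k_o}, \code{curve}.
#' @export
derive_score_definition <- function(results, cohort, model_kind = "ridge",
                                    feature_set = "clinical_early",
                                    k_max = 10) {
  imp <- generalized_importance(results, model_kind, feature_set)
  x <- assemble_features(cohort, feature_set)
  sel <- select_score_size(imp, x, derive_label(cohort$trg), k_max)
  top <- imp[seq_len(sel$k_o), ]
  list(score = score_definition(top$feature, top$beta, "derived"),
       importance = imp, k_o = sel$k_o, curve = sel$curve)
}

#' Sign-consistency audit of repeated coefficients
#'
#' For each feature, the fraction of repeats (among those where the
#' feature survived selection) whose coefficient sign matches the sign of
#' its across-repeat mean; a stable score feature should sit near 1.
#'
#' @inheritParams generalized_importance
#' @param features Features to audit (default: all in the feature set).
#' @return Data frame with \code{feature}, \code{selection_count},
#'   \code{n_repeats}, \code{sign_consistency} (NA when never selected).
#' @export
sign_consistency_audit <- function(results, features = NULL,
                                   model_kind = "ridge",
                                   feature_set = "clinical_early") {
  imp <- generalized_importance(results, model_kind, feature_set)
  if (!is.null(features)) {
    unknown <- setdiff(features, imp$feature)
    if (length(unknown)) {
      stop("feature(s) not in the feature set: ",
           paste(unknown, collapse = ", "))
    }
    imp <- imp[match(features, imp$feature), ]
  }
  out <- imp[, c("feature", "selection_count", "n_repeats",
                 "sign_consistency")]
  rownames(out) <- NULL
  out
}

#' Compare a score against single blood features and indicators
#'
#' AUROC versus the poor-responder label for every single blood feature
#' (pre- and early-CRT), the pre-CRT NLR/PLR/LMR/PNI, the early-CRT
#' NLR/PLR/LMR (no early PNI: no early albumin), and the score itself.
#' Any predictor whose AUROC falls below 0.5 is re-reported as its
#' negation with a "-" prefix. Records with undefined indicator inputs are
#' excluded from that predictor's ROC.
#'
#' @param cohort Cohort data frame.
#' @param score_defn A \code{\link{score_definition}} (default: the
#'   published RPS).
#' @param score_name Row label for the score.
#' @return Data frame sorted by decreasing AUROC: \code{predictor},
#'   \code{auroc}, \code{n_used}, \code{negated}.
#' @export
compare_predictors <- function(cohort, score_defn = published_rps(),
                               score_name = "RPS") {
  y <- derive_label(cohort$trg)
  sch <- cohort_schema()
  blood <- sch$name[sch$epoch %in% c("pre_cbc", "pre_chem", "early_cbc")]
  preds <- lapply(stats::setNames(nm = blood),
                  function(f) as.numeric(cohort[[f]]))

  ind <- function(epoch) {
    pfx <- if (epoch == "pre") "pre_" else "early_"
    list(nlr = cohort[[paste0(pfx, "neutrophil")]] /
           cohort[[paste0(pfx, "lymphocyte")]],
         plr = cohort[[paste0(pfx, "plt")]] * 1000 /
           cohort[[paste0(pfx, "lymphocyte")]],
         lmr = cohort[[paste0(pfx, "lymphocyte")]] /
           cohort[[paste0(pfx, "monocyte")]])
  }
  pre_i <- ind("pre"); early_i <- ind("early")
  preds[["pre_NLR"]] <- pre_i$nlr
  preds[["pre_PLR"]] <- pre_i$plr
  preds[["pre_LMR"]] <- pre_i$lmr
  preds[["pre_PNI"]] <- 10 * cohort$pre_albumin +
    0.005 * cohort$pre_lymphocyte
  preds[["early_NLR"]] <- early_i$nlr
  preds[["early_PLR"]] <- early_i$plr
  preds[["early_LMR"]] <- early_i$lmr

  complete <- stats::complete.cases(as.data.frame(cohort)[score_defn$features])
  sc <- rep(NA_real_, nrow(cohort))
  sc[complete] <- evaluate_score(score_defn, cohort[complete, ])
  preds[[score_name]] <- sc

  rows <- lapply(names(preds), function(nm) {
    v <- preds[[nm]]
    keep <- is.finite(v) & !is.na(y)
    a <- auroc(v[keep], y[keep])
    negated <- a < 0.5
    data.frame(
      predictor = if (negated) paste0("-", nm) else nm,
      auroc = if (negated) 1 - a else a,
      n_used = sum(keep), negated = negated,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$auroc), ]
  rownames(out) <- NULL
  out
}

#' Quartile stratification of outcomes by score
#'
#' Groups patients at the empirical first quartile, median and third
#' quartile of the score (linear-interpolation quantile convention,
#' \code{stats::quantile} type 7) and tabulates the TRG distribution and
#' the downstaging outcomes per group.
#'
#' @param scores Numeric scores, one per patient (n >= 8).
#' @param outcomes Data frame with columns \code{trg}, \code{clinical_t},
#'   \code{clinical_n}, \code{ypt}, \code{ypn} (a cohort works).
#' @return Object of class \code{stratification_report}: \code{thresholds}
#'   (Q1/median/Q3), \code{group_sizes}, \code{trg_table} (groups x TRG
#'   counts), \code{downstaging} (per-group counts and rates of overall,
#'   T- and N-downstaging plus the good-response rate).
#' @export
stratify_quartiles <- function(scores, outcomes) {
  if (length(scores) < 8) stop("stratification requires n >= 8")
  if (length(scores) != nrow(outcomes)) {
    stop("scores and outcomes must have matching length")
  }
  qs <- stats::quantile(scores, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  grp <- cut(scores, breaks = c(-Inf, qs, Inf),
             labels = c("Q1", "Q2", "Q3", "Q4"), right = TRUE)
  if (any(table(grp) == 0)) {
    warning("heavily tied scores left a quartile group empty")
  }
  ds <- derive_downstaging(outcomes)
  lab <- derive_label(outcomes$trg)
  trg_table <- table(group = grp, trg = factor(outcomes$trg, levels = 0:3))
  down <- do.call(rbind, lapply(levels(grp), function(g) {
    sel <- grp == g
    data.frame(group = g, n = sum(sel),
               good_response_rate = mean(lab[sel] == 0),
               overall_rate = mean(ds$overall[sel]),
               t_down_rate = mean(ds$t_down[sel]),
               n_down_rate = mean(ds$n_down[sel]),
               stringsAsFactors = FALSE)
  }))
  structure(
    list(thresholds = stats::setNames(qs, c("q1", "median", "q3")),
         group_sizes = as.integer(table(grp)),
         trg_table = trg_table, downstaging = down),
    class = "stratification_report"
  )
}

#' @export
print.stratification_report <- function(x, ...) {
  cat(sprintf("Score quartile thresholds: Q1 %.4f, median %.4f, Q3 %.4f\n",
              x$thresholds[1], x$thresholds[2], x$thresholds[3]))
  cat("TRG distribution by score quartile group:\n")
  print(x$trg_table)
  cat("Response and downstaging rates by group:\n")
  print(x$downstaging, row.names = FALSE, digits = 3)
  invisible(x)
}
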