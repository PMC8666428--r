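#' Inflammatory and nutritional indicators from a blood panel
#'
#' Computes the neutrophil-to-lymphocyte ratio (NLR), platelet-to-lymphocyte
#' ratio (PLR), lymphocyte-to-monocyte ratio (LMR) and, for the pre-CRT
#' epoch only, the prognostic nutritional index
#' PNI = 10 x albumin (g/dL) + 0.005 x lymphocyte count (/mm3).
#' The early-CRT panel carries no chemistry, so the PNI is undefined there.
#'
#' @param panel Named list or one-row data frame with entries
#'   \code{neutrophil}, \code{lymphocyte}, \code{monocyte} (cells/uL) and
#'   \code{plt} (10^3/uL). The PLR is computed on the platelet count in
#'   cells/uL (plt x 1000), the conventional scale for this ratio.
#' @param epoch \code{"pre"} or \code{"early"}.
#' @param albumin Serum albumin in g/dL; required for the PNI, only
#'   meaningful when \code{epoch = "pre"}.
#' @return A list of class \code{indicator_set} with \code{nlr}, \code{plr},
#'   \code{lmr}, \code{pni} (NA unless pre-CRT with albumin supplied) and
#'   \code{epoch}.
#' @examples
#' compute_indicators(list(neutrophil = 4000, lymphocyte = 2000,
#'                         monocyte = 500, plt = 250),
#'                    epoch = "pre", albumin = 4.0)
#' @export
compute_indicators <- function(panel, epoch = c("pre", "early"),
                               albumin = NULL) {
  epoch <- match.arg(epoch)
  need <- c("neutrophil", "lymphocyte", "monocyte", "plt")
  panel <- as.list(panel)
  missing_f <- setdiff(need, names(panel))
  if (length(missing_f)) {
    stop("panel is missing count(s): ", paste(missing_f, collapse = ", "))
  }
  lym <- as.numeric(panel$lymphocyte)
  if (!is.finite(lym) || lym <= 0) {
    if (is.finite(lym) && lym == 0 && epoch == "pre" && !is.null(albumin)) {
      # ratios undefined, but the PNI is still well defined at zero count
      return(structure(list(nlr = NA_real_, plr = NA_real_, lmr = NA_real_,
                            pni = 10 * albumin, epoch = epoch),
                       class = "indicator_set"))
    }
    stop("undefined indicator: lymphocyte count must be positive")
  }
  mono <- as.numeric(panel$monocyte)
  if (!is.finite(mono) || mono <= 0) {
    stop("undefined indicator: monocyte count must be positive for the LMR")
  }
  pni <- NA_real_
  if (!is.null(albumin)) {
    if (epoch == "early") {
      stop("unsupported indicator: the PNI requires albumin, ",
           "which is not measured in the early-CRT panel")
    }
    pni <- 10 * as.numeric(albumin) + 0.005 * lym
  }
  structure(
    list(nlr = as.numeric(panel$neutrophil) / lym,
         plr = as.numeric(panel$plt) * 1000 / lym,
         lmr = lym / mono,
         pni = pni,
         epoch = epoch),
    class = "indicator_set"
  )
}

#' Binary response label from the tumor regression grade
#'
#' The positive class is the poor responder: TRG 2-3. Good responders
#' (TRG 0-1, the complete and moderate responses) are labelled 0.
#'
#' @param trg Integer vector with values in \{0, 1, 2, 3\}.
#' @return Integer vector of 0/1 labels (1 = poor responder).
#' @examples
#' derive_label(c(0, 1, 2, 3))
#' @export
derive_label <- function(trg) {
  ok <- !is.na(trg) & trg %in% 0:3
  if (!all(ok)) {
    stop("TRG must be in {0, 1, 2, 3}; offending value(s): ",
         paste(unique(trg[!ok]), collapse = ", "))
  }
  as.integer(trg >= 2)
}

#' Downstaging outcomes after chemoradiotherapy
#'
#' Overall downstaging is ypT0-2N0 (the cohort is M0 by definition);
#' T-downstaging is a pathologic T classification strictly below the
#' clinical one, and likewise for N.
#'
#' @param record Data frame (one or more rows) with columns
#'   \code{clinical_t}, \code{clinical_n}, \code{ypt}, \code{ypn}.
#' @return Data frame with logical columns \code{overall}, \code{t_down},
#'   \code{n_down}.
#' @examples
#' derive_downstaging(data.frame(clinical_t = 3, clinical_n = 1,
#'                               ypt = 2, ypn = 0))
#' @export
derive_downstaging <- function(record) {
  need <- c("clinical_t", "clinical_n", "ypt", "ypn")
  missing_f <- setdiff(need, names(record))
  if (length(missing_f)) {
    stop("record is missing stage column(s): ",
         paste(missing_f, collapse = ", "))
  }
  if (anyNA(record[need])) stop("stage values must not be missing")
  data.frame(
    overall = record$ypt <= 2 & record$ypn == 0,
    t_down = record$ypt < record$clinical_t,
    n_down = record$ypn < record$clinical_n
  )
}

#' Assemble a model feature matrix for a named feature set
#'
#' Categorical features are carried as their integer codes (sex 0/1, tumor
#' grade 1-3, clinical T/N stage); derived indicators are never included.
#'
#' @param cohort Cohort data frame.
#' @param set_name One of \code{feature_set_names()}.
#' @return Numeric matrix, one row per patient, columns in stable order.
#' @examples
#' cohort <- generate_cohort(synth_config(n_patients = 30, seed = 1))
#' dim(assemble_features(cohort, "tumor_clinical"))
#' @export
assemble_features <- function(cohort, set_name) {
  members <- feature_set_members(set_name)
  missing_f <- setdiff(members, names(cohort))
  if (length(missing_f)) {
    stop("cohort is missing feature column(s): ",
         paste(missing_f, collapse = ", "))
  }
  m <- as.matrix(as.data.frame(lapply(cohort[members], as.numeric)))
  colnames(m) <- members
  rownames(m) <- NULL
  m
}
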