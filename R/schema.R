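#' Cohort feature schema
#'
#' Column dictionary for the per-patient cohort table: every clinical
#' feature, the pre-chemoradiotherapy (pre-CRT) blood panel (17 CBC-with-
#' differential features plus 12 chemistry features), the early-CRT panel
#' (CBC with differential only, drawn 1-2 weeks after the start of CRT),
#' and the pathologic outcomes. The same dictionary is shipped as a plain
#' CSV in \code{inst/extdata/cohort_schema.csv}.
#'
#' @return A data frame with one row per cohort column: \code{name},
#'   \code{epoch} (one of \code{id}, \code{clinical}, \code{pre_cbc},
#'   \code{pre_chem}, \code{early_cbc}, \code{outcome}), \code{type}
#'   (\code{continuous} or \code{categorical}), \code{unit}, and
#'   \code{description}.
#' @examples
#' head(cohort_schema())
#' @export
cohort_schema <- function() {
  cbc <- c(
    rbc        = "red blood cell count",
    hb         = "hemoglobin",
    hct        = "hematocrit",
    mcv        = "mean red cell volume",
    mch        = "mean red cell hemoglobin",
    mchc       = "mean red cell hemoglobin concentration",
    rdw        = "red cell distribution width",
    plt        = "platelet count",
    pct        = "plateletcrit",
    mpv        = "mean platelet volume",
    pdw        = "platelet distribution width",
    wbc        = "white blood cell count",
    neutrophil = "absolute neutrophil count",
    lymphocyte = "absolute lymphocyte count",
    monocyte   = "absolute monocyte count",
    eosinophil = "absolute eosinophil count",
    basophil   = "absolute basophil count"
  )
  cbc_units <- c(
    rbc = "10^6/uL", hb = "g/dL", hct = "%", mcv = "fL", mch = "pg",
    mchc = "g/dL", rdw = "%", plt = "10^3/uL", pct = "%", mpv = "fL",
    pdw = "%", wbc = "10^3/uL", neutrophil = "/uL", lymphocyte = "/uL",
    monocyte = "/uL", eosinophil = "/uL", basophil = "/uL"
  )
  chem <- c(
    calcium = "serum calcium", phosphorus = "serum phosphorus",
    glucose = "serum glucose", uric_acid = "serum uric acid",
    cholesterol = "total cholesterol", total_protein = "total protein",
    albumin = "serum albumin", total_bilirubin = "total bilirubin",
    ast = "aspartate transaminase", alt = "alanine aminotransferase",
    alp = "alkaline phosphatase", creatinine = "serum creatinine"
  )
  chem_units <- c(
    calcium = "mg/dL", phosphorus = "mg/dL", glucose = "mg/dL",
    uric_acid = "mg/dL", cholesterol = "mg/dL", total_protein = "g/dL",
    albumin = "g/dL", total_bilirubin = "mg/dL", ast = "U/L", alt = "U/L",
    alp = "U/L", creatinine = "mg/dL"
  )
  rows <- rbind(
    data.frame(
      name = "id", epoch = "id", type = "id", unit = "",
      description = "opaque patient identifier",
      stringsAsFactors = FALSE
    ),
    data.frame(
      name = c("age", "sex", "distance_anal_verge", "cea", "tumor_grade",
               "clinical_t", "clinical_n"),
      epoch = "clinical",
      type = c("continuous", "categorical", "continuous", "continuous",
               "categorical", "categorical", "categorical"),
      unit = c("years", "0=female,1=male", "cm", "ng/mL",
               "1=well,2=moderate,3=poor", "cT 1-4", "cN 0-2"),
      description = c(
        "age at diagnosis", "sex",
        "distance of the tumor from the anal verge",
        "carcinoembryonic antigen", "histologic tumor grade",
        "clinical T classification", "clinical N classification"
      ),
      stringsAsFactors = FALSE
    ),
    data.frame(
      name = paste0("pre_", names(cbc)), epoch = "pre_cbc",
      type = "continuous", unit = unname(cbc_units),
      description = paste("pre-CRT", unname(cbc)),
      stringsAsFactors = FALSE
    ),
    data.frame(
      name = paste0("pre_", names(chem)), epoch = "pre_chem",
      type = "continuous", unit = unname(chem_units),
      description = paste("pre-CRT", unname(chem)),
      stringsAsFactors = FALSE
    ),
    data.frame(
      name = paste0("early_", names(cbc)), epoch = "early_cbc",
      type = "continuous", unit = unname(cbc_units),
      description = paste("early-CRT (1-2 weeks into CRT)", unname(cbc)),
      stringsAsFactors = FALSE
    ),
    data.frame(
      name = c("trg", "ypt", "ypn"),
      epoch = "outcome", type = "categorical",
      unit = c("AJCC TRG 0-3", "ypT 0-4", "ypN 0-2"),
      description = c(
        "AJCC tumor regression grade (0 = complete response, 3 = poor)",
        "pathologic T classification after CRT and surgery",
        "pathologic N classification after CRT and surgery"
      ),
      stringsAsFactors = FALSE
    )
  )
  rownames(rows) <- NULL
  rows
}

# Internal: names of the CBC-with-differential features (unprefixed).
cbc_feature_names <- function() {
  c("rbc", "hb", "hct", "mcv", "mch", "mchc", "rdw", "plt", "pct", "mpv",
    "pdw", "wbc", "neutrophil", "lymphocyte", "monocyte", "eosinophil",
    "basophil")
}

# Internal: names of the chemistry features (unprefixed).
chem_feature_names <- function() {
  c("calcium", "phosphorus", "glucose", "uric_acid", "cholesterol",
    "total_protein", "albumin", "total_bilirubin", "ast", "alt", "alp",
    "creatinine")
}

#' Names of the five model feature sets
#'
#' @return Character vector of the five feature-set identifiers.
#' @export
feature_set_names <- function() {
  c("tumor_clinical", "clinical", "clinical_pre", "clinical_early",
    "clinical_pre_early")
}

#' Member features of a named feature set
#'
#' The tumor-related clinical trio is distance from the anal verge, CEA and
#' tumor grade. "Clinical" adds age, sex and clinical T/N stage (the study
#' does not enumerate its clinical set beyond the trio; this membership is a
#' documented assumption). The pre-CRT panel contributes 17 CBC and 12
#' chemistry features; the early-CRT panel contributes the 17 CBC features
#' only. Derived inflammatory/nutritional indicators (NLR, PLR, LMR, PNI)
#' are never model inputs; they are comparison baselines.
#'
#' @param set_name One of \code{feature_set_names()}.
#' @return Character vector of cohort column names, in stable order.
#' @examples
#' feature_set_members("tumor_clinical")
#' @export
feature_set_members <- function(set_name) {
  set_name <- match.arg(set_name, feature_set_names())
  tumor <- c("distance_anal_verge", "cea", "tumor_grade")
  clinical <- c(tumor, "age", "sex", "clinical_t", "clinical_n")
  pre <- c(paste0("pre_", cbc_feature_names()),
           paste0("pre_", chem_feature_names()))
  early <- paste0("early_", cbc_feature_names())
  switch(set_name,
    tumor_clinical     = tumor,
    clinical           = clinical,
    clinical_pre       = c(clinical, pre),
    clinical_early     = c(clinical, early),
    clinical_pre_early = c(clinical, pre, early)
  )
}

# Internal: feature type lookup (continuous vs categorical) for selection.
feature_types <- function(features) {
  sch <- cohort_schema()
  tp <- sch$type[match(features, sch$name)]
  if (anyNA(tp)) {
    stop("unknown feature name(s): ",
         paste(features[is.na(tp)], collapse = ", "))
  }
  stats::setNames(tp, features)
}
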