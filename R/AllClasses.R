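#' @import methods
#' @importFrom stats median pchisq pnorm qnorm rbeta rbinom rexp rmultinom
#'   rnbinom runif sd setNames t.test
#' @importFrom utils read.delim write.table
NULL

EFFECT_LEVELS <- c("missense", "synonymous", "splice", "nonsense", "other")
ARM_LEVELS <- c("docetaxel", "atezolizumab")
SEX_LEVELS <- c("male", "female", "unknown")
SMOKING_LEVELS <- c("smoker", "non_smoker", "unknown")
HISTOLOGY_LEVELS <- c("LUSC", "non_LUSC", "unknown")
DRIVER_LEVELS <- c("positive", "negative", "unknown")
RESPONSE_LEVELS <- c("CR", "PR", "SD", "PD", "NE", "unknown")
CHARACTERISTICS <- c("sex", "smoking", "histology", "driver_gene", "metastases")
BIOMARKERS <- c("btmb", "sbtmb", "ums")

#' MutationCohort: joined ctDNA mutation and clinical tables
#'
#' The universal pipeline input: a clinical table (one row per patient,
#' survival endpoints plus stratification covariates) and a somatic mutation
#' table from ctDNA sequencing (one row per called mutation, classified as
#' missense / synonymous / splice / nonsense / other). Every mutation's
#' patient must exist in the clinical table; patients with zero mutation rows
#' are legal and later receive burden 0.
#'
#' @slot clinical data.frame with columns patient_id, arm, cohort, sex,
#'   smoking, histology, driver_gene, metastasis_sites, os_months, os_event,
#'   pfs_months, pfs_event, best_response.
#' @slot mutations data.frame with columns patient_id, gene, effect.
#' @slot provenance free-text label recording where the tables came from.
#' @export
setClass("MutationCohort",
  representation(clinical = "data.frame", mutations = "data.frame",
                 provenance = "character"))

setValidity("MutationCohort", function(object) {
  cl <- object@clinical
  mu <- object@mutations
  msgs <- character()
  need <- c("patient_id", "arm", "cohort", "sex", "smoking", "histology",
            "driver_gene", "metastasis_sites", "os_months", "os_event",
            "pfs_months", "pfs_event", "best_response")
  miss <- setdiff(need, names(cl))
  if (length(miss))
    msgs <- c(msgs, paste("clinical lacks columns:", paste(miss, collapse = ", ")))
  else {
    if (anyDuplicated(cl$patient_id))
      msgs <- c(msgs, "duplicate patient_id in clinical table")
    if (any(cl$os_months < 0, na.rm = TRUE) || any(cl$pfs_months < 0, na.rm = TRUE))
      msgs <- c(msgs, "negative survival times")
  }
  needm <- c("patient_id", "gene", "effect")
  missm <- setdiff(needm, names(mu))
  if (length(missm))
    msgs <- c(msgs, paste("mutations lacks columns:", paste(missm, collapse = ", ")))
  else {
    if (nrow(mu)) {
      if (!all(mu$effect %in% EFFECT_LEVELS))
        msgs <- c(msgs, "mutation effect outside the allowed vocabulary")
      if (any(!nzchar(mu$gene)))
        msgs <- c(msgs, "empty gene symbol in mutation table")
      if (length(miss) == 0 && !all(mu$patient_id %in% cl$patient_id))
        msgs <- c(msgs, "mutation rows reference patients absent from clinical")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn MutationCohort number of patients
#' @param x,object a MutationCohort
#' @export
setMethod("length", "MutationCohort", function(x) nrow(x@clinical))

setMethod("show", "MutationCohort", function(object) {
  cat("MutationCohort:", nrow(object@clinical), "patients,",
      nrow(object@mutations), "mutations\n")
  if (nrow(object@clinical)) {
    cat("  arms:", paste(names(table(object@clinical$arm)),
                         table(object@clinical$arm), collapse = ", "), "\n")
  }
  if (nzchar(object@provenance))
    cat("  provenance:", object@provenance, "\n")
})

#' @describeIn MutationCohort clinical table accessor
#' @export
clinicalData <- function(object) object@clinical

#' @describeIn MutationCohort mutation table accessor
#' @export
mutationData <- function(object) object@mutations

#' @describeIn MutationCohort patient identifiers
#' @export
patientIDs <- function(object) object@clinical$patient_id

#' BiomarkerCutoff: a fitted log-rank-optimal stratification rule
#'
#' Either a single threshold (responders are \code{value <= c1}) or a dual
#' "low-or-high vs middle" rule for U-shaped responses
#' (responders are \code{value <= c1 | value > c2}). Carries the full scan
#' trace (every admissible cut-off with its log-rank p) for diagnostics.
#'
#' @slot biomarker biomarker name scanned.
#' @slot shape "single" or "dual".
#' @slot c1,c2 the fitted thresholds; c2 is NA for single rules.
#' @slot responder_rule human-readable rule string.
#' @slot p_min log-rank p at the chosen cut-off(s).
#' @slot endpoint "OS" or "PFS".
#' @slot scan_trace data.frame of candidate cut-offs and their p-values.
#' @export
setClass("BiomarkerCutoff",
  representation(biomarker = "character", shape = "character",
                 c1 = "numeric", c2 = "numeric", responder_rule = "character",
                 p_min = "numeric", endpoint = "character",
                 scan_trace = "data.frame"))

setValidity("BiomarkerCutoff", function(object) {
  msgs <- character()
  if (!object@shape %in% c("single", "dual"))
    msgs <- c(msgs, "shape must be 'single' or 'dual'")
  if (object@shape == "dual" && !(is.finite(object@c2) && object@c1 < object@c2))
    msgs <- c(msgs, "dual shape requires c1 < c2")
  if (nrow(object@scan_trace) &&
      abs(object@p_min - min(object@scan_trace$p)) > 1e-12)
    msgs <- c(msgs, "p_min does not equal the minimum p of the scan trace")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "BiomarkerCutoff", function(object) {
  cat("BiomarkerCutoff [", object@biomarker, ", ", object@endpoint, "]\n",
      sep = "")
  cat("  rule:", object@responder_rule, "\n")
  cat("  log-rank p:", format(object@p_min, digits = 4),
      " (", nrow(object@scan_trace), " candidates scanned)\n", sep = "")
})

#' @describeIn BiomarkerCutoff fitted threshold(s): c1, and c2 for dual rules
#' @param object a BiomarkerCutoff
#' @export
cutoffValues <- function(object) {
  if (object@shape == "dual") c(c1 = object@c1, c2 = object@c2)
  else c(c1 = object@c1)
}

#' @describeIn BiomarkerCutoff the scan diagnostics table
#' @export
scanTrace <- function(object) object@scan_trace

#' UnfavourableGeneTable: genes surviving per-gene survival screening
#'
#' Genes whose carriers have worse survival (log-rank p < 0.3 and
#' carrier-vs-non-carrier Mantel-Haenszel hazard ratio > 1), each assigned a
#' 1-5 score by binning its p-value. Defines the unfavourable mutation score
#' (UMS): a patient's UMS is the sum of scores of the distinct retained genes
#' they carry.
#'
#' @slot table data.frame (gene, carriers, p_value, carrier_hr, score).
#' @slot arm trial arm the screen was run on.
#' @slot endpoint endpoint used ("OS" or "PFS").
#' @export
setClass("UnfavourableGeneTable",
  representation(table = "data.frame", arm = "character",
                 endpoint = "character"))

setValidity("UnfavourableGeneTable", function(object) {
  tb <- object@table
  msgs <- character()
  need <- c("gene", "carriers", "p_value", "carrier_hr", "score")
  if (!all(need %in% names(tb)))
    msgs <- c(msgs, "table lacks required columns")
  else if (nrow(tb)) {
    if (any(tb$p_value >= 0.3)) msgs <- c(msgs, "retained gene with p >= 0.3")
    if (any(tb$carrier_hr <= 1)) msgs <- c(msgs, "retained gene with HR <= 1")
    if (any(tb$score != scoreFromP(tb$p_value)))
      msgs <- c(msgs, "score inconsistent with p-value binning")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "UnfavourableGeneTable", function(object) {
  cat("UnfavourableGeneTable:", nrow(object@table), "genes retained (",
      object@arm, ",", object@endpoint, ")\n")
  if (nrow(object@table)) {
    print(utils::head(object@table[order(object@table$p_value), ], 5),
          row.names = FALSE)
    if (nrow(object@table) > 5) cat("  ...\n")
  }
})

#' @describeIn UnfavourableGeneTable the screening table as a data.frame
#' @param object an UnfavourableGeneTable
#' @export
geneTable <- function(object) object@table

#' TMIModel: the composite tumour mutation index
#'
#' Per (clinical characteristic stratum x biomarker) fitted cut-offs and
#' hazard ratios, the HR-score rule, and the discovery-cohort median TMI used
#' as the frozen low/high threshold. Fit on a discovery cohort with
#' \code{\link{fitTMI}}; applied frozen with \code{\link{applyTMI}}.
#'
#' @slot arm the arm the model was fitted on.
#' @slot endpoint endpoint driving component fitting.
#' @slot components data.frame with one row per fitted component
#'   (characteristic, stratum, biomarker, shape, c1, c2, hr, n_stratum).
#' @slot skipped data.frame of (characteristic, stratum, biomarker, reason)
#'   for components that could not be fitted.
#' @slot score_rule identifier of the scoring rule ("hr_if_responder").
#' @slot median_threshold discovery-cohort median TMI; scores <= threshold
#'   are labelled low.
#' @export
setClass("TMIModel",
  representation(arm = "character", endpoint = "character",
                 components = "data.frame", skipped = "data.frame",
                 score_rule = "character", median_threshold = "numeric"))

setValidity("TMIModel", function(object) {
  msgs <- character()
  cp <- object@components
  need <- c("characteristic", "stratum", "biomarker", "shape", "c1", "c2",
            "hr", "n_stratum")
  if (!all(need %in% names(cp)))
    msgs <- c(msgs, "components lacks required columns")
  else if (nrow(cp)) {
    key <- paste(cp$characteristic, cp$stratum, cp$biomarker)
    if (anyDuplicated(key))
      msgs <- c(msgs, "duplicate (characteristic, stratum, biomarker) component")
    if (any(!is.finite(cp$hr)) || any(cp$hr <= 0))
      msgs <- c(msgs, "component HR must be finite and positive")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TMIModel", function(object) {
  cat("TMIModel (", object@arm, ", ", object@endpoint, ")\n", sep = "")
  cat("  components:", nrow(object@components), "fitted,",
      nrow(object@skipped), "skipped\n")
  cat("  score rule:", object@score_rule, "\n")
  cat("  median TMI threshold:", format(object@median_threshold, digits = 5),
      "\n")
})

#' @describeIn TMIModel the fitted component table
#' @param object a TMIModel
#' @export
tmiComponents <- function(object) object@components

#' @describeIn TMIModel the frozen discovery-median threshold
#' @export
tmiThreshold <- function(object) object@median_threshold
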