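# Readers, validators and subsetters for the two pipeline input tables.
# TSV is the canonical mutation dialect; MAF column/class mapping is a
# convenience layer with an overridable mapping table.

#' Default MAF Variant_Classification -> effect-class mapping
#'
#' Maps MAF variant classes onto the five effect classes used by the burden
#' scores. Any class not listed maps to \code{other} (counted in neither bTMB
#' nor sbTMB), never dropped. Pass a modified copy to
#' \code{\link{readMutations}} to override.
#'
#' @return named character vector, MAF class -> effect class.
#' @export
mafEffectMap <- function() {
  c(Missense_Mutation = "missense",
    Silent = "synonymous",
    Splice_Site = "splice",
    Splice_Region = "splice",
    Nonsense_Mutation = "nonsense")
}

#' Read a somatic mutation table
#'
#' @param path path to a tab-separated file. The \code{simple_tsv} dialect
#'   needs columns patient_id, gene, effect; the \code{maf} dialect needs
#'   Tumor_Sample_Barcode, Hugo_Symbol, Variant_Classification.
#' @param dialect "simple_tsv" or "maf".
#' @param effectMap named vector mapping raw MAF classes to effect classes
#'   (default \code{\link{mafEffectMap}}); unmapped classes become "other".
#' @return data.frame (patient_id, gene, effect), one row per mutation.
#'   Unknown effect labels map to "other" with a warning, never dropped.
#' @export
readMutations <- function(path, dialect = c("simple_tsv", "maf"),
                          effectMap = mafEffectMap()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("mutation file not found: ", path)
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  cols <- switch(dialect,
    simple_tsv = c(patient_id = "patient_id", gene = "gene", effect = "effect"),
    maf = c(patient_id = "Tumor_Sample_Barcode", gene = "Hugo_Symbol",
            effect = "Variant_Classification"))
  miss <- setdiff(unname(cols), names(raw))
  if (length(miss))
    stop("mutation table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (nrow(raw) == 0) {
    warning("empty mutation table: ", path)
    return(data.frame(patient_id = character(), gene = character(),
                      effect = character(), stringsAsFactors = FALSE))
  }
  out <- data.frame(patient_id = as.character(raw[[cols["patient_id"]]]),
                    gene = as.character(raw[[cols["gene"]]]),
                    effect = as.character(raw[[cols["effect"]]]),
                    stringsAsFactors = FALSE)
  if (dialect == "maf") {
    mapped <- unname(effectMap[out$effect])
    mapped[is.na(mapped)] <- "other"
    out$effect <- mapped
  } else {
    eff <- tolower(trimws(out$effect))
    bad <- !eff %in% EFFECT_LEVELS
    if (any(bad)) {
      warning(sum(bad), " mutation row(s) with unknown effect label mapped ",
              "to 'other' (e.g. '", out$effect[which(bad)[1]], "')")
      eff[bad] <- "other"
    }
    out$effect <- eff
  }
  if (any(!nzchar(out$gene))) stop("empty gene symbol in mutation table")
  out
}

.CLIN_VOCAB <- list(
  arm = ARM_LEVELS,
  sex = SEX_LEVELS,
  smoking = SMOKING_LEVELS,
  histology = HISTOLOGY_LEVELS,
  driver_gene = DRIVER_LEVELS,
  best_response = RESPONSE_LEVELS)

.foldCategorical <- function(x, field, levels) {
  val <- tolower(trimws(as.character(x)))
  canon <- setNames(levels, tolower(levels))
  out <- unname(canon[val])
  out[is.na(x) | val == ""] <- "unknown"
  bad <- is.na(out)
  if (any(bad)) {
    warning(sum(bad), " unparseable value(s) in '", field,
            "' set to unknown (e.g. '", x[which(bad)[1]], "')")
    out[bad] <- "unknown"
  }
  out
}

.parseFlag <- function(x, field) {
  val <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(val))
  out[val %in% c("1", "true", "t", "yes", "event", "dead", "progressed")] <- TRUE
  out[val %in% c("0", "false", "f", "no", "censored", "alive")] <- FALSE
  if (anyNA(out)) stop("unparseable event flag in column '", field, "'")
  out
}

#' Read a clinical table
#'
#' Tab-separated, one row per patient. Required columns: patient_id, arm,
#' os_months, os_event, pfs_months, pfs_event. Optional columns (cohort, sex,
#' smoking, histology, driver_gene, metastasis_sites, best_response) default
#' to unknown. Categorical values are matched case-insensitively against the
#' documented vocabulary; anything else becomes unknown with a warning.
#'
#' @param path path to the TSV file.
#' @return data.frame with the full clinical schema (one row per patient).
#' @export
readClinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("patient_id", "arm", "os_months", "os_event", "pfs_months",
            "pfs_event")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("clinical table is missing required column(s): ",
         paste(miss, collapse = ", "))
  id <- as.character(raw$patient_id)
  if (anyDuplicated(id))
    stop("duplicate patient_id in clinical table: ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  osm <- as.numeric(raw$os_months)
  pfm <- as.numeric(raw$pfs_months)
  if (any(is.na(osm)) || any(is.na(pfm)))
    stop("non-numeric survival time in clinical table")
  if (any(osm < 0) || any(pfm < 0))
    stop("negative survival time in clinical table")
  grab <- function(col) if (col %in% names(raw)) raw[[col]] else NA
  met <- suppressWarnings(as.integer(grab("metastasis_sites")))
  if (any(met < 0, na.rm = TRUE))
    stop("negative metastasis_sites in clinical table")
  out <- data.frame(
    patient_id = id,
    arm = .foldCategorical(raw$arm, "arm", ARM_LEVELS),
    cohort = ifelse(is.na(grab("cohort")), "unlabelled",
                    as.character(grab("cohort"))),
    sex = .foldCategorical(grab("sex"), "sex", SEX_LEVELS),
    smoking = .foldCategorical(grab("smoking"), "smoking", SMOKING_LEVELS),
    histology = .foldCategorical(grab("histology"), "histology",
                                 HISTOLOGY_LEVELS),
    driver_gene = .foldCategorical(grab("driver_gene"), "driver_gene",
                                   DRIVER_LEVELS),
    metastasis_sites = met,
    os_months = osm,
    os_event = .parseFlag(raw$os_event, "os_event"),
    pfs_months = pfm,
    pfs_event = .parseFlag(raw$pfs_event, "pfs_event"),
    best_response = .foldCategorical(grab("best_response"), "best_response",
                                     RESPONSE_LEVELS),
    stringsAsFactors = FALSE)
  if (any(out$arm == "unknown"))
    stop("clinical rows with unrecognised trial arm")
  both <- out$os_event & out$pfs_event
  if (any(out$pfs_months[both] > out$os_months[both]))
    warning("some patients have observed PFS exceeding observed OS; ",
            "retained as given")
  out
}

#' Assemble a MutationCohort from its two tables
#'
#' Mutations referencing patients absent from the clinical table are dropped
#' with a counted warning; patients with zero mutation rows are retained
#' (their burdens compute to 0).
#'
#' @param clinical data.frame from \code{\link{readClinical}} (or equivalent).
#' @param mutations data.frame from \code{\link{readMutations}}.
#' @param provenance free-text label.
#' @return a validated \code{\linkS4class{MutationCohort}}.
#' @export
buildCohort <- function(clinical, mutations, provenance = "") {
  orphan <- !mutations$patient_id %in% clinical$patient_id
  if (any(orphan)) {
    warning(sum(orphan), " mutation row(s) dropped: patient absent from ",
            "the clinical table")
    mutations <- mutations[!orphan, , drop = FALSE]
  }
  rownames(clinical) <- NULL
  rownames(mutations) <- NULL
  new("MutationCohort", clinical = clinical, mutations = mutations,
      provenance = provenance)
}

.SUBGROUPS <- c("male", "female", "smoker", "non_smoker", "LUSC", "non_LUSC",
                "driver_positive", "driver_negative", "met_lt3", "met_ge3")

.subgroupMask <- function(clinical, subgroup) {
  switch(subgroup,
    male = clinical$sex == "male",
    female = clinical$sex == "female",
    smoker = clinical$smoking == "smoker",
    non_smoker = clinical$smoking == "non_smoker",
    LUSC = clinical$histology == "LUSC",
    non_LUSC = clinical$histology == "non_LUSC",
    driver_positive = clinical$driver_gene == "positive",
    driver_negative = clinical$driver_gene == "negative",
    met_lt3 = !is.na(clinical$metastasis_sites) & clinical$metastasis_sites < 3,
    met_ge3 = !is.na(clinical$metastasis_sites) & clinical$metastasis_sites >= 3,
    stop("unknown subgroup: ", subgroup))
}

#' Subgroup selector names
#'
#' The ten clinical subgroups used throughout the stratification analyses:
#' sex, smoking history, histology (LUSC vs non-LUSC), driver-gene status
#' and the metastasis-site dichotomy at <3 vs >=3. Patients with an unknown
#' level of the relevant characteristic belong to no subgroup of it.
#'
#' @return character vector of selector names accepted by
#'   \code{\link{filterCohort}}.
#' @export
subgroupNames <- function() .SUBGROUPS

#' Restrict a cohort to a trial arm and/or clinical subgroup
#'
#' @param cohort a MutationCohort.
#' @param arm optional: "docetaxel" or "atezolizumab".
#' @param subgroup optional: one of \code{\link{subgroupNames}}.
#' @return the sub-cohort, with mutations restricted to retained patients.
#'   An empty result is returned as an empty cohort, not an error.
#' @export
filterCohort <- function(cohort, arm = NULL, subgroup = NULL) {
  cl <- cohort@clinical
  keep <- rep(TRUE, nrow(cl))
  if (!is.null(arm)) {
    arm <- match.arg(arm, ARM_LEVELS)
    keep <- keep & cl$arm == arm
  }
  if (!is.null(subgroup)) keep <- keep & .subgroupMask(cl, subgroup)
  cl <- cl[keep, , drop = FALSE]
  if (nrow(cl) == 0)
    warning("filter produced an empty cohort")
  mu <- cohort@mutations
  mu <- mu[mu$patient_id %in% cl$patient_id, , drop = FALSE]
  rownames(cl) <- NULL
  rownames(mu) <- NULL
  new("MutationCohort", clinical = cl, mutations = mu,
      provenance = cohort@provenance)
}

#' Write a cohort back to its two TSV tables
#'
#' Inverse of \code{\link{readClinical}} / \code{\link{readMutations}}
#' (simple_tsv dialect): reading the written files reproduces the tables.
#'
#' @param cohort a MutationCohort.
#' @param clinicalPath,mutationsPath output TSV paths.
#' @return invisibly, the two paths.
#' @export
writeCohort <- function(cohort, clinicalPath, mutationsPath) {
  write.table(cohort@clinical, clinicalPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort@mutations, mutationsPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(clinicalPath, mutationsPath))
}
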