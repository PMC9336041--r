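# The composite tumour mutation index (TMI).
#
# Fitting: within each stratum of each of the five clinical characteristics
# (sex, smoking, histology, driver-gene status, metastasis dichotomy), and
# for each of the three biomarkers (bTMB, sbTMB, UMS), the optimal cut-off
# is scanned and the responder-vs-non-responder hazard ratio recorded: one
# component per (characteristic, stratum, biomarker), up to 5 x 2 x 3 = 30.
#
# Scoring ("hr_if_responder" rule): a patient accumulates, for each
# (characteristic, biomarker) pair, the component HR of their own stratum
# when they satisfy that component's responder rule, and 1.0 otherwise
# (also 1.0 when the characteristic is unknown or the component was
# skipped). The TMI is the sum of the 15 terms; with favourable components
# (HR < 1) a lower TMI means a better predicted prognosis. Patients are
# split at the discovery-cohort median TMI (ties to low), and that
# threshold is frozen for validation cohorts.

.STRATA <- list(
  sex = c("male", "female"),
  smoking = c("smoker", "non_smoker"),
  histology = c("LUSC", "non_LUSC"),
  driver_gene = c("positive", "negative"),
  metastases = c("lt3", "ge3"))

.stratumOf <- function(clinical, characteristic) {
  if (characteristic == "metastases") {
    m <- clinical$metastasis_sites
    ifelse(is.na(m), "unknown", ifelse(m < 3, "lt3", "ge3"))
  } else {
    clinical[[characteristic]]
  }
}

.biomarkerMatrix <- function(cohort, burdens, ums) {
  cl <- cohort@clinical
  bi <- match(cl$patient_id, burdens$patient_id)
  ui <- match(cl$patient_id, ums$patient_id)
  if (anyNA(bi)) stop("biomarker value missing: btmb/sbtmb for some patients")
  if (anyNA(ui)) stop("biomarker value missing: ums for some patients")
  cbind(btmb = burdens$btmb[bi], sbtmb = burdens$sbtmb[bi],
        ums = ums$ums[ui])
}

#' Fit a TMI model on a discovery cohort
#'
#' @param discovery a MutationCohort restricted to one trial arm.
#' @param burdens data.frame from \code{\link{computeBurdens}} on the same
#'   cohort.
#' @param ums data.frame from \code{\link{computeUMS}}.
#' @param shapes named character vector giving the scan shape per biomarker
#'   ("single" or "dual"); default all "single" (the chemotherapy-style
#'   monotone response). Dual is the usual choice for checkpoint-inhibitor
#'   bTMB/sbTMB.
#' @param endpoint endpoint driving component fitting; "OS" default.
#' @param minStratum strata smaller than this are skipped with a flag
#'   (default 20).
#' @param minGroupFrac group floor forwarded to the scans.
#' @return a \code{\linkS4class{TMIModel}} with the frozen discovery-median
#'   threshold.
#' @export
fitTMI <- function(discovery, burdens, ums,
                   shapes = c(btmb = "single", sbtmb = "single",
                              ums = "single"),
                   endpoint = c("OS", "PFS"), minStratum = 20,
                   minGroupFrac = 0.10) {
  endpoint <- match.arg(endpoint)
  cl <- discovery@clinical
  arms <- unique(cl$arm)
  if (length(arms) != 1)
    stop("fitTMI requires a cohort restricted to one trial arm")
  stopifnot(all(BIOMARKERS %in% names(shapes)),
            all(shapes %in% c("single", "dual")))
  bm <- .biomarkerMatrix(discovery, burdens, ums)
  comps <- list(); skips <- list()
  for (ch in CHARACTERISTICS) {
    levs <- .stratumOf(cl, ch)
    for (st in .STRATA[[ch]]) {
      inStratum <- levs == st
      for (b in BIOMARKERS) {
        key <- paste(ch, st, b)
        if (sum(inStratum) < minStratum) {
          skips[[key]] <- data.frame(characteristic = ch, stratum = st,
                                     biomarker = b, reason = "stratum too small",
                                     stringsAsFactors = FALSE)
          next
        }
        sub <- filterCohortMask(discovery, inStratum)
        vals <- bm[inStratum, b]
        comp <- tryCatch({
          scan <- if (shapes[[b]] == "dual") scanDualCutoff else scanSingleCutoff
          co <- scan(vals, sub, endpoint = endpoint,
                     minGroupFrac = minGroupFrac, biomarker = b)
          resp <- labelResponders(vals, co)
          if (!any(resp) || all(resp)) stop("degenerate responder split")
          cmp <- compareGroups(sub, resp, endpoint = endpoint)
          if (!is.finite(cmp$hr) || cmp$hr <= 0) stop("HR undefined in stratum")
          data.frame(characteristic = ch, stratum = st, biomarker = b,
                     shape = co@shape, c1 = co@c1, c2 = co@c2, hr = cmp$hr,
                     n_stratum = sum(inStratum), stringsAsFactors = FALSE)
        }, error = function(e) e)
        if (inherits(comp, "error")) {
          skips[[key]] <- data.frame(characteristic = ch, stratum = st,
                                     biomarker = b,
                                     reason = conditionMessage(comp),
                                     stringsAsFactors = FALSE)
        } else comps[[key]] <- comp
      }
    }
  }
  if (length(comps) == 0) stop("no TMI component could be fitted")
  components <- do.call(rbind, comps); rownames(components) <- NULL
  skipped <- if (length(skips)) do.call(rbind, skips) else
    data.frame(characteristic = character(), stratum = character(),
               biomarker = character(), reason = character(),
               stringsAsFactors = FALSE)
  rownames(skipped) <- NULL
  model <- new("TMIModel", arm = arms, endpoint = endpoint,
               components = components, skipped = skipped,
               score_rule = "hr_if_responder", median_threshold = NA_real_)
  tmis <- .tmiValues(model, cl, bm)
  model@median_threshold <- median(tmis)
  validObject(model)
  model
}

# subset a cohort by a logical mask over clinical rows
filterCohortMask <- function(cohort, mask) {
  cl <- cohort@clinical[mask, , drop = FALSE]
  mu <- cohort@mutations
  mu <- mu[mu$patient_id %in% cl$patient_id, , drop = FALSE]
  rownames(cl) <- NULL; rownames(mu) <- NULL
  new("MutationCohort", clinical = cl, mutations = mu,
      provenance = cohort@provenance)
}

.tmiValues <- function(model, clinical, bm) {
  cp <- model@components
  n <- nrow(clinical)
  tmi <- rep(0, n)
  for (ch in CHARACTERISTICS) {
    levs <- .stratumOf(clinical, ch)
    for (b in BIOMARKERS) {
      term <- rep(1.0, n)
      for (st in .STRATA[[ch]]) {
        row <- cp[cp$characteristic == ch & cp$stratum == st &
                  cp$biomarker == b, , drop = FALSE]
        if (nrow(row) == 0) next
        inStratum <- levs == st
        resp <- if (row$shape == "single") bm[, b] <= row$c1
                else bm[, b] <= row$c1 | bm[, b] > row$c2
        term[inStratum & resp] <- row$hr
      }
      tmi <- tmi + term
    }
  }
  tmi
}

#' Score patients with a fitted TMI model
#'
#' Applies the model's "hr_if_responder" rule and the frozen
#' discovery-median threshold; label is "low" when tmi <= threshold.
#'
#' @param model a \code{\linkS4class{TMIModel}}.
#' @param cohort a MutationCohort on the model's arm.
#' @param burdens,ums per-patient biomarker tables for this cohort.
#' @return data.frame (patient_id, tmi, label).
#' @export
tmiScores <- function(model, cohort, burdens, ums) {
  cl <- cohort@clinical
  bm <- .biomarkerMatrix(cohort, burdens, ums)
  tmi <- .tmiValues(model, cl, bm)
  data.frame(patient_id = cl$patient_id, tmi = tmi,
             label = ifelse(tmi <= model@median_threshold, "low", "high"),
             stringsAsFactors = FALSE)
}

#' Apply a frozen TMI model to a cohort
#'
#' Scores every patient with the discovery-median threshold (no re-fitting)
#' and compares the low- vs high-TMI groups on the model's endpoint.
#'
#' @inheritParams tmiScores
#' @param endpoint endpoint for the low-vs-high comparison; defaults to the
#'   model's fitting endpoint.
#' @return list(scores = per-patient data.frame, comparison = one-row
#'   low-vs-high \code{\link{compareGroups}} summary).
#' @export
applyTMI <- function(model, cohort, burdens, ums, endpoint = NULL) {
  armsC <- unique(cohort@clinical$arm)
  if (length(armsC) != 1 || armsC != model@arm)
    stop("cohort arm (", paste(armsC, collapse = ","),
         ") does not match model arm (", model@arm, ")")
  if (is.null(endpoint)) endpoint <- model@endpoint
  sc <- tmiScores(model, cohort, burdens, ums)
  cmp <- compareGroups(cohort, sc$label == "low", endpoint = endpoint)
  list(scores = sc, comparison = cmp)
}

#' Persist a TMI model as structured text
#'
#' Writes a versioned YAML file portable between discovery and validation
#' runs; \code{\link{readTMIModel}} restores an identical model.
#'
#' @param model a TMIModel.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeTMIModel <- function(model, path) {
  obj <- list(schema = "tmistrat-model/1", arm = model@arm,
              endpoint = model@endpoint, score_rule = model@score_rule,
              median_threshold = model@median_threshold,
              components = lapply(seq_len(nrow(model@components)), function(i)
                as.list(model@components[i, ])),
              skipped = lapply(seq_len(nrow(model@skipped)), function(i)
                as.list(model@skipped[i, ])))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname writeTMIModel
#' @export
readTMIModel <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$schema) || obj$schema != "tmistrat-model/1")
    stop("not a TMI model file (schema mismatch): ", path)
  bindRows <- function(lst, template) {
    if (length(lst) == 0) return(template)
    df <- do.call(rbind, lapply(lst, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
    df$c2 <- if ("c2" %in% names(df)) as.numeric(df$c2) else df$c2
    df
  }
  compTemplate <- data.frame(characteristic = character(),
                             stratum = character(), biomarker = character(),
                             shape = character(), c1 = numeric(),
                             c2 = numeric(), hr = numeric(),
                             n_stratum = integer(), stringsAsFactors = FALSE)
  skipTemplate <- data.frame(characteristic = character(),
                             stratum = character(), biomarker = character(),
                             reason = character(), stringsAsFactors = FALSE)
  new("TMIModel", arm = obj$arm, endpoint = obj$endpoint,
      components = bindRows(obj$components, compTemplate),
      skipped = bindRows(obj$skipped, skipTemplate),
      score_rule = obj$score_rule,
      median_threshold = as.numeric(obj$median_threshold))
}
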