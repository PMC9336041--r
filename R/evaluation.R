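# Responder-prediction ROC/AUC, landmark outcomes, subgroup HR tables,
# burden-by-response comparison and clinical-efficacy summaries.

#' ROC curve and AUC for responder prediction
#'
#' Threshold sweep over the score values; AUC by the trapezoid rule with a
#' rank-based large-sample (DeLong) confidence interval and a null test of
#' AUC = 0.5 from the same variance estimate. The orientation is chosen so
#' that AUC >= 0.5 means "higher score predicts the positive class"; the
#' applied orientation is reported.
#'
#' @param scores per-patient real-valued scores.
#' @param outcome per-patient binary outcome (logical or 0/1).
#' @param conf confidence level (default 0.95).
#' @return list(auc, ci_low, ci_high, p_null, n_pos, n_neg, orientation,
#'   curve) where curve is a data.frame (fpr, tpr) from (0,0) to (1,1).
#' @export
rocAuc <- function(scores, outcome, conf = 0.95) {
  outcome <- as.logical(outcome)
  if (length(scores) != length(outcome) || anyNA(scores) || anyNA(outcome))
    stop("scores and outcome must be complete and of equal length")
  if (!any(outcome) || all(outcome))
    stop("both outcome classes must be present")
  r <- pROC::roc(response = outcome, predictor = scores, quiet = TRUE,
                 direction = "auto", levels = c(FALSE, TRUE))
  auc <- as.numeric(pROC::auc(r))
  v <- suppressWarnings(pROC::var(r, method = "delong"))
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, conf.level = conf,
                                                 method = "delong")))
  z <- if (v > 0) (auc - 0.5) / sqrt(v) else Inf
  curve <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  curve <- curve[order(curve$fpr, curve$tpr), , drop = FALSE]
  rownames(curve) <- NULL
  list(auc = auc, ci_low = max(0, ci[1]), ci_high = min(1, ci[3]),
       p_null = 2 * pnorm(-abs(z)),
       n_pos = sum(outcome), n_neg = sum(!outcome),
       orientation = if (r$direction == "<") "higher_score_positive"
                     else "lower_score_positive",
       curve = curve)
}

#' Landmark survival outcome
#'
#' Positive = survival beyond the landmark (time > landmark, whatever the
#' event flag); negative = event at or before the landmark; patients
#' censored at or before the landmark carry no information and are excluded.
#'
#' @param cohort a MutationCohort.
#' @param endpoint "OS" (default) or "PFS".
#' @param landmarkMonths landmark time in months (> 0); a common choice is
#'   the arm's median OS.
#' @return list(outcome = named logical over included patients,
#'   excluded = patient_ids censored before the landmark).
#' @export
defineOutcome <- function(cohort, endpoint = c("OS", "PFS"),
                          landmarkMonths) {
  endpoint <- match.arg(endpoint)
  if (landmarkMonths <= 0) stop("landmarkMonths must be positive")
  cl <- cohort@clinical
  tm <- if (endpoint == "OS") cl$os_months else cl$pfs_months
  ev <- if (endpoint == "OS") cl$os_event else cl$pfs_event
  excluded <- tm <= landmarkMonths & !ev
  if (all(excluded)) stop("every patient is censored before the landmark")
  outcome <- setNames(tm > landmarkMonths, cl$patient_id)[!excluded]
  list(outcome = outcome, excluded = cl$patient_id[excluded])
}

#' Hazard-ratio table over the clinical subgroups
#'
#' One \code{\link{compareGroups}} row per subgroup (the ten clinical
#' subgroups plus "all"), comparing the two label groups on the endpoint.
#' Subgroups with fewer than \code{minPerGroup} patients in either label
#' group are flagged, not computed.
#'
#' @param cohort a MutationCohort.
#' @param labels logical per patient (TRUE = group A, e.g. responder),
#'   aligned with or named by patient_id.
#' @param endpoint "OS" or "PFS".
#' @param minPerGroup minimum patients per comparison arm (default 10).
#' @return data.frame (subgroup, n, n_a, n_b, hr, ci_low, ci_high, p,
#'   flagged).
#' @export
subgroupHRTable <- function(cohort, labels, endpoint = c("OS", "PFS"),
                            minPerGroup = 10) {
  endpoint <- match.arg(endpoint)
  cl <- cohort@clinical
  if (!is.null(names(labels))) labels <- labels[cl$patient_id]
  if (length(labels) != nrow(cl) || anyNA(labels))
    stop("labels must cover every patient in the cohort")
  names(labels) <- cl$patient_id
  rows <- lapply(c("all", subgroupNames()), function(sg) {
    mask <- if (sg == "all") rep(TRUE, nrow(cl)) else .subgroupMask(cl, sg)
    la <- labels[mask]
    base <- data.frame(subgroup = sg, n = sum(mask), n_a = sum(la),
                       n_b = sum(!la), hr = NA_real_, ci_low = NA_real_,
                       ci_high = NA_real_, p = NA_real_, flagged = TRUE,
                       stringsAsFactors = FALSE)
    if (sum(la) < minPerGroup || sum(!la) < minPerGroup) return(base)
    sub <- filterCohortMask(cohort, mask)
    cmp <- tryCatch(compareGroups(sub, la, endpoint = endpoint),
                    error = function(e) NULL)
    if (is.null(cmp)) return(base)
    base$hr <- cmp$hr; base$ci_low <- cmp$hr_ci_low
    base$ci_high <- cmp$hr_ci_high; base$p <- cmp$p_value
    base$flagged <- FALSE
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare mutation burden between responders and non-responders
#'
#' Unpaired two-sample t test on the burden values between the two label
#' groups (classical equal-variance t by default, matching the usual
#' "unpaired t test"; Welch available).
#'
#' @param burdenValues per-patient burden values.
#' @param labels logical per patient; TRUE = responder.
#' @param welch use the Welch (unequal-variance) form (default FALSE).
#' @return list(t, df, p_value, mean_responders, mean_nonresponders,
#'   flagged).
#' @export
burdenByResponse <- function(burdenValues, labels, welch = FALSE) {
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("both label groups must be non-empty")
  a <- burdenValues[labels]; b <- burdenValues[!labels]
  ma <- mean(a); mb <- mean(b)
  if ((length(a) < 2 || sd(a) == 0) && (length(b) < 2 || sd(b) == 0)) {
    if (length(a) == 1 && length(b) == 1) {
      warning("one patient per group: zero degrees of freedom, p undefined")
      return(list(t = NA_real_, df = 0, p_value = NA_real_,
                  mean_responders = ma, mean_nonresponders = mb,
                  flagged = TRUE))
    }
    if (isTRUE(all.equal(sd(c(a - ma, b - mb)), 0))) {
      warning("zero variance in both groups; p set to 1")
      return(list(t = 0, df = length(a) + length(b) - 2, p_value = 1,
                  mean_responders = ma, mean_nonresponders = mb,
                  flagged = TRUE))
    }
  }
  tt <- t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_responders = ma, mean_nonresponders = mb,
       flagged = FALSE)
}

#' Clinical-efficacy summary by label group
#'
#' Counts of best response CR/PR/SD/PD/NE per label group, with rates over
#' the evaluable patients (CR+PR+SD+PD); unknowns are excluded and counted.
#'
#' @param cohort a MutationCohort with best_response populated.
#' @param labels logical per patient; TRUE = e.g. low-TMI group.
#' @return data.frame with one row per (group, response) giving count and
#'   rate (NA rate for NE and when no patient is evaluable), plus an
#'   n_unknown attribute per group in the "unknown_excluded" attribute.
#' @export
efficacySummary <- function(cohort, labels) {
  cl <- cohort@clinical
  if (!is.null(names(labels))) labels <- labels[cl$patient_id]
  if (length(labels) != nrow(cl) || anyNA(labels))
    stop("labels must cover every patient in the cohort")
  if (all(cl$best_response == "unknown"))
    stop("best_response is unknown for every patient")
  cats <- c("CR", "PR", "SD", "PD", "NE")
  rows <- lapply(c(TRUE, FALSE), function(g) {
    br <- cl$best_response[labels == g]
    cnt <- table(factor(br, levels = cats))
    evaluable <- sum(cnt[c("CR", "PR", "SD", "PD")])
    data.frame(group = if (g) "A" else "B", response = cats,
               count = as.integer(cnt),
               rate = ifelse(cats == "NE", NA_real_,
                             if (evaluable > 0) as.integer(cnt) / evaluable
                             else NA_real_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "unknown_excluded") <-
    c(A = sum(cl$best_response[labels] == "unknown"),
      B = sum(cl$best_response[!labels] == "unknown"))
  out
}
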