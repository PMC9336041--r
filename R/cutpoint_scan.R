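# Optimal biomarker cut-offs by exhaustive log-rank p minimisation.
#
# Single rule: responders are (value <= c1). Dual rule, for U-shaped
# responses seen with checkpoint-inhibitor burden biomarkers: responders are
# (value <= c1 OR value > c2), non-responders the middle band. The dual
# search enumerates every admissible pair of observed values, which subsumes
# sequential first-then-second-cut-off heuristics. Scanning p-values carry
# the usual optimal-cutpoint selection bias; no multiplicity correction is
# applied (a permutation-adjusted p is available separately).

.endpointFields <- function(cohort, endpoint) {
  cl <- cohort@clinical
  if (endpoint == "OS") list(time = cl$os_months, event = cl$os_event)
  else list(time = cl$pfs_months, event = cl$pfs_event)
}

.alignValues <- function(values, cohort) {
  cl <- cohort@clinical
  if (!is.null(names(values))) values <- values[cl$patient_id]
  if (length(values) != nrow(cl) || anyNA(values))
    stop("biomarker values must cover every patient in the cohort")
  unname(values)
}

.scanP <- function(labels, ep) {
  lr <- suppressWarnings(logrankTest(ep$time[labels], ep$event[labels],
                                     ep$time[!labels], ep$event[!labels]))
  lr$p_value
}

#' Scan for the optimal single cut-off
#'
#' Candidates are the distinct observed biomarker values whose induced split
#' (value <= c vs value > c) leaves at least \code{minGroupFrac} of patients
#' in each group. Each candidate is tested with the two-group log-rank test
#' on the chosen endpoint; the returned cut-off minimises p. Ties on p are
#' broken toward the larger responder group, then the smaller c1.
#'
#' @param values per-patient biomarker values (optionally named by
#'   patient_id).
#' @param cohort a MutationCohort.
#' @param endpoint "OS" (default) or "PFS".
#' @param minGroupFrac group-size floor as a fraction of patients, in
#'   (0, 0.5); default 0.10, guarding against degenerate argmins at the
#'   extreme tails.
#' @param biomarker name recorded on the result.
#' @return a \code{\linkS4class{BiomarkerCutoff}} with shape "single" and
#'   the full scan trace.
#' @export
scanSingleCutoff <- function(values, cohort, endpoint = c("OS", "PFS"),
                             minGroupFrac = 0.10, biomarker = "biomarker") {
  endpoint <- match.arg(endpoint)
  if (minGroupFrac <= 0 || minGroupFrac >= 0.5)
    stop("minGroupFrac must lie in (0, 0.5)")
  values <- .alignValues(values, cohort)
  if (length(unique(values)) < 2)
    stop("need at least 2 distinct biomarker values to scan")
  ep <- .endpointFields(cohort, endpoint)
  n <- length(values)
  floorN <- minGroupFrac * n
  cands <- sort(unique(values))
  nResp <- vapply(cands, function(c) sum(values <= c), 0L)
  ok <- nResp >= floorN & (n - nResp) >= floorN
  if (!any(ok)) stop("no admissible cut-off candidate under the group floor")
  cands <- cands[ok]
  nResp <- nResp[ok]
  p <- vapply(cands, function(c) .scanP(values <= c, ep), 0)
  trace <- data.frame(c1 = cands, n_responders = nResp, p = p)
  best <- order(p, -nResp, cands)[1]
  new("BiomarkerCutoff", biomarker = biomarker, shape = "single",
      c1 = cands[best], c2 = NA_real_,
      responder_rule = sprintf("value <= %g", cands[best]),
      p_min = p[best], endpoint = endpoint, scan_trace = trace)
}

#' Scan for the optimal dual (U-shaped) cut-off pair
#'
#' Exhaustive grid over ordered pairs c1 < c2 of distinct observed values;
#' responders are (value <= c1 OR value > c2), non-responders the middle
#' band, with the group-size floor applied to both groups. Returns the
#' argmin-p pair; ties break toward the larger responder group, then the
#' smaller c1, then the smaller c2. With c2 = max(values) the rule reduces
#' exactly to the single cut-off at c1.
#'
#' @inheritParams scanSingleCutoff
#' @return a \code{\linkS4class{BiomarkerCutoff}} with shape "dual".
#' @export
scanDualCutoff <- function(values, cohort, endpoint = c("OS", "PFS"),
                           minGroupFrac = 0.10, biomarker = "biomarker") {
  endpoint <- match.arg(endpoint)
  if (minGroupFrac <= 0 || minGroupFrac >= 0.5)
    stop("minGroupFrac must lie in (0, 0.5)")
  values <- .alignValues(values, cohort)
  uv <- sort(unique(values))
  if (length(uv) < 3)
    stop("need at least 3 distinct biomarker values for a dual scan")
  ep <- .endpointFields(cohort, endpoint)
  n <- length(values)
  floorN <- minGroupFrac * n
  pairs <- expand.grid(c1 = uv, c2 = uv)
  pairs <- pairs[pairs$c1 < pairs$c2, , drop = FALSE]
  nResp <- mapply(function(a, b) sum(values <= a | values > b),
                  pairs$c1, pairs$c2)
  ok <- nResp >= floorN & (n - nResp) >= floorN
  if (!any(ok)) stop("no admissible cut-off pair under the group floor")
  pairs <- pairs[ok, , drop = FALSE]
  nResp <- nResp[ok]
  p <- mapply(function(a, b) .scanP(values <= a | values > b, ep),
              pairs$c1, pairs$c2)
  trace <- data.frame(c1 = pairs$c1, c2 = pairs$c2, n_responders = nResp,
                      p = p)
  rownames(trace) <- NULL
  best <- order(p, -nResp, pairs$c1, pairs$c2)[1]
  new("BiomarkerCutoff", biomarker = biomarker, shape = "dual",
      c1 = pairs$c1[best], c2 = pairs$c2[best],
      responder_rule = sprintf("value <= %g | value > %g",
                               pairs$c1[best], pairs$c2[best]),
      p_min = p[best], endpoint = endpoint, scan_trace = trace)
}

#' Apply a fitted cut-off rule
#'
#' @param values per-patient biomarker values on the same scale the cut-off
#'   was fitted on.
#' @param cutoff a \code{\linkS4class{BiomarkerCutoff}}.
#' @return logical vector, TRUE = responder. The single rule is inclusive at
#'   c1 (value <= c1); the dual rule is inclusive at c1 and exclusive at c2
#'   (value <= c1 | value > c2), so value == c2 is a non-responder.
#' @export
labelResponders <- function(values, cutoff) {
  stopifnot(is(cutoff, "BiomarkerCutoff"))
  if (cutoff@shape == "single") values <= cutoff@c1
  else values <= cutoff@c1 | values > cutoff@c2
}

#' Permutation-adjusted p-value for a completed scan
#'
#' The scan's minimal p-value is biased by the search; this utility re-runs
#' the identical scan on cohorts with permuted biomarker values and reports
#' the fraction of permutations achieving an equal or smaller minimal p.
#'
#' @param values,cohort,endpoint,minGroupFrac as in the original scan.
#' @param cutoff the fitted BiomarkerCutoff whose p_min is to be adjusted.
#' @param nPerm number of permutations (default 200).
#' @param seed RNG seed for the permutations.
#' @return the adjusted p-value (add-one permutation estimate).
#' @export
permutationAdjustedP <- function(values, cohort, cutoff,
                                 endpoint = c("OS", "PFS"),
                                 minGroupFrac = 0.10, nPerm = 200,
                                 seed = 1L) {
  endpoint <- match.arg(endpoint)
  values <- .alignValues(values, cohort)
  scan <- if (cutoff@shape == "single") scanSingleCutoff else scanDualCutoff
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(nPerm)) {
    perm <- sample(values)
    pmin_i <- tryCatch(
      scan(perm, cohort, endpoint = endpoint,
           minGroupFrac = minGroupFrac)@p_min,
      error = function(e) Inf)
    if (pmin_i <= cutoff@p_min) hits <- hits + 1L
  }
  (hits + 1) / (nPerm + 1)
}

#' Cut-offs printed for the OAK/POPLAR reproduction runs
#'
#' The stratification thresholds reported for the deposited OAK and POPLAR
#' ctDNA cohorts, shipped as fixture constants so a reproduction run against
#' the externally downloaded trial tables can apply them directly with
#' \code{\link{labelResponders}} without re-scanning. Desk-scale analyses
#' (simulated cohorts) do not use these numbers.
#'
#' @return data.frame (cohort, arm, biomarker, endpoint, shape, c1, c2,
#'   responder_rule).
#' @export
publishedCutoffs <- function() {
  df <- data.frame(
    cohort = c("OAK", "OAK", "OAK", "OAK", "OAK", "OAK",
               "POPLAR", "POPLAR"),
    arm = c("docetaxel", "docetaxel", "docetaxel",
            "atezolizumab", "atezolizumab", "atezolizumab",
            "docetaxel", "docetaxel"),
    biomarker = c("btmb", "sbtmb", "ums", "btmb", "sbtmb", "ums",
                  "btmb", "sbtmb"),
    endpoint = c("OS", "OS", "OS", "OS", "OS", "OS", "PFS", "OS"),
    shape = c("single", "single", "single", "dual", "dual", "single",
              "single", "single"),
    c1 = c(10, 9, 9, 7, 4, 3, 5, 4),
    c2 = c(NA, NA, NA, 20, 17, NA, NA, NA),
    stringsAsFactors = FALSE)
  df$responder_rule <- ifelse(is.na(df$c2),
                              sprintf("value <= %g", df$c1),
                              sprintf("value <= %g | value > %g",
                                      df$c1, df$c2))
  df
}
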