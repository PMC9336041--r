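# Two-group time-to-event machinery. Kaplan-Meier estimation and the
# log-rank chi-square are delegated to the survival package; the
# Mantel-Haenszel (O/E) hazard ratio with its log-scale CI is assembled from
# the survdiff components, matching the Prism-style workflow in which
# published biomarker HRs of this kind are usually produced. Cox with Efron
# tie handling is the alternative estimator.

.checkSample <- function(times, events, what = "sample") {
  if (length(times) != length(events))
    stop(what, ": times and events differ in length")
  if (length(times) == 0) stop(what, ": empty survival sample")
  if (any(times < 0)) stop(what, ": negative survival time")
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimate of the survival function. Censored subjects leave
#' the risk set without producing a step.
#'
#' @param times event/censoring times in months (non-negative).
#' @param events logical; TRUE = event observed.
#' @return data.frame (time, n_risk, n_event, n_censor, survival), one row
#'   per distinct observed time, survival right-continuous non-increasing
#'   with S(0) = 1 implied.
#' @export
kmEstimate <- function(times, events) {
  .checkSample(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
             n_censor = fit$n.censor, survival = fit$surv)
}

#' Median survival from a Kaplan-Meier curve
#'
#' The smallest observed time at which S(t) <= 0.5. When censoring floors
#' the curve above 0.5 the median is undefined and NA is returned (reported
#' downstream as "undefined", the convention for such curves).
#'
#' @param curve data.frame from \code{\link{kmEstimate}}.
#' @return months, or NA_real_ when the curve never reaches 0.5.
#' @export
kmMedian <- function(curve) {
  hit <- which(curve$survival <= 0.5 + 1e-12)
  if (length(hit) == 0) return(NA_real_)
  curve$time[hit[1]]
}

#' Two-group log-rank test
#'
#' Standard (hypergeometric-variance) log-rank statistic with p from the
#' chi-square distribution on 1 df. Symmetric under group swap. With no
#' events in either group the statistic is 0 and p is 1, with a warning.
#'
#' @param timesA,eventsA,timesB,eventsB the two survival samples.
#' @return list(chi_square, p_value).
#' @export
logrankTest <- function(timesA, eventsA, timesB, eventsB) {
  .checkSample(timesA, eventsA, "group A")
  .checkSample(timesB, eventsB, "group B")
  if (!any(eventsA) && !any(eventsB)) {
    warning("no events in either group; log-rank undefined, returning p = 1")
    return(list(chi_square = 0, p_value = 1))
  }
  time <- c(timesA, timesB)
  event <- c(eventsA, eventsB)
  grp <- rep(c(0L, 1L), c(length(timesA), length(timesB)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  chi <- unname(sd$chisq)
  list(chi_square = chi, p_value = pchisq(chi, df = 1, lower.tail = FALSE))
}

#' Hazard ratio of group A versus group B
#'
#' \code{mantel_haenszel} (default): HR = (O_A/E_A)/(O_B/E_B) from the
#' pooled log-rank observed/expected events, with the log-scale CI using
#' variance 1/E_A + 1/E_B. \code{cox}: univariable proportional-hazards
#' estimate (Efron ties) with Wald CI.
#'
#' @param timesA,eventsA,timesB,eventsB the two survival samples.
#' @param method "mantel_haenszel" or "cox".
#' @param conf confidence level (default 0.95).
#' @return list(hr, ci_low, ci_high, method). When a group has zero expected
#'   events the HR is undefined: NA with a warning.
#' @export
hazardRatio <- function(timesA, eventsA, timesB, eventsB,
                        method = c("mantel_haenszel", "cox"), conf = 0.95) {
  method <- match.arg(method)
  .checkSample(timesA, eventsA, "group A")
  .checkSample(timesB, eventsB, "group B")
  if (!any(eventsA) && !any(eventsB))
    stop("hazard ratio requires at least one event")
  z <- qnorm(1 - (1 - conf) / 2)
  if (method == "mantel_haenszel") {
    time <- c(timesA, timesB)
    event <- c(eventsA, eventsB)
    grp <- rep(c(0L, 1L), c(length(timesA), length(timesB)))
    sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
    O <- sd$obs; E <- sd$exp
    if (any(E <= 0)) {
      warning("zero expected events in a group; HR undefined")
      return(list(hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  method = method))
    }
    hr <- (O[1] / E[1]) / (O[2] / E[2])
    se <- sqrt(1 / E[1] + 1 / E[2])
    list(hr = unname(hr), ci_low = unname(hr * exp(-z * se)),
         ci_high = unname(hr * exp(z * se)), method = method)
  } else {
    time <- c(timesA, timesB)
    event <- c(eventsA, eventsB)
    grp <- factor(rep(c("A", "B"), c(length(timesA), length(timesB))),
                  levels = c("B", "A"))
    fit <- survival::coxph(survival::Surv(time, event) ~ grp,
                           ties = "efron")
    beta <- unname(stats::coef(fit))
    se <- sqrt(unname(stats::vcov(fit)[1, 1]))
    list(hr = exp(beta), ci_low = exp(beta - z * se),
         ci_high = exp(beta + z * se), method = method)
  }
}

#' Full two-group survival comparison on a cohort
#'
#' Bundles group sizes, per-group Kaplan-Meier medians, the log-rank test
#' and the hazard ratio (A vs B) into a single one-row summary.
#'
#' @param cohort a MutationCohort.
#' @param labels logical per patient, aligned with \code{patientIDs(cohort)}
#'   (or named by patient_id); TRUE = group A.
#' @param endpoint "OS" or "PFS".
#' @param method HR estimator passed to \code{\link{hazardRatio}}.
#' @return data.frame row: n_a, n_b, median_a, median_b, chi_square,
#'   p_value, hr, hr_ci_low, hr_ci_high, method.
#' @export
compareGroups <- function(cohort, labels, endpoint = c("OS", "PFS"),
                          method = c("mantel_haenszel", "cox")) {
  endpoint <- match.arg(endpoint)
  method <- match.arg(method)
  cl <- cohort@clinical
  if (!is.null(names(labels))) labels <- labels[cl$patient_id]
  if (length(labels) != nrow(cl) || anyNA(labels))
    stop("labels must cover every patient in the cohort")
  if (!any(labels)) stop("group A is empty")
  if (all(labels)) stop("group B is empty")
  tm <- if (endpoint == "OS") cl$os_months else cl$pfs_months
  ev <- if (endpoint == "OS") cl$os_event else cl$pfs_event
  lr <- logrankTest(tm[labels], ev[labels], tm[!labels], ev[!labels])
  hr <- hazardRatio(tm[labels], ev[labels], tm[!labels], ev[!labels],
                    method = method)
  data.frame(
    n_a = sum(labels), n_b = sum(!labels),
    median_a = kmMedian(kmEstimate(tm[labels], ev[labels])),
    median_b = kmMedian(kmEstimate(tm[!labels], ev[!labels])),
    chi_square = lr$chi_square, p_value = lr$p_value,
    hr = hr$hr, hr_ci_low = hr$ci_low, hr_ci_high = hr$ci_high,
    method = hr$method, stringsAsFactors = FALSE)
}
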