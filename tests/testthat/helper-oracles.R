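# Independent oracles, written from scratch (no calls into the package's
# survival path): hand-coded hypergeometric log-rank statistic, exact
# permutation log-rank p, brute-force cut-off enumeration, trapezoid AUC.

logrankHand <- function(t1, e1, t2, e2) {
  tt <- c(t1, t2); ee <- c(e1, e2)
  g <- rep(1:2, c(length(t1), length(t2)))
  O <- 0; E <- 0; V <- 0
  for (u in sort(unique(tt[ee]))) {
    at <- tt >= u
    n <- sum(at); n1 <- sum(at & g == 1)
    d <- sum(tt == u & ee); d1 <- sum(tt == u & ee & g == 1)
    O <- O + d1; E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) return(list(chi = 0, p = 1))
  chi <- (O - E)^2 / V
  list(chi = chi, p = pchisq(chi, 1, lower.tail = FALSE))
}

# exact permutation p: enumerate every assignment of the pooled subjects
# into groups of the observed sizes
permLogrankP <- function(t1, e1, t2, e2) {
  tt <- c(t1, t2); ee <- c(e1, e2)
  n <- length(tt); nA <- length(t1)
  obs <- logrankHand(t1, e1, t2, e2)$chi
  idx <- utils::combn(n, nA)
  stats <- apply(idx, 2, function(i)
    logrankHand(tt[i], ee[i], tt[-i], ee[-i])$chi)
  mean(stats >= obs - 1e-9)
}

# brute-force single-cutoff enumeration with the documented tie-break
# (smallest p, then larger responder group, then smaller c1)
bruteForceSingle <- function(values, times, events, minGroupFrac = 0.10) {
  n <- length(values)
  cands <- sort(unique(values))
  rows <- lapply(cands, function(c) {
    resp <- values <= c
    if (sum(resp) < minGroupFrac * n || sum(!resp) < minGroupFrac * n)
      return(NULL)
    data.frame(c1 = c, nresp = sum(resp),
               p = logrankHand(times[resp], events[resp],
                               times[!resp], events[!resp])$p)
  })
  tab <- do.call(rbind, rows)
  tab[order(tab$p, -tab$nresp, tab$c1)[1], ]
}

bruteForceDual <- function(values, times, events, minGroupFrac = 0.10) {
  n <- length(values)
  uv <- sort(unique(values))
  rows <- list()
  for (a in uv) for (b in uv) {
    if (a >= b) next
    resp <- values <= a | values > b
    if (sum(resp) < minGroupFrac * n || sum(!resp) < minGroupFrac * n) next
    rows[[length(rows) + 1]] <- data.frame(
      c1 = a, c2 = b, nresp = sum(resp),
      p = logrankHand(times[resp], events[resp],
                      times[!resp], events[!resp])$p)
  }
  tab <- do.call(rbind, rows)
  tab[order(tab$p, -tab$nresp, tab$c1, tab$c2)[1], ]
}

trapezoidAUC <- function(scores, outcome) {
  thr <- c(-Inf, sort(unique(scores)), Inf)
  fpr <- vapply(thr, function(t) mean(scores[!outcome] >= t), 0)
  tpr <- vapply(thr, function(t) mean(scores[outcome] >= t), 0)
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# small deterministic exponential-survival cohort builder for direct tests
makeSurvCohort <- function(times, events, ids = NULL, arm = "docetaxel",
                           extra = list()) {
  n <- length(times)
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  cl <- data.frame(
    patient_id = ids, arm = arm, cohort = "test",
    sex = rep_len(if (is.null(extra$sex)) "male" else extra$sex, n),
    smoking = rep_len("smoker", n), histology = rep_len("non_LUSC", n),
    driver_gene = rep_len("negative", n),
    metastasis_sites = rep_len(1L, n),
    os_months = times, os_event = events,
    pfs_months = times / 2, pfs_event = events,
    best_response = rep_len("SD", n), stringsAsFactors = FALSE)
  buildCohort(cl, data.frame(patient_id = character(), gene = character(),
                             effect = character(), stringsAsFactors = FALSE))
}
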