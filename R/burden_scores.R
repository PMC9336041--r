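# Mutation-class burden scores and the unfavourable-gene screen.
#
# bTMB counts a patient's ctDNA mutation rows classified missense,
# synonymous, splice or nonsense; sbTMB restricts to missense and splice.
# Rows, not genes: two mutations in one gene count twice (configurable
# questions about panel composition are out of scope; the counting unit is
# documented here and asserted in tests). The unfavourable mutation score
# (UMS) sums 1-5 scores over the distinct screened genes a patient carries.

BTMB_EFFECTS <- c("missense", "synonymous", "splice", "nonsense")
SBTMB_EFFECTS <- c("missense", "splice")

#' Per-patient mutation burdens (bTMB and sbTMB)
#'
#' @param cohort a MutationCohort.
#' @return data.frame (patient_id, btmb, sbtmb), one row per patient in
#'   clinical order; patients without mutation rows get 0.
#' @export
computeBurdens <- function(cohort) {
  cl <- cohort@clinical
  mu <- cohort@mutations
  tallies <- function(effects) {
    sub <- mu[mu$effect %in% effects, , drop = FALSE]
    cnt <- table(factor(sub$patient_id, levels = cl$patient_id))
    as.integer(cnt)
  }
  data.frame(patient_id = cl$patient_id,
             btmb = tallies(BTMB_EFFECTS),
             sbtmb = tallies(SBTMB_EFFECTS),
             stringsAsFactors = FALSE)
}

#' Score an unfavourable gene from its screening p-value
#'
#' Left-closed bins over the screening window [0, 0.3): p in [0, 0.05) scores
#' 5, [0.05, 0.10) scores 4, [0.10, 0.15) scores 3, [0.15, 0.20) scores 2,
#' [0.20, 0.30) scores 1, and p >= 0.30 scores 0 (the gene is excluded).
#'
#' @param p p-value(s) in [0, 1]; vectorised.
#' @return integer score(s) in 0..5.
#' @export
scoreFromP <- function(p) {
  if (any(p < 0 | p > 1 | is.na(p)))
    stop("p-values must lie in [0, 1]")
  breaks <- c(0, 0.05, 0.10, 0.15, 0.20, 0.30, Inf)
  scores <- c(5L, 4L, 3L, 2L, 1L, 0L)
  scores[findInterval(p, breaks, left.open = FALSE)]
}

#' Screen for unfavourable mutated genes
#'
#' For every gene carried by at least \code{minCarriers} patients, compares
#' carriers vs non-carriers with the log-rank test on the chosen endpoint.
#' Genes with p < 0.3 AND carrier Mantel-Haenszel HR > 1 (the unfavourable
#' direction) are retained and scored with \code{\link{scoreFromP}}.
#' Per-gene p-values are not multiplicity-adjusted, a deliberate (and
#' statistically liberal) property of the screen that the documentation
#' flags.
#'
#' @param cohort a MutationCohort restricted to one trial arm.
#' @param endpoint "OS" (default) or "PFS".
#' @param minCarriers minimum carriers for a gene to be tested (default 3,
#'   avoiding degenerate log-rank groups).
#' @return an \code{\linkS4class{UnfavourableGeneTable}}; empty with a
#'   warning when no gene survives.
#' @export
screenUnfavourableGenes <- function(cohort, endpoint = c("OS", "PFS"),
                                    minCarriers = 3) {
  endpoint <- match.arg(endpoint)
  if (minCarriers < 1) stop("minCarriers must be >= 1")
  cl <- cohort@clinical
  arms <- unique(cl$arm)
  if (length(arms) != 1)
    stop("the screen must run on a single trial arm; found: ",
         paste(arms, collapse = ", "))
  mu <- cohort@mutations
  tm <- if (endpoint == "OS") cl$os_months else cl$pfs_months
  ev <- if (endpoint == "OS") cl$os_event else cl$pfs_event
  carriersOf <- split(mu$patient_id, mu$gene)
  rows <- lapply(names(carriersOf), function(g) {
    carrier <- cl$patient_id %in% carriersOf[[g]]
    n <- sum(carrier)
    if (n < minCarriers || n == nrow(cl)) return(NULL)
    lr <- suppressWarnings(
      logrankTest(tm[carrier], ev[carrier], tm[!carrier], ev[!carrier]))
    hr <- suppressWarnings(tryCatch(
      hazardRatio(tm[carrier], ev[carrier], tm[!carrier], ev[!carrier]),
      error = function(e) list(hr = NA_real_)))
    if (is.na(hr$hr) || lr$p_value >= 0.3 || hr$hr <= 1) return(NULL)
    data.frame(gene = g, carriers = n, p_value = lr$p_value,
               carrier_hr = hr$hr, score = scoreFromP(lr$p_value),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    warning("no unfavourable gene retained")
    tab <- data.frame(gene = character(), carriers = integer(),
                      p_value = numeric(), carrier_hr = numeric(),
                      score = integer(), stringsAsFactors = FALSE)
  } else {
    tab <- tab[order(tab$p_value), , drop = FALSE]
    rownames(tab) <- NULL
  }
  new("UnfavourableGeneTable", table = tab, arm = arms, endpoint = endpoint)
}

#' Per-patient unfavourable mutation score (UMS)
#'
#' UMS = sum of the scores of the distinct retained genes the patient
#' carries; carrying a gene more than once counts once. Patients carrying no
#' retained gene score 0.
#'
#' @param cohort a MutationCohort.
#' @param genes an \code{\linkS4class{UnfavourableGeneTable}} built on a
#'   compatible arm.
#' @return data.frame (patient_id, ums) in clinical order.
#' @export
computeUMS <- function(cohort, genes) {
  stopifnot(is(genes, "UnfavourableGeneTable"))
  cl <- cohort@clinical
  mu <- cohort@mutations
  tab <- genes@table
  score <- setNames(tab$score, tab$gene)
  carried <- unique(mu[mu$gene %in% tab$gene, c("patient_id", "gene")])
  per <- tapply(score[carried$gene], carried$patient_id, sum)
  ums <- as.integer(per[cl$patient_id])
  ums[is.na(ums)] <- 0L
  data.frame(patient_id = cl$patient_id, ums = ums, stringsAsFactors = FALSE)
}
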