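# Seeded synthetic NSCLC ctDNA cohorts with the statistical structure the
# pipeline assumes: overdispersed per-patient mutation counts, multinomial
# effect classes, independent clinical covariates, exponential
# (constant-baseline-hazard) survival under proportional hazards with
# independent exponential censoring, and optional planted effects — a
# single biomarker cut-off, a U-shaped middle-band hazard, and
# unfavourable carrier genes. A SimTruth record of every planted parameter
# and latent membership accompanies each cohort for recovery tests.
#
# Determinism: one global seed drives a fixed stream-splitting scheme (a
# documented per-stage offset added to the seed, reduced mod 2^31) so that
# adding a later generator stage never perturbs earlier draws.

.STAGE_OFFSETS <- c(counts = 11L, effects = 23L, genes = 37L, planted = 41L,
                    covariates = 53L, survival = 67L, censoring = 79L,
                    pfs = 97L, response = 113L)

.stageSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 127 + .STAGE_OFFSETS[[stage]]) %% 2147483647)
}

#' Build a synthetic-cohort configuration
#'
#' Defaults emulate an OAK-like second-line NSCLC trial arm: ~300 patients,
#' a targeted panel of 300 genes, a mean of 10 somatic ctDNA calls per
#' patient with negative-binomial overdispersion, effect-class mix dominated
#' by missense, a baseline hazard giving ~8 months median OS, and light
#' independent censoring. Clinical covariates are drawn independently of the
#' biomarkers so planted effects are attributable.
#'
#' @param nPatients number of patients.
#' @param seed mandatory integer seed.
#' @param nGenes panel size (genes are "G001".."Gnnn").
#' @param mutationMean,mutationDispersion negative-binomial mean and size
#'   for per-patient total mutation counts.
#' @param effectProbs probabilities over the five effect classes, summing
#'   to 1.
#' @param covariatePrevalences named list: male, smoker, LUSC,
#'   driver_positive prevalences and metMean (Poisson mean of
#'   metastasis-site counts).
#' @param baselineHazard events per month (0.087 ~ 8-month median OS).
#' @param censoringRate independent exponential censoring rate per month;
#'   0 disables censoring.
#' @param arm "docetaxel" or "atezolizumab".
#' @param plantedSingleCutoff optional list(biomarker, cstar, multiplier):
#'   patients with biomarker > cstar have their hazard multiplied.
#' @param plantedUShape optional list(biomarker, c1star, c2star,
#'   multiplier): hazard multiplied in the middle band
#'   (c1star < value <= c2star).
#' @param plantedUnfavourableGenes optional list of list(gene, multiplier,
#'   prevalence): carriers drawn at the prevalence receive an extra
#'   mutation in the gene and the hazard multiplier.
#' @param pfsShrink mean fraction of the latent OS time at which
#'   progression occurs (PFS is a noisy scaled-down OS).
#' @return a validated config list of class "SimConfig".
#' @export
simConfig <- function(nPatients = 300, seed, nGenes = 300,
                      mutationMean = 10, mutationDispersion = 2,
                      effectProbs = c(missense = 0.55, synonymous = 0.25,
                                      splice = 0.05, nonsense = 0.10,
                                      other = 0.05),
                      covariatePrevalences = list(male = 0.6, smoker = 0.8,
                                                  LUSC = 0.25,
                                                  driver_positive = 0.15,
                                                  metMean = 2.2),
                      baselineHazard = 0.087, censoringRate = 0.02,
                      arm = "docetaxel",
                      plantedSingleCutoff = NULL, plantedUShape = NULL,
                      plantedUnfavourableGenes = NULL,
                      pfsShrink = 0.5) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(nPatients >= 1, nGenes >= 1, mutationMean > 0,
            mutationDispersion > 0, baselineHazard > 0, censoringRate >= 0,
            pfsShrink > 0, pfsShrink < 1)
  if (abs(sum(effectProbs) - 1) > 1e-8 || any(effectProbs < 0) ||
      !setequal(names(effectProbs), EFFECT_LEVELS))
    stop("effectProbs must be named over the five effect classes and sum to 1")
  arm <- match.arg(arm, ARM_LEVELS)
  if (!is.null(plantedSingleCutoff) && !is.null(plantedUShape) &&
      identical(plantedSingleCutoff$biomarker, plantedUShape$biomarker))
    stop("contradictory planted rules on the same biomarker")
  for (pl in list(plantedSingleCutoff, plantedUShape))
    if (!is.null(pl) && pl$multiplier <= 0)
      stop("planted hazard multipliers must be positive")
  cfg <- list(nPatients = nPatients, seed = as.integer(seed),
              nGenes = nGenes, mutationMean = mutationMean,
              mutationDispersion = mutationDispersion,
              effectProbs = effectProbs[EFFECT_LEVELS],
              covariatePrevalences = covariatePrevalences,
              baselineHazard = baselineHazard, censoringRate = censoringRate,
              arm = arm, plantedSingleCutoff = plantedSingleCutoff,
              plantedUShape = plantedUShape,
              plantedUnfavourableGenes = plantedUnfavourableGenes,
              pfsShrink = pfsShrink)
  class(cfg) <- "SimConfig"
  cfg
}

.simBiomarker <- function(name, mutations, ids) {
  eff <- switch(name, btmb = BTMB_EFFECTS, sbtmb = SBTMB_EFFECTS,
                stop("planted rules support biomarkers 'btmb' and 'sbtmb'"))
  sub <- mutations[mutations$effect %in% eff, , drop = FALSE]
  as.integer(table(factor(sub$patient_id, levels = ids)))
}

#' Simulate a cohort with known ground truth
#'
#' @param config a \code{\link{simConfig}}.
#' @return list(cohort = \code{\linkS4class{MutationCohort}},
#'   truth = SimTruth list recording the planted parameters, per-patient
#'   hazard multipliers and latent group memberships).
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  n <- config$nPatients
  ids <- sprintf("P%04d", seq_len(n))
  genes <- sprintf("G%03d", seq_len(config$nGenes))

  set.seed(.stageSeed(config$seed, "counts"))
  nMut <- rnbinom(n, mu = config$mutationMean,
                  size = config$mutationDispersion)

  set.seed(.stageSeed(config$seed, "effects"))
  total <- sum(nMut)
  effects <- sample(EFFECT_LEVELS, total, replace = TRUE,
                    prob = config$effectProbs)

  set.seed(.stageSeed(config$seed, "genes"))
  geneDraw <- sample(genes, total, replace = TRUE)
  mutations <- data.frame(patient_id = rep(ids, nMut), gene = geneDraw,
                          effect = effects, stringsAsFactors = FALSE)

  carriers <- list()
  if (!is.null(config$plantedUnfavourableGenes)) {
    set.seed(.stageSeed(config$seed, "planted"))
    for (pg in config$plantedUnfavourableGenes) {
      isCarrier <- runif(n) < pg$prevalence
      carriers[[pg$gene]] <- ids[isCarrier]
      if (any(isCarrier)) {
        extra <- data.frame(
          patient_id = ids[isCarrier], gene = pg$gene,
          effect = sample(EFFECT_LEVELS, sum(isCarrier), replace = TRUE,
                          prob = config$effectProbs),
          stringsAsFactors = FALSE)
        mutations <- rbind(mutations, extra)
      }
    }
    ord <- order(match(mutations$patient_id, ids))
    mutations <- mutations[ord, , drop = FALSE]
    rownames(mutations) <- NULL
  }

  set.seed(.stageSeed(config$seed, "covariates"))
  cp <- config$covariatePrevalences
  clinical <- data.frame(
    patient_id = ids, arm = config$arm, cohort = "simulated",
    sex = ifelse(runif(n) < cp$male, "male", "female"),
    smoking = ifelse(runif(n) < cp$smoker, "smoker", "non_smoker"),
    histology = ifelse(runif(n) < cp$LUSC, "LUSC", "non_LUSC"),
    driver_gene = ifelse(runif(n) < cp$driver_positive, "positive",
                         "negative"),
    metastasis_sites = stats::rpois(n, cp$metMean),
    stringsAsFactors = FALSE)

  logMult <- rep(0, n)
  latent <- list()
  if (!is.null(config$plantedSingleCutoff)) {
    pl <- config$plantedSingleCutoff
    v <- .simBiomarker(pl$biomarker, mutations, ids)
    above <- v > pl$cstar
    logMult <- logMult + ifelse(above, log(pl$multiplier), 0)
    latent$single_above <- above
  }
  if (!is.null(config$plantedUShape)) {
    pl <- config$plantedUShape
    v <- .simBiomarker(pl$biomarker, mutations, ids)
    middle <- v > pl$c1star & v <= pl$c2star
    logMult <- logMult + ifelse(middle, log(pl$multiplier), 0)
    latent$u_middle <- middle
  }
  for (g in names(carriers)) {
    pg <- Filter(function(x) x$gene == g,
                 config$plantedUnfavourableGenes)[[1]]
    isC <- ids %in% carriers[[g]]
    logMult <- logMult + ifelse(isC, log(pg$multiplier), 0)
    latent[[paste0("carrier_", g)]] <- isC
  }
  rate <- config$baselineHazard * exp(logMult)

  set.seed(.stageSeed(config$seed, "survival"))
  osLatent <- rexp(n, rate)

  set.seed(.stageSeed(config$seed, "censoring"))
  cens <- if (config$censoringRate > 0) rexp(n, config$censoringRate)
          else rep(Inf, n)

  set.seed(.stageSeed(config$seed, "pfs"))
  frac <- rbeta(n, shape1 = 4 * config$pfsShrink / (1 - config$pfsShrink),
                shape2 = 4)
  pfsLatent <- osLatent * frac

  clinical$os_months <- round(pmin(osLatent, cens), 4)
  clinical$os_event <- osLatent <= cens
  clinical$pfs_months <- round(pmin(pfsLatent, cens), 4)
  clinical$pfs_event <- pfsLatent <= cens

  set.seed(.stageSeed(config$seed, "response"))
  # longer latent survival -> better best response, with noise
  q <- rank(osLatent, ties.method = "first") / n + rnorm(n, sd = 0.15)
  clinical$best_response <- cut(q, c(-Inf, 0.3, 0.65, 0.9, 0.97, Inf),
                                labels = c("PD", "SD", "PR", "CR", "NE"))
  clinical$best_response <- as.character(clinical$best_response)

  cohort <- buildCohort(clinical, mutations,
                        provenance = sprintf("simulated(seed=%d)",
                                             config$seed))
  truth <- list(config = config, hazard_multiplier = exp(logMult),
                latent = latent, carriers = carriers,
                os_latent = osLatent, censor_time = cens)
  class(truth) <- "SimTruth"
  list(cohort = cohort, truth = truth)
}

#' Standard test fixtures
#'
#' Small named cohorts with documented seeds used across the test suite:
#' a null cohort (no planted effect), a planted single-cutoff cohort, a
#' planted U-shape cohort, a planted unfavourable-gene cohort, and a tiny
#' six-patient cohort whose burdens are hand-checkable.
#'
#' @return named list; each element is list(cohort, truth) except "tiny",
#'   which is a deterministic hand-built list(cohort).
#' @export
makeFixtureSuite <- function() {
  suite <- list(
    null = simulateCohort(simConfig(nPatients = 300, seed = 101L)),
    single_cutoff = simulateCohort(simConfig(
      nPatients = 500, seed = 202L,
      plantedSingleCutoff = list(biomarker = "btmb", cstar = 10,
                                 multiplier = 2.5))),
    u_shape = simulateCohort(simConfig(
      nPatients = 600, seed = 303L, arm = "atezolizumab",
      plantedUShape = list(biomarker = "btmb", c1star = 6, c2star = 13,
                           multiplier = 2.5))),
    unfavourable_gene = simulateCohort(simConfig(
      nPatients = 400, seed = 404L,
      plantedUnfavourableGenes = list(list(gene = "G001", multiplier = 3,
                                           prevalence = 0.3)))))
  suite$tiny <- list(cohort = tinyCohort())
  suite
}

#' A deterministic six-patient cohort with hand-checkable burdens
#'
#' @return a MutationCohort; patient T1 carries one mutation of each effect
#'   class (bTMB 4, sbTMB 2), T6 carries none (burden 0).
#' @export
tinyCohort <- function() {
  clinical <- data.frame(
    patient_id = paste0("T", 1:6),
    arm = "docetaxel", cohort = "tiny",
    sex = c("male", "female", "male", "female", "male", "female"),
    smoking = c("smoker", "smoker", "non_smoker", "smoker", "smoker",
                "non_smoker"),
    histology = c("LUSC", "non_LUSC", "non_LUSC", "LUSC", "non_LUSC",
                  "non_LUSC"),
    driver_gene = c("negative", "negative", "positive", "negative",
                    "unknown", "negative"),
    metastasis_sites = c(1L, 3L, 0L, 5L, 2L, 1L),
    os_months = c(12, 3, 8, 2, 20, 15),
    os_event = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    pfs_months = c(6, 1.5, 4, 1, 10, 9),
    pfs_event = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    best_response = c("PR", "PD", "SD", "PD", "CR", "PR"),
    stringsAsFactors = FALSE)
  mutations <- data.frame(
    patient_id = c("T1", "T1", "T1", "T1", "T1",
                   "T2", "T2", "T3", "T4", "T4", "T5"),
    gene = c("TP53", "KRAS", "EGFR", "STK11", "KEAP1",
             "TP53", "TP53", "KRAS", "TP53", "STK11", "EGFR"),
    effect = c("missense", "synonymous", "splice", "nonsense", "other",
               "missense", "missense", "synonymous", "nonsense", "splice",
               "missense"),
    stringsAsFactors = FALSE)
  buildCohort(clinical, mutations, provenance = "tiny-fixture")
}
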