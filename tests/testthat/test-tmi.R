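# helpers to build small TMI models by hand
mkCutRow <- function(ch, st, b, c1, hr, shape = "single", c2 = NA_real_)
  data.frame(characteristic = ch, stratum = st, biomarker = b, shape = shape,
             c1 = c1, c2 = c2, hr = hr, n_stratum = 50L,
             stringsAsFactors = FALSE)

emptySkip <- data.frame(characteristic = character(), stratum = character(),
                        biomarker = character(), reason = character(),
                        stringsAsFactors = FALSE)

fullModel <- function(hr, c1 = 100, threshold = 10) {
  comps <- do.call(rbind, lapply(names(TMIstrat:::.STRATA), function(ch)
    do.call(rbind, lapply(TMIstrat:::.STRATA[[ch]], function(st)
      do.call(rbind, lapply(c("btmb", "sbtmb", "ums"), function(b)
        mkCutRow(ch, st, b, c1, hr)))))))
  new("TMIModel", arm = "docetaxel", endpoint = "OS", components = comps,
      skipped = emptySkip, score_rule = "hr_if_responder",
      median_threshold = threshold)
}

tinyBio <- function(co, btmb) {
  list(burdens = data.frame(patient_id = patientIDs(co), btmb = btmb,
                            sbtmb = btmb, stringsAsFactors = FALSE),
       ums = data.frame(patient_id = patientIDs(co), ums = btmb,
                        stringsAsFactors = FALSE))
}

test_that("hr_if_responder scoring follows the stated arithmetic", {
  co <- makeSurvCohort(c(5, 8), c(TRUE, TRUE))
  bio <- tinyBio(co, c(0, 0))

  # all 30 components with HR 0.5 and cut-off far above every value:
  # every patient satisfies every responder rule -> TMI = 15 x 0.5 = 7.5
  m <- fullModel(0.5, c1 = 100)
  sc <- tmiScores(m, co, bio$burdens, bio$ums)
  expect_equal(sc$tmi, c(7.5, 7.5))

  # cut-off below every value: nobody responds -> neutral sum 15 x 1.0
  m2 <- fullModel(0.5, c1 = -1)
  sc2 <- tmiScores(m2, co, bio$burdens, bio$ums)
  expect_equal(sc2$tmi, c(15, 15))

  # single-component toy: responder adds the stratum HR, else 1.0
  one <- new("TMIModel", arm = "docetaxel", endpoint = "OS",
             components = mkCutRow("sex", "male", "btmb", 5, 0.5),
             skipped = emptySkip, score_rule = "hr_if_responder",
             median_threshold = 14.75)
  bio3 <- tinyBio(co, c(3, 9))   # first responder (3 <= 5), second not
  sc3 <- tmiScores(one, co, bio3$burdens, bio3$ums)
  expect_equal(sc3$tmi, c(14 + 0.5, 15))
  expect_equal(sc3$label, c("low", "high"))  # ties at threshold go low
})

test_that("unknown characteristic levels contribute neutrally", {
  co <- makeSurvCohort(c(5, 8), c(TRUE, TRUE))
  cl <- clinicalData(co)
  cl$driver_gene <- c("unknown", "negative")
  co <- buildCohort(cl, mutationData(co))
  bio <- tinyBio(co, c(0, 0))
  # driver components exist for the negative stratum only
  comps <- do.call(rbind, lapply(c("btmb", "sbtmb", "ums"), function(b)
    mkCutRow("driver_gene", "negative", b, 100, 0.4)))
  m <- new("TMIModel", arm = "docetaxel", endpoint = "OS",
           components = comps, skipped = emptySkip,
           score_rule = "hr_if_responder", median_threshold = 10)
  sc <- tmiScores(m, co, bio$burdens, bio$ums)
  # unknown driver patient: all 15 terms neutral; negative-stratum
  # responder gains 3 x 0.4 in place of 3 x 1.0
  expect_equal(sc$tmi, c(15, 12 + 3 * 0.4))

  # replacing a neutral term by a responder term with hr < 1 lowers the TMI
  expect_lt(sc$tmi[2], sc$tmi[1])
})

test_that("TMI is invariant to patient order and the model freezes under apply", {
  sim <- simulateCohort(simConfig(nPatients = 150, seed = 61L))
  co <- sim$cohort
  b <- computeBurdens(co)
  g <- suppressWarnings(screenUnfavourableGenes(co))
  u <- computeUMS(co, g)
  m <- fitTMI(co, b, u, minStratum = 10)

  sc <- tmiScores(m, co, b, u)
  perm <- sample(nrow(clinicalData(co)))
  co2 <- TMIstrat:::filterCohortMask(co, rep(TRUE, length(perm)))
  co2@clinical <- clinicalData(co)[perm, ]
  sc2 <- tmiScores(m, co2, b, u)
  expect_equal(sc2$tmi[match(sc$patient_id, sc2$patient_id)], sc$tmi)

  # freeze: applying to a fresh cohort leaves the model bit-identical
  before <- capture.output(str(m))
  sim2 <- simulateCohort(simConfig(nPatients = 100, seed = 62L))
  b2 <- computeBurdens(sim2$cohort)
  u2 <- computeUMS(sim2$cohort, g)
  res <- applyTMI(m, sim2$cohort, b2, u2)
  expect_identical(capture.output(str(m)), before)
  expect_equal(nrow(res$scores), 100)

  # applying to the discovery cohort splits it at the median, ties to low
  resD <- applyTMI(m, co, b, u)
  expect_gte(sum(resD$scores$label == "low"), 75)
  expect_true(all((resD$scores$tmi <= tmiThreshold(m)) ==
                  (resD$scores$label == "low")))
})

test_that("fitTMI skips undersized strata and rejects mixed arms", {
  sim <- simulateCohort(simConfig(nPatients = 120, seed = 63L))
  co <- sim$cohort
  b <- computeBurdens(co)
  u <- data.frame(patient_id = patientIDs(co), ums = 0L)
  # force a rare stratum: almost nobody is LUSC
  cl <- clinicalData(co)
  cl$histology <- c(rep("LUSC", 5), rep("non_LUSC", nrow(cl) - 5))
  co <- buildCohort(cl, mutationData(co))
  m <- fitTMI(co, b, u, minStratum = 20)
  expect_true(all(c("histology") %in% m@skipped$characteristic))
  expect_true(all(m@skipped$reason[m@skipped$stratum == "LUSC"] ==
                  "stratum too small"))
  # ums is constant 0 here: its scans fail and are skipped, not fatal
  expect_false("ums" %in% m@components$biomarker)

  cl2 <- clinicalData(co); cl2$arm[1] <- "atezolizumab"
  co2 <- buildCohort(cl2, mutationData(co))
  expect_error(fitTMI(co2, b, u), "one trial arm")
})

test_that("model round-trips through its structured text file", {
  sim <- simulateCohort(simConfig(nPatients = 150, seed = 64L))
  b <- computeBurdens(sim$cohort)
  g <- suppressWarnings(screenUnfavourableGenes(sim$cohort))
  u <- computeUMS(sim$cohort, g)
  m <- fitTMI(sim$cohort, b, u, minStratum = 10)
  path <- withr::local_tempfile(fileext = ".yaml")
  writeTMIModel(m, path)
  m2 <- readTMIModel(path)
  expect_equal(m2@median_threshold, m@median_threshold, tolerance = 1e-12)
  expect_equal(m2@components$hr, m@components$hr, tolerance = 1e-12)
  expect_equal(m2@components$c1, m@components$c1)
  sc <- tmiScores(m, sim$cohort, b, u)
  sc2 <- tmiScores(m2, sim$cohort, b, u)
  expect_equal(sc2$tmi, sc$tmi, tolerance = 1e-12)
})
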