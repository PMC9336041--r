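writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("mutation reader parses both dialects and maps effect classes", {
  p <- writeTSV(data.frame(patient_id = c("P1", "P2"),
                           gene = c("TP53", "KRAS"),
                           effect = c("missense", "MISSENSE")),
                withr::local_tempfile(fileext = ".tsv"))
  mu <- readMutations(p, "simple_tsv")
  expect_equal(mu$effect, c("missense", "missense"))

  maf <- writeTSV(data.frame(
    Tumor_Sample_Barcode = c("P1", "P1", "P1", "P2"),
    Hugo_Symbol = c("TP53", "KRAS", "EGFR", "STK11"),
    Variant_Classification = c("Silent", "In_Frame_Del", "Splice_Site",
                               "Nonsense_Mutation")),
    withr::local_tempfile(fileext = ".maf"))
  mm <- readMutations(maf, "maf")
  expect_equal(mm$effect, c("synonymous", "other", "splice", "nonsense"))

  # unknown raw labels map to other with a warning, never dropped
  bad <- writeTSV(data.frame(patient_id = "P1", gene = "TP53",
                             effect = "frameshift"),
                  withr::local_tempfile(fileext = ".tsv"))
  expect_warning(mb <- readMutations(bad), "other")
  expect_equal(nrow(mb), 1)
  expect_equal(mb$effect, "other")

  # missing column is a hard error naming the column
  noeff <- writeTSV(data.frame(patient_id = "P1", gene = "TP53"),
                    withr::local_tempfile(fileext = ".tsv"))
  expect_error(readMutations(noeff), "effect")
})

test_that("clinical reader folds case, falls back to unknown, rejects bad rows", {
  base <- data.frame(patient_id = c("P1", "P2"), arm = c("Docetaxel", "docetaxel"),
                     sex = c("FEMALE", "male"), smoking = c("smoker", "ex-smoker"),
                     os_months = c(10, 5), os_event = c(1, 0),
                     pfs_months = c(5, 2), pfs_event = c(1, 1))
  p <- writeTSV(base, withr::local_tempfile(fileext = ".tsv"))
  expect_warning(cl <- readClinical(p), "smoking")
  expect_equal(cl$sex, c("female", "male"))
  expect_equal(cl$smoking, c("smoker", "unknown"))
  expect_equal(cl$histology, c("unknown", "unknown"))  # absent column
  expect_equal(cl$os_event, c(TRUE, FALSE))

  neg <- base; neg$os_months[1] <- -1
  expect_error(readClinical(writeTSV(neg, withr::local_tempfile(fileext = ".tsv"))),
               "negative")
  dup <- base; dup$patient_id <- c("P1", "P1")
  expect_error(readClinical(writeTSV(dup, withr::local_tempfile(fileext = ".tsv"))),
               "duplicate")
  noos <- base; noos$os_months <- NULL
  expect_error(readClinical(writeTSV(noos, withr::local_tempfile(fileext = ".tsv"))),
               "os_months")
})

test_that("buildCohort drops orphan mutations with a counted warning and is idempotent", {
  tc <- tinyCohort()
  expect_equal(length(tc), 6)
  expect_equal(nrow(mutationData(tc)), 11)

  mu <- rbind(mutationData(tc),
              data.frame(patient_id = "GHOST", gene = "TP53",
                         effect = "missense"))
  expect_warning(co <- buildCohort(clinicalData(tc), mu), "1 mutation row")
  expect_equal(nrow(mutationData(co)), 11)

  # idempotent: rebuilding from the same inputs yields an identical cohort
  co2 <- buildCohort(clinicalData(co), mutationData(co))
  expect_identical(clinicalData(co), clinicalData(co2))
  expect_identical(mutationData(co), mutationData(co2))

  # a patient with zero mutation rows is legal and retained
  expect_true("T6" %in% patientIDs(tc))
  expect_false("T6" %in% mutationData(tc)$patient_id)
  expect_true(validObject(tc))
})

test_that("cohort tables round-trip through write and read", {
  tc <- tinyCohort()
  cp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".tsv")
  writeCohort(tc, cp, mp)
  back <- buildCohort(readClinical(cp), readMutations(mp))
  expect_equal(clinicalData(back), clinicalData(tc))
  expect_equal(mutationData(back), mutationData(tc))
})

test_that("filterCohort selects arms and subgroups with the >= 3 metastasis boundary", {
  tc <- tinyCohort()
  m <- filterCohort(tc, subgroup = "met_ge3")
  expect_setequal(patientIDs(m), c("T2", "T4"))  # sites 3 and 5
  l <- filterCohort(tc, subgroup = "met_lt3")
  expect_setequal(patientIDs(l), c("T1", "T3", "T5", "T6"))

  # mutations restricted to retained patients
  expect_true(all(mutationData(m)$patient_id %in% patientIDs(m)))

  # unknown levels belong to no subgroup of the characteristic
  dn <- filterCohort(tc, subgroup = "driver_negative")
  expect_false("T5" %in% patientIDs(dn))  # T5 driver unknown
  dp <- filterCohort(tc, subgroup = "driver_positive")
  expect_false("T5" %in% patientIDs(dp))

  # sequential filters commute with the combined predicate
  a <- filterCohort(filterCohort(tc, subgroup = "male"), subgroup = "smoker")
  b <- filterCohort(filterCohort(tc, subgroup = "smoker"), subgroup = "male")
  expect_identical(clinicalData(a), clinicalData(b))

  # empty result is a warning, not an error
  expect_warning(e <- filterCohort(tc, arm = "atezolizumab"), "empty")
  expect_equal(length(e), 0)
})
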