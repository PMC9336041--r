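test_that("Kaplan-Meier estimate matches hand computations", {
  # no censoring: KM equals the empirical survival, steps of 1/n
  k <- kmEstimate(c(2, 4, 6, 8, 10), rep(TRUE, 5))
  expect_equal(k$survival, c(0.8, 0.6, 0.4, 0.2, 0))
  expect_equal(k$survival[k$time == 6], 0.4)

  # product-limit with a censored subject at a tied time
  k2 <- kmEstimate(c(1, 2, 2, 3), c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(k2$survival[k2$time == 1], 0.75)
  expect_equal(k2$survival[k2$time == 2], 0.5)
  expect_equal(k2$survival[k2$time == 3], 0, tolerance = 1e-12)

  # all censored: flat at 1, undefined median
  k3 <- kmEstimate(c(1, 2, 3), rep(FALSE, 3))
  expect_true(all(k3$survival == 1))
  expect_true(is.na(kmMedian(k3)))

  # right-continuous non-increasing
  expect_true(all(diff(k$survival) <= 0))
  expect_error(kmEstimate(numeric(), logical()), "empty")
})

test_that("median is the first time the curve reaches 0.5, NA when floored above", {
  expect_equal(kmMedian(kmEstimate(c(2, 4, 6, 8, 10), rep(TRUE, 5))), 6)
  expect_equal(kmMedian(kmEstimate(5, TRUE)), 5)
  # heavy early censoring floors the curve above 0.5
  k <- kmEstimate(c(1, 2, 3, 4, 5), c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_true(min(k$survival) > 0.5)
  expect_true(is.na(kmMedian(k)))
  # exact 0.5 plateau reports the first time at 0.5
  k2 <- kmEstimate(c(1, 1, 2, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(kmMedian(k2), 1)
})

test_that("log-rank test is symmetric, null on identical groups, matches the hand statistic", {
  a <- list(t = c(1, 3, 5, 7, 9), e = c(TRUE, TRUE, FALSE, TRUE, TRUE))
  b <- list(t = c(2, 4, 6, 8, 12), e = c(TRUE, FALSE, TRUE, TRUE, TRUE))
  lr <- logrankTest(a$t, a$e, b$t, b$e)
  swap <- logrankTest(b$t, b$e, a$t, a$e)
  expect_equal(lr$chi_square, swap$chi_square, tolerance = 1e-12)
  expect_equal(lr$p_value, swap$p_value, tolerance = 1e-12)

  same <- logrankTest(a$t, a$e, a$t, a$e)
  expect_equal(same$chi_square, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)

  hand <- logrankHand(a$t, a$e, b$t, b$e)
  expect_equal(lr$chi_square, hand$chi, tolerance = 1e-9)

  # cross-group tied event times: the hypergeometric treatment agrees
  # between the backend and the hand-coded statistic
  tt <- list(t1 = c(1, 3, 3, 7), e1 = c(TRUE, TRUE, TRUE, FALSE),
             t2 = c(1, 3, 5, 9), e2 = c(TRUE, TRUE, TRUE, TRUE))
  expect_equal(logrankTest(tt$t1, tt$e1, tt$t2, tt$e2)$chi_square,
               logrankHand(tt$t1, tt$e1, tt$t2, tt$e2)$chi,
               tolerance = 1e-9)

  expect_warning(z <- logrankTest(c(1, 2), c(FALSE, FALSE),
                                  c(3, 4), c(FALSE, FALSE)), "no events")
  expect_equal(z$p_value, 1)
})

test_that("chi-square log-rank p tracks the exact permutation oracle at n <= 10", {
  cases <- list(
    list(t1 = c(1, 2, 3), e1 = rep(TRUE, 3),
         t2 = c(10, 20, 30), e2 = rep(TRUE, 3)),
    list(t1 = c(1, 2, 2, 5), e1 = c(TRUE, TRUE, FALSE, TRUE),
         t2 = c(3, 4, 6, 8), e2 = c(TRUE, FALSE, TRUE, TRUE)),
    list(t1 = c(2, 4, 6, 8, 10), e1 = rep(TRUE, 5),
         t2 = c(1, 3, 5, 7, 9), e2 = rep(TRUE, 5)),
    list(t1 = c(1, 1, 2), e1 = rep(TRUE, 3),
         t2 = c(2, 3, 4, 5), e2 = c(TRUE, TRUE, FALSE, TRUE)),
    list(t1 = c(5, 6, 7, 8, 9), e1 = rep(TRUE, 5),
         t2 = c(1, 2, 3, 4, 10), e2 = c(rep(TRUE, 4), FALSE)))
  for (cs in cases) {
    p_asym <- logrankTest(cs$t1, cs$e1, cs$t2, cs$e2)$p_value
    p_perm <- permLogrankP(cs$t1, cs$e1, cs$t2, cs$e2)
    expect_lt(abs(p_asym - p_perm), 0.15)
  }
  # complete separation of {1,2,3} vs {10,20,30}: significant by the
  # chi-square form, and the most extreme of all 20 assignments (the
  # squared statistic counts both orientations, so the exact p is 2/20)
  p_asym <- logrankTest(c(1, 2, 3), rep(TRUE, 3),
                        c(10, 20, 30), rep(TRUE, 3))$p_value
  expect_lt(p_asym, 0.05)
  expect_equal(permLogrankP(c(1, 2, 3), rep(TRUE, 3),
                            c(10, 20, 30), rep(TRUE, 3)), 2 / 20)
})

test_that("hazard ratio obeys reciprocity, unity on identical groups, both estimators agree", {
  a <- list(t = c(1, 3, 5, 7, 9, 11), e = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE))
  b <- list(t = c(2, 4, 6, 8, 10, 14), e = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE))
  for (m in c("mantel_haenszel", "cox")) {
    h <- hazardRatio(a$t, a$e, b$t, b$e, method = m)
    hs <- hazardRatio(b$t, b$e, a$t, a$e, method = m)
    expect_equal(h$hr, 1 / hs$hr, tolerance = 1e-12)
    expect_equal(h$ci_low, 1 / hs$ci_high, tolerance = 1e-12)
    expect_true(h$ci_low <= h$hr && h$hr <= h$ci_high)
    same <- hazardRatio(a$t, a$e, a$t, a$e, method = m)
    expect_equal(same$hr, 1, tolerance = 1e-6)
  }

  # planted proportional hazards, true HR 2, n = 1000/arm, no censoring:
  # Cox recovers the truth within asymptotic tolerance, and the O/E
  # estimator agrees with Cox within 15%
  set.seed(11)
  tA <- rexp(1000, 0.2); tB <- rexp(1000, 0.1)
  cox <- hazardRatio(tA, rep(TRUE, 1000), tB, rep(TRUE, 1000), method = "cox")
  expect_gt(cox$hr, 1.8); expect_lt(cox$hr, 2.2)
  mh <- hazardRatio(tA, rep(TRUE, 1000), tB, rep(TRUE, 1000))
  expect_lt(abs(mh$hr - cox$hr) / cox$hr, 0.15)
})

test_that("compareGroups bundles medians, log-rank and HR, routing the endpoint", {
  set.seed(21)
  n <- 600
  lab <- rep(c(TRUE, FALSE), each = n / 2)
  t <- ifelse(lab, rexp(n, 0.05), rexp(n, 0.10))  # planted HR 0.5 for A
  co <- makeSurvCohort(t, rep(TRUE, n))
  cmp <- compareGroups(co, lab, "OS")
  expect_lt(cmp$hr, 1)
  expect_lt(cmp$hr_ci_high, 1)  # CI excludes 1 at this n
  expect_equal(cmp$n_a, 300)

  # clone comparison is exactly null
  co2 <- makeSurvCohort(c(1, 2, 3, 4), c(TRUE, TRUE, TRUE, FALSE))
  cl <- clinicalData(co2)
  cl2 <- cl; cl2$patient_id <- paste0(cl$patient_id, "b")
  both <- buildCohort(rbind(cl, cl2),
                      data.frame(patient_id = character(),
                                 gene = character(), effect = character()))
  cmp2 <- compareGroups(both, rep(c(TRUE, FALSE), each = 4), "OS")
  expect_equal(cmp2$p_value, 1, tolerance = 1e-9)
  expect_equal(cmp2$hr, 1, tolerance = 1e-9)

  # PFS endpoint uses the pfs fields (here pfs = os/2)
  pf <- compareGroups(co, lab, "PFS")
  expect_equal(pf$median_a, cmp$median_a / 2, tolerance = 1e-9)

  expect_error(compareGroups(co, rep(TRUE, n), "OS"), "group B")
})
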