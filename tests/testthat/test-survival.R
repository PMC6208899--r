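test_that("the DRP coefficient rescales exactly with scalePoints", {
  coh <- simulateCohort(nPatients = 140, seed = 201)
  f50 <- fitCoxContinuous(coh, scalePoints = 50)
  f25 <- fitCoxContinuous(coh, scalePoints = 25)
  expect_equal(coxSummary(f50)$coef, 2 * coxSummary(f25)$coef,
               tolerance = 1e-10)
  # the hazard ratio for a fixed difference is scale-free
  expect_equal(hrForDifference(f50, 80), hrForDifference(f25, 80),
               tolerance = 1e-8)
})

test_that("one-sided p is the protective-direction half of the two-sided p", {
  coh <- simulateCohort(nPatients = 200, beta50 = log(0.5), seed = 202)
  s <- coxSummary(fitCoxContinuous(coh))
  expect_lt(s$coef, 0)
  expect_equal(s$pOneSided, s$pTwoSided / 2)

  cohH <- simulateCohort(nPatients = 300, beta50 = log(2.5), seed = 203)
  sH <- coxSummary(fitCoxContinuous(cohH))
  expect_gt(sH$coef, 0)
  expect_equal(sH$pOneSided, 1 - sH$pTwoSided / 2)
})

test_that("complete-case counting is exact and errors are explicit", {
  coh <- makeTinyCohort(40)
  coh$drp[c(3, 9)] <- NA
  fit <- fitCoxContinuous(coh)
  expect_equal(fit@nUsed, 38L)
  expect_equal(fit@nEvents, sum(coh$progression[-c(3, 9)]))

  noEvents <- makeTinyCohort(20)
  noEvents$progression <- FALSE
  expect_error(fitCoxContinuous(noEvents), "at least 2 events")
  flat <- makeTinyCohort(20)
  flat$drp <- 50
  expect_error(fitCoxContinuous(flat), "constant")
})

test_that("binary-covariate Cox score test equals the log-rank chi-square", {
  coh <- makeTinyCohort(30)
  coh$drp <- ifelse(seq_len(30) %% 2 == 0, 100, 0)  # binary covariate
  fit <- fitCoxContinuous(coh, strataVar = NULL)
  lr <- survival::survdiff(
    survival::Surv(ttp_months, progression) ~ drp, data = coh)
  expect_equal(unname(summary(fit@fit)$sctest["test"]), lr$chisq,
               tolerance = 1e-6)
})

test_that("hazard-ratio rescaling matches the analytic transform", {
  expect_equal(hrForDifference(0.55, 0), 1)
  expect_equal(hrForDifference(0.55, 50), 0.55)
  expect_equal(round(hrForDifference(0.55, 80), 4), 0.3842)
  # against a fitted model: delta = scalePoints returns exp(coef)
  coh <- simulateCohort(nPatients = 200, seed = 204)
  fit <- fitCoxContinuous(coh)
  expect_equal(hrForDifference(fit, 50), coxSummary(fit)$hr)
  expect_equal(hrForDifference(fit, 0), 1)
})

test_that("the one-sided Wald test is calibrated under the null", {
  pvals <- vapply(1:400, function(i) {
    coh <- simulateCohort(nPatients = 140, beta50 = 0, seed = 1000 + i)
    coxSummary(fitCoxContinuous(coh))$pOneSided
  }, numeric(1))
  rejection <- mean(pvals < 0.05)
  expect_lt(abs(rejection - 0.05), 0.03)
  # p-values roughly uniform
  expect_lt(abs(mean(pvals) - 0.5), 0.05)
})

test_that("multivariate model uses the stated reference levels", {
  coh <- simulateCohort(nPatients = 2000, seed = 205)
  fit <- fitCoxMultivariate(coh)
  cf <- names(coef(fit@fit))
  # reference levels never appear as coefficients
  expect_false(any(grepl("er_statuspositive", cf)))
  expect_false(any(grepl("age_group50-60", cf, fixed = TRUE)))
  expect_false(any(grepl("n_met_sites1$", cf)))
  expect_false(any(grepl("ps0-1", cf, fixed = TRUE)))
  expect_true("er_statusnegative" %in% cf)
  expect_true("drp_scaled" %in% cf)
  # complete-case: records with missing ER or PS are dropped
  used <- complete.cases(coh[, c("drp", "ttp_months", "progression",
                                 "age_group", "er_status", "n_met_sites",
                                 "ps", "line")])
  expect_equal(fit@nUsed, sum(used))
})

test_that("multivariate fit recovers a planted ER-negative hazard", {
  coh <- simulateCohort(nPatients = 5000,
                        covariateBetas = list(er_negative = log(4.5)),
                        seed = 206)
  fit <- fitCoxMultivariate(coh)
  hrER <- exp(coef(fit@fit)["er_statusnegative"])
  expect_gt(unname(hrER), 3.8)
  expect_lt(unname(hrER), 5.3)
})

test_that("independent covariates leave the DRP estimate unconfounded", {
  coh <- simulateCohort(nPatients = 5000, seed = 207)
  bUni <- coxSummary(fitCoxContinuous(coh))$coef
  fitMv <- fitCoxMultivariate(coh)
  bMv <- unname(coef(fitMv@fit)["drp_scaled"])
  seUni <- coxSummary(fitCoxContinuous(coh))$se
  expect_lt(abs(bMv - bUni), 2 * seUni)
})

test_that("interaction test behaves at the null, with power, and on errors", {
  # planted product term log(2): detectable at n = 2000
  set.seed(208)
  coh <- simulateCohort(nPatients = 2000, beta50 = log(0.55), seed = 208)
  rate <- 0.135 * exp(log(0.55) * coh$drp / 50 +
                        log(2) * (coh$drp / 50) * coh$prior_chemo)
  coh$ttp_months <- rexp(2000) / rate
  coh$progression <- TRUE
  res <- testInteraction(coh, "prior_chemo")
  expect_lt(res$p, 0.05)
  expect_equal(res$df, 1L)

  # constant or fully missing modifier -> error
  cohC <- simulateCohort(nPatients = 100, seed = 209)
  cohC$prior_taxane <- TRUE
  expect_error(testInteraction(cohC, "prior_taxane"), "constant")
  cohC$prior_taxane <- NA
  expect_error(testInteraction(cohC, "prior_taxane"), "no observed")
})

test_that("interaction test is calibrated when only main effects exist", {
  pvals <- vapply(1:200, function(i) {
    coh <- simulateCohort(nPatients = 140, beta50 = log(0.55),
                          seed = 3000 + i)
    testInteraction(coh, "prior_chemo")$p
  }, numeric(1))
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.05)
})

test_that("dichotomized KM detects a planted group difference", {
  set.seed(210)
  coh <- simulateCohort(nPatients = 1000, beta50 = log(0.5) / 2, seed = 210)
  # sharpen to an exact two-group HR of 0.5
  rate <- 0.1 * ifelse(coh$drp >= 50, 0.5, 1)
  coh$ttp_months <- rexp(1000) / rate
  coh$progression <- TRUE
  km <- kmLogrankDichotomized(coh)
  expect_lt(km@pOneSided, 0.001)
  expect_gt(km@medians["high"], km@medians["low"])
  expect_equal(sum(km@groupSizes), 1000L)
})

test_that("KM one-sided p centres on 0.5 for exchangeable groups", {
  pvals <- vapply(1:150, function(i) {
    coh <- simulateCohort(nPatients = 200, beta50 = 0, seed = 4000 + i)
    kmLogrankDichotomized(coh)@pOneSided
  }, numeric(1))
  expect_lt(abs(mean(pvals) - 0.5), 0.08)
})

test_that("degenerate KM inputs raise explicit errors", {
  coh <- makeTinyCohort(20)
  coh$drp <- coh$drp / 2  # all below 50
  expect_error(kmLogrankDichotomized(coh), "empty group")
  coh2 <- makeTinyCohort(20)
  coh2$progression <- FALSE
  expect_error(kmLogrankDichotomized(coh2), "no events")
})

test_that("martingale residuals sum to zero and flag planted curvature", {
  coh <- simulateCohort(nPatients = 140, seed = 211)
  fit <- fitCoxContinuous(coh)
  d <- martingaleDiagnostics(fit)
  expect_lt(abs(d$residualSum), 1e-8)
  expect_length(d$residuals, fit@nUsed)
  expect_true(is.finite(d$phP))

  # quadratic log-hazard in DRP -> curvature detected
  set.seed(212)
  n <- 2000
  drp <- runif(n, 0, 100)
  rate <- 0.1 * exp(log(0.4) * (drp / 50)^2)
  cohQ <- data.frame(patient_id = as.character(1:n), drp = drp,
                     ttp_months = rexp(n) / rate, progression = TRUE,
                     os_months = 1, death = FALSE, line = "1")
  fitQ <- fitCoxContinuous(cohQ)
  expect_lt(martingaleDiagnostics(fitQ)$quadraticP, 0.05)
})

test_that("martingale curvature test is calibrated under linearity", {
  pvals <- vapply(1:150, function(i) {
    coh <- simulateCohort(nPatients = 200, beta50 = log(0.55),
                          seed = 5000 + i)
    martingaleDiagnostics(fitCoxContinuous(coh))$quadraticP
  }, numeric(1))
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.06)
})

test_that("rescaling one stratum's baseline hazard leaves beta stable", {
  h <- setNames(c(0.115, 0.125, 0.135, 0.15, 0.165),
                c("1", "2", "3", "4", "5+"))
  h2 <- h; h2["3"] <- 5 * h2["3"]
  cohA <- simulateCohort(nPatients = 10000, baselineHazards = h,
                         seed = 213)
  cohB <- simulateCohort(nPatients = 10000, baselineHazards = h2,
                         seed = 213)
  sA <- coxSummary(fitCoxContinuous(cohA))
  sB <- coxSummary(fitCoxContinuous(cohB))
  expect_lt(abs(sA$coef - sB$coef), 3 * sqrt(sA$se^2 + sB$se^2))
})

test_that("the OS endpoint runs through the identical code path", {
  coh <- simulateCohort(nPatients = 500, osBeta50 = log(0.48), seed = 214)
  fit <- fitCoxContinuous(coh, endpoint = "os")
  expect_equal(fit@endpoint, "os")
  expect_equal(fit@nEvents,
               sum(coh$death[complete.cases(coh[, c("drp", "os_months",
                                                    "death", "line")])]))
  expect_lt(coxSummary(fit)$coef, 0)
  km <- kmLogrankDichotomized(coh, endpoint = "os")
  expect_s4_class(km, "DrpKMResult")
})
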