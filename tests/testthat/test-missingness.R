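# Missingness induction: exact independent-mechanism counts, calibrated
# dependent mechanisms, DAG structure.

test_that("independent mechanism assigns exact pattern counts", {
  pars <- make_scenario_params()
  cohort <- generate_cohort(pars$dgp, pars$outcome, n = 1000, seed = 1)
  miss <- induce_independent(cohort, 30, seed = 2)
  ms <- missingness_summary(miss)
  counts <- setNames(ms$n, ms$pattern)
  expect_equal(counts[["both"]], 150)
  expect_equal(counts[["petown_only"]], 75)
  expect_equal(counts[["antevd_only"]], 75)
  expect_equal(counts[["complete"]], 700)
  expect_equal(sum(ms$n), 1000)

  cohort200 <- generate_cohort(pars$dgp, pars$outcome, n = 200, seed = 3)
  miss200 <- induce_independent(cohort200, 15, seed = 4)
  ms200 <- missingness_summary(miss200)
  expect_equal(sum(ms200$n[ms200$pattern != "complete"]), 30)
  expect_equal(ms200$n[ms200$pattern == "both"], 15)

  expect_identical(induce_independent(cohort, 0), cohort)
  expect_error(induce_independent(cohort, 120))
})

test_that("only petown and antevd are ever masked", {
  pars <- make_scenario_params("observed", "enhanced", "RR")
  mp <- calibrate_intercepts(pars$dgp, pars$outcome,
                             missingness_params("DMO", 30), n_cal = 50000)
  cohort <- generate_cohort(pars$dgp, pars$outcome, n = 2000, seed = 11)
  for (m in list(induce_independent(cohort, 30, seed = 1),
                 induce_dependent(cohort, mp, seed = 2))) {
    other <- setdiff(names(cohort), c("petown", "antevd"))
    expect_false(anyNA(m[other]))
  }
})

test_that("zero-slope calibration matches the closed-form solution", {
  pars <- make_scenario_params()
  mp <- missingness_params("DMO", 30, nu_slopes = c(foodallergy = 0, cauc = 0, mage = 0),
                           tau_slopes = c(foodallergy = 0, cauc = 0, mage = 0))
  mp <- calibrate_intercepts(pars$dgp, pars$outcome, mp, n_cal = 20000,
                             use_cache = FALSE)
  # with no covariate dependence the two-pattern system solves analytically:
  # P(M_pet) = P(M_ant) = 0.225, P(both) = 0.15
  expect_equal(mp$nu[["nu0"]], logit(0.225), tolerance = 1e-6)
  expect_equal(mp$tau[["tau0"]], logit(0.075 / 0.775), tolerance = 1e-6)
  expect_equal(mp$tau[["tau0"]] + mp$tau[["tau4"]], logit(0.15 / 0.225),
               tolerance = 1e-6)
})

test_that("calibrated dependent missingness hits its target proportions", {
  pars <- make_scenario_params("observed", "enhanced", "RR")
  mp <- calibrate_intercepts(pars$dgp, pars$outcome,
                             missingness_params("DMO", 15), n_cal = 200000)
  big <- generate_cohort(pars$dgp, pars$outcome, n = 200000, seed = 21)
  miss <- induce_dependent(big, mp, seed = 22)
  ms <- missingness_summary(miss)
  incomplete <- 100 - ms$percent[ms$pattern == "complete"]
  expect_lt(abs(incomplete - 15), 0.5)
  expect_lt(abs(ms$percent[ms$pattern == "both"] - 7.5), 0.5)
  # equal singleton masses by construction of the calibration targets
  expect_lt(abs(ms$percent[ms$pattern == "petown_only"] -
                  ms$percent[ms$pattern == "antevd_only"]), 0.5)
})

test_that("DME slopes are exactly double the DMO slopes and recalibration differs", {
  dmo <- missingness_params("DMO", 30)
  dme <- missingness_params("DME", 30)
  expect_equal(unname(dme$nu[-1]), unname(2 * dmo$nu[-1]))
  expect_equal(unname(dme$tau[2:4]), unname(2 * dmo$tau[2:4]))
  pars <- make_scenario_params("observed", "enhanced", "RR")
  dmo <- calibrate_intercepts(pars$dgp, pars$outcome, dmo, n_cal = 30000)
  dme <- calibrate_intercepts(pars$dgp, pars$outcome, dme, n_cal = 30000)
  expect_false(isTRUE(all.equal(dmo$nu[["nu0"]], dme$nu[["nu0"]])))
})

test_that("dependent missingness concentrates in cases when outcome slopes are positive", {
  pars <- make_scenario_params("observed", "enhanced", "RR")
  mp <- missingness_params("DMO", 30,
                           nu_slopes = c(foodallergy = 3, cauc = 0, mage = 0),
                           tau_slopes = c(foodallergy = 3, cauc = 0, mage = 0))
  mp <- calibrate_intercepts(pars$dgp, pars$outcome, mp, n_cal = 30000)
  cohort <- generate_cohort(pars$dgp, pars$outcome, n = 50000, seed = 31)
  miss <- induce_dependent(cohort, mp, seed = 32)
  p_case <- mean(is.na(miss$antevd[miss$foodallergy == 1]))
  p_ctrl <- mean(is.na(miss$antevd[miss$foodallergy == 0]))
  expect_gt(p_case, p_ctrl)
})

test_that("an effectively -Inf intercept yields no petown missingness", {
  pars <- make_scenario_params()
  cohort <- generate_cohort(pars$dgp, pars$outcome, n = 1000, seed = 41)
  mp <- missingness_params("DMO", 30)
  mp$nu[["nu0"]] <- -50
  mp$tau[["tau0"]] <- -50; mp$tau[["tau4"]] <- 0
  miss <- induce_dependent(cohort, mp, seed = 42)
  expect_false(anyNA(miss$petown))
  expect_false(anyNA(miss$antevd))
})
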