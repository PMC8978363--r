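# FCS and MVNI engines and the weight-accommodation strategies.

test_that("strategy declarations enforce the framework rules", {
  expect_equal(imputation_strategy("FCS-WM")$accommodation, "weighted_model")
  expect_equal(imputation_strategy(framework = "MVNI",
                                   accommodation = "stratum_specific")$label,
               "MVNI-SS")
  expect_error(imputation_strategy(framework = "MVNI",
                                   accommodation = "weighted_model"),
               "only available under FCS")
  expect_equal(length(mi_strategies()), 7)
})

test_that("the imputation design matches each strategy's contract", {
  s <- make_test_sample(seed = 70)
  base <- c("foodallergy", "vdi", "cauc", "hxfamall", "nsib1", "nsib2",
            "antevd", "mage", "seifa1", "seifa2")
  des <- build_imputation_design(s, imputation_strategy("FCS-WO"))
  expect_setequal(des$petown$predictors, base)
  expect_false(des$petown$stratify_by_outcome)

  des <- build_imputation_design(s, imputation_strategy("FCS-SS"))
  expect_false("foodallergy" %in% des$petown$predictors)
  expect_true(des$petown$stratify_by_outcome)

  des <- build_imputation_design(s, imputation_strategy("FCS-WX"))
  expect_true(all(c("foodallergy:vdi", "foodallergy:cauc",
                    "foodallergy:antevd") %in% des$petown$predictors))
  expect_false("foodallergy:petown" %in% des$petown$predictors)

  des <- build_imputation_design(s, imputation_strategy("FCS-WM"))
  expect_true(des$antevd$weighted)
})

test_that("observed cells are immutable under every strategy", {
  s <- make_test_sample(n = 500, seed = 71)
  cfg <- imputation_config(m = 2, fcs_cycles = 3, mvni_burnin = 20)
  obs_pet <- !is.na(s$petown); obs_ant <- !is.na(s$antevd)
  for (lab in names(mi_strategies())) {
    imp <- impute_sample(s, imputation_strategy(lab), cfg, seed = 72)
    expect_true(imp$converged, label = lab)
    for (d in imp$datasets) {
      expect_identical(d$petown[obs_pet], s$petown[obs_pet])
      expect_identical(d$antevd[obs_ant], s$antevd[obs_ant])
      expect_identical(d[setdiff(names(s), c("petown", "antevd"))],
                       s[setdiff(names(s), c("petown", "antevd"))])
      expect_false(anyNA(d$petown)); expect_false(anyNA(d$antevd))
    }
  }
})

test_that("imputations vary between datasets and FCS values are binary", {
  s <- make_test_sample(n = 500, seed = 73)
  cfg <- imputation_config(m = 5, fcs_cycles = 3, mvni_burnin = 20)
  na_pet <- is.na(s$petown)
  impF <- impute_sample(s, imputation_strategy("FCS-WO"), cfg, seed = 74)
  vals <- sapply(impF$datasets, function(d) d$petown[na_pet])
  expect_true(all(vals %in% 0:1))
  expect_gt(var(colMeans(vals)), 0)

  impM <- impute_sample(s, imputation_strategy("MVNI-WO"), cfg, seed = 75)
  valsM <- sapply(impM$datasets, function(d) d$petown[na_pet])
  # joint-normal draws are continuous and carried without rounding
  expect_gt(mean(valsM != round(valsM)), 0.5)
  expect_gt(var(colMeans(valsM)), 0)
})

test_that("with no missing values every strategy returns m copies of the input", {
  pars <- make_scenario_params("observed", "enhanced", "RR")
  cohort <- generate_cohort(pars$dgp, pars$outcome, n = 300, seed = 76)
  s <- select_subcohort(cohort, 0.3, seed = 77)
  cfg <- imputation_config(m = 3, fcs_cycles = 2, mvni_burnin = 5)
  for (lab in c("FCS-WO", "MVNI-WX")) {
    imp <- impute_sample(s, imputation_strategy(lab), cfg, seed = 78)
    expect_true(imp$converged)
    expect_length(imp$datasets, 3)
    expect_identical(imp$datasets[[1]], s)
  }
})

test_that("a single missing value is imputed from its posterior predictive", {
  # petown generated independently of everything at prevalence 0.8; the
  # long-run imputation frequency must match the posterior predictive of
  # the observed data, estimated by direct Monte Carlo over posterior
  # coefficient draws
  pars <- make_scenario_params("observed", "enhanced", "RR")
  cohort <- generate_cohort(pars$dgp, pars$outcome, n = 200, seed = 79)
  set.seed(80)
  cohort$petown <- rbinom(200, 1, 0.8)
  cohort$weight <- 1
  miss_row <- 17
  cohort$petown[miss_row] <- NA
  cfg <- imputation_config(m = 400, fcs_cycles = 2)
  imp <- fcs_impute(cohort, imputation_strategy("FCS-WO"), cfg, seed = 81)
  freq <- mean(vapply(imp$datasets, function(d) d$petown[miss_row], 0))

  # oracle: fit the same logistic model, draw 10,000 coefficient vectors
  # from N(beta, V), average expit at the missing record's covariates
  d <- transform(cohort[-miss_row, ], nsib1 = as.integer(nsib == 1),
                 nsib2 = as.integer(nsib == 2),
                 seifa1 = as.integer(seifa == 1),
                 seifa2 = as.integer(seifa == 2))
  fit <- glm(petown ~ foodallergy + vdi + cauc + hxfamall + nsib1 + nsib2 +
               antevd + mage + seifa1 + seifa2, family = binomial(),
             data = d)
  xr <- transform(cohort[miss_row, ], nsib1 = as.integer(nsib == 1),
                  nsib2 = as.integer(nsib == 2),
                  seifa1 = as.integer(seifa == 1),
                  seifa2 = as.integer(seifa == 2))
  X <- as.matrix(cbind(1, xr[c("foodallergy", "vdi", "cauc", "hxfamall",
                               "nsib1", "nsib2", "antevd", "mage",
                               "seifa1", "seifa2")]))
  set.seed(82)
  bdraws <- MASS::mvrnorm(10000, coef(fit), vcov(fit))
  oracle <- mean(plogis(bdraws %*% t(X)))
  # 400 draws: binomial MC error ~ sqrt(p q / 400) ~ 0.02
  expect_lt(abs(freq - oracle), 0.08)
})

test_that("FCS preserves marginals under MCAR missingness", {
  pars <- make_scenario_params("observed", "enhanced", "RR")
  cohort <- generate_cohort(pars$dgp, pars$outcome, n = 2000, seed = 83)
  truth <- mean(cohort$antevd)
  miss <- induce_independent(cohort, 30, seed = 84)
  miss$weight <- 1
  imp <- fcs_impute(miss, imputation_strategy("FCS-WO"),
                    imputation_config(m = 30, fcs_cycles = 5), seed = 85)
  expect_true(imp$converged)
  pooled_prev <- mean(vapply(imp$datasets, function(d) mean(d$antevd), 0))
  expect_lt(abs(pooled_prev - truth), 0.05)
})

test_that("MVNI reproduces the conditional-normal oracle on a bivariate toy", {
  # x fully observed, y jointly normal with known correlation 0: imputed
  # values must match y's marginal within MC error
  set.seed(86)
  n <- 400
  toy <- data.frame(
    foodallergy = rbinom(n, 1, 0.3), vdi = rbinom(n, 1, 0.5),
    cauc = rbinom(n, 1, 0.5), hxfamall = rbinom(n, 1, 0.5),
    nsib = sample(0:2, n, replace = TRUE),
    seifa = sample(0:2, n, replace = TRUE),
    mage = rnorm(n, 30, 4),
    petown = rnorm(n, 2, 1),     # continuous stand-in, independent
    antevd = rbinom(n, 1, 0.5), weight = 1)
  mask <- seq_len(150)
  truth_vals <- toy$petown[mask]
  toy$petown[mask] <- NA
  imp <- mvni_impute(toy, imputation_strategy("MVNI-WO"),
                     imputation_config(m = 20, mvni_burnin = 30), seed = 87)
  expect_true(imp$converged)
  imputed <- unlist(lapply(imp$datasets, function(d) d$petown[mask]))
  expect_lt(abs(mean(imputed) - 2), 3 * 1 / sqrt(250) + 0.1)
  expect_lt(abs(sd(imputed) - 1), 0.15)
})

test_that("posterior coefficient draws follow N(beta, V)", {
  b <- c(0.5, -1, 2)
  V <- matrix(c(0.04, 0.01, 0, 0.01, 0.09, -0.02, 0, -0.02, 0.16), 3)
  draws <- t(replicate(10000, posterior_draw_glm(b, V)))
  expect_lt(max(abs(colMeans(draws) - b)), 0.02)
  expect_lt(max(abs(cov(draws) - V)), 0.01)
  # zero-covariance limit returns the estimate itself
  expect_equal(posterior_draw_glm(b, matrix(0, 3, 3)), b)
  # seeded draws reproduce
  expect_identical(posterior_draw_glm(b, V, seed = 9),
                   posterior_draw_glm(b, V, seed = 9))
  # a negative-definite covariance flags failure
  expect_null(posterior_draw_glm(b, -V))
})

test_that("weight-proxy strategies coincide when weights carry no information", {
  # missingness independent of outcome and outcome independent of
  # covariates: FCS-WO, FCS-SS and FCS-WM all reduce to the same
  # conditional model, so pooled estimates agree statistically
  pars <- make_scenario_params("observed", "observed", "OR")
  spec <- pars$outcome
  spec$coef[2:8] <- 0
  cohort <- generate_cohort(pars$dgp, spec, n = 4000, seed = 88)
  miss <- induce_independent(cohort, 30, seed = 89)
  miss$weight <- 1
  cfg <- imputation_config(m = 20, fcs_cycles = 5)
  pooled <- vapply(c("FCS-WO", "FCS-SS", "FCS-WM"), function(lab) {
    imp <- fcs_impute(miss, imputation_strategy(lab), cfg,
                      seed = 90 + match(lab, c("FCS-WO", "FCS-SS", "FCS-WM")))
    fits <- lapply(imp$datasets, function(d) fit_ipw_glm(d, family = "OR"))
    rubin_pool(vapply(fits, `[[`, 0, "estimate"),
               vapply(fits, `[[`, 0, "se"))$estimate
  }, numeric(1))
  # differences bounded well inside one pooled SE (~0.15 on this design)
  expect_lt(max(pooled) - min(pooled), 0.15)
})
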