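# Sequential cohort generator: marginals, conditional structure,
# degenerate limits, determinism.

test_that("scenario parameter assembly follows the variant and association rules", {
  sp <- make_scenario_params("observed", "observed", "RR")
  expect_equal(sp$outcome$coef[["vdi"]], log(1.16))
  sp <- make_scenario_params("observed", "enhanced", "OR")
  expect_equal(sp$outcome$coef[["vdi"]], log(2.0))
  expect_equal(make_scenario_params("observed", "observed", "OR")$outcome$coef[["vdi"]],
               log(1.18))
  # extreme variant doubles (by default) the maternal-age slopes of the
  # petown, antevd and exposure models, leaving other slopes untouched
  obs <- dgp_params("observed"); ext <- dgp_params("extreme")
  expect_equal(ext$rho[["r1"]], 2 * obs$rho[["r1"]])
  expect_equal(ext$phi[["f1"]], 2 * obs$phi[["f1"]])
  expect_equal(ext$psi[["p1"]], 2 * obs$psi[["p1"]])
  expect_equal(ext$kappa[["k1"]], obs$kappa[["k1"]])
  ext3 <- dgp_params("extreme", strengthen = 3)
  expect_equal(ext3$psi[["p1"]], 3 * obs$psi[["p1"]])
  expect_error(make_scenario_params("bogus"), "arg")
})

test_that("generated marginals match an independent forward-simulator oracle", {
  n <- 200000
  params <- dgp_params("observed")
  cohort <- generate_covariates(params, n, seed = 101)
  set.seed(202)
  oracle <- oracle_covariates(params, n)
  for (v in c("cauc", "hxfamall", "petown", "antevd", "vdi")) {
    # each empirical marginal carries MC error ~0.001; 0.01 covers both
    expect_lt(abs(mean(cohort[[v]]) - mean(oracle[[v]])), 0.01)
  }
  for (k in 0:2) {
    expect_lt(abs(mean(cohort$nsib == k) - mean(oracle$nsib == k)), 0.01)
    expect_lt(abs(mean(cohort$seifa == k) - mean(oracle$seifa == k)), 0.01)
  }
  expect_lt(abs(mean(cohort$mage) - mean(oracle$mage)), 0.1)
  expect_lt(abs(sd(cohort$mage) - sd(oracle$mage)), 0.1)
})

test_that("conditional models recover their generating coefficients", {
  n <- 200000
  params <- dgp_params("observed")
  cohort <- generate_covariates(params, n, seed = 77)
  # maternal age on its single parent (identity link)
  fit <- lm(mage ~ cauc, data = cohort)
  expect_lt(abs(coef(fit)[["cauc"]] - params$delta[["d1"]]),
            3 * summary(fit)$coefficients["cauc", 2])
  # pet ownership on its stated parents (logit link)
  df <- transform(cohort, s1 = as.integer(seifa == 1),
                  s2 = as.integer(seifa == 2),
                  n1 = as.integer(nsib == 1), n2 = as.integer(nsib == 2))
  fit <- glm(petown ~ mage + cauc + s1 + s2 + hxfamall + n1 + n2,
             family = binomial(), data = df)
  truth <- params$rho[-1]
  est <- coef(fit)[-1]
  se <- summary(fit)$coefficients[-1, 2]
  expect_true(all(abs(est - truth) < 3 * se))
  # no dependence on non-parents: hxfamall depends only on cauc
  fit <- glm(hxfamall ~ cauc + mage, family = binomial(), data = df)
  expect_lt(abs(coef(fit)[["mage"]]),
            3 * summary(fit)$coefficients["mage", 2])
})

test_that("degenerate parameter settings behave analytically", {
  params <- dgp_params("observed")
  params$delta[["d1"]] <- 0; params$sigma <- 0
  cohort <- generate_covariates(params, 500, seed = 5)
  expect_true(all(cohort$mage == params$delta[["d0"]]))

  params <- dgp_params("observed")
  params$psi[] <- 0
  params$psi[["p0"]] <- logit(0.3)
  cohort <- generate_covariates(params, 100000, seed = 6)
  expect_lt(abs(mean(cohort$vdi) - 0.3), 3 * sqrt(0.3 * 0.7 / 100000) + 0.001)
})

test_that("outcome generation matches its link and guards the log link", {
  params <- dgp_params("observed")
  cohort <- generate_covariates(params, 100000, seed = 8)
  spec <- outcome_spec("RR", "observed")
  spec$coef[] <- 0; spec$coef[["intercept"]] <- log(0.2)
  out <- generate_outcome(cohort, spec, seed = 9)
  expect_lt(abs(mean(out$foodallergy) - 0.2), 0.005)

  # a log-link model implying p >= 1 must fail loudly with the pattern
  bad <- outcome_spec("RR", "enhanced")
  bad$coef[["intercept"]] <- 0.5
  expect_error(generate_outcome(cohort, bad), "probability >= 1")

  # null OR model: adjusted association ~ 1
  spec0 <- outcome_spec("OR", "observed")
  spec0$coef[["vdi"]] <- 0
  out <- generate_outcome(cohort, spec0, seed = 10)
  fit <- fit_ipw_glm(out, family = "OR")
  expect_lt(abs(fit$estimate), 3 * fit$se)
})

test_that("generation is bit-identical under a fixed seed", {
  params <- dgp_params("extreme")
  spec <- outcome_spec("RR", "enhanced", "extreme")
  a <- generate_cohort(params, spec, n = 400, seed = 33)
  b <- generate_cohort(params, spec, n = 400, seed = 33)
  expect_identical(a, b)
  c <- generate_cohort(params, spec, n = 400, seed = 34)
  expect_false(identical(a, c))
})

test_that("parameter registry round-trips through the plain-text format", {
  p <- dgp_params("extreme")
  path <- withr::local_tempfile(fileext = ".txt")
  write_registry(p, path)
  flat <- read_registry(path)
  expect_equal(unname(flat["psi.p1"]), p$psi[["p1"]])
  expect_equal(unname(flat["sigma"]), p$sigma)
  expect_equal(length(flat), length(ccmisim:::flatten_params(p)))
})
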