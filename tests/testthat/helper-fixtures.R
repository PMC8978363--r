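# Shared fixtures: all simulated in code at test time.

# A small case-cohort sample with induced independent missingness,
# weights attached.
make_test_sample <- function(n = 600, p = 30, pi = 0.3, seed = 42,
                             estimand = "RR") {
  pars <- make_scenario_params("observed", "enhanced", estimand)
  cohort <- generate_cohort(pars$dgp, pars$outcome, n = n, seed = seed)
  miss <- induce_independent(cohort, p, seed = seed + 1)
  select_subcohort(miss, pi, seed = seed + 2)
}

# Independent forward simulator for the covariate DGP, written directly
# from the generating equations (used as the brute-force oracle for
# marginal checks; deliberately shares no code with the package
# generator).
oracle_covariates <- function(params, n) {
  ex <- function(x) 1 / (1 + exp(-x))
  cauc <- runif(n) < params$p_cauc
  mage <- params$delta[["d0"]] + params$delta[["d1"]] * cauc +
    rnorm(n, 0, params$sigma)
  z <- params$zeta; e <- params$eta
  w1 <- exp(z[["z0"]] + z[["z1"]] * mage + z[["z2"]] * cauc)
  w2 <- exp(e[["e0"]] + e[["e1"]] * mage + e[["e2"]] * cauc)
  u <- runif(n) * (1 + w1 + w2)
  seifa <- ifelse(u < 1, 0, ifelse(u < 1 + w1, 1, 2))
  hx <- runif(n) < ex(params$iota[["i0"]] + params$iota[["i1"]] * cauc)
  k <- params$kappa; l <- params$lambda
  w1 <- exp(k[["k0"]] + k[["k1"]] * mage + k[["k2"]] * cauc +
              k[["k3"]] * (seifa == 1) + k[["k4"]] * (seifa == 2) +
              k[["k5"]] * hx)
  w2 <- exp(l[["l0"]] + l[["l1"]] * mage + l[["l2"]] * cauc +
              l[["l3"]] * (seifa == 1) + l[["l4"]] * (seifa == 2) +
              l[["l5"]] * hx)
  u <- runif(n) * (1 + w1 + w2)
  nsib <- ifelse(u < 1, 0, ifelse(u < 1 + w1, 1, 2))
  r <- params$rho
  pet <- runif(n) < ex(r[["r0"]] + r[["r1"]] * mage + r[["r2"]] * cauc +
                         r[["r3"]] * (seifa == 1) + r[["r4"]] * (seifa == 2) +
                         r[["r5"]] * hx + r[["r6"]] * (nsib == 1) +
                         r[["r7"]] * (nsib == 2))
  f <- params$phi
  ant <- runif(n) < ex(f[["f0"]] + f[["f1"]] * mage + f[["f2"]] * cauc +
                         f[["f3"]] * (seifa == 1) + f[["f4"]] * (seifa == 2) +
                         f[["f5"]] * hx + f[["f6"]] * (nsib == 1) +
                         f[["f7"]] * (nsib == 2))
  ps <- params$psi
  vdi <- runif(n) < ex(ps[["p0"]] + ps[["p1"]] * mage + ps[["p2"]] * cauc +
                         ps[["p3"]] * (seifa == 1) + ps[["p4"]] * (seifa == 2) +
                         ps[["p5"]] * hx + ps[["p6"]] * (nsib == 1) +
                         ps[["p7"]] * (nsib == 2) + ps[["p8"]] * pet +
                         ps[["p9"]] * ant)
  data.frame(cauc = cauc + 0, mage = mage, seifa = seifa, hxfamall = hx + 0,
             nsib = nsib, petown = pet + 0, antevd = ant + 0, vdi = vdi + 0)
}
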