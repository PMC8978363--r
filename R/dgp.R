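# Sequential synthetic-cohort generator.
#
# Variables are drawn in causal order, each from its conditional model
# given previously generated parents:
#   cauc     ~ Bernoulli(p_cauc)
#   mage     = d0 + d1 cauc + N(0, sigma^2)
#   seifa    ~ baseline-category logit (zeta, eta) on mage, cauc
#   hxfamall ~ logistic (iota) on cauc
#   nsib     ~ baseline-category logit (kappa, lambda) on mage, cauc,
#              seifa indicators, hxfamall
#   petown   ~ logistic (rho)  on mage, cauc, seifa, hxfamall, nsib
#   antevd   ~ logistic (phi)  on the same parents as petown
#   vdi      ~ logistic (psi)  on all of the above plus petown, antevd
# The outcome is added afterwards by generate_outcome() under a log-link
# (risk ratio) or logit-link (odds ratio) model so the target analysis is
# correctly specified.

#' Generate the covariates of one complete cohort
#'
#' @param params a `ccmi_dgp_params` registry, see [dgp_params()].
#' @param n cohort size.
#' @param seed optional integer seed; when supplied the draw is
#'   reproducible independent of the caller's RNG state.
#' @return a data frame (one row per infant) with columns `id`, `cauc`,
#'   `mage`, `seifa`, `hxfamall`, `nsib`, `petown`, `antevd`, `vdi`.
#' @export
generate_covariates <- function(params, n, seed = NULL) {
  validate_dgp_params(params)
  stopifnot(n >= 1)
  with_seed(seed, {
    cauc <- stats::rbinom(n, 1, params$p_cauc)
    mage <- params$delta[["d0"]] + params$delta[["d1"]] * cauc +
      stats::rnorm(n, 0, params$sigma)

    z <- params$zeta; e <- params$eta
    seifa <- rcat_logit(cbind(
      z[["z0"]] + z[["z1"]] * mage + z[["z2"]] * cauc,
      e[["e0"]] + e[["e1"]] * mage + e[["e2"]] * cauc))
    s1 <- as.integer(seifa == 1); s2 <- as.integer(seifa == 2)

    i <- params$iota
    hxfamall <- stats::rbinom(n, 1, expit(i[["i0"]] + i[["i1"]] * cauc))

    k <- params$kappa; l <- params$lambda
    nsib <- rcat_logit(cbind(
      k[["k0"]] + k[["k1"]] * mage + k[["k2"]] * cauc + k[["k3"]] * s1 +
        k[["k4"]] * s2 + k[["k5"]] * hxfamall,
      l[["l0"]] + l[["l1"]] * mage + l[["l2"]] * cauc + l[["l3"]] * s1 +
        l[["l4"]] * s2 + l[["l5"]] * hxfamall))
    n1 <- as.integer(nsib == 1); n2 <- as.integer(nsib == 2)

    r <- params$rho
    petown <- stats::rbinom(n, 1, expit(
      r[["r0"]] + r[["r1"]] * mage + r[["r2"]] * cauc + r[["r3"]] * s1 +
        r[["r4"]] * s2 + r[["r5"]] * hxfamall + r[["r6"]] * n1 +
        r[["r7"]] * n2))

    f <- params$phi
    antevd <- stats::rbinom(n, 1, expit(
      f[["f0"]] + f[["f1"]] * mage + f[["f2"]] * cauc + f[["f3"]] * s1 +
        f[["f4"]] * s2 + f[["f5"]] * hxfamall + f[["f6"]] * n1 +
        f[["f7"]] * n2))

    p <- params$psi
    vdi <- stats::rbinom(n, 1, expit(
      p[["p0"]] + p[["p1"]] * mage + p[["p2"]] * cauc + p[["p3"]] * s1 +
        p[["p4"]] * s2 + p[["p5"]] * hxfamall + p[["p6"]] * n1 +
        p[["p7"]] * n2 + p[["p8"]] * petown + p[["p9"]] * antevd))

    # petown and antevd are stored as doubles: they are the imputable
    # covariates and joint-normal imputation fills them with continuous
    # values
    data.frame(id = seq_len(n), cauc = cauc, mage = mage, seifa = seifa,
               hxfamall = hxfamall, nsib = nsib,
               petown = as.numeric(petown), antevd = as.numeric(antevd),
               vdi = vdi)
  })
}

# Linear predictor of the outcome analysis model evaluated on a cohort or
# case-cohort sample; `coef` is the named vector of an outcome spec.
outcome_linpred <- function(data, coef) {
  coef[["intercept"]] +
    coef[["vdi"]] * data$vdi +
    coef[["cauc"]] * data$cauc +
    coef[["petown"]] * data$petown +
    coef[["nsib1"]] * as.integer(data$nsib == 1) +
    coef[["nsib2"]] * as.integer(data$nsib == 2) +
    coef[["antevd"]] * data$antevd +
    coef[["hxfamall"]] * data$hxfamall
}

#' Add the binary outcome to a complete cohort
#'
#' Draws `foodallergy ~ Bernoulli(p_i)` where `log p_i` (risk-ratio
#' estimand) or `logit p_i` (odds-ratio estimand) is the analysis-model
#' linear predictor, so the target analysis is correctly specified by
#' construction.  Under the log link, any covariate pattern implying
#' `p_i >= 1` aborts generation with a diagnostic listing the offending
#' pattern.
#'
#' @param cohort output of [generate_covariates()].
#' @param spec a `ccmi_outcome_spec`.
#' @param seed optional integer seed.
#' @return the cohort with a `foodallergy` column appended.
#' @export
generate_outcome <- function(cohort, spec, seed = NULL) {
  stopifnot(inherits(spec, "ccmi_outcome_spec"))
  if (anyNA(cohort[c("cauc", "mage", "seifa", "hxfamall", "nsib", "petown",
                     "antevd", "vdi")]))
    stop("cohort must be complete before outcome generation")
  lp <- outcome_linpred(cohort, spec$coef)
  if (spec$estimand == "RR") {
    pr <- exp(lp)
    if (any(pr >= 1)) {
      bad <- cohort[which.max(pr), c("vdi", "cauc", "petown", "nsib",
                                     "antevd", "hxfamall")]
      stop("log-link outcome model implies probability >= 1 (max ",
           signif(max(pr), 4), ") at covariate pattern: ",
           paste(names(bad), unlist(bad), sep = "=", collapse = ", "))
    }
  } else {
    pr <- expit(lp)
  }
  with_seed(seed, {
    cohort$foodallergy <- stats::rbinom(nrow(cohort), 1, pr)
  })
  cohort
}

#' Generate one complete cohort (covariates plus outcome)
#'
#' Convenience wrapper around [generate_covariates()] and
#' [generate_outcome()] drawing both from a single seed.
#'
#' @param params a `ccmi_dgp_params`.
#' @param spec a `ccmi_outcome_spec`.
#' @param n cohort size (default 1000).
#' @param seed optional integer seed.
#' @export
generate_cohort <- function(params, spec, n = 1000, seed = NULL) {
  with_seed(seed, {
    cohort <- generate_covariates(params, n)
    generate_outcome(cohort, spec)
  })
}
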