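# Induction of covariate missingness in petown and antevd.
#
# Three mechanisms:
#   independent - missingness assigned completely at random with exact
#     pattern counts: of the p% incomplete records, half miss both
#     covariates and the remaining half miss exactly one (split evenly).
#   DMO - "dependent missingness, observed strength": indicators drawn
#     from logistic models on the outcome, Caucasian ethnicity and
#     maternal age, with the antevd indicator additionally depending on
#     the realized petown indicator (which controls the both-missing
#     overlap).
#   DME - "dependent missingness, enhanced": identical structure with all
#     slope coefficients exactly doubled.
# Intercepts (nu0, tau0) and the indicator-dependence coefficient (tau4)
# are not fixed constants: they are calibrated against a large cohort so
# the realized proportions hit the targets p% incomplete overall and
# p/2 % missing both covariates, with equal singleton masses.

.dmo_slopes <- list(nu = c(foodallergy = 0.5, cauc = -0.3, mage = 0.05),
                    tau = c(foodallergy = 0.5, cauc = -0.3, mage = 0.05))

#' Missingness mechanism parameters
#'
#' @param mechanism `"independent"`, `"DMO"` or `"DME"`.
#' @param p target overall percentage of records with at least one
#'   incomplete covariate (15 or 30 in the default grid).
#' @param nu_slopes,tau_slopes named slope vectors (foodallergy, cauc,
#'   mage) of the petown / antevd missingness models.  Defaults are the
#'   observed-strength values; under DME they are doubled exactly.
#' @return an object of class `ccmi_missingness_params`.  Intercepts
#'   `nu0`, `tau0` and the indicator-dependence coefficient `tau4` are
#'   `NA` until set by [calibrate_intercepts()].
#' @export
missingness_params <- function(mechanism = c("independent", "DMO", "DME"),
                               p = 30,
                               nu_slopes = .dmo_slopes$nu,
                               tau_slopes = .dmo_slopes$tau) {
  mechanism <- match.arg(mechanism)
  stopifnot(p >= 0, p < 100)
  mult <- if (mechanism == "DME") 2 else 1
  mp <- list(
    mechanism = mechanism, p = p,
    nu = c(nu0 = NA_real_, mult * nu_slopes),
    tau = c(tau0 = NA_real_, mult * tau_slopes, tau4 = NA_real_)
  )
  class(mp) <- "ccmi_missingness_params"
  mp
}

#' Independent (completely random) missingness with exact pattern counts
#'
#' Masks exactly `round(n p / 200)` records in both covariates and splits
#' the remaining incomplete records evenly between petown-only and
#' antevd-only (the extra record, when the split is odd, goes to
#' petown-only).  Records are chosen uniformly without replacement.
#'
#' @param cohort a complete cohort.
#' @param p target overall percentage incomplete.
#' @param seed optional integer seed.
#' @return the cohort with `NA`s in `petown` / `antevd`.
#' @export
induce_independent <- function(cohort, p, seed = NULL) {
  stopifnot(p >= 0, p < 100,
            !anyNA(cohort$petown), !anyNA(cohort$antevd))
  if (p == 0) return(cohort)
  n <- nrow(cohort)
  n_inc <- round(n * p / 100)
  n_both <- round(n * p / 200)
  if (n_inc > n) stop("p = ", p, " implies more masked records (", n_inc,
                      ") than cohort size ", n)
  rem <- n_inc - n_both
  n_pet <- ceiling(rem / 2)
  with_seed(seed, {
    idx <- sample.int(n, n_inc)
    both <- idx[seq_len(n_both)]
    pet_only <- idx[n_both + seq_len(n_pet)]
    ant_only <- idx[setdiff(seq_len(n_inc), seq_len(n_both + n_pet))]
    cohort$petown[c(both, pet_only)] <- NA_real_
    cohort$antevd[c(both, ant_only)] <- NA_real_
  })
  cohort
}

miss_linpred <- function(coef, cohort) {
  coef[[1]] + coef[["foodallergy"]] * cohort$foodallergy +
    coef[["cauc"]] * cohort$cauc + coef[["mage"]] * cohort$mage
}

#' Dependent missingness from calibrated logistic indicator models
#'
#' Draws the petown missingness indicator from its logistic model on the
#' outcome, ethnicity and maternal age, then the antevd indicator from
#' its model which additionally conditions on the realized petown
#' indicator, and masks the corresponding values.
#'
#' @param cohort a complete cohort including `foodallergy`.
#' @param mparams calibrated `ccmi_missingness_params` (see
#'   [calibrate_intercepts()]).
#' @param seed optional integer seed.
#' @export
induce_dependent <- function(cohort, mparams, seed = NULL) {
  stopifnot(inherits(mparams, "ccmi_missingness_params"),
            mparams$mechanism %in% c("DMO", "DME"))
  if (anyNA(mparams$nu) || anyNA(mparams$tau))
    stop("missingness intercepts are uncalibrated; run calibrate_intercepts()")
  with_seed(seed, {
    m_pet <- stats::rbinom(nrow(cohort), 1,
                           expit(miss_linpred(mparams$nu, cohort)))
    lp_ant <- miss_linpred(mparams$tau, cohort) +
      mparams$tau[["tau4"]] * m_pet
    m_ant <- stats::rbinom(nrow(cohort), 1, expit(lp_ant))
    cohort$petown[m_pet == 1] <- NA_real_
    cohort$antevd[m_ant == 1] <- NA_real_
  })
  cohort
}

#' Induce missingness under any mechanism
#'
#' @param cohort a complete cohort with outcome.
#' @param mparams `ccmi_missingness_params`; under the independent
#'   mechanism only the target `p` is used.
#' @param seed optional integer seed.
#' @export
induce_missingness <- function(cohort, mparams, seed = NULL) {
  if (mparams$mechanism == "independent")
    induce_independent(cohort, mparams$p, seed)
  else
    induce_dependent(cohort, mparams, seed)
}

# Cache of calibrated parameter sets, keyed by the full numeric content of
# (dgp, outcome, missingness) so any change re-triggers calibration.
.calibration_cache <- new.env(parent = emptyenv())

#' Calibrate the dependent-missingness intercepts
#'
#' Chooses `nu0`, `tau0` and `tau4` such that, in expectation over a large
#' calibration cohort generated from the supplied DGP, the proportions of
#' the four missingness patterns hit their targets: p% of records
#' incomplete overall, p/2 % missing both covariates, and the two
#' singleton patterns equal (p/4 % each).  Marginally this means
#' P(M_petown) = P(M_antevd) = 3p/400 and P(both) = p/200.
#'
#' Calibration is deterministic given the calibration cohort: target
#' probabilities are expectations of the logistic models over the cohort,
#' not Bernoulli realizations, and each intercept is found by monotone
#' root-finding.  `nu0` solves the petown marginal; `tau0` solves the
#' antevd-only mass (which does not involve `tau4`); `tau4` then solves
#' the both-missing mass.  Results are cached per parameter set.
#'
#' @param dgp a `ccmi_dgp_params`.
#' @param spec a `ccmi_outcome_spec`.
#' @param mparams `ccmi_missingness_params` with mechanism DMO or DME.
#' @param n_cal calibration cohort size (default 200,000).
#' @param tol tolerance, in percentage points, on the achieved overall and
#'   both-missing percentages (default 0.25).
#' @param seed seed for the calibration cohort (default 760813).
#' @param use_cache reuse a previous calibration for identical parameters.
#' @return `mparams` with `nu0`, `tau0`, `tau4` filled in and an
#'   `achieved` attribute recording the expected pattern percentages.
#' @export
calibrate_intercepts <- function(dgp, spec, mparams, n_cal = 200000,
                                 tol = 0.25, seed = 760813,
                                 use_cache = TRUE) {
  stopifnot(mparams$mechanism %in% c("DMO", "DME"))
  key <- paste(c(flatten_params(dgp), spec$coef, spec$estimand,
                 mparams$p, mparams$nu[-1], mparams$tau[-1],
                 n_cal, seed), collapse = "|")
  if (use_cache && !is.null(.calibration_cache[[key]]))
    return(.calibration_cache[[key]])

  cohort <- generate_cohort(dgp, spec, n = n_cal, seed = seed)
  p <- mparams$p / 100
  t_marg <- 0.75 * p    # P(M_petown) = P(M_antevd)
  t_both <- 0.5 * p     # P(both missing)
  t_ant_only <- t_marg - t_both

  lp_nu <- miss_linpred(c(0, mparams$nu[-1]), cohort)
  nu0 <- stats::uniroot(function(a) mean(expit(a + lp_nu)) - t_marg,
                        c(-40, 40), tol = 1e-10)$root
  q_pet <- expit(nu0 + lp_nu)

  lp_tau <- miss_linpred(c(0, mparams$tau[-c(1, length(mparams$tau))]),
                         cohort)
  tau0 <- stats::uniroot(
    function(a) mean((1 - q_pet) * expit(a + lp_tau)) - t_ant_only,
    c(-40, 40), tol = 1e-10)$root
  tau4 <- stats::uniroot(
    function(a) mean(q_pet * expit(tau0 + a + lp_tau)) - t_both,
    c(-40, 40), tol = 1e-10)$root

  q_both <- q_pet * expit(tau0 + tau4 + lp_tau)
  q_ant <- (1 - q_pet) * expit(tau0 + lp_tau) + q_both
  achieved <- 100 * c(overall = mean(q_pet + q_ant - q_both),
                      both = mean(q_both), petown = mean(q_pet),
                      antevd = mean(q_ant))
  if (abs(achieved[["overall"]] - mparams$p) > tol ||
      abs(achieved[["both"]] - mparams$p / 2) > tol)
    stop("missingness calibration did not converge: achieved overall ",
         round(achieved[["overall"]], 3), "%, both ",
         round(achieved[["both"]], 3), "%")

  mparams$nu[["nu0"]] <- nu0
  mparams$tau[["tau0"]] <- tau0
  mparams$tau[["tau4"]] <- tau4
  attr(mparams, "achieved") <- achieved
  if (use_cache) .calibration_cache[[key]] <- mparams
  mparams
}

#' Tabulate missingness patterns
#'
#' @param cohort a cohort possibly containing `NA`s in `petown` / `antevd`.
#' @return a data frame with one row per pattern (`complete`,
#'   `petown_only`, `antevd_only`, `both`) and columns `n` and `percent`.
#' @export
missingness_summary <- function(cohort) {
  mp <- is.na(cohort$petown); ma <- is.na(cohort$antevd)
  n <- c(complete = sum(!mp & !ma), petown_only = sum(mp & !ma),
         antevd_only = sum(!mp & ma), both = sum(mp & ma))
  data.frame(pattern = names(n), n = as.integer(n),
             percent = 100 * as.integer(n) / nrow(cohort),
             row.names = NULL)
}
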