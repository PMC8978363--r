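# Scenario orchestration and simulation performance measures.
#
# A scenario fixes the DGP variant, exposure-outcome association,
# estimand, missingness mechanism, missingness proportion p and subcohort
# selection probability pi.  Each replicate generates a cohort, induces
# missingness, draws the case-cohort sample, and analyses it by the
# complete-data comparator, the complete-case analysis and the seven MI
# strategies.  A replicate counts as converged only when every method
# converges; a scenario retains the first `nsim` converged replicates out
# of a generation buffer.  Performance measures (relative bias, empirical
# and model-based SE, coverage) follow the standard simulation-study
# conventions, each with its Monte Carlo standard error.

#' Scenario configuration
#'
#' The full default grid reproduces the 78-scenario design: 2 DGP
#' variants' observed family (2 associations x 2 estimands x 3 mechanisms
#' x 2 missingness proportions x 3 subcohort probabilities = 72) plus 6
#' extreme-condition scenarios (extreme DGP, enhanced association, DME at
#' 30%, 2 estimands x 3 subcohort probabilities).
#'
#' @param variant,association,estimand see [make_scenario_params()].
#' @param mechanism,p see [missingness_params()].
#' @param pi subcohort selection probability (0.20, 0.30 or 0.40 in the
#'   default grid).
#' @param n cohort size (default 1000).
#' @param nsim replicates retained per scenario (default 2000).
#' @param buffer replicates generated to allow for non-convergence
#'   (default 2200).
#' @param m,fcs_cycles,mvni_burnin see [imputation_config()].
#' @param seed root seed; replicate k derives its stream by the
#'   documented seed-splitting rule.
#' @export
scenario_config <- function(variant = "observed", association = "observed",
                            estimand = "RR", mechanism = "independent",
                            p = 30, pi = 0.2, n = 1000, nsim = 2000,
                            buffer = ceiling(1.1 * nsim), m = 30,
                            fcs_cycles = 10, mvni_burnin = 200, seed = 1) {
  stopifnot(buffer >= nsim, pi > 0, pi <= 1, n >= 1)
  cfg <- list(variant = variant, association = association,
              estimand = estimand, mechanism = mechanism, p = p, pi = pi,
              n = n, nsim = nsim, buffer = buffer,
              impconfig = imputation_config(m, fcs_cycles, mvni_burnin),
              seed = seed)
  cfg$id <- paste(variant, association, estimand, mechanism, p,
                  format(pi, nsmall = 2), sep = "_")
  class(cfg) <- "ccmi_scenario"
  cfg
}

# Stable integer hash of the scenario id for seed derivation.
scenario_hash <- function(cfg) {
  derive_seed(1, utf8ToInt(cfg$id))
}

# complete-data comparator, complete-case analysis, then the 7 MI methods
.method_labels <- c("complete_data", "CCA", "FCS-WO", "FCS-WX", "FCS-SS",
                    "FCS-WM", "MVNI-WO", "MVNI-WX", "MVNI-SS")

#' Run one simulation replicate
#'
#' Generates a cohort, induces missingness, selects the case-cohort
#' sample (the same subcohort serves the missing-data and complete-data
#' analyses), and applies the complete-data comparator, CCA and all seven
#' MI strategies.
#'
#' @param config a [scenario_config()].
#' @param mparams calibrated missingness parameters for the scenario.
#' @param rep_seed integer seed for this replicate.
#' @return a data frame with one row per method: `method`, `estimate`,
#'   `se`, `lower`, `upper`, `converged`.
#' @export
run_replicate <- function(config, mparams, rep_seed) {
  pars <- make_scenario_params(config$variant, config$association,
                               config$estimand)
  fam <- config$estimand
  cohort <- generate_cohort(pars$dgp, pars$outcome, n = config$n,
                            seed = derive_seed(rep_seed, 11))
  miss <- induce_missingness(cohort, mparams,
                             seed = derive_seed(rep_seed, 12))

  blank <- data.frame(method = .method_labels, estimate = NA_real_,
                      se = NA_real_, lower = NA_real_, upper = NA_real_,
                      converged = FALSE)
  with_seed(derive_seed(rep_seed, 13), {
    in_sub <- stats::rbinom(config$n, 1, config$pi) == 1
  })
  sample_miss <- try(make_casecohort(miss, in_sub, config$pi),
                     silent = TRUE)
  if (inherits(sample_miss, "try-error")) return(blank)
  sample_full <- make_casecohort(cohort, in_sub, config$pi)

  rows <- list()
  rec <- fit_ipw_glm(sample_full, sample_full$weight, fam)
  rows[["complete_data"]] <- rec
  rec <- try(cca_estimate(sample_miss, fam), silent = TRUE)
  rows[["CCA"]] <- if (inherits(rec, "try-error"))
    list(estimate = NA_real_, se = NA_real_, lower = NA_real_,
         upper = NA_real_, converged = FALSE) else rec

  for (lab in .mi_labels) {
    strat <- imputation_strategy(lab)
    imp <- impute_sample(sample_miss, strat, config$impconfig,
                         seed = derive_seed(rep_seed, 14, match(lab, .mi_labels)))
    if (!imp$converged) {
      rows[[lab]] <- list(estimate = NA_real_, se = NA_real_,
                          lower = NA_real_, upper = NA_real_,
                          converged = FALSE)
      next
    }
    fits <- lapply(imp$datasets, function(d)
      fit_ipw_glm(d, d$weight, fam))
    okay <- vapply(fits, `[[`, TRUE, "converged")
    if (!all(okay)) {
      rows[[lab]] <- list(estimate = NA_real_, se = NA_real_,
                          lower = NA_real_, upper = NA_real_,
                          converged = FALSE)
      next
    }
    pool <- rubin_pool(vapply(fits, `[[`, 0, "estimate"),
                       vapply(fits, `[[`, 0, "se"))
    rows[[lab]] <- list(estimate = pool$estimate, se = pool$se,
                        lower = pool$lower, upper = pool$upper,
                        converged = TRUE)
  }
  data.frame(method = .method_labels,
             estimate = vapply(rows[.method_labels], `[[`, 0, "estimate"),
             se = vapply(rows[.method_labels], `[[`, 0, "se"),
             lower = vapply(rows[.method_labels], `[[`, 0, "lower"),
             upper = vapply(rows[.method_labels], `[[`, 0, "upper"),
             converged = vapply(rows[.method_labels], `[[`, TRUE,
                                "converged"),
             row.names = NULL)
}

#' Run a full scenario with the convergence-retention protocol
#'
#' Replicates are executed in fixed seed order until `nsim` replicates on
#' which every method converged have been retained, or the generation
#' buffer is exhausted.  All performance measures are computed on the
#' retained replicates; per-method convergence rates are computed over
#' every replicate executed.
#'
#' @param config a [scenario_config()].
#' @param mparams optional pre-calibrated missingness parameters; by
#'   default calibration is run (and cached) for dependent mechanisms.
#' @return a list with `summary` (one row per method of
#'   [performance_metrics()] output plus convergence rate), `replicates`
#'   (long data frame of every retained per-method result), `n_executed`,
#'   `n_retained`, and the config.
#' @export
run_scenario <- function(config, mparams = NULL) {
  pars <- make_scenario_params(config$variant, config$association,
                               config$estimand)
  if (is.null(mparams)) {
    mparams <- missingness_params(config$mechanism, config$p)
    if (config$mechanism != "independent")
      mparams <- calibrate_intercepts(pars$dgp, pars$outcome, mparams)
  }
  truth <- pars$outcome$coef[["vdi"]]
  sh <- scenario_hash(config)
  retained <- list()
  conv_counts <- stats::setNames(numeric(length(.method_labels)),
                                 .method_labels)
  executed <- 0
  for (k in seq_len(config$buffer)) {
    res <- run_replicate(config, mparams, derive_seed(config$seed, sh, k))
    executed <- executed + 1
    conv_counts <- conv_counts + res$converged
    if (all(res$converged)) {
      res$replicate <- k
      retained[[length(retained) + 1]] <- res
    }
    if (length(retained) >= config$nsim) break
  }
  n_ret <- length(retained)
  if (n_ret < config$nsim)
    warning("only ", n_ret, " of the requested ", config$nsim,
            " replicates converged within the buffer of ", config$buffer)
  reps <- do.call(rbind, retained)
  summ <- do.call(rbind, lapply(.method_labels, function(lab) {
    r <- reps[reps$method == lab, , drop = FALSE]
    pm <- performance_metrics(r$estimate, r$se, r$lower, r$upper, truth)
    cbind(method = lab, pm,
          convergence_rate = 100 * conv_counts[[lab]] / executed)
  }))
  rownames(summ) <- NULL
  list(summary = summ, replicates = reps, truth = truth,
       n_executed = executed, n_retained = n_ret, config = config)
}

#' Simulation performance measures with Monte Carlo standard errors
#'
#' Conventions: relative bias = 100 (mean(est) - truth)/truth; empirical
#' SE = SD of the estimates; model-based SE = sqrt(mean(se^2)); coverage
#' = percentage of CIs containing the truth.  MCSEs use the standard
#' formulas: bias MCSE = empSE/sqrt(nsim); empSE MCSE =
#' empSE/sqrt(2(nsim - 1)); model-SE MCSE =
#' sqrt(var(se^2)/(4 nsim modSE^2)); coverage MCSE from the binomial
#' variance.  When truth = 0, absolute bias is reported in place of
#' relative bias, with a warning.
#'
#' @param estimates,ses,lower,upper per-replicate point estimates,
#'   standard errors and CI bounds.
#' @param truth the generating value of the target coefficient.
#' @return a one-row data frame.
#' @export
performance_metrics <- function(estimates, ses, lower, upper, truth) {
  nsim <- length(estimates)
  stopifnot(nsim >= 2)
  emp_se <- stats::sd(estimates)
  bias <- mean(estimates) - truth
  if (truth != 0) {
    rel_bias <- 100 * bias / truth
    rel_bias_mcse <- 100 * emp_se / sqrt(nsim) / abs(truth)
  } else {
    warning("truth is 0; reporting absolute bias in place of relative bias")
    rel_bias <- bias
    rel_bias_mcse <- emp_se / sqrt(nsim)
  }
  mod_se <- sqrt(mean(ses^2))
  mod_se_mcse <- sqrt(stats::var(ses^2) / (4 * nsim * mod_se^2))
  cover <- mean(lower <= truth & truth <= upper)
  data.frame(
    nsim = nsim, mean_estimate = mean(estimates), bias = bias,
    relative_bias = rel_bias, relative_bias_mcse = rel_bias_mcse,
    empirical_se = emp_se,
    empirical_se_mcse = emp_se / sqrt(2 * (nsim - 1)),
    model_se = mod_se, model_se_mcse = mod_se_mcse,
    coverage = 100 * cover, coverage_mcse = coverage_mcse(cover, nsim))
}

#' Monte Carlo standard error of a coverage estimate
#'
#' @param coverage coverage as a proportion in \[0, 1\].
#' @param nsim number of simulation replicates.
#' @return the MCSE in percentage points:
#'   `100 * sqrt(coverage (1 - coverage) / nsim)`.
#' @export
coverage_mcse <- function(coverage, nsim) {
  stopifnot(coverage >= 0, coverage <= 1, nsim >= 1)
  100 * sqrt(coverage * (1 - coverage) / nsim)
}

#' The default 78-scenario grid
#'
#' @param nsim,m overrides propagated to every scenario (defaults are the
#'   full-size 2000 and 30).
#' @param seed root seed shared by all scenarios.
#' @return a list of [scenario_config()] objects.
#' @export
scenario_grid <- function(nsim = 2000, m = 30, seed = 1) {
  grid <- expand.grid(association = c("observed", "enhanced"),
                      estimand = c("RR", "OR"),
                      mechanism = c("independent", "DMO", "DME"),
                      p = c(15, 30), pi = c(0.2, 0.3, 0.4),
                      stringsAsFactors = FALSE)
  cfgs <- lapply(seq_len(nrow(grid)), function(i)
    scenario_config(variant = "observed",
                    association = grid$association[i],
                    estimand = grid$estimand[i],
                    mechanism = grid$mechanism[i], p = grid$p[i],
                    pi = grid$pi[i], nsim = nsim, m = m, seed = seed))
  extreme <- expand.grid(estimand = c("RR", "OR"), pi = c(0.2, 0.3, 0.4),
                         stringsAsFactors = FALSE)
  cfgs <- c(cfgs, lapply(seq_len(nrow(extreme)), function(i)
    scenario_config(variant = "extreme", association = "enhanced",
                    estimand = extreme$estimand[i], mechanism = "DME",
                    p = 30, pi = extreme$pi[i], nsim = nsim, m = m,
                    seed = seed)))
  names(cfgs) <- vapply(cfgs, `[[`, "", "id")
  cfgs
}
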