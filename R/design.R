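# Case-cohort subsampling and Borgan inverse-probability weights.
#
# The analysed sample comprises every case plus a random subcohort drawn
# from the full cohort (each record independently with probability pi).
# The exposure is treated as measured only within that sample -- it is
# missing by design for non-case non-subcohort members, who are excluded
# from analysis.  Unequal selection is handled by stratified-sampling
# weights with stratification on the outcome: w = 1 for cases and
# n0 / m0 for non-case subcohort members, where n0 counts non-cases in
# the full cohort and m0 non-cases in the subcohort.

#' Select a case-cohort sample
#'
#' @param cohort a full cohort with generated outcome (may already contain
#'   covariate missingness).
#' @param pi subcohort selection probability in (0, 1].
#' @param seed optional integer seed.
#' @return a data frame of class `ccmi_casecohort`: the analysed records
#'   (all cases plus the subcohort) with columns `in_subcohort` and
#'   `weight` appended, and attributes `pi`, `n`, `n0`, `m0`.
#' @export
select_subcohort <- function(cohort, pi, seed = NULL) {
  stopifnot(pi > 0, pi <= 1, "foodallergy" %in% names(cohort))
  with_seed(seed, {
    in_sub <- stats::rbinom(nrow(cohort), 1, pi) == 1
  })
  make_casecohort(cohort, in_sub, pi)
}

# Build the analysed sample from a realized subcohort indicator.  Shared
# by select_subcohort() and the per-replicate pipeline, which reuses one
# indicator for the missing-data and complete-data analyses.
make_casecohort <- function(cohort, in_sub, pi) {
  keep <- in_sub | cohort$foodallergy == 1
  sample <- cohort[keep, , drop = FALSE]
  sample$in_subcohort <- in_sub[keep]
  rownames(sample) <- NULL
  attr(sample, "pi") <- pi
  attr(sample, "n") <- nrow(cohort)
  attr(sample, "n0") <- sum(cohort$foodallergy == 0)
  attr(sample, "m0") <- sum(in_sub & cohort$foodallergy == 0)
  class(sample) <- c("ccmi_casecohort", "data.frame")
  compute_weights(sample)
}

#' Attach Borgan weights to a case-cohort sample
#'
#' Idempotent: weights are recomputed from the stored full-cohort and
#' subcohort non-case counts (`n0`, `m0`) on every call.
#'
#' @param sample a `ccmi_casecohort` from [select_subcohort()].
#' @return the sample with its `weight` column set.
#' @export
compute_weights <- function(sample) {
  n0 <- attr(sample, "n0"); m0 <- attr(sample, "m0")
  if (is.null(n0) || is.null(m0)) stop("sample lacks n0/m0 attributes")
  if (m0 == 0 && n0 > 0)
    stop("degenerate case-cohort sample: no non-case subcohort members")
  sample$weight <- ifelse(sample$foodallergy == 1, 1, n0 / m0)
  sample
}
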