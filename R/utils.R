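# Small numeric helpers shared across modules.

#' Inverse logit
#'
#' @param x numeric vector on the log-odds scale.
#' @return probabilities in (0, 1).
#' @export
expit <- function(x) 1 / (1 + exp(-x))

#' Logit
#'
#' @param p probabilities strictly in (0, 1).
#' @return log-odds.
#' @export
logit <- function(p) log(p / (1 - p))

#' Derive a child seed from a root seed and integer keys
#'
#' Deterministic seed-splitting rule used throughout the package so that
#' every replicate, calibration run and imputation chain is independently
#' reproducible from a single root seed.  The rule is a fixed-point
#' multiplicative mix (a splitmix-style fold) over the root seed and any
#' number of integer keys, reduced modulo 2^31 - 1 so the result is always
#' a valid R integer seed.
#'
#' @param root integer root seed.
#' @param ... integer keys (e.g. scenario index, replicate index).
#' @return a single integer in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(root, ...) {
  keys <- c(root, ...)
  stopifnot(length(keys) >= 1, all(is.finite(keys)))
  m <- 2147483647  # 2^31 - 1, prime
  h <- 0
  for (k in as.numeric(keys)) {
    # 48271 is the MINSTD multiplier; the fold keeps everything < 2^53
    h <- (h * 48271 + (k %% m) + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Draw from a baseline-category (multinomial) logit with category 0 as the
# reference.  `lp` is a matrix with one column per non-reference category of
# linear predictors log{P(k)/P(0)}.  Returns integer categories 0..K.
rcat_logit <- function(lp) {
  stopifnot(is.matrix(lp))
  e <- cbind(1, exp(lp))
  p <- e / rowSums(e)
  u <- stats::runif(nrow(p))
  cum <- t(apply(p, 1L, cumsum))
  as.integer(rowSums(u > cum[, -ncol(cum), drop = FALSE]))
}

# Locally set the RNG seed when one is supplied; otherwise use the caller's
# RNG stream untouched.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}

#' Write a simulated cohort to CSV
#'
#' Missing values are written as empty fields so the file round-trips
#' through [read_cohort_csv()].
#'
#' @param cohort a cohort or case-cohort sample data frame.
#' @param path output file path.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort written by [write_cohort_csv()]
#'
#' @param path CSV file path.
#' @return a data frame with empty fields restored as `NA`.
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, na.strings = "")
}
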