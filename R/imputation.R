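# Multiple-imputation engines for the two incomplete covariates (petown,
# antevd) in a case-cohort sample.
#
# Two frameworks:
#   FCS  - fully conditional specification: univariate logistic imputation
#     models, cycled in fixed order petown -> antevd.  Each cycle refits
#     the model on records with the target observed, draws coefficients
#     from the approximate normal posterior, and redraws the missing
#     values Bernoulli(expit(X beta*)).
#   MVNI - joint multivariate-normal imputation by a data-augmentation
#     sampler: all analysis variables (binary as 0/1, categorical as
#     indicator columns) are modelled jointly normal; each imputation runs
#     an independent chain alternating a (mean, covariance) posterior draw
#     under the Jeffreys prior with a conditional-normal draw of the
#     missing entries, and the post-burn-in state is retained.  Imputed
#     values are used as is, without rounding.
#
# Four accommodations of the case-cohort weights (the design has only two
# weight classes, collinear with the outcome, so the outcome acts as a
# weight proxy):
#   weight_only (WO)         - outcome included as a predictor.
#   weight_interactions (WX) - adds outcome x variable interactions;
#     passively recomputed each cycle under FCS, "just another variable"
#     columns under MVNI.
#   stratum_specific (SS)    - impute cases and non-cases separately, no
#     outcome term.
#   weighted_model (WM)      - FCS only: conditional logistic fits
#     maximize the weight-multiplied log-likelihood and the posterior
#     draw uses that fit's model-based covariance.
#
# Both engines work on a numeric matrix whose columns are the analysis
# variables with nsib/seifa expanded to indicators; interaction columns
# are appended under WX and the ones involving an incomplete covariate
# are kept in sync with it.

.mi_labels <- c("FCS-WO", "FCS-WX", "FCS-SS", "FCS-WM",
                "MVNI-WO", "MVNI-WX", "MVNI-SS")

.accommodations <- c(WO = "weight_only", WX = "weight_interactions",
                     SS = "stratum_specific", WM = "weighted_model")

#' Declare a multiple-imputation strategy
#'
#' @param label one of `"FCS-WO"`, `"FCS-WX"`, `"FCS-SS"`, `"FCS-WM"`,
#'   `"MVNI-WO"`, `"MVNI-WX"`, `"MVNI-SS"`; alternatively supply
#'   `framework` and `accommodation`.
#' @param framework `"FCS"` or `"MVNI"`.
#' @param accommodation one of `"weight_only"`, `"weight_interactions"`,
#'   `"stratum_specific"`, `"weighted_model"`.
#' @return an object of class `ccmi_strategy`.  A weighted imputation
#'   model is only available under FCS.
#' @export
imputation_strategy <- function(label = NULL, framework = NULL,
                                accommodation = NULL) {
  if (!is.null(label)) {
    label <- match.arg(label, .mi_labels)
    parts <- strsplit(label, "-", fixed = TRUE)[[1]]
    framework <- parts[1]
    accommodation <- unname(.accommodations[parts[2]])
  } else {
    framework <- match.arg(framework, c("FCS", "MVNI"))
    accommodation <- match.arg(accommodation, unname(.accommodations))
    label <- paste0(framework, "-",
                    names(.accommodations)[.accommodations == accommodation])
  }
  if (framework == "MVNI" && accommodation == "weighted_model")
    stop("a weighted imputation model is only available under FCS")
  out <- list(framework = framework, accommodation = accommodation,
              label = label)
  class(out) <- "ccmi_strategy"
  out
}

#' The seven MI strategies under comparison
#'
#' @return a named list of `ccmi_strategy` objects.
#' @export
mi_strategies <- function() {
  out <- lapply(.mi_labels, imputation_strategy)
  names(out) <- .mi_labels
  out
}

#' Imputation engine configuration
#'
#' @param m number of imputations (default 30, matching the largest
#'   missingness proportion considered).
#' @param fcs_cycles chained-equation cycles per imputation (default 10).
#' @param mvni_burnin data-augmentation iterations before each retained
#'   draw (default 200); chains are independent across imputations.
#' @export
imputation_config <- function(m = 30, fcs_cycles = 10, mvni_burnin = 200) {
  stopifnot(m >= 2, fcs_cycles >= 1, mvni_burnin >= 1)
  structure(list(m = m, fcs_cycles = fcs_cycles,
                 mvni_burnin = mvni_burnin),
            class = "ccmi_impconfig")
}

.incomplete_vars <- c("petown", "antevd")
# variables interacted with the outcome under WX ("all other analysis
# variables"; auxiliaries are not interacted)
.wx_partners <- c("vdi", "cauc", "hxfamall", "nsib1", "nsib2", "petown",
                  "antevd")

#' Describe the imputation design implied by a strategy
#'
#' Returns, for each incomplete variable, its predictor set, and flags for
#' outcome-stratified and weighted fitting.  This is the declarative
#' contract that both engines follow.
#'
#' @param sample the case-cohort sample (used only to identify incomplete
#'   variables).
#' @param strategy a `ccmi_strategy`.
#' @export
build_imputation_design <- function(sample, strategy) {
  stopifnot(inherits(strategy, "ccmi_strategy"))
  targets <- .incomplete_vars[vapply(.incomplete_vars,
                                     function(v) anyNA(sample[[v]]), TRUE)]
  if (length(targets) == 0) targets <- .incomplete_vars
  des <- lapply(targets, function(v) {
    other <- setdiff(.incomplete_vars, v)
    base <- c("foodallergy", "vdi", "cauc", "hxfamall", "nsib1", "nsib2",
              other, "mage", "seifa1", "seifa2")
    preds <- switch(strategy$accommodation,
      weight_only = base,
      weighted_model = base,
      weight_interactions = c(base,
        paste0("foodallergy:", setdiff(.wx_partners, v))),
      stratum_specific = setdiff(base, "foodallergy"))
    list(target = v, predictors = preds,
         stratify_by_outcome = strategy$accommodation == "stratum_specific",
         weighted = strategy$accommodation == "weighted_model")
  })
  names(des) <- targets
  des
}

#' Draw imputation-model coefficients from their approximate posterior
#'
#' Proper-imputation step: returns `beta* ~ N(beta_hat, V_hat)`.  The
#' covariance factor uses Cholesky with an eigendecomposition fallback
#' for semi-definite matrices; negative eigenvalues beyond numerical
#' noise flag the draw as failed, and the zero-covariance limit returns
#' `beta_hat` itself.
#'
#' @param coef estimated coefficient vector.
#' @param vcov its covariance matrix.
#' @param seed optional integer seed.
#' @return the drawn coefficient vector, or `NULL` if `vcov` is not
#'   positive semi-definite.
#' @export
posterior_draw_glm <- function(coef, vcov, seed = NULL) {
  if (!all(is.finite(vcov)) || !all(is.finite(coef))) return(NULL)
  ch <- tryCatch(chol(vcov), error = function(e) NULL)
  if (is.null(ch)) {
    eg <- eigen((vcov + t(vcov)) / 2, symmetric = TRUE)
    tol <- 1e-8 * max(1, abs(eg$values[1]))
    if (any(eg$values < -tol)) return(NULL)
    ch <- sqrt(pmax(eg$values, 0)) * t(eg$vectors)
  }
  with_seed(seed, {
    drop(coef + stats::rnorm(length(coef)) %*% ch)
  })
}

# ---- shared data matrix ----------------------------------------------------

# Numeric matrix of analysis variables with indicator-expanded
# categoricals; WX appends outcome-by-variable product columns named
# "fa.<var>".
mi_matrix <- function(data, wx = FALSE) {
  M <- cbind(`(Intercept)` = 1,
             foodallergy = data$foodallergy, vdi = data$vdi,
             cauc = data$cauc, hxfamall = data$hxfamall,
             nsib1 = as.integer(data$nsib == 1),
             nsib2 = as.integer(data$nsib == 2),
             petown = data$petown, antevd = data$antevd,
             mage = data$mage,
             seifa1 = as.integer(data$seifa == 1),
             seifa2 = as.integer(data$seifa == 2))
  if (wx) {
    XI <- M[, "foodallergy"] * M[, .wx_partners]
    colnames(XI) <- paste0("fa.", .wx_partners)
    M <- cbind(M, XI)
  }
  M
}

# ---- FCS engine ------------------------------------------------------------

# Column names of the imputation design for `target` within the shared
# matrix (intercept first).
fcs_cols <- function(target, strategy) {
  other <- setdiff(.incomplete_vars, target)
  cols <- c("(Intercept)", "foodallergy", "vdi", "cauc", "hxfamall",
            "nsib1", "nsib2", other, "mage", "seifa1", "seifa2")
  if (strategy$accommodation == "stratum_specific")
    cols <- setdiff(cols, "foodallergy")
  if (strategy$accommodation == "weight_interactions")
    cols <- c(cols, paste0("fa.", setdiff(.wx_partners, target)))
  cols
}

# Weighted logistic fit; returns coef and model-based covariance, or NULL
# on failure (non-convergence, rank deficiency, or non-finite curvature --
# the engine's separation guard).
fcs_fit <- function(X, y, w) {
  fit <- tryCatch(suppressWarnings(
    stats::glm.fit(X, y, weights = w, family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged || fit$rank < ncol(X) ||
      !all(is.finite(fit$coefficients)))
    return(NULL)
  XW <- X * sqrt(fit$weights)
  V <- tryCatch(chol2inv(chol(crossprod(XW))), error = function(e) NULL)
  if (is.null(V) || !all(is.finite(V))) return(NULL)
  list(coef = fit$coefficients, vcov = V)
}

# One imputation: initialize missing entries by resampling observed
# values, run the chained cycles, return the completed matrix (or NULL on
# any fit failure).
fcs_one_imputation <- function(M, na_mask, strategy, cycles, w) {
  wx <- strategy$accommodation == "weight_interactions"
  for (v in .incomplete_vars) {
    na_v <- na_mask[[v]]
    if (!any(na_v)) next
    M[na_v, v] <- sample(M[!na_v, v], sum(na_v), replace = TRUE)
    if (wx) M[na_v, paste0("fa.", v)] <-
        M[na_v, "foodallergy"] * M[na_v, v]
  }
  strata <- if (strategy$accommodation == "stratum_specific")
    list(which(M[, "foodallergy"] == 0), which(M[, "foodallergy"] == 1))
  else list(seq_len(nrow(M)))
  wfit <- if (strategy$accommodation == "weighted_model") w
          else rep(1, nrow(M))
  colsets <- lapply(.incomplete_vars, fcs_cols, strategy = strategy)
  names(colsets) <- .incomplete_vars
  for (cyc in seq_len(cycles)) {
    for (v in .incomplete_vars) {
      na_v <- na_mask[[v]]
      if (!any(na_v)) next
      for (rows in strata) {
        mis <- rows[na_v[rows]]
        if (length(mis) == 0) next
        obs <- rows[!na_v[rows]]
        Xo <- M[obs, colsets[[v]], drop = FALSE]
        fit <- fcs_fit(Xo, M[obs, v], wfit[obs])
        if (is.null(fit)) return(NULL)
        bstar <- posterior_draw_glm(fit$coef, fit$vcov)
        if (is.null(bstar)) return(NULL)
        pr <- expit(drop(M[mis, colsets[[v]], drop = FALSE] %*% bstar))
        M[mis, v] <- stats::rbinom(length(mis), 1, pr)
        if (wx) M[mis, paste0("fa.", v)] <-
            M[mis, "foodallergy"] * M[mis, v]
      }
    }
  }
  M
}

#' Impute by fully conditional specification
#'
#' @param data a case-cohort sample (or any data frame with the analysis
#'   columns plus `weight`) with missing values confined to `petown` and
#'   `antevd`.
#' @param strategy a `ccmi_strategy` with framework `"FCS"`.
#' @param config an [imputation_config()].
#' @param seed optional integer seed.
#' @return list with `datasets` (m completed copies of `data`),
#'   `converged` (`FALSE` if any conditional fit failed, in which case
#'   `datasets` is `NULL`), and `strategy`.
#' @export
fcs_impute <- function(data, strategy, config = imputation_config(),
                       seed = NULL) {
  stopifnot(strategy$framework == "FCS")
  na_mask <- lapply(data[.incomplete_vars], is.na)
  w <- if (is.null(data$weight)) rep(1, nrow(data)) else data$weight
  M0 <- mi_matrix(data, wx = strategy$accommodation == "weight_interactions")
  out <- vector("list", config$m)
  with_seed(seed, {
    for (i in seq_len(config$m)) {
      M <- fcs_one_imputation(M0, na_mask, strategy, config$fcs_cycles, w)
      if (is.null(M))
        return(list(datasets = NULL, converged = FALSE,
                    strategy = strategy))
      completed <- data
      for (v in .incomplete_vars)
        completed[[v]][na_mask[[v]]] <- M[na_mask[[v]], v]
      out[[i]] <- completed
    }
    list(datasets = out, converged = TRUE, strategy = strategy)
  })
}

# ---- MVNI engine -----------------------------------------------------------

# One data-augmentation iteration body; errors (singular factorizations)
# propagate to the chain wrapper.  Y excludes the intercept column.
mvni_iterate <- function(Y, pats, ridge) {
  n <- nrow(Y); p <- ncol(Y)
  ybar <- colMeans(Y)
  S <- crossprod(Y) - n * tcrossprod(ybar)
  if (ridge > 0) S <- S + ridge * mean(diag(S)) * diag(p)
  Sinv <- chol2inv(chol(S))
  W <- stats::rWishart(1, n - 1, Sinv)[, , 1]
  Rw <- chol(W)
  Sigma <- chol2inv(Rw)
  mu <- ybar + backsolve(Rw, stats::rnorm(p)) / sqrt(n)
  for (pat in pats) {
    M <- pat$M; O <- pat$O; rows <- pat$rows
    B <- Sigma[M, O, drop = FALSE] %*%
      chol2inv(chol(Sigma[O, O, drop = FALSE]))
    condvar <- Sigma[M, M, drop = FALSE] - B %*% Sigma[O, M, drop = FALSE]
    condvar <- (condvar + t(condvar)) / 2 +
      1e-10 * mean(diag(Sigma)) * diag(length(M))
    ch <- chol(condvar)
    resid <- Y[rows, O, drop = FALSE] -
      matrix(mu[O], length(rows), length(O), byrow = TRUE)
    condmean <- resid %*% t(B) +
      matrix(mu[M], length(rows), length(M), byrow = TRUE)
    z <- matrix(stats::rnorm(length(rows) * length(M)), length(rows))
    Y[rows, M] <- condmean + z %*% ch
  }
  Y
}

# One chain: initialize missing entries by resampling observed column
# values, run `burnin` iterations, return the final state.  Singular
# covariance draws trigger a ridge-stabilized retry of the whole chain;
# persistent failure returns NULL.
mvni_chain <- function(Y, miss, burnin) {
  p <- ncol(Y)
  for (j in seq_len(p)) {
    mj <- miss[, j]
    if (any(mj)) Y[mj, j] <- sample(Y[!mj, j], sum(mj), replace = TRUE)
  }
  pat_key <- apply(miss, 1, function(r) paste(which(r), collapse = ","))
  inc_rows <- which(pat_key != "")
  pats <- lapply(split(inc_rows, pat_key[inc_rows]), function(rows) {
    M <- as.integer(strsplit(pat_key[rows[1]], ",", fixed = TRUE)[[1]])
    list(M = M, O = setdiff(seq_len(p), M), rows = rows)
  })
  for (ridge in c(0, 1e-6, 1e-3)) {
    res <- tryCatch({
      Yc <- Y
      for (it in seq_len(burnin)) Yc <- mvni_iterate(Yc, pats, ridge)
      Yc
    }, error = function(e) NULL)
    if (!is.null(res)) return(res)
  }
  NULL
}

#' Impute under the joint multivariate-normal model
#'
#' All analysis variables (binary coded 0/1, categorical as indicator
#' columns, and under weight-interactions the outcome-by-variable products
#' as their own "just another variable" columns) are modelled jointly
#' normal.  Each of the m imputations is the state of an independent
#' data-augmentation chain after `mvni_burnin` iterations.  Imputed values
#' are continuous and are carried into the analysis without rounding.
#' Stratum-specific imputation runs a separate sampler per outcome
#' stratum.
#'
#' @inheritParams fcs_impute
#' @param strategy a `ccmi_strategy` with framework `"MVNI"`.
#' @export
mvni_impute <- function(data, strategy, config = imputation_config(),
                        seed = NULL) {
  stopifnot(strategy$framework == "MVNI")
  na_mask <- lapply(data[.incomplete_vars], is.na)
  wx <- strategy$accommodation == "weight_interactions"
  Y0 <- mi_matrix(data, wx = wx)
  Y0 <- Y0[, setdiff(colnames(Y0), "(Intercept)"), drop = FALSE]
  if (strategy$accommodation == "stratum_specific")
    Y0 <- Y0[, setdiff(colnames(Y0), "foodallergy"), drop = FALSE]
  miss <- matrix(FALSE, nrow(Y0), ncol(Y0),
                 dimnames = list(NULL, colnames(Y0)))
  miss[, "petown"] <- na_mask$petown
  miss[, "antevd"] <- na_mask$antevd
  if (wx) {
    miss[, "fa.petown"] <- na_mask$petown
    miss[, "fa.antevd"] <- na_mask$antevd
  }
  strata <- if (strategy$accommodation == "stratum_specific")
    split(seq_len(nrow(data)), data$foodallergy)
  else list(seq_len(nrow(data)))
  out <- vector("list", config$m)
  with_seed(seed, {
    for (i in seq_len(config$m)) {
      Y <- Y0
      for (rows in strata) {
        if (!any(miss[rows, ])) next
        Ys <- mvni_chain(Y0[rows, , drop = FALSE],
                         miss[rows, , drop = FALSE], config$mvni_burnin)
        if (is.null(Ys))
          return(list(datasets = NULL, converged = FALSE,
                      strategy = strategy))
        Y[rows, ] <- Ys
      }
      completed <- data
      for (v in .incomplete_vars)
        completed[[v]][na_mask[[v]]] <- Y[na_mask[[v]], v]
      out[[i]] <- completed
    }
    list(datasets = out, converged = TRUE, strategy = strategy)
  })
}

#' Impute a sample under any strategy
#'
#' Dispatches to [fcs_impute()] or [mvni_impute()]; with no missing values
#' the input is returned unchanged m times.
#'
#' @inheritParams fcs_impute
#' @param strategy a `ccmi_strategy`.
#' @export
impute_sample <- function(data, strategy, config = imputation_config(),
                          seed = NULL) {
  if (!anyNA(data[.incomplete_vars]))
    return(list(datasets = rep(list(data), config$m), converged = TRUE,
                strategy = strategy))
  if (strategy$framework == "FCS") fcs_impute(data, strategy, config, seed)
  else mvni_impute(data, strategy, config, seed)
}
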