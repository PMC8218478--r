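#' Free-parameter count of the latent class regression model
#'
#' `Npar = K (C-1) (1 + P) + (K-1) (1 + Q)` where `C` is the number of
#' outcome categories, `P` the predictor columns and `Q` the covariate
#' columns: each class carries `C-1` outcome regressions with intercepts,
#' and the membership logit carries `K-1` contrasts with intercepts.
#' For the default design (C = 3, P = 8, Q = 17) this gives 18, 54, 90
#' for K = 1, 2, 3.
#'
#' @param K Number of classes (>= 1).
#' @param n_outcome_categories,n_predictor_columns,n_covariate_columns
#'   Model dimensions.
#' @return Integer parameter count.
#' @export
count_parameters <- function(K, n_outcome_categories = 3,
                             n_predictor_columns = 8,
                             n_covariate_columns = 17) {
  if (K < 1) stop("K must be >= 1")
  as.integer(K * (n_outcome_categories - 1) * (1 + n_predictor_columns) +
               (K - 1) * (1 + n_covariate_columns))
}

#' Residual degrees of freedom
#' @param N Sample size.
#' @param Npar Free-parameter count.
#' @return `N - Npar`.
#' @export
degrees_of_freedom <- function(N, Npar) as.integer(N - Npar)

#' Penalized fit indices on the L2 scale
#'
#' Information criteria penalised on the likelihood-ratio (L2) scale, the
#' convention in which each index subtracts its penalty times the residual
#' degrees of freedom from the goodness-of-fit statistic:
#' `BIC(L2) = L2 - ln(N) df`, `AIC(L2) = L2 - 2 df`,
#' `AIC3(L2) = L2 - 3 df`, `CAIC(L2) = L2 - (ln(N)+1) df`,
#' `SABIC(L2) = L2 - ln((N+2)/24) df`.  Lower is better.  Because
#' `L2 = -2 logLik + const` and `df = N - Npar`, these differ from the
#' conventional log-likelihood-scale indices only by a constant in N, so
#' the two scales always rank a set of models identically.
#'
#' @param L2 Goodness-of-fit statistic.
#' @param df Residual degrees of freedom.
#' @param N Sample size.
#' @return Named list with the five indices.
#' @export
information_criteria <- function(L2, df, N) {
  list(BIC_L2   = L2 - log(N) * df,
       AIC_L2   = L2 - 2 * df,
       AIC3_L2  = L2 - 3 * df,
       CAIC_L2  = L2 - (log(N) + 1) * df,
       SABIC_L2 = L2 - log((N + 2) / 24) * df)
}

# Conventional log-likelihood-scale criteria, emitted alongside for
# cross-package comparability.
ll_information_criteria <- function(loglik, Npar, N) {
  m2ll <- -2 * loglik
  list(BIC_LL   = m2ll + log(N) * Npar,
       AIC_LL   = m2ll + 2 * Npar,
       AIC3_LL  = m2ll + 3 * Npar,
       CAIC_LL  = m2ll + (log(N) + 1) * Npar,
       SABIC_LL = m2ll + log((N + 2) / 24) * Npar)
}

#' L2 goodness-of-fit statistic
#'
#' With continuous covariates every case is its own covariate pattern, so
#' the saturated reference is taken as perfect per-case prediction
#' (saturated log-likelihood 0), giving `L2 = -2 logLik`.  This
#' convention reproduces the `df = N - Npar` bookkeeping exactly and
#' leaves all model differences (`-2LLDiff`) unchanged whatever the
#' convention; it is recorded in the result.  The p-value is the
#' upper-tail chi-square probability of L2 at df (undefined and flagged
#' when df <= 0).
#'
#' @param fitted An `lcra_fit`.
#' @param design Optional `lcra_design`; defaults to the fit's own.
#' @return List with `L2`, `df`, `p_value`, `saturation`.
#' @export
l2_statistic <- function(fitted, design = fitted$design) {
  ll <- if (inherits(fitted, "lcra_fit")) fitted$log_likelihood else
    lcra_loglik(design, fitted)
  npar <- if (inherits(fitted, "lcra_fit")) fitted$n_par else
    count_parameters(fitted$K, 3, fitted$n_predictor_cols,
                     fitted$n_covariate_cols)
  N <- nrow(design$covariates)
  L2 <- -2 * ll
  df <- degrees_of_freedom(N, npar)
  p <- if (df > 0) stats::pchisq(L2, df, lower.tail = FALSE) else NA_real_
  list(L2 = L2, df = df, p_value = p,
       p_defined = df > 0,
       saturation = "perfect per-case prediction (saturated logLik = 0)")
}

#' Likelihood-ratio statistic between nested class solutions
#'
#' `-2LLDiff = 2 (logLik_big - logLik_small)`, equivalently
#' `L2_small - L2_big`; non-negative for properly nested converged fits.
#' Accepts two `lcra_fit` objects, or two numeric L2 values (small-model
#' first).
#'
#' @param fit_small,fit_big Fits (or L2 scalars) for the smaller and
#'   larger model.
#' @return The statistic.
#' @export
neg2_ll_diff <- function(fit_small, fit_big) {
  if (is.numeric(fit_small) && is.numeric(fit_big)) {
    return(fit_small - fit_big)
  }
  stopifnot(inherits(fit_small, "lcra_fit"), inherits(fit_big, "lcra_fit"))
  2 * (fit_big$log_likelihood - fit_small$log_likelihood)
}

#' Classification error
#'
#' Mean posterior probability mass off the modal class:
#' `CE = mean_i (1 - max_k posterior_ik)`; 0 for perfectly separated
#' classes, at most `1 - 1/K`.
#'
#' @param posteriors N x K posterior matrix.
#' @return Scalar in `[0, 1 - 1/K]`.
#' @export
classification_error <- function(posteriors) {
  m <- as.matrix(posteriors)
  mean(1 - apply(m, 1, max))
}

#' Entropy-based outcome-prediction pseudo-R2
#'
#' `1 - sum_i(-log f(y_i | z_i)) / sum_i(-log f0(y_i))` where `f` is the
#' model's mixture outcome density and the null `f0` is the
#' outcome-marginal (intercept-only, class-free) model.  Equals 0 when
#' the model matches the null and 1 under perfect prediction.
#'
#' @param fitted An `lcra_fit`.
#' @param design Optional design; defaults to the fit's own.
#' @return Scalar, bounded above by 1.
#' @export
outcome_r2 <- function(fitted, design = fitted$design) {
  y <- design$outcome
  stopifnot(!anyNA(y))
  pm <- mixture_outcome_probs(fitted$params, design$covariates,
                              design$predictors)
  pm <- matrix(pm, ncol = 3)
  h_model <- -log(pm[cbind(seq_along(y), y + 1L)])
  marg <- tabulate(y + 1L, nbins = 3) / length(y)
  h_null <- -log(marg[y + 1L])
  1 - sum(h_model) / sum(h_null)
}

#' Class-enumeration table
#'
#' Fits the model for `K = 1 .. K_max` and reports, per K: the parameter
#' count, log-likelihood, L2, the five L2-scale information criteria, the
#' residual df and chi-square p, the classification error, the
#' entropy-based pseudo-R2, and the `-2LLDiff` against the previous K.
#' Conventional log-likelihood-scale criteria are included as extra
#' columns; because the two scales differ by a constant per N their
#' rankings always agree (recorded in the `ranking_agreement` attribute).
#'
#' @param design An `lcra_design` with outcomes.
#' @param K_max Largest number of classes to fit.
#' @param config An `lcra_fit_config` (its `K` is overridden per row).
#' @return Data frame of class `lcra_selection`, one row per K, with the
#'   fitted models in the `fits` attribute and the saturation convention
#'   in the `saturation` attribute.
#' @export
selection_table <- function(design, K_max, config = fit_config()) {
  stopifnot(K_max >= 1)
  N <- nrow(design$covariates)
  fits <- vector("list", K_max)
  rows <- vector("list", K_max)
  for (K in seq_len(K_max)) {
    cfg <- config
    cfg$K <- as.integer(K)
    fit <- fit_em(design, cfg, align = TRUE, se = FALSE)
    fits[[K]] <- fit
    gl <- l2_statistic(fit, design)
    ic <- information_criteria(gl$L2, gl$df, N)
    icll <- ll_information_criteria(fit$log_likelihood, fit$n_par, N)
    rows[[K]] <- data.frame(
      K = K, Npar = fit$n_par, logLik = fit$log_likelihood,
      L2 = gl$L2,
      BIC_L2 = ic$BIC_L2, AIC_L2 = ic$AIC_L2, AIC3_L2 = ic$AIC3_L2,
      CAIC_L2 = ic$CAIC_L2, SABIC_L2 = ic$SABIC_L2,
      df = gl$df, p = gl$p_value,
      CE = classification_error(fit$posteriors),
      R2 = outcome_r2(fit, design),
      neg2LLdiff = if (K == 1L) NA_real_ else
        neg2_ll_diff(fits[[K - 1L]], fit),
      BIC_LL = icll$BIC_LL, AIC_LL = icll$AIC_LL, AIC3_LL = icll$AIC3_LL,
      CAIC_LL = icll$CAIC_LL, SABIC_LL = icll$SABIC_LL,
      converged = fit$converged)
  }
  tab <- do.call(rbind, rows)
  agree <- all(vapply(c("BIC", "AIC", "AIC3", "CAIC", "SABIC"),
                      function(nm) {
                        identical(order(tab[[paste0(nm, "_L2")]]),
                                  order(tab[[paste0(nm, "_LL")]]))
                      }, logical(1)))
  structure(tab, class = c("lcra_selection", "data.frame"),
            fits = fits,
            saturation = "perfect per-case prediction (saturated logLik = 0)",
            ranking_agreement = agree)
}

#' Parametric bootstrap likelihood-ratio test for the number of classes
#'
#' Tests a `K_small`-class against a `K_big`-class solution.  `B`
#' datasets are simulated from the fitted small model (covariates and
#' predictors kept fixed, outcomes regenerated from the fitted mixture);
#' both models are refitted on each replicate and the `-2LLDiff`
#' statistics collected.  The Monte-Carlo p-value is
#' `(1 + #\{replicate >= observed\}) / (B_used + 1)`.  Replicates on which
#' either refit fails to converge are dropped and counted; if more than
#' 20\% drop, the result is flagged unreliable.
#'
#' @param design An `lcra_design` with outcomes.
#' @param K_small,K_big Nested class counts, `K_big > K_small`.
#' The observed statistic and every replicate statistic are computed by
#' the identical refitting procedure (same random-start count, iteration
#' budget and tolerances), which keeps observed and replicate statistics
#' exchangeable under the null — the Monte-Carlo test stays calibrated
#' even under a deliberately limited refit budget.
#'
#' @param B Number of bootstrap replicates (>= 1).
#' @param config An `lcra_fit_config`; `boot_restarts` controls the
#'   random starts used inside replicates, `seed` drives all randomness.
#' @param refit_max_iter,refit_tol,refit_mstep_iter EM budget used for the
#'   observed and replicate refits.
#' @return Object of class `lcra_boot_lrt`.
#' @export
bootstrap_lrt <- function(design, K_small, K_big, B = 500,
                          config = fit_config(),
                          refit_max_iter = 100, refit_tol = 1e-7,
                          refit_mstep_iter = 1) {
  if (B < 1) stop("B must be >= 1")
  if (K_big <= K_small) stop("K_big must exceed K_small")
  if (anyNA(design$outcome)) stop("bootstrap LRT requires observed outcomes")
  # the null model whose fitted mixture generates the replicate outcomes:
  # fitted with the full configuration
  cfg_s <- config; cfg_s$K <- as.integer(K_small)
  fit_s <- suppressWarnings(fit_em(design, cfg_s, align = FALSE, se = FALSE))
  Pmix <- mixture_outcome_probs(fit_s$params, design$covariates,
                                design$predictors)
  Pmix <- matrix(Pmix, ncol = 3)
  cum <- row_cumsum(Pmix)
  # observed statistic and all replicate statistics come from the identical
  # refitting procedure (same restarts / iteration budget / tolerances), so
  # the statistics are exchangeable under the null whatever the budget
  set.seed(config$seed)
  res <- boot_lrt_cpp(cbind(1, design$covariates), cbind(1, design$predictors),
                      design$outcome, cum, as.integer(B),
                      as.integer(K_small), as.integer(K_big),
                      as.integer(config$boot_restarts),
                      as.integer(refit_max_iter), refit_tol, config$ridge,
                      as.integer(refit_mstep_iter), 1e-10)
  d2 <- pmax(0, 2 * (res$ll_big - res$ll_small))
  stat <- d2[1]
  # a replicate is a failure only when a refit produced a non-finite
  # log-likelihood; exhausting the shared iteration budget is part of the
  # procedure, not a failure (see the exchangeability note above)
  keep <- is.finite(res$ll_big[-1]) & is.finite(res$ll_small[-1])
  kept <- d2[-1][keep]
  dropped <- sum(!keep)
  p <- (1 + sum(kept >= stat - 1e-8)) / (length(kept) + 1)
  structure(list(statistic = stat, B_requested = B, B_used = length(kept),
                 replicates = kept, n_dropped = dropped,
                 unreliable = dropped > 0.2 * B,
                 p_value = p, seed = config$seed,
                 K_small = K_small, K_big = K_big,
                 fit_small = fit_s),
            class = "lcra_boot_lrt")
}

#' @export
print.lcra_boot_lrt <- function(x, ...) {
  cat(sprintf("bootstrap LRT %d vs %d classes: -2LLDiff = %.2f, p = %.4f (B = %d used / %d requested%s)\n",
              x$K_small, x$K_big, x$statistic, x$p_value, x$B_used,
              x$B_requested,
              if (x$unreliable) "; UNRELIABLE: >20% replicates dropped" else ""))
  invisible(x)
}
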