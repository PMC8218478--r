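#' Estimation configuration
#'
#' @param K Number of latent classes.
#' @param n_restarts Number of random EM starts (random per-case Dirichlet
#'   posteriors); the best final log-likelihood wins.
#' @param max_iter Maximum EM iterations per start.
#' @param tol Relative observed-data log-likelihood convergence tolerance.
#' @param seed Integer seed; fitting is deterministic given seed + data.
#' @param ridge Ridge stabiliser added to the Newton Hessian diagonal in
#'   the M-step solvers; guards against quasi-separation on small classes
#'   while perturbing estimates below reporting precision.
#' @param z_threshold Absolute Wald-Z cutoff for flagging effects.  The
#'   default 1.80 corresponds to a two-sided type-I rate of about 0.07
#'   (the exact two-sided 0.07 quantile is z = 1.812; 1.80 is the
#'   conventional rounded rule used with these models).
#' @param alpha Nominal two-sided level documented alongside the flag.
#' @param boot_restarts Random starts used when refitting within bootstrap
#'   replicates (smaller than `n_restarts` for speed).
#' @return An object of class `lcra_fit_config`.
#' @export
fit_config <- function(K = 3, n_restarts = 25, max_iter = 500, tol = 1e-8,
                       seed = 1, ridge = 1e-6, z_threshold = 1.80,
                       alpha = 0.07, boot_restarts = 2) {
  stopifnot(K >= 1, n_restarts >= 1, max_iter >= 1, tol > 0, ridge >= 0,
            boot_restarts >= 1)
  structure(list(K = as.integer(K), n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed), ridge = ridge,
                 z_threshold = z_threshold, alpha = alpha,
                 boot_restarts = as.integer(boot_restarts)),
            class = "lcra_fit_config")
}

# Internal: one EM run from a random per-case Dirichlet(1) posterior.
# Initial parameters are obtained by applying the M-step to the random
# posterior, then EM alternates full E/M steps in compiled code.
run_em_start <- function(Zc1, Zp1, y, K, config) {
  N <- nrow(Zc1)
  W0 <- matrix(stats::rexp(N * K), N, K)
  W0 <- W0 / rowSums(W0)
  gamma0 <- matrix(0, max(K - 1L, 0L), ncol(Zc1))
  if (K > 1L) {
    gamma0 <- mlogit_fit_cpp(Zc1, W0, rep(1, N), gamma0, config$ridge,
                             50L, 1e-10)$coef
  }
  Ty <- matrix(0, N, 3)
  Ty[cbind(seq_len(N), ifelse(y == 1L, 1L, ifelse(y == 2L, 2L, 3L)))] <- 1
  beta0 <- array(0, dim = c(2, ncol(Zp1), K))
  for (k in seq_len(K)) {
    beta0[, , k] <- mlogit_fit_cpp(Zp1, Ty, W0[, k],
                                   matrix(0, 2, ncol(Zp1)),
                                   config$ridge, 50L, 1e-10)$coef
  }
  em_lcra_cpp(Zc1, Zp1, y, K, gamma0, beta0, config$max_iter, config$tol,
              config$ridge, 25L, 1e-10)
}

#' Fit the latent class regression model by EM
#'
#' Maximum-likelihood estimation of the concomitant-covariate mixture by
#' expectation-maximisation with multi-start.  The E-step computes
#' posterior class probabilities; the M-step solves two families of
#' posterior-weighted multinomial-logit maximisations by ridge-stabilised
#' Newton iterations: the concomitant coefficients (covariates against the
#' posterior class indicators) and, per class, the outcome coefficients
#' (predictors against the outcome with posterior case weights).  The
#' observed-data log-likelihood is non-decreasing across iterations; the
#' best of `n_restarts` seeded random starts is returned.
#'
#' @param design An `lcra_design` with outcomes present for every case.
#' @param config An `lcra_fit_config`.
#' @param align Reorder classes by descending probability of no
#'   reoffending (class 1 = lowest risk) via [align_labels()].
#' @param se Compute observed-information standard errors (can be slow for
#'   large K; disable inside bootstrap loops).
#' @return An object of class `lcra_fit`: parameters, log-likelihood and
#'   trace, convergence flag, posterior matrix, standard errors and
#'   restart diagnostics.
#' @export
fit_em <- function(design, config = fit_config(), align = TRUE, se = TRUE) {
  stopifnot(inherits(design, "lcra_design"))
  y <- design$outcome
  if (anyNA(y)) {
    stop("outcome missing for case(s): ",
         paste(design$ids[is.na(y)], collapse = ", "))
  }
  K <- config$K
  N <- nrow(design$covariates)
  npar <- count_parameters(K, 3L, ncol(design$predictors),
                           ncol(design$covariates))
  if (N <= npar) {
    warning(sprintf("N = %d does not exceed the %d free parameters; estimates will be unstable",
                    N, npar))
  }
  Zc1 <- cbind(1, design$covariates)
  Zp1 <- cbind(1, design$predictors)
  n_starts <- if (K == 1L) 1L else config$n_restarts
  set.seed(config$seed)
  start_seeds <- sample.int(.Machine$integer.max - 1L, n_starts)
  runs <- vector("list", n_starts)
  for (r in seq_len(n_starts)) {
    set.seed(start_seeds[r])
    runs[[r]] <- run_em_start(Zc1, Zp1, y, K, config)
  }
  lls <- vapply(runs, function(x) x$loglik, numeric(1))
  best <- which.max(lls)
  res <- runs[[best]]
  diagnostics <- data.frame(
    start = seq_len(n_starts), seed = start_seeds, loglik = lls,
    converged = vapply(runs, function(x) isTRUE(x$converged), logical(1)),
    iterations = vapply(runs, function(x) x$iterations, numeric(1)))
  if (!any(diagnostics$converged)) {
    warning("EM did not converge in any restart; result flagged converged = FALSE")
  }
  beta <- array(0, dim = c(K, 2, ncol(Zp1)))
  for (k in seq_len(K)) beta[k, , ] <- res$beta[, , k]
  params <- lcra_params(K, res$gamma, beta,
                        covariate_names = design$covariate_names,
                        predictor_names = design$predictor_names)
  post <- res$posteriors
  colnames(post) <- params$class_labels
  attr(post, "assignment") <- "modal"
  eff_sizes <- colSums(post)
  if (any(eff_sizes < 1)) {
    warning("degenerate class (effective size < 1 case) at index ",
            paste(which(eff_sizes < 1), collapse = ", "))
  }
  fit <- structure(list(
    params = params,
    log_likelihood = res$loglik,
    ll_trace = res$trace,
    converged = diagnostics$converged[best],
    posteriors = post,
    n_cases = N,
    n_par = npar,
    restart_diagnostics = diagnostics,
    config = config,
    design = design,
    standard_errors = NULL
  ), class = "lcra_fit")
  if (align) fit <- align_labels(fit, recompute_se = FALSE)
  if (se) fit$standard_errors <- standard_errors(design, fit$params)
  fit
}

#' @export
print.lcra_fit <- function(x, ...) {
  cat(sprintf("lcra_fit: K = %d, N = %d, logLik = %.4f, Npar = %d, converged = %s\n",
              x$params$K, x$n_cases, x$log_likelihood, x$n_par, x$converged))
  cat("class sizes:", paste(sprintf("%.3f", class_sizes(x$posteriors)),
                            collapse = " "), "\n")
  invisible(x)
}

# ---- parameter packing and the analytic observed-data score ----

pack_params <- function(params) {
  c(as.vector(t(params$gamma)), as.vector(aperm(params$beta, c(3, 2, 1))))
}

unpack_params <- function(theta, template) {
  K <- template$K
  Pc1 <- ncol(template$gamma)
  Pp1 <- dim(template$beta)[3]
  ng <- (K - 1L) * Pc1
  gamma <- if (ng > 0) matrix(theta[seq_len(ng)], nrow = K - 1L, byrow = TRUE) else
    template$gamma
  beta <- array(aperm(array(theta[ng + seq_len(K * 2L * Pp1)],
                            dim = c(Pp1, 2, K)), c(3, 2, 1)),
                dim = c(K, 2, Pp1))
  lcra_params(K, gamma, beta, class_labels = template$class_labels,
              covariate_names = template$covariate_names,
              predictor_names = template$predictor_names)
}

# Gradient of the observed-data log-likelihood: the standard concomitant
# mixture score.  For the membership block, d/d gamma_k = sum_i
# (W_ik - pi_ik) zc_i; for the outcome block, d/d beta_kc = sum_i W_ik
# (1[y_i = c] - p_ikc) zp_i, with W the posterior at theta.
lcra_score <- function(theta, design, template) {
  params <- unpack_params(theta, template)
  K <- params$K
  Zc1 <- cbind(1, design$covariates)
  Zp1 <- cbind(1, design$predictors)
  y <- design$outcome
  N <- nrow(Zc1)
  W <- posterior_class_probs(design, params)
  g <- numeric(0)
  if (K > 1L) {
    pi_mat <- membership_matrix(params, design$covariates)
    for (k in seq_len(K - 1L)) {
      g <- c(g, colSums((W[, k] - pi_mat[, k]) * Zc1))
    }
  }
  for (k in seq_len(K)) {
    p_out <- outcome_matrix(params, design$predictors, k)
    for (cc in 1:2) {
      ind <- as.numeric(y == cc)
      g <- c(g, colSums(W[, k] * (ind - p_out[, cc + 1L]) * Zp1))
    }
  }
  g
}

# Analytic multinomial-logit Hessian for the K = 1 case (the observed
# log-likelihood is then an ordinary multinomial logit in beta).
mlogit_hessian_k1 <- function(design, params) {
  Zp1 <- cbind(1, design$predictors)
  P <- ncol(Zp1)
  p_out <- outcome_matrix(params, design$predictors, 1L)
  H <- matrix(0, 2 * P, 2 * P)
  for (j in 1:2) {
    for (l in j:2) {
      d <- if (j == l) p_out[, j + 1L] * (1 - p_out[, j + 1L]) else
        -p_out[, j + 1L] * p_out[, l + 1L]
      blk <- crossprod(Zp1, Zp1 * d)
      H[(j - 1) * P + 1:P, (l - 1) * P + 1:P] <- blk
      if (l != j) H[(l - 1) * P + 1:P, (j - 1) * P + 1:P] <- t(blk)
    }
  }
  -H
}

#' Observed-information standard errors
#'
#' Standard errors from the observed information matrix of the full
#' observed-data log-likelihood at the fitted parameters.  For `K = 1`
#' the exact analytic multinomial-logit Hessian is used; for mixtures the
#' Hessian is obtained by central finite differences of the analytic
#' score.  When the information matrix is singular in some directions
#' (a duplicated design column; a boundary membership solution), the
#' standard errors of the parameters loading on those directions are
#' flagged unavailable (`NA`), never fabricated; identified parameters
#' keep their generalized-inverse standard errors and the result carries
#' `ok = FALSE` with an explanatory message.
#'
#' @param design An `lcra_design` with outcomes.
#' @param params An `lcra_params` at (or near) a local maximum.
#' @return List with elements `gamma` (matrix of SEs), `beta` (array of
#'   SEs), `ok` (logical), `message`, and `vcov`.
#' @export
standard_errors <- function(design, params) {
  theta <- pack_params(params)
  p <- length(theta)
  if (params$K == 1L) {
    H <- mlogit_hessian_k1(design, params)
  } else {
    H <- matrix(0, p, p)
    for (j in seq_len(p)) {
      h <- 1e-5 * max(1, abs(theta[j]))
      tp <- theta; tp[j] <- tp[j] + h
      tm <- theta; tm[j] <- tm[j] - h
      H[, j] <- (lcra_score(tp, design, params) -
                   lcra_score(tm, design, params)) / (2 * h)
    }
    H <- (H + t(H)) / 2
  }
  info <- -H
  # Identify non-identified directions (boundary membership solutions,
  # collinear columns): parameters loading on near-null eigenvectors of
  # the information matrix are flagged unavailable; the rest keep their
  # generalized-inverse standard errors.
  ev <- eigen(info, symmetric = TRUE)
  keep <- ev$values > max(ev$values, 0) * 1e-10
  if (!any(keep)) {
    return(list(gamma = matrix(NA_real_, nrow(params$gamma),
                               ncol(params$gamma)),
                beta = array(NA_real_, dim = dim(params$beta)),
                ok = FALSE,
                message = "information matrix has no positive spectrum",
                vcov = NULL))
  }
  V <- ev$vectors
  vcov <- V[, keep, drop = FALSE] %*%
    (t(V[, keep, drop = FALSE]) / ev$values[keep])
  se <- sqrt(pmax(diag(vcov), 0))
  affected <- rowSums(V[, !keep, drop = FALSE]^2) > 1e-8
  se[affected] <- NA_real_
  ok <- all(keep)
  msg <- if (ok) "ok" else
    sprintf("information matrix singular in %d direction(s); affected standard errors flagged unavailable",
            sum(!keep))
  K <- params$K
  Pc1 <- ncol(params$gamma)
  Pp1 <- dim(params$beta)[3]
  ng <- (K - 1L) * Pc1
  gamma_se <- if (ng > 0) matrix(se[seq_len(ng)], nrow = K - 1L, byrow = TRUE) else
    params$gamma
  beta_se <- array(aperm(array(se[ng + seq_len(K * 2 * Pp1)],
                               dim = c(Pp1, 2, K)), c(3, 2, 1)),
                   dim = c(K, 2, Pp1))
  list(gamma = gamma_se, beta = beta_se, ok = ok, message = msg,
       vcov = vcov)
}

#' Wald-Z effect table
#'
#' `Z = estimate / SE` for every free coefficient, flagged when
#' `|Z| >= z_threshold` (default 1.80, a two-sided type-I rate of about
#' 0.07).  The table is partitioned into the covariate block (class
#' formation: concomitant coefficients, contrasts against the reference
#' class) and the predictor block (per-class outcome regressions).
#'
#' @param fitted An `lcra_fit` with standard errors.
#' @param config Optional `lcra_fit_config`; defaults to the fit's own.
#' @return Data frame with columns `block`, `class`, `outcome`, `term`,
#'   `estimate`, `se`, `z`, `flagged`.
#' @export
wald_z_table <- function(fitted, config = fitted$config) {
  stopifnot(inherits(fitted, "lcra_fit"))
  se <- fitted$standard_errors
  if (is.null(se)) se <- standard_errors(fitted$design, fitted$params)
  params <- fitted$params
  K <- params$K
  cov_terms <- c("(intercept)", params$covariate_names)
  pred_terms <- c("(intercept)", params$predictor_names)
  rows <- list()
  if (K > 1L) {
    for (k in seq_len(K - 1L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        block = "covariate",
        class = sprintf("%s vs %s", params$class_labels[k],
                        params$class_labels[K]),
        outcome = NA_character_,
        term = cov_terms,
        estimate = params$gamma[k, ],
        se = se$gamma[k, ],
        stringsAsFactors = FALSE)
    }
  }
  for (k in seq_len(K)) {
    for (cc in 1:2) {
      rows[[length(rows) + 1L]] <- data.frame(
        block = "predictor",
        class = params$class_labels[k],
        outcome = params$outcome_levels[cc + 1L],
        term = pred_terms,
        estimate = params$beta[k, cc, ],
        se = se$beta[k, cc, ],
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$z <- ifelse(!is.na(tab$se) & tab$se > 0, tab$estimate / tab$se, NA_real_)
  tab$flagged <- !is.na(tab$z) & abs(tab$z) >= config$z_threshold
  rownames(tab) <- NULL
  attr(tab, "z_threshold") <- config$z_threshold
  attr(tab, "alpha") <- config$alpha
  tab
}

#' Resolve label switching by ordering classes on risk
#'
#' Mixture classes are identified only up to permutation.  The default
#' rule orders classes by descending class-conditional probability of
#' "no reoffending", so class 1 is the lowest-risk class; ties (to 1e-9)
#' break by class size, descending.  Posteriors and `beta` are permuted;
#' `gamma` is re-expressed against the new reference class (the full
#' class-logit matrix is permuted and re-anchored), leaving the
#' log-likelihood unchanged.
#'
#' @param fitted An `lcra_fit`.
#' @param recompute_se Recompute standard errors after realignment (the
#'   concomitant block is reference-dependent, so permuted SEs are not
#'   simply reordered).
#' @return The realigned `lcra_fit`.
#' @export
align_labels <- function(fitted, recompute_se = TRUE) {
  stopifnot(inherits(fitted, "lcra_fit"))
  params <- fitted$params
  K <- params$K
  if (K == 1L) return(fitted)
  profile <- class_outcome_profile(fitted$design, params, fitted$posteriors)
  sizes <- class_sizes(fitted$posteriors)
  ord <- order(-round(profile[, "no"], 9), -sizes)
  if (identical(ord, seq_len(K))) return(fitted)
  A <- rbind(params$gamma, 0)[ord, , drop = FALSE]
  A <- sweep(A, 2, A[K, ])
  gamma_new <- A[-K, , drop = FALSE]
  beta_new <- params$beta[ord, , , drop = FALSE]
  fitted$params <- lcra_params(K, gamma_new, beta_new,
                               covariate_names = params$covariate_names,
                               predictor_names = params$predictor_names)
  post <- fitted$posteriors[, ord, drop = FALSE]
  colnames(post) <- fitted$params$class_labels
  attr(post, "assignment") <- "modal"
  fitted$posteriors <- post
  if (recompute_se && !is.null(fitted$standard_errors)) {
    fitted$standard_errors <- standard_errors(fitted$design, fitted$params)
  }
  fitted
}
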