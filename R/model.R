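#' Latent class regression parameters
#'
#' The model factorises the outcome density as
#' `f(y | zc, zp) = sum_k pi(k | zc) f(y | k, zp)`:
#' a concomitant multinomial logit `pi` forming `K` latent classes from the
#' covariates, and within each class a multinomial logit for the 3-category
#' outcome on the predictors.
#'
#' Conventions (fixed; results are invariant up to reparameterisation):
#' class `K` is the reference class of the membership logit; outcome
#' category `"no"` (no reoffending) is the reference of the within-class
#' regressions; column 1 of each coefficient block is the intercept.
#'
#' @param K Number of latent classes (>= 1).
#' @param gamma `(K-1) x (1 + n_covariates)` matrix of concomitant
#'   coefficients (empty matrix for `K = 1`).
#' @param beta `K x 2 x (1 + n_predictors)` array of within-class outcome
#'   coefficients; the second dimension indexes the contrasts
#'   non-violent-vs-no and violent-vs-no.
#' @param class_labels Optional display names, length `K`.
#' @param covariate_names,predictor_names Optional design column names
#'   (without the intercept).
#' @return An object of class `lcra_params`.
#' @export
lcra_params <- function(K, gamma, beta, class_labels = NULL,
                        covariate_names = NULL, predictor_names = NULL) {
  K <- as.integer(K)
  if (is.na(K) || K < 1L) stop("K must be an integer >= 1")
  gamma <- as.matrix(gamma)
  if (K == 1L && length(gamma) == 0L) {
    gamma <- matrix(numeric(0), nrow = 0,
                    ncol = if (ncol(gamma) > 0) ncol(gamma) else
                      length(covariate_names) + 1L)
  }
  if (nrow(gamma) != K - 1L) {
    stop(sprintf("gamma must have K-1 = %d rows, found %d", K - 1L, nrow(gamma)))
  }
  if (!is.array(beta) || length(dim(beta)) != 3L) {
    stop("beta must be a 3-d array: K x 2 x (1 + n_predictors)")
  }
  if (dim(beta)[1] != K || dim(beta)[2] != 2L) {
    stop(sprintf("beta must be K x 2 x (1+P); found %s",
                 paste(dim(beta), collapse = " x ")))
  }
  if (K > 1L && any(!is.finite(gamma))) stop("gamma must be finite")
  if (any(!is.finite(beta))) stop("beta must be finite")
  if (is.null(class_labels)) class_labels <- paste0("class", seq_len(K))
  stopifnot(length(class_labels) == K)
  dimnames(gamma) <- NULL   # canonical form; names live in *_names fields
  dimnames(beta) <- NULL
  structure(list(K = K, gamma = gamma, beta = beta,
                 class_labels = as.character(class_labels),
                 covariate_names = covariate_names,
                 predictor_names = predictor_names,
                 outcome_levels = c("no", "non-violent", "violent"),
                 n_covariate_cols = ncol(gamma) - 1L,
                 n_predictor_cols = dim(beta)[3] - 1L),
            class = "lcra_params")
}

#' @export
print.lcra_params <- function(x, ...) {
  cat(sprintf("lcra_params: K = %d classes, %d covariate columns, %d predictor columns\n",
              x$K, x$n_covariate_cols, x$n_predictor_cols))
  invisible(x)
}

# Row-wise cumulative sum that keeps matrix shape for single-column input.
row_cumsum <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) > 1L) for (j in 2:ncol(m)) m[, j] <- m[, j - 1L] + m[, j]
  m
}

# Row-wise softmax with log-sum-exp stabilisation; finite for linear
# predictors of magnitude up to several hundred.
softmax_rows <- function(eta) {
  m <- apply(eta, 1, max)
  e <- exp(eta - m)
  e / rowSums(e)
}

log_softmax_rows <- function(eta) {
  m <- apply(eta, 1, max)
  cen <- eta - m
  cen - log(rowSums(exp(cen)))
}

# Internal: N x K membership probability matrix from a covariate matrix
# (no intercept column; added here).
membership_matrix <- function(params, Zcov) {
  N <- nrow(Zcov)
  if (params$K == 1L) return(matrix(1, N, 1))
  if (ncol(Zcov) != params$n_covariate_cols) {
    stop(sprintf("covariate matrix has %d columns; parameters expect %d",
                 ncol(Zcov), params$n_covariate_cols))
  }
  eta <- cbind(cbind(1, Zcov) %*% t(params$gamma), 0)
  softmax_rows(eta)
}

# Internal: N x 3 within-class outcome probability matrix for class k.
outcome_matrix <- function(params, Zpred, k) {
  if (ncol(Zpred) != params$n_predictor_cols) {
    stop(sprintf("predictor matrix has %d columns; parameters expect %d",
                 ncol(Zpred), params$n_predictor_cols))
  }
  b <- matrix(params$beta[k, , ], nrow = 2)
  eta <- cbind(0, cbind(1, Zpred) %*% t(b))
  softmax_rows(eta)
}

#' Class-membership probabilities from the concomitant model
#'
#' Evaluates `pi(k | zc)` for one covariate row or a matrix of rows.
#'
#' @param params An `lcra_params`.
#' @param covariates Numeric vector of length `n_covariate_cols`, or a
#'   matrix with that many columns.
#' @return A probability vector over the K classes (or an N x K matrix).
#' @export
class_membership_probs <- function(params, covariates) {
  single <- is.null(dim(covariates))
  Z <- if (single) matrix(covariates, nrow = 1) else as.matrix(covariates)
  out <- membership_matrix(params, Z)
  colnames(out) <- params$class_labels
  if (single) out[1, ] else out
}

#' Within-class outcome probabilities
#'
#' Evaluates `f(y | k, zp)` over the outcome categories
#' (no, non-violent, violent) for class `k`.
#'
#' @param params An `lcra_params`.
#' @param predictors Numeric vector of length `n_predictor_cols` or matrix.
#' @param k Class index in 1..K.
#' @return A 3-probability vector (or N x 3 matrix).
#' @export
outcome_probs_given_class <- function(params, predictors, k) {
  stopifnot(k >= 1, k <= params$K)
  single <- is.null(dim(predictors))
  Z <- if (single) matrix(predictors, nrow = 1) else as.matrix(predictors)
  out <- outcome_matrix(params, Z, k)
  colnames(out) <- params$outcome_levels
  if (single) out[1, ] else out
}

#' Marginal (mixture) outcome probabilities
#'
#' The model's predictive distribution for a case:
#' `f(y | zc, zp) = sum_k pi(k | zc) f(y | k, zp)`.
#'
#' @inheritParams class_membership_probs
#' @inheritParams outcome_probs_given_class
#' @export
mixture_outcome_probs <- function(params, covariates, predictors) {
  single <- is.null(dim(covariates)) && is.null(dim(predictors))
  Zc <- if (is.null(dim(covariates))) matrix(covariates, nrow = 1) else as.matrix(covariates)
  Zp <- if (is.null(dim(predictors))) matrix(predictors, nrow = 1) else as.matrix(predictors)
  stopifnot(nrow(Zc) == nrow(Zp))
  pi_mat <- membership_matrix(params, Zc)
  out <- matrix(0, nrow(Zc), 3, dimnames = list(NULL, params$outcome_levels))
  for (k in seq_len(params$K)) {
    out <- out + pi_mat[, k] * outcome_matrix(params, Zp, k)
  }
  if (single) out[1, ] else out
}

#' Observed-data log-likelihood
#'
#' `sum_i log f(y_i | zc_i, zp_i)` under the mixture; requires an observed
#' outcome for every case.
#'
#' @param design An `lcra_design` with outcomes.
#' @param params An `lcra_params`.
#' @return Scalar log-likelihood.
#' @export
lcra_loglik <- function(design, params) {
  y <- design$outcome
  if (anyNA(y)) {
    stop("outcome missing for case(s): ",
         paste(design$ids[is.na(y)], collapse = ", "))
  }
  jm <- joint_log_matrix(design, params)
  m <- apply(jm, 1, max)
  sum(m + log(rowSums(exp(jm - m))))
}

# Internal: N x K matrix of log(pi_k(zc_i) * f(y_i | k, zp_i)).
joint_log_matrix <- function(design, params) {
  N <- nrow(design$covariates)
  y <- design$outcome
  if (params$K == 1L) {
    logpi <- matrix(0, N, 1)
  } else {
    eta <- cbind(cbind(1, design$covariates) %*% t(params$gamma), 0)
    logpi <- log_softmax_rows(eta)
  }
  logf <- matrix(0, N, params$K)
  Zp1 <- cbind(1, design$predictors)
  for (k in seq_len(params$K)) {
    b <- matrix(params$beta[k, , ], nrow = 2)
    lp <- log_softmax_rows(cbind(0, Zp1 %*% t(b)))
    logf[, k] <- lp[cbind(seq_len(N), y + 1L)]
  }
  logpi + logf
}

#' Posterior class-membership probabilities
#'
#' By Bayes' rule on the model factors: for a case with observed outcome,
#' posterior(k) is proportional to `pi(k | zc) f(y | k, zp)`; for a case
#' with unknown outcome the posterior is the concomitant prior
#' `pi(k | zc)` (the new-case prediction mode).
#'
#' @param design An `lcra_design`; outcomes may be partly missing.
#' @param params An `lcra_params`.
#' @return An N x K matrix with unit row sums, class labels as column
#'   names, and attribute `assignment = "modal"`.
#' @export
posterior_class_probs <- function(design, params) {
  N <- nrow(design$covariates)
  K <- params$K
  pi_mat <- membership_matrix(params, design$covariates)
  W <- pi_mat
  obs <- which(!is.na(design$outcome))
  if (length(obs) > 0L && K > 1L) {
    sub <- design
    sub$covariates <- design$covariates[obs, , drop = FALSE]
    sub$predictors <- design$predictors[obs, , drop = FALSE]
    sub$outcome <- design$outcome[obs]
    jm <- joint_log_matrix(sub, params)
    m <- apply(jm, 1, max)
    e <- exp(jm - m)
    W[obs, ] <- e / rowSums(e)
  }
  colnames(W) <- params$class_labels
  attr(W, "assignment") <- "modal"
  W
}

#' Class sizes from a posterior matrix
#'
#' The marginal class-size proportions: the mean of the posterior columns.
#'
#' @param posteriors An N x K posterior matrix.
#' @return K-vector summing to 1.
#' @export
class_sizes <- function(posteriors) {
  colMeans(as.matrix(posteriors))
}

#' Class-conditional outcome profile
#'
#' Row `k` is the posterior-weighted average over cases of the
#' within-class outcome distribution `f(. | k, zp_i)` — the class's
#' expected reoffending profile (probability of no / non-violent / violent
#' reoffending).
#'
#' @param design An `lcra_design`.
#' @param params An `lcra_params`.
#' @param posteriors Optional N x K weight matrix; defaults to
#'   [posterior_class_probs()].
#' @return K x 3 matrix with unit row sums.
#' @export
class_outcome_profile <- function(design, params, posteriors = NULL) {
  if (is.null(posteriors)) posteriors <- posterior_class_probs(design, params)
  posteriors <- as.matrix(posteriors)
  K <- params$K
  out <- matrix(0, K, 3, dimnames = list(params$class_labels,
                                         params$outcome_levels))
  for (k in seq_len(K)) {
    fmat <- outcome_matrix(params, design$predictors, k)
    w <- posteriors[, k]
    sw <- sum(w)
    out[k, ] <- if (sw > 0) colSums(fmat * w) / sw else colMeans(fmat)
  }
  out
}

#' Serialize fitted parameters as JSON
#'
#' The JSON document records `K`, `gamma`, `beta` (as a list of per-class
#' 2 x (1+P) matrices), labels, column names and the reference
#' conventions; it is the exchange format between the fit, predict and
#' validate stages.
#'
#' @param params An `lcra_params`.
#' @param path Output path.
#' @export
write_params <- function(params, path) {
  beta_list <- lapply(seq_len(params$K), function(k)
    matrix(params$beta[k, , ], nrow = 2))
  doc <- list(
    K = params$K,
    gamma = params$gamma,
    beta = beta_list,
    class_labels = params$class_labels,
    covariate_names = params$covariate_names,
    predictor_names = params$predictor_names,
    outcome_levels = params$outcome_levels,
    conventions = list(reference_class = "last",
                       reference_outcome = "no",
                       intercept_column = 1)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  K <- as.integer(doc$K)
  ncov1 <- if (K > 1L) ncol(as.matrix(doc$gamma)) else
    length(doc$covariate_names) + 1L
  gamma <- if (K > 1L) matrix(as.numeric(as.matrix(doc$gamma)),
                              nrow = K - 1L) else
    matrix(numeric(0), 0, ncov1)
  beta_list <- doc$beta
  if (is.array(beta_list) && length(dim(beta_list)) == 3L) {
    beta_list <- lapply(seq_len(dim(beta_list)[1]), function(k)
      matrix(beta_list[k, , ], nrow = 2))
  }
  P1 <- ncol(beta_list[[1]])
  beta <- array(0, dim = c(K, 2, P1))
  for (k in seq_len(K)) beta[k, , ] <- as.matrix(beta_list[[k]])
  lcra_params(K, gamma, beta, class_labels = doc$class_labels,
              covariate_names = doc$covariate_names,
              predictor_names = doc$predictor_names)
}
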