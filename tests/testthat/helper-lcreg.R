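# Shared fixtures and independent brute-force oracles.  The oracles are
# deliberately naive re-derivations (plain exp/normalise, explicit loops)
# so they stay independent of the package's vectorised implementations.

naive_softmax <- function(eta) {
  e <- exp(eta)
  e / sum(e)
}

# Brute-force class-membership probabilities for one covariate row.
bf_membership <- function(params, zc) {
  K <- params$K
  if (K == 1) return(1)
  eta <- numeric(K)
  for (k in seq_len(K - 1)) {
    eta[k] <- params$gamma[k, 1] + sum(params$gamma[k, -1] * zc)
  }
  naive_softmax(eta)
}

# Brute-force within-class outcome probabilities for one predictor row.
bf_outcome <- function(params, zp, k) {
  eta <- c(0, 0, 0)
  for (cc in 1:2) {
    eta[cc + 1] <- params$beta[k, cc, 1] + sum(params$beta[k, cc, -1] * zp)
  }
  naive_softmax(eta)
}

# Brute-force mixture outcome probabilities (explicit double loop).
bf_mixture <- function(params, zc, zp) {
  pi_k <- bf_membership(params, zc)
  out <- c(0, 0, 0)
  for (k in seq_len(params$K)) {
    out <- out + pi_k[k] * bf_outcome(params, zp, k)
  }
  out
}

# Brute-force posterior over classes given an observed outcome code (0..2).
bf_posterior <- function(params, zc, zp, y) {
  pi_k <- bf_membership(params, zc)
  num <- numeric(params$K)
  for (k in seq_len(params$K)) {
    num[k] <- pi_k[k] * bf_outcome(params, zp, k)[y + 1]
  }
  num / sum(num)
}

# Random small parameter set on the full 17/8-column codebook.  Slopes are
# drawn per-SD of their variable (dummies have SD-scale 1) so that random
# parameters produce non-degenerate outcome and class distributions on the
# raw measurement scales.
design_column_sds <- function() {
  marg <- default_marginals()
  sd_of <- function(f) marg[[f]]$sd
  cov_sds <- c(sd_of("age"), 1, 1, 1, 1,
               sd_of("ypi_interpersonal"), sd_of("ypi_affective"),
               sd_of("ypi_behavioral"), sd_of("bpm_internalizing"),
               sd_of("bpm_externalizing"), sd_of("bpm_attention"), 1, 1, 1, 1,
               sd_of("treatment_motivation"), sd_of("trauma"))
  pred_sds <- vapply(predictor_column_names(), sd_of, numeric(1))
  list(covariates = cov_sds, predictors = unname(pred_sds))
}

design_column_means <- function() {
  marg <- default_marginals()
  mean_of <- function(f) marg[[f]]$mean
  cov_means <- c(mean_of("age"),
                 marg$ses$probs[2], marg$ses$probs[3],
                 marg$ethnicity$probs[2], marg$ethnicity$probs[3],
                 mean_of("ypi_interpersonal"), mean_of("ypi_affective"),
                 mean_of("ypi_behavioral"), mean_of("bpm_internalizing"),
                 mean_of("bpm_externalizing"), mean_of("bpm_attention"),
                 marg$criminal_friends$probs[2],
                 marg$substance_use$probs[2], marg$substance_use$probs[3],
                 marg$substance_use$probs[4],
                 mean_of("treatment_motivation"), mean_of("trauma"))
  pred_means <- vapply(predictor_column_names(), mean_of, numeric(1))
  list(covariates = unname(cov_means), predictors = unname(pred_means))
}

rand_params <- function(K, seed, scale = 0.4) {
  set.seed(seed)
  sds <- design_column_sds()
  mus <- design_column_means()
  gamma <- if (K > 1) {
    g <- matrix(rnorm((K - 1) * 18, sd = scale), K - 1, 18)
    g <- sweep(g, 2, c(1, sds$covariates), "/")
    g[, 1] <- g[, 1] - as.vector(g[, -1] %*% mus$covariates)
    g
  } else matrix(numeric(0), 0, 18)
  beta <- array(rnorm(K * 2 * 9, sd = scale), dim = c(K, 2, 9))
  for (j in 2:9) beta[, , j] <- beta[, , j] / sds$predictors[j - 1]
  for (k in seq_len(K)) for (cc in 1:2) {
    beta[k, cc, 1] <- beta[k, cc, 1] - sum(beta[k, cc, -1] * mus$predictors)
  }
  lcra_params(K, gamma, beta,
              covariate_names = covariate_column_names(),
              predictor_names = predictor_column_names())
}

# Small synthetic design with outcomes, drawn from the default marginals
# under given (or random) parameters.
make_design <- function(n, seed, params = rand_params(2, seed + 1)) {
  cohort <- generate_cohort(generator_spec(n = n, seed = seed, params = params))
  list(design = encode_cases(cohort$cases), cohort = cohort, params = params)
}

# Case records with rounded numerics (exact CSV round trips).
make_records <- function(n, seed) {
  cohort <- generate_cohort(generator_spec(n = n, seed = seed,
                                           params = rand_params(2, seed)))
  cases <- cohort$cases
  for (nm in names(cases)) {
    if (is.numeric(cases[[nm]])) cases[[nm]] <- round(cases[[nm]], 3)
  }
  cases
}

# The published external-validation confusion table (with-neuro block).
published_confusion <- function() {
  path <- system.file("extdata", "external_validation_confusion.csv",
                      package = "lcreg")
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  as_confusion(m)
}

# One-class null parameters: outcome unrelated to every predictor.
null_k1_params <- function(p_no = 0.62, p_nv = 0.23) {
  beta <- array(0, dim = c(1, 2, 9))
  beta[1, 1, 1] <- log(p_nv / p_no)
  beta[1, 2, 1] <- log((1 - p_no - p_nv) / p_no)
  lcra_params(1, matrix(numeric(0), 0, 18), beta,
              covariate_names = covariate_column_names(),
              predictor_names = predictor_column_names())
}
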