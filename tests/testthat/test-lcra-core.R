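test_that("class-membership probabilities follow the concomitant logit", {
  p1 <- rand_params(1, seed = 1)
  expect_equal(class_membership_probs(p1, rnorm(17)), c(class1 = 1))

  p3 <- lcra_params(3, matrix(0, 2, 18), array(0, dim = c(3, 2, 9)))
  expect_equal(unname(class_membership_probs(p3, rnorm(17))), rep(1 / 3, 3))

  g <- matrix(0, 1, 18); g[1, 1] <- log(3)
  p2 <- lcra_params(2, g, array(0, dim = c(2, 2, 9)))
  expect_equal(unname(class_membership_probs(p2, rnorm(17))), c(0.75, 0.25))

  expect_error(class_membership_probs(rand_params(2, 2), rnorm(5)), "columns")
})

test_that("within-class outcome probabilities match a naive softmax oracle", {
  p <- rand_params(2, seed = 3)
  p$beta[1, , ] <- 0
  expect_equal(unname(outcome_probs_given_class(p, rnorm(8), 1)), rep(1 / 3, 3))

  b <- array(0, dim = c(1, 2, 9))
  b[1, 1, 1] <- log(2); b[1, 2, 1] <- log(1)
  pp <- lcra_params(1, matrix(numeric(0), 0, 18), b)
  expect_equal(unname(outcome_probs_given_class(pp, rnorm(8), 1)),
               c(0.25, 0.50, 0.25))

  set.seed(9)
  for (i in 1:20) {
    pr <- rand_params(3, seed = 100 + i, scale = 1)
    zp <- rnorm(8)
    k <- sample(3, 1)
    expect_equal(unname(outcome_probs_given_class(pr, zp, k)),
                 bf_outcome(pr, zp, k), tolerance = 1e-12)
  }
})

test_that("mixture outcome probabilities equal the brute-force double sum", {
  p1 <- rand_params(1, seed = 4)
  zc <- rnorm(17); zp <- rnorm(8)
  expect_equal(mixture_outcome_probs(p1, zc, zp),
               outcome_probs_given_class(p1, zp, 1))

  # arithmetic mixture: memberships (0.5, 0.5), fixed class outcome rows
  expect_equal(0.5 * c(0.7, 0.2, 0.1) + 0.5 * c(0.1, 0.2, 0.7),
               c(0.4, 0.2, 0.4))

  for (i in 1:20) {
    pr <- rand_params(3, seed = 200 + i, scale = 0.8)
    zc <- rnorm(17); zp <- rnorm(8)
    expect_equal(unname(mixture_outcome_probs(pr, zc, zp)),
                 bf_mixture(pr, zc, zp), tolerance = 1e-12)
  }
})

test_that("log-likelihood sums per-case log mixture probabilities", {
  # single case whose mixture probability for its outcome is exactly 0.5
  b <- array(0, dim = c(1, 2, 9))
  b[1, 1, 1] <- log(0.5); b[1, 2, 1] <- log(0.5)   # probs (0.5, 0.25, 0.25)
  p <- lcra_params(1, matrix(numeric(0), 0, 18), b,
                   covariate_names = covariate_column_names(),
                   predictor_names = predictor_column_names())
  md <- make_design(1, seed = 6, params = p)
  d <- md$design
  d$outcome <- 0L
  d$predictors[] <- 0
  expect_equal(lcra_loglik(d, p), log(0.5), tolerance = 1e-12)

  md <- make_design(10, seed = 7, params = rand_params(3, 70))
  d <- md$design
  pr <- md$params
  oracle <- 0
  for (i in 1:10) {
    oracle <- oracle +
      log(bf_mixture(pr, d$covariates[i, ], d$predictors[i, ])[d$outcome[i] + 1])
  }
  expect_equal(lcra_loglik(d, pr), oracle, tolerance = 1e-10)

  # additivity: duplicating every row doubles the value
  d2 <- d
  d2$covariates <- rbind(d$covariates, d$covariates)
  d2$predictors <- rbind(d$predictors, d$predictors)
  d2$outcome <- c(d$outcome, d$outcome)
  d2$ids <- c(d$ids, paste0(d$ids, "b"))
  expect_equal(lcra_loglik(d2, pr), 2 * lcra_loglik(d, pr), tolerance = 1e-10)

  # permutation invariance
  set.seed(1); idx <- sample(10)
  d3 <- d
  d3$covariates <- d$covariates[idx, ]; d3$predictors <- d$predictors[idx, ]
  d3$outcome <- d$outcome[idx]; d3$ids <- d$ids[idx]
  expect_equal(lcra_loglik(d3, pr), lcra_loglik(d, pr), tolerance = 1e-12)

  d$outcome[3] <- NA
  expect_error(lcra_loglik(d, pr), d$ids[3])
})

test_that("posterior class probabilities apply Bayes' rule on the model factors", {
  md <- make_design(5, seed = 8, params = rand_params(1, 80))
  expect_equal(unname(posterior_class_probs(md$design, md$params)[, 1]),
               rep(1, 5))

  # equal priors, class outcome likelihoods 0.7 vs 0.1 for the observed "no"
  b <- array(0, dim = c(2, 2, 9))
  b[1, 1, 1] <- log(0.2 / 0.7); b[1, 2, 1] <- log(0.1 / 0.7)
  b[2, 1, 1] <- log(0.2 / 0.1); b[2, 2, 1] <- log(0.7 / 0.1)
  p <- lcra_params(2, matrix(0, 1, 18), b,
                   covariate_names = covariate_column_names(),
                   predictor_names = predictor_column_names())
  md <- make_design(1, seed = 9, params = p)
  d <- md$design
  d$predictors[] <- 0
  d$covariates[] <- 0
  d$outcome <- 0L
  expect_equal(unname(posterior_class_probs(d, p)[1, ]), c(0.875, 0.125),
               tolerance = 1e-12)

  md <- make_design(8, seed = 10, params = rand_params(3, 101))
  d <- md$design; pr <- md$params
  W <- posterior_class_probs(d, pr)
  for (i in 1:8) {
    expect_equal(unname(W[i, ]),
                 bf_posterior(pr, d$covariates[i, ], d$predictors[i, ],
                              d$outcome[i]), tolerance = 1e-12)
  }
  expect_equal(unname(rowSums(W)), rep(1, 8), tolerance = 1e-10)

  # missing outcome: posterior falls back to the concomitant prior
  d$outcome[2] <- NA
  W2 <- posterior_class_probs(d, pr)
  expect_equal(unname(W2[2, ]),
               bf_membership(pr, d$covariates[2, ]), tolerance = 1e-12)
})

test_that("class sizes and outcome profiles aggregate the posteriors", {
  expect_equal(class_sizes(matrix(1, 4, 1)), 1)
  expect_equal(unname(class_sizes(rbind(c(1, 0), c(0, 1)))), c(0.5, 0.5))

  p1 <- rand_params(1, 12)
  p1$beta[] <- 0
  md <- make_design(6, seed = 13, params = p1)
  prof <- class_outcome_profile(md$design, p1)
  expect_equal(unname(prof[1, ]), rep(1 / 3, 3))

  pr <- rand_params(3, seed = 14)
  md <- make_design(12, seed = 15, params = pr)
  d <- md$design
  unif <- matrix(1 / 3, 12, 3)
  prof_u <- class_outcome_profile(d, pr, unif)
  for (k in 1:3) {
    man <- colMeans(t(vapply(seq_len(12), function(i)
      bf_outcome(pr, d$predictors[i, ], k), numeric(3))))
    expect_equal(unname(prof_u[k, ]), man, tolerance = 1e-12)
  }
  W <- posterior_class_probs(d, pr)
  prof <- class_outcome_profile(d, pr, W)
  for (k in 1:3) {
    fm <- t(vapply(seq_len(12), function(i)
      bf_outcome(pr, d$predictors[i, ], k), numeric(3)))
    expect_equal(unname(prof[k, ]), colSums(fm * W[, k]) / sum(W[, k]),
                 tolerance = 1e-12)
  }
  expect_equal(unname(rowSums(prof)), rep(1, 3), tolerance = 1e-10)
})

test_that("softmax computations stay finite for coefficients up to +/-50", {
  g <- matrix(50, 2, 18)
  b <- array(c(-50, 50), dim = c(3, 2, 9))
  p <- lcra_params(3, g, b,
                   covariate_names = covariate_column_names(),
                   predictor_names = predictor_column_names())
  md <- make_design(5, seed = 16, params = rand_params(3, 160))
  d <- md$design
  pi_mat <- class_membership_probs(p, d$covariates)
  expect_true(all(is.finite(pi_mat)))
  expect_equal(unname(rowSums(pi_mat)), rep(1, 5), tolerance = 1e-10)
  pm <- mixture_outcome_probs(p, d$covariates, d$predictors)
  expect_true(all(is.finite(pm)))
  expect_true(is.finite(lcra_loglik(d, p)))
})

test_that("parameters serialize to JSON and back exactly", {
  for (K in c(1, 3)) {
    p <- rand_params(K, seed = 17 + K)
    path <- tempfile(fileext = ".json")
    write_params(p, path)
    p2 <- read_params(path)
    expect_equal(p2$gamma, p$gamma, tolerance = 1e-12)
    expect_equal(p2$beta, p$beta, tolerance = 1e-12)
    expect_identical(p2$K, p$K)
    expect_identical(p2$covariate_names, p$covariate_names)
  }
})
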