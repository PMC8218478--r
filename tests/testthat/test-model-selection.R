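test_that("parameter accounting matches the model structure", {
  expect_identical(count_parameters(1), 18L)
  expect_identical(count_parameters(2), 54L)
  expect_identical(count_parameters(3), 90L)
  expect_error(count_parameters(0))

  # brute-force enumeration of free coefficient slots in a parameter object
  for (K in 1:3) {
    p <- rand_params(K, seed = K)
    slots <- length(p$gamma) + length(p$beta)
    expect_identical(count_parameters(K), as.integer(slots))
  }
  # reduced model: intercept-only outcome regressions
  expect_identical(count_parameters(3, n_predictor_columns = 0),
                   3L * 2L + 2L * 18L)

  expect_identical(degrees_of_freedom(223, 18), 205L)
  expect_identical(degrees_of_freedom(223, 90), 133L)
  expect_identical(degrees_of_freedom(100, 100), 0L)
})

test_that("information criteria satisfy their closed-form identities", {
  set.seed(31)
  for (i in 1:25) {
    L2 <- runif(1, 0, 500); N <- sample(50:5000, 1); df <- N - sample(10:40, 1)
    ic <- information_criteria(L2, df, N)
    expect_equal(ic$AIC_L2, L2 - 2 * df)
    expect_equal(ic$AIC3_L2, L2 - 3 * df)
    expect_equal(ic$BIC_L2, L2 - log(N) * df)
    expect_equal(ic$CAIC_L2, L2 - (log(N) + 1) * df)
    expect_equal(ic$SABIC_L2, L2 - log((N + 2) / 24) * df)
  }
  ic0 <- information_criteria(0, 0, 100)
  expect_true(all(unlist(ic0) == 0))
})

test_that("L2 uses the per-case saturation convention and nests monotonically", {
  md <- make_design(150, seed = 32, params = default_study_spec()$params)
  f1 <- fit_em(md$design, fit_config(K = 1, seed = 1), se = FALSE)
  f2 <- suppressWarnings(
    fit_em(md$design, fit_config(K = 2, n_restarts = 3, seed = 1), se = FALSE))
  g1 <- l2_statistic(f1); g2 <- l2_statistic(f2)
  expect_equal(g1$L2, -2 * f1$log_likelihood)
  expect_gte(g1$L2, g2$L2)      # smaller model fits no better
  expect_identical(g1$df, 150L - 18L)
  expect_true(g1$p_defined)

  # saturated (perfect per-case prediction) means L2 = 0
  perfect <- f1; perfect$log_likelihood <- 0
  expect_equal(l2_statistic(perfect)$L2, 0)

  # df <= 0 leaves the p-value undefined and flagged
  tiny <- make_design(10, seed = 33, params = rand_params(1, 330))
  ft <- fit_em(tiny$design, fit_config(K = 1, seed = 1), se = FALSE)
  gt <- l2_statistic(ft)
  expect_false(gt$p_defined)
  expect_true(is.na(gt$p_value))
})

test_that("-2LLDiff works on fits and on printed L2 values", {
  expect_equal(neg2_ll_diff(383.92, 268.71), 115.21)
  md <- make_design(120, seed = 34, params = default_study_spec()$params)
  f1 <- fit_em(md$design, fit_config(K = 1, seed = 1), se = FALSE)
  expect_equal(neg2_ll_diff(f1, f1), 0)
  f2 <- suppressWarnings(
    fit_em(md$design, fit_config(K = 2, n_restarts = 2, seed = 1), se = FALSE))
  expect_equal(neg2_ll_diff(f1, f2),
               2 * (f2$log_likelihood - f1$log_likelihood), tolerance = 1e-8)
  expect_equal(neg2_ll_diff(f1, f2),
               l2_statistic(f1)$L2 - l2_statistic(f2)$L2, tolerance = 1e-8)
})

test_that("classification error averages off-modal posterior mass", {
  expect_equal(classification_error(diag(3)[c(1, 2, 3, 1), ]), 0)
  expect_equal(classification_error(matrix(1 / 3, 5, 3)), 2 / 3)
  expect_equal(classification_error(rbind(c(0.9, 0.1, 0), c(0.6, 0.3, 0.1))),
               0.25)
})

test_that("entropy pseudo-R2 is 0 at the null and 1 under perfect prediction", {
  md <- make_design(200, seed = 35, params = null_k1_params())
  d <- md$design
  marg <- tabulate(d$outcome + 1L, 3) / 200
  b <- array(0, dim = c(1, 2, 9))
  b[1, 1, 1] <- log(marg[2] / marg[1]); b[1, 2, 1] <- log(marg[3] / marg[1])
  p_marg <- lcra_params(1, matrix(numeric(0), 0, 18), b,
                        covariate_names = covariate_column_names(),
                        predictor_names = predictor_column_names())
  null_fit <- list(params = p_marg, log_likelihood = NA, design = d,
                   n_par = 18L)
  class(null_fit) <- "lcra_fit"
  expect_equal(outcome_r2(null_fit, d), 0, tolerance = 1e-12)

  # near-deterministic outcome model: R2 approaches 1
  b2 <- array(0, dim = c(1, 2, 9))
  b2[1, 1, 2] <- 40; b2[1, 2, 3] <- 40; b2[1, 1, 1] <- -20; b2[1, 2, 1] <- -20
  p_det <- lcra_params(1, matrix(numeric(0), 0, 18), b2,
                       covariate_names = covariate_column_names(),
                       predictor_names = predictor_column_names())
  dd <- d
  dd$predictors[, 1] <- rep_len(c(1, 0, 0), 200)
  dd$predictors[, 2] <- rep_len(c(0, 1, 0), 200)
  pm <- mixture_outcome_probs(p_det, dd$covariates, dd$predictors)
  dd$outcome <- max.col(matrix(pm, ncol = 3)) - 1L
  det_fit <- null_fit; det_fit$params <- p_det
  expect_gt(outcome_r2(det_fit, dd), 0.999)

  # recomputation oracle on a seeded fit
  md2 <- make_design(150, seed = 36, params = rand_params(2, 360))
  fit <- suppressWarnings(
    fit_em(md2$design, fit_config(K = 2, n_restarts = 2, seed = 4), se = FALSE))
  pmx <- matrix(mixture_outcome_probs(fit$params, md2$design$covariates,
                                      md2$design$predictors), ncol = 3)
  y <- md2$design$outcome
  h_m <- -log(pmx[cbind(seq_along(y), y + 1)])
  mg <- tabulate(y + 1L, 3) / length(y)
  expect_equal(outcome_r2(fit), 1 - sum(h_m) / sum(-log(mg[y + 1])),
               tolerance = 1e-10)
})

test_that("selection table rows satisfy every index identity", {
  md <- make_design(180, seed = 37, params = default_study_spec()$params)
  cfg <- fit_config(n_restarts = 2, seed = 3)
  tab1 <- suppressWarnings(selection_table(md$design, 1, cfg))
  expect_identical(nrow(tab1), 1L)
  expect_true(is.na(tab1$neg2LLdiff[1]))

  tab <- suppressWarnings(selection_table(md$design, 2, cfg))
  N <- 180
  for (r in 1:2) {
    expect_equal(tab$df[r] + tab$Npar[r], N)
    expect_equal(tab$AIC_L2[r], tab$L2[r] - 2 * tab$df[r])
    expect_equal(tab$AIC3_L2[r], tab$L2[r] - 3 * tab$df[r])
    expect_equal(tab$BIC_L2[r], tab$L2[r] - log(N) * tab$df[r])
    expect_equal(tab$CAIC_L2[r], tab$L2[r] - (log(N) + 1) * tab$df[r])
    expect_equal(tab$SABIC_L2[r], tab$L2[r] - log((N + 2) / 24) * tab$df[r])
  }
  expect_equal(tab$neg2LLdiff[2], tab$L2[1] - tab$L2[2], tolerance = 1e-8)
  # L2-scale and logLik-scale indices always rank identically
  expect_true(attr(tab, "ranking_agreement"))
})

test_that("class enumeration recovers the generating three-class structure", {
  spec <- default_study_spec(n = 2000, seed = 38)
  cohort <- generate_cohort(spec)
  d <- encode_cases(cohort$cases)
  tab <- suppressWarnings(
    selection_table(d, 3, fit_config(n_restarts = 4, seed = 6)))
  expect_identical(which.min(tab$AIC_L2), 3L)
  expect_identical(which.min(tab$SABIC_L2), 3L)
})

test_that("bootstrap LRT is seeded, valid and rejects invalid input", {
  md <- make_design(150, seed = 39, params = null_k1_params())
  expect_error(bootstrap_lrt(md$design, 1, 2, B = 0), "B must be")
  expect_error(bootstrap_lrt(md$design, 2, 2, B = 5), "exceed")

  r1 <- bootstrap_lrt(md$design, 1, 2, B = 19,
                      fit_config(seed = 11, boot_restarts = 1))
  r2 <- bootstrap_lrt(md$design, 1, 2, B = 19,
                      fit_config(seed = 11, boot_restarts = 1))
  expect_identical(r1$p_value, r2$p_value)
  expect_identical(r1$replicates, r2$replicates)
  expect_gt(r1$p_value, 0)
  expect_lte(r1$p_value, 1)
  expect_true(all(r1$replicates >= 0))
  expect_equal(r1$p_value,
               (1 + sum(r1$replicates >= r1$statistic - 1e-8)) /
                 (r1$B_used + 1))
})

test_that("bootstrap LRT detects a true two-class structure", {
  # power check, scaled down from a 50-replication experiment
  spec <- default_study_spec()
  A <- rbind(spec$params$gamma, 0)[c(1, 3), ]
  A <- sweep(A, 2, A[2, ])
  p2 <- lcra_params(2, A[1, , drop = FALSE],
                    spec$params$beta[c(1, 3), , , drop = FALSE],
                    covariate_names = spec$params$covariate_names,
                    predictor_names = spec$params$predictor_names)
  rejections <- 0L
  for (s in 1:5) {
    co <- generate_cohort(generator_spec(n = 500, seed = 400 + s, params = p2))
    d <- encode_cases(co$cases)
    r <- bootstrap_lrt(d, 1, 2, B = 99,
                       fit_config(seed = 400 + s, boot_restarts = 1))
    rejections <- rejections + (r$p_value < 0.05)
  }
  expect_gte(rejections, 4L)
})
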