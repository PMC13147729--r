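# Per-probe OLS, empirical-Bayes moderation, BH correction, global tests
# and sensitivity reruns.

test_that("fit_probe_models recovers exact and noiseless slopes", {
  cov <- toy_covariates(12)
  m <- rbind(
    exact = 0.1 * cov$age,       # pure age signal
    flat  = rep(2.5, 12)         # constant probe
  )
  colnames(m) <- cov$subject_id
  fits <- fit_probe_models(m, cov)
  expect_equal(fits$slope_age[1], 0.1, tolerance = 1e-10)
  expect_equal(fits$slope_age[2], 0, tolerance = 1e-12)
  expect_equal(fits$sigma2[2], 0, tolerance = 1e-20)
  expect_equal(fits$df_residual, rep(12 - 4, 2))
  expect_equal(fits$mean_m[2], 2.5)

  cov2 <- cov
  cov2$bmi2 <- cov2$bmi * 2      # perfectly collinear column
  expect_error(fit_probe_models(m, cov2, ~ age + bmi + bmi2), "rank deficient")
})

test_that("OLS slope estimates are unbiased under Monte-Carlo replication", {
  set.seed(77)
  n <- 63
  cov <- data.frame(subject_id = sprintf("S%02d", 1:n),
                    age = sample(18:35, n, replace = TRUE),
                    bmi = runif(n, 19, 32),
                    patient = rbinom(n, 1, 0.24))
  reps <- 1000
  m <- matrix(-0.05 * cov$age, reps, n, byrow = TRUE) +
    matrix(rnorm(reps * n, sd = 0.3), reps, n)
  rownames(m) <- paste0("r", seq_len(reps)); colnames(m) <- cov$subject_id
  fits <- fit_probe_models(m, cov)
  expect_lt(abs(mean(fits$slope_age) + 0.05), 0.005)
})

test_that("moderation limits: d0 = 0 gives the ordinary t, d0 = Inf full shrinkage", {
  set.seed(5)
  cov <- toy_covariates(15)
  m <- matrix(rnorm(30 * 15, sd = rep(seq(0.1, 1, length.out = 30), 15)), 30, 15)
  dimnames(m) <- list(paste0("p", 1:30), cov$subject_id)
  fits <- fit_probe_models(m, cov)

  none <- moderate_statistics(fits, prior_df = 0)
  expect_equal(none$table$mod_t, fits$t_ordinary)
  expect_equal(none$table$df_total, fits$df_residual)
  expect_equal(none$table$var_posterior, fits$sigma2)

  full <- moderate_statistics(fits, prior_df = Inf)
  expect_equal(full$table$var_posterior,
               rep(full$prior$var_prior, nrow(fits)))
})

test_that("posterior variances match the convex-combination oracle and stay bounded", {
  s2 <- c(0.5, 1.2, 0.05, 2.4, 0.9, 0.33, 1.8, 0.7, 0.12, 1.05)
  fits <- data.frame(probe_id = paste0("p", 1:10), slope_age = rnorm(10),
                     sigma2 = s2, df_residual = 59, stdev_unscaled = 0.02)
  mod <- moderate_statistics(fits)
  d0 <- mod$prior$df_prior; s02 <- mod$prior$var_prior
  expect_equal(mod$table$var_posterior,
               posterior_var_oracle(s2, rep(59, 10), d0, s02))
  # posterior variance lies between the probe variance and the prior
  expect_true(all(mod$table$var_posterior >= pmin(s2, s02) - 1e-12))
  expect_true(all(mod$table$var_posterior <= pmax(s2, s02) + 1e-12))
  expect_error(
    moderate_statistics(data.frame(probe_id = "a", slope_age = 1, sigma2 = 0,
                                   df_residual = 5, stdev_unscaled = 1)[c(1, 1), ]),
    "zero")
})

test_that("moderated statistics agree with an independent empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(42)
  n <- 20; n_probes <- 200
  cov <- toy_covariates(n, seed = 42)
  sds <- sqrt(0.2 / rchisq(n_probes, df = 8) * 8)  # heteroscedastic truth
  m <- matrix(rnorm(n_probes * n, sd = rep(sds, n)), n_probes, n)
  dimnames(m) <- list(paste0("p", seq_len(n_probes)), cov$subject_id)

  fits <- fit_probe_models(m, cov)
  mod <- moderate_statistics(fits)

  design <- model.matrix(~ age + bmi + patient, cov)
  lfit <- limma::eBayes(limma::lmFit(m, design))
  expect_true(is.finite(mod$prior$df_prior))
  expect_equal(mod$prior$df_prior, lfit$df.prior, tolerance = 1e-6)
  expect_equal(mod$prior$var_prior, lfit$s2.prior, tolerance = 1e-6)
  expect_equal(mod$table$mod_t, unname(lfit$t[, "age"]), tolerance = 1e-8)
  expect_equal(mod$table$p_raw, unname(lfit$p.value[, "age"]), tolerance = 1e-8)
})

test_that("BH adjustment reproduces the step-up procedure and is order-stable", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.37), 0.37)
  expect_equal(adjust_fdr(c(1, 1)), c(1, 1))
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(9)
  p <- runif(50)^2
  perm <- sample(50)
  expect_equal(adjust_fdr(p)[perm], adjust_fdr(p[perm]))
  expect_true(all(adjust_fdr(p) >= p))
})

test_that("global methylation tests behave at the deterministic extremes", {
  cov <- toy_covariates(10)
  # global means strictly increasing with age -> r = 1
  beta <- matrix(rep(seq(0.3, 0.5, length.out = 10), each = 20), 20, 10)
  dimnames(beta) <- list(paste0("p", 1:20), cov$subject_id)
  res <- global_methylation_tests(beta, cov)
  r_all <- res$tests[res$tests$probe_set == "All" &
                       res$tests$test == "pearson_age", ]
  expect_equal(r_all$estimate, 1, tolerance = 1e-12)

  # identical distributions in both strata -> tie-corrected U-test p = 1
  beta2 <- matrix(rep(rep(c(0.3, 0.3, 0.3, 0.4, 0.4), 2), each = 20), 20, 10)
  dimnames(beta2) <- dimnames(beta)
  cov2 <- cov; cov2$patient <- rep(c(0, 1), each = 5)
  res2 <- global_methylation_tests(beta2, cov2)
  u <- res2$tests[res2$tests$probe_set == "All" &
                    res2$tests$test == "mannwhitney_patient", ]
  expect_equal(u$p_value, 1)

  # constant global means are flagged, not NaN-propagated
  beta3 <- matrix(0.5, 20, 10, dimnames = dimnames(beta))
  res3 <- global_methylation_tests(beta3, cov)
  flagged <- res3$tests[res3$tests$test == "pearson_age", ]
  expect_true(all(grepl("undefined", flagged$note)))
  expect_error(global_methylation_tests(beta[, 1:2], cov[1:2, ]), "3 subjects")
})

test_that("age-global correlation keeps its nominal type-I error on null arrays", {
  n_rep <- 200
  cfg <- generator_config(n_subjects = 63, n_probes = 2000,
                          effect_fraction = 0, seed = 1)
  cov <- make_covariates(63, cfg)
  ann <- make_annotation(2000, cfg)
  set.seed(1)
  rep_seeds <- sample.int(2147483646L, n_rep)  # well-separated substreams
  p_vals <- vapply(rep_seeds, function(s) {
    cfg_i <- cfg; cfg_i$seed <- s
    beta <- make_beta_matrix(ann, cov, cfg_i)$beta
    g <- colMeans(beta)
    cor.test(g, cov$age)$p.value
  }, numeric(1))
  # rejection rate at most nominal 5% plus a 99% Monte-Carlo allowance
  mc_bound <- 0.05 + qnorm(0.995) * sqrt(0.05 * 0.95 / n_rep)
  expect_lte(mean(p_vals <= 0.05), mc_bound)
})

test_that("sensitivity scenarios with empty exclusion sets reproduce the main fit", {
  cfg <- generator_config(n_subjects = 16, n_probes = 200, snp_rate = 0,
                          seed = 13)
  ds <- simulate_dataset(cfg)
  main <- run_ewas(ds)
  sens <- sensitivity_rerun(ds, "drop_snp_probes", main = main)
  expect_equal(sens$table$slope_m_per_year, main$slope_m_per_year)
  expect_equal(sens$comparison$sign_agreement, 1)
  expect_equal(sens$comparison$spearman_rho, 1)

  tiny <- ds
  tiny$covariates$patient <- c(rep(1, 13), rep(0, 3))
  expect_error(sensitivity_rerun(tiny, "drop_patients", main = main),
               "infeasible")
})

test_that("planted slopes keep their sign when patients are excluded", {
  cfg <- generator_config(
    n_subjects = 63, n_probes = 3000, effect_fraction = 0.05,
    effect_sizes = list(dist = "fixed", value = 0.05), seed = 17)
  ds <- simulate_dataset(cfg)
  main <- run_ewas(ds)
  sens <- sensitivity_rerun(ds, "drop_patients", main = main)
  planted <- ds$truth$probe_id[ds$truth$planted]
  s_main <- main$slope_m_per_year[match(planted, main$probe_id)]
  s_sens <- sens$table$slope_m_per_year[match(planted, sens$table$probe_id)]
  expect_gte(mean(sign(s_main) == sign(s_sens)), 0.95)
})

test_that("add_covariate extends the design and refits", {
  cfg <- generator_config(n_subjects = 63, n_probes = 300, seed = 23)
  ds <- simulate_dataset(cfg)
  main <- run_ewas(ds)
  sens <- sensitivity_rerun(ds, "add_covariate", main = main,
                            extra = "sperm_quality")
  expect_equal(nrow(sens$table), nrow(main))
  expect_gt(sens$comparison$spearman_rho, 0.9)
})
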