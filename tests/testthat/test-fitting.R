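quick_data <- function(seed = 2) {
  plan <- generate_trial_plan(study_layout("study2"), 1, seed = 7)
  p <- model_params(alpha = 0.5, omega = c(low = 0.2, high = 0.7),
                    beta = 2, pi = 0.2, rho = 0)
  simulate_agent(p, plan, seed = seed, missing_rate = 0.02)
}

test_that("prior densities match their analytic forms", {
  pr <- prior_spec()
  expect_equal(pr$log_density("omega", 0.5), log(1.5)) # Beta(2,2) mode
  expect_equal(pr$log_density("alpha", 0.25),
               stats::dbeta(0.25, 2, 2, log = TRUE))
  expect_equal(pr$log_density("pi", 0.7), dnorm(0.7, 0, 1, log = TRUE))
  expect_equal(pr$log_density("beta", 0.4),
               dgamma(0.4, shape = 3, scale = 0.2, log = TRUE))
  # Gamma(shape 3, scale 0.2) has mode (3 - 1) * 0.2 = 0.4
  grid <- seq(0.05, 2, by = 0.01)
  expect_equal(grid[which.max(pr$log_density("beta", grid))], 0.4)
})

test_that("log posterior is likelihood plus free-parameter priors", {
  b <- quick_data()
  variant <- variant_study2()
  pr <- prior_spec()
  p <- model_params(alpha = 0.4, omega = c(low = 0.3, high = 0.6),
                    beta = 0.5, pi = 0.1, rho = -0.2)
  # independent density-summation oracle
  manual <- log_likelihood(p, b) +
    dbeta(0.4, 2, 2, log = TRUE) +
    dgamma(0.5, shape = 3, scale = 0.2, log = TRUE) +
    dbeta(0.3, 2, 2, log = TRUE) + dbeta(0.6, 2, 2, log = TRUE) +
    dnorm(0.1, log = TRUE) + dnorm(-0.2, log = TRUE)
  expect_equal(log_posterior(p, b, pr, variant), manual, tolerance = 1e-10)
  # flat-choice closed form: a near-zero beta makes choices uninformative,
  # so the likelihood term approaches n_valid * log(0.5)
  p0 <- model_params(alpha = 0.4, omega = c(low = 0.3, high = 0.6),
                     beta = 1e-9, pi = 0, rho = 0)
  n_valid <- sum(b$missing_stage1 == 0L)
  expect_equal(log_likelihood(p0, b), n_valid * log(0.5), tolerance = 1e-6)
  # out-of-support parameters signal and return -Inf
  p_bad <- p
  p_bad$beta <- -1
  p_bad$omega <- c(low = 0.3, high = 0.6)
  expect_warning(lp <- log_posterior(p_bad, b, pr, variant), "support")
  expect_identical(lp, -Inf)
})

test_that("MAP fitting recovers structure and respects the AIC identity", {
  b <- quick_data()
  fit <- fit_map(b, n_starts = 8, seed = 1)
  expect_equal(fit$aic, 2 * fit$n_free_params - 2 * fit$log_likelihood)
  expect_identical(fit$n_free_params, 6L) # alpha, beta, 2 omegas, pi, rho
  # bounded estimates strictly inside their bounds (logit-scale optimizer)
  expect_true(fit$params$alpha > 0 && fit$params$alpha < 1)
  expect_true(all(fit$params$omega > 0 & fit$params$omega < 1))
  expect_gt(fit$params$beta, 0)
  # deterministic given the seed
  fit2 <- fit_map(b, n_starts = 8, seed = 1)
  expect_equal(fit$log_posterior, fit2$log_posterior)
  expect_equal(fit$params$omega, fit2$params$omega)
})

test_that("more restarts never lower the returned log posterior", {
  b <- quick_data()
  lp1 <- fit_map(b, n_starts = 1, seed = 5)$log_posterior
  lp10 <- fit_map(b, n_starts = 10, seed = 5)$log_posterior
  expect_gte(lp10, lp1)
})

test_that("uninformative data shrink omega toward the prior mode", {
  # a beta = 0 generator makes choices carry no information about omega
  plan <- generate_trial_plan(study_layout("study2"), 1, seed = 3)
  p0 <- model_params(alpha = 0.5, omega = c(low = 0.9, high = 0.05),
                     beta = 0, pi = 0, rho = 0)
  b <- simulate_agent(p0, plan, seed = 4)
  fit <- fit_map(b, n_starts = 10, seed = 2)
  expect_lt(fit$params$beta, 0.5)
  expect_true(all(abs(fit$params$omega - 0.5) < 0.2))
})

test_that("AIC model comparison applies the penalty arithmetic", {
  mk <- function(ll, k) {
    structure(list(aic = 2 * k - 2 * ll, log_likelihood = ll,
                   n_free_params = as.integer(k)), class = "fit_result")
  }
  # identical likelihoods: the smaller variant wins by 2 per participant
  small <- lapply(rep(-100, 5), mk, k = 7)
  large <- lapply(rep(-100, 5), mk, k = 8)
  cmp <- compare_models_aic(list(small = small, large = large))
  expect_identical(cmp$selected, "small")
  d <- diff(cmp$table$total_aic)
  expect_equal(abs(d), 2 * 5)
  # single participant, printed AIC values
  cmp2 <- compare_models_aic(list(a = list(mk(-100, 7)),
                                  b = list(mk(-98, 10))))
  expect_equal(cmp2$table$total_aic, c(214, 216))
  expect_identical(cmp2$selected, "a")
  expect_error(compare_models_aic(list(a = small, b = large[1:3])),
               "different participant")
})

test_that("variant selection prefers the generating structure", {
  # sessions generated without eligibility traces (lam = 0): the lam-fixed
  # variant should win the summed AIC in most replicate cohorts
  layout <- study_layout("study2")
  variant_free <- model_variant(layout, free = c("lam", "pi", "rho"),
                                name = "lam+pi+rho")
  variant_fixed <- variant_study2()
  wins <- 0L
  for (rep in 1:3) {
    fits_free <- list()
    fits_fixed <- list()
    for (i in 1:4) {
      plan <- generate_trial_plan(layout, ((i - 1L) %% 2L) + 1L, seed = 7)
      p <- model_params(alpha = 0.5, lam = 0,
                        omega = c(low = 0.3, high = 0.7),
                        beta = 2, pi = 0.1, rho = 0)
      b <- simulate_agent(p, plan, seed = 100 * rep + i)
      fits_free[[i]] <- fit_map(b, variant_free, n_starts = 5,
                                seed = 10 * rep + i)
      fits_fixed[[i]] <- fit_map(b, variant_fixed, n_starts = 5,
                                 seed = 10 * rep + i)
    }
    cmp <- compare_models_aic(list(free = fits_free, fixed = fits_fixed))
    wins <- wins + (cmp$selected == "fixed")
  }
  expect_gte(wins, 2L)
})

test_that("n_starts and empty data are validated", {
  b <- quick_data()
  expect_error(fit_map(b, n_starts = 0), ">= 1")
  expect_error(fit_map(b[0, ]), "empty")
})
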