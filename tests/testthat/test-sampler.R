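test_that("initial state has the documented defaults and jitter behaviour", {
  d <- std_data()
  des <- build_design(d$panel, d$cohort, 5)
  st <- initialize_state(des)
  expect_true(all(st$beta == 0))
  expect_equal(dim(st$gamma), c(5, 5, 2))
  expect_true(all(st$gamma == 0))
  expect_true(all(st$alpha == 0))
  expect_equal(st$Sigma$v, rep(1, 5))
  s1 <- initialize_state(des, seed = 1, jitter = 0.5)
  s2 <- initialize_state(des, seed = 1, jitter = 0.5)
  s3 <- initialize_state(des, seed = 2, jitter = 0.5)
  expect_identical(s1, s2)
  expect_false(identical(s1$beta, s3$beta))
  expect_equal(dim(s1$beta), dim(st$beta))
  # variant 2: no random-effect components
  expect_null(initialize_state(build_design(d$panel, d$cohort, 2))$alpha)
})

test_that("chains are reproducible from the seed", {
  d <- std_data()
  s <- mcmc_settings(n_iter = 400, burn_in = 100, seed = 11)
  f1 <- fit_variant(d$panel, d$cohort, 4, settings = s)
  f2 <- fit_variant(d$panel, d$cohort, 4, settings = s)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$deviance, f2$deviance)
  s2 <- mcmc_settings(n_iter = 400, burn_in = 100, seed = 12)
  f3 <- fit_variant(d$panel, d$cohort, 4, settings = s2)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("retained-draw bookkeeping honours burn-in and thinning", {
  d <- std_data()
  s <- mcmc_settings(n_iter = 500, burn_in = 200, thin = 3, seed = 13)
  f <- fit_variant(d$panel, d$cohort, 2, settings = s)
  expect_equal(nrow(f$draws), (500 - 200) %/% 3)
  expect_equal(ncol(f$dev_wave), 2)       # lag variant: waves 2, 3 only
  expect_equal(f$deviance, rowSums(f$dev_wave))
})

test_that("MCMC matches grid quadrature on the two-parameter toy", {
  qc <- quadrature_check(seed = 21, n_iter = 40000, burn_in = 3000)
  expect_lt(qc$max_abs_diff, 0.05)
})

test_that("acceptance rates after adaptation sit in the working range", {
  f <- std_fit()
  rates <- f$accept[c("beta", "gamma", "alpha")]
  expect_true(all(rates > 0.1 & rates < 0.6),
              info = paste(round(rates, 3), collapse = " "))
})

test_that("with the likelihood disabled the sampler reproduces the priors", {
  coh <- generate_cohort(4, c(1, 1, 1, 1), seed = 31)
  pan <- simulate_panel(coh, truth_record(3, Sigma = 1), seed = 32)
  f <- fit_variant(pan, coh, 3,
                   settings = mcmc_settings(n_iter = 21000, burn_in = 1000,
                                            thin = 20, seed = 33,
                                            likelihood_weight = 0))
  b <- f$draws[, "beta.weight_kg.Sed4"]
  expect_lt(abs(mean(b)), 3 * sqrt(1000 / length(b)))
  expect_gt(stats::ks.test(b, "pnorm", 0, sqrt(1000))$p.value, 0.001)
  s <- f$draws[, "Sigma.Sed3"]
  expect_true(all(s > 0 & s < 100))
  expect_gt(stats::ks.test(s, "punif", 0, 100)$p.value, 0.001)
})

test_that("paired covariance mode keeps the off-diagonal inside its bounds", {
  d <- std_data()
  pr <- prior_spec(sigma_mode = "paired", pair = c(5, 6))
  f <- fit_variant(d$panel, d$cohort, 3, priors = pr,
                   settings = mcmc_settings(n_iter = 600, burn_in = 200,
                                            seed = 41))
  cv <- f$draws[, "Sigma.cov.Sed5.Sed6"]
  v5 <- f$draws[, "Sigma.Sed5"]; v6 <- f$draws[, "Sigma.Sed6"]
  expect_true(all(abs(cv) <= sqrt(v5 * v6)))
  expect_true(all(v5 > 0 & v5 < 100))
})

test_that("per-contrast fits run on the observation subset", {
  d <- std_data()
  f <- fit_variant(d$panel, d$cohort, 3, contrast = 6,
                   settings = mcmc_settings(n_iter = 400, burn_in = 100,
                                            seed = 51))
  expect_true(all(grepl("Sed6$", colnames(f$draws))))
  expect_equal(f$design$L, 2L)
})

test_that("a free per-level intercept opens the saturated high-variance regime", {
  # motivates the no-intercept default: same truth, same data scale, but the
  # design with a free intercept lets the random-effect variances inflate
  p <- length(design_colnames(TRUE))
  beta <- matrix(rep_len(c(0.6, -0.4, 0, 0.8, -0.7, 0.3), p * 5), p, 5)
  gamma <- matrix(0, 5, 5); diag(gamma) <- 1.2
  truth <- truth_record(3, beta = beta, gamma = gamma, Sigma = 0.5,
                        include_intercept = TRUE, standardize = TRUE)
  coh <- generate_cohort(150, c(37, 37, 38, 38), seed = 55)
  pan <- simulate_panel(coh, truth, seed = 56)
  fit <- fit_variant(pan, coh, 3,
                     settings = mcmc_settings(n_iter = 2500, burn_in = 500,
                                              seed = 57),
                     include_intercept = TRUE, standardize = TRUE)
  sig <- colMeans(fit$draws[, paste0("Sigma.Sed", 2:6)])
  expect_gt(stats::median(sig), 10)   # far above the true value 0.5
})
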