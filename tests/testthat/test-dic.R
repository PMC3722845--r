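test_that("DIC identities hold exactly", {
  f <- std_fit()
  for (w in c("all", "23")) for (fc in c("patient", "marginal")) {
    d <- compute_dic(f, w, focus = fc, max_draws = 50)
    expect_lt(abs(d$DIC - (d$Dbar + d$pD)), 1e-9)
    expect_lt(abs(d$DIC - (2 * d$Dbar - d$Dhat)), 1e-9)
    expect_lt(abs(d$pD - (d$Dbar - d$Dhat)), 1e-9)
    expect_true(is.finite(d$DIC))
  }
})

test_that("a point-mass chain has zero effective parameters", {
  d <- dic_from_deviances(rep(123.4, 500), 123.4)
  expect_identical(d$pD, 0)
  expect_identical(d$DIC, d$Dhat)
})

test_that("the quadratic-deviance toy has one effective parameter", {
  # y ~ N(theta, 1), flat prior: posterior N(ybar, 1/n); deviance quadratic
  # in theta, so pD equals n * Var(theta | y) = 1
  set.seed(71)
  n <- 30
  y <- rnorm(n, 2, 1)
  theta <- rnorm(10000, mean(y), sqrt(1 / n))
  dev <- vapply(theta, function(t) sum((y - t)^2), numeric(1))
  d <- dic_from_deviances(dev, sum((y - mean(theta))^2))
  expect_lt(abs(d$pD - 1), 0.1)
})

test_that("DIC is stable under thinning within Monte-Carlo error", {
  f <- std_fit()
  devs <- f$deviance
  full <- dic_from_deviances(devs, 0)
  thinned <- dic_from_deviances(devs[seq(1, length(devs), by = 5)], 0)
  se <- stats::sd(devs) / sqrt(length(devs) / 20)  # generous autocorrelation
  expect_lt(abs(full$Dbar - thinned$Dbar), 3 * se)
})

test_that("variant 1 has more deviance over all waves than over waves 2,3", {
  d <- std_data()
  f1 <- fit_variant(d$panel, d$cohort, 1,
                    settings = mcmc_settings(n_iter = 800, burn_in = 300,
                                             seed = 72))
  dall <- compute_dic(f1, "all")
  d23 <- compute_dic(f1, "23")
  expect_gt(dall$Dbar, d23$Dbar)
  expect_gt(dall$DIC, d23$DIC)
  expect_null(dall$note)
  # lag variants: DIC* note that supports equal likelihoods
  f2 <- fit_variant(d$panel, d$cohort, 2,
                    settings = mcmc_settings(n_iter = 500, burn_in = 200,
                                             seed = 73))
  expect_match(compute_dic(f2, "23")$note, "already restricted")
})

test_that("comparison table covers all variants and enforces shared data", {
  d <- std_data()
  fits <- lapply(1:5, function(v)
    fit_variant(d$panel, d$cohort, v,
                settings = mcmc_settings(n_iter = 500, burn_in = 200,
                                         seed = 80 + v)))
  expect_warning(tab <- compare_variants(fits), "DIC_star")
  expect_equal(nrow(tab), 5)
  expect_setequal(tab$variant, 1:5)
  expect_true(!is.unsorted(tab$DIC_star))
  # a fit on different data is rejected
  pan2 <- simulate_panel(d$cohort, d$truth, seed = 999)
  f_other <- fit_variant(pan2, d$cohort, 2,
                         settings = mcmc_settings(n_iter = 300, burn_in = 100,
                                                  seed = 86))
  expect_error(suppressWarnings(compare_variants(c(fits[1:2], list(f_other)))),
               "same data")
})
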