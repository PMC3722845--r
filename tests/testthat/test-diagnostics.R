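fake_fit <- function(draws, chain) {
  structure(list(draws = draws, chain = chain), class = "sed_fit")
}

test_that("iid chains pass split-Rhat and recover their sample size", {
  set.seed(61)
  n <- 2000; ch <- 4
  draws <- cbind(theta = rnorm(n * ch))
  f <- fake_fit(draws, rep(1:ch, each = n))
  dg <- convergence_diagnostics(f)
  expect_gt(dg$rhat, 0.99)
  expect_lt(dg$rhat, 1.02)
  expect_gt(dg$ess, 0.5 * n * ch)
  expect_false(dg$flagged)
})

test_that("a trending chain is flagged", {
  set.seed(62)
  n <- 1000
  drift <- cbind(theta = c(rnorm(n), rnorm(n) + seq(0, 3, length.out = n)))
  f <- fake_fit(drift, rep(1:2, each = n))
  dg <- convergence_diagnostics(f)
  expect_gt(dg$rhat, 1.05)
  expect_true(dg$flagged)
})

test_that("degenerate constant chains are flagged without crashing", {
  f <- fake_fit(cbind(theta = rep(1, 400)), rep(1:2, each = 200))
  dg <- convergence_diagnostics(f)
  expect_true(is.na(dg$rhat))
  expect_true(dg$flagged)
})

test_that("diagnostics preconditions are enforced", {
  f1 <- fake_fit(cbind(theta = rnorm(400)), rep(1L, 400))
  expect_error(convergence_diagnostics(f1), "2 chains")
  f2 <- fake_fit(cbind(theta = rnorm(40)), rep(1:2, each = 20))
  expect_error(convergence_diagnostics(f2), "few")
})

test_that("multi-chain fits with jittered starts feed the diagnostics", {
  d <- std_data()
  f <- fit_variant(d$panel, d$cohort, 2,
                   settings = mcmc_settings(n_iter = 700, burn_in = 300,
                                            chains = 2, jitter = 0.2,
                                            seed = 63))
  expect_equal(sort(unique(f$chain)), 1:2)
  dg <- convergence_diagnostics(f)
  expect_equal(nrow(dg), ncol(f$draws))
  expect_true(all(is.finite(dg$rhat) | dg$flagged))
})
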