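# Shared small fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

# Study-scale cohort (127 children) + a variant-3 panel with known truth.
std_data <- function() {
  if (is.null(fixture_env$dat)) {
    coh <- generate_cohort(127, c(30, 31, 32, 34), seed = 101)
    gamma <- matrix(0, 5, 5); diag(gamma) <- 1.2
    truth <- truth_record(3, beta = 0.2, gamma = gamma, Sigma = 0.5,
                          standardize = TRUE)
    pan <- simulate_panel(coh, truth, seed = 102)
    fixture_env$dat <- list(cohort = coh, panel = pan, truth = truth)
  }
  fixture_env$dat
}

# A short but adapted variant-3 fit on the standard data, reused across
# sampler / DIC / reporting tests.
std_fit <- function() {
  if (is.null(fixture_env$fit)) {
    d <- std_data()
    fixture_env$fit <- fit_variant(
      d$panel, d$cohort, 3L,
      settings = mcmc_settings(n_iter = 2000, burn_in = 600, seed = 103),
      standardize = TRUE)
  }
  fixture_env$fit
}

# Random (finite) linear-predictor matrices for property tests.
random_eta <- function(n, L = 6L, scale = 3) {
  matrix(stats::rnorm(n * L, 0, scale), n, L) * cbind(0, matrix(1, n, L - 1))
}
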