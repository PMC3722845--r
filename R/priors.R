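#' Prior specification
#'
#' Noninformative priors matching the study protocol: independent
#' Normal(0, 10^3) priors on every regression (`beta`) and lag (`gamma`)
#' coefficient, and Uniform(0, 100) priors on the random-effect variances.
#' Two readings of the random-effect covariance are supported:
#'
#' * `"diagonal"` (default): independent patient intercepts per non-reference
#'   level, each variance Uniform(0, `sigma_max`).
#' * `"paired"`: a user-chosen pair of levels gets a full 2x2 covariance with
#'   Uniform(0, `sigma_max`) diagonals and a conditionally uniform
#'   off-diagonal on `(-sqrt(S_kk S_ll), +sqrt(S_kk S_ll))`; remaining levels
#'   stay independent diagonal.
#'
#' @param beta_var,gamma_var prior variances of the coefficients.
#' @param sigma_max upper bound of the uniform prior on the random-effect
#'   variance (or standard deviation if `sigma_scale = "sd"`).
#' @param sigma_scale whether the Uniform(0, `sigma_max`) prior sits on the
#'   variance (default, literal reading of a variance-covariance matrix) or
#'   on the standard deviation.
#' @param sigma_mode `"diagonal"` or `"paired"`.
#' @param pair the two response levels (in 2..6) sharing the 2x2 block when
#'   `sigma_mode = "paired"`.
#' @return list of class `prior_spec`.
#' @export
prior_spec <- function(beta_var = 1000, gamma_var = 1000,
                       sigma_max = 100,
                       sigma_scale = c("variance", "sd"),
                       sigma_mode = c("diagonal", "paired"),
                       pair = c(5L, 6L)) {
  sigma_scale <- match.arg(sigma_scale)
  sigma_mode <- match.arg(sigma_mode)
  stopifnot(beta_var > 0, gamma_var > 0, sigma_max > 0)
  if (sigma_mode == "paired") {
    pair <- sort(as.integer(pair))
    if (length(pair) != 2L || any(pair < 2L) || any(pair > 6L) ||
        pair[1] == pair[2])
      stop("pair must be two distinct levels in 2..6")
  }
  out <- list(beta_var = beta_var, gamma_var = gamma_var,
              sigma_max = sigma_max, sigma_scale = sigma_scale,
              sigma_mode = sigma_mode, pair = pair)
  class(out) <- "prior_spec"
  out
}

#' MCMC settings
#'
#' Defaults follow the study protocol: 10,000 iterations with the first
#' 1,000 discarded as burn-in. Proposal scales adapt (Robbins-Monro toward a
#' target acceptance rate) during burn-in only, so the retained chain is a
#' valid fixed-kernel Markov chain.
#'
#' @param n_iter total iterations per chain.
#' @param burn_in iterations discarded from the front of each chain.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param chains number of independent chains.
#' @param seed integer seed; chain `c` uses `seed + 1000 * (c - 1)`.
#' @param adapt adapt proposal scales during burn-in.
#' @param target_accept Robbins-Monro target acceptance rate for the
#'   element-wise random-walk proposals.
#' @param jitter sd of the random offset applied to each chain's starting
#'   coefficients (0 = identical deterministic starts).
#' @param store_alpha keep per-draw random intercepts (memory-heavy for
#'   large cohorts; their running posterior mean is always kept).
#' @param likelihood_weight internal test hook: 0 switches the likelihood
#'   off so the sampler targets the prior; leave at 1 for inference.
#' @param init optional warm-start state (a list shaped like
#'   [initialize_state()] output); unspecified components keep their
#'   defaults.
#' @return list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 10000L, burn_in = 1000L, thin = 1L,
                          chains = 1L, seed = 1L, adapt = TRUE,
                          target_accept = 0.44, jitter = 0,
                          store_alpha = FALSE, likelihood_weight = 1,
                          init = NULL) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  stopifnot(thin >= 1L, chains >= 1L, target_accept > 0, target_accept < 1,
            jitter >= 0, likelihood_weight >= 0)
  out <- list(n_iter = n_iter, burn_in = burn_in, thin = as.integer(thin),
              chains = as.integer(chains), seed = as.integer(seed),
              adapt = isTRUE(adapt), target_accept = target_accept,
              jitter = jitter, store_alpha = isTRUE(store_alpha),
              likelihood_weight = likelihood_weight, init = init)
  class(out) <- "mcmc_settings"
  out
}
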