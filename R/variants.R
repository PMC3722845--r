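#' Model variant specification
#'
#' The five linear-predictor variants for the sedation-level model. Writing
#' `eta_itj = log(mu_itj)` for patient `i`, wave `t` and level `j` (level 1 is
#' the reference with `eta_it1 = 0`):
#'
#' * variant 1: `X'beta_j + alpha_ij` (random intercepts, no lag)
#' * variant 2: `X'beta_j + Z'gamma_j` (constant lag effects)
#' * variant 3: `X'beta_j + Z'gamma_j + alpha_ij`
#' * variant 4: `X'beta_j + Z'gamma_jt` (wave-varying lag effects)
#' * variant 5: `X'beta_j + Z'gamma_jt + alpha_ij`
#'
#' `Z` holds indicators of the previous wave's level (levels 2..6; previous
#' level 1 is the reference and codes as all-zero). Lag variants condition on
#' wave 1, so their likelihood runs over waves 2 and 3 only; variant 1 covers
#' all three waves.
#'
#' @param id integer in 1..5.
#' @return an object of class `variant_spec`: a list with elements `id`,
#'   `has_lag`, `lag_time_varying`, `has_random_effect`.
#' @export
#' @examples
#' variant_spec(3)
variant_spec <- function(id) {
  id <- as.integer(id)
  if (length(id) != 1L || is.na(id) || id < 1L || id > 5L)
    stop("variant id must be a single integer in 1..5")
  spec <- switch(id,
    list(has_lag = FALSE, lag_time_varying = FALSE, has_random_effect = TRUE),
    list(has_lag = TRUE,  lag_time_varying = FALSE, has_random_effect = FALSE),
    list(has_lag = TRUE,  lag_time_varying = FALSE, has_random_effect = TRUE),
    list(has_lag = TRUE,  lag_time_varying = TRUE,  has_random_effect = FALSE),
    list(has_lag = TRUE,  lag_time_varying = TRUE,  has_random_effect = TRUE))
  spec <- c(list(id = id), spec)
  class(spec) <- "variant_spec"
  spec
}

as_variant <- function(variant) {
  if (inherits(variant, "variant_spec")) variant else variant_spec(variant)
}

#' @export
print.variant_spec <- function(x, ...) {
  lag <- if (!x$has_lag) "none" else if (x$lag_time_varying) "wave-varying" else "constant"
  cat(sprintf("Model variant %d: lag = %s, random effects = %s\n",
              x$id, lag, if (x$has_random_effect) "yes" else "no"))
  invisible(x)
}

# Waves whose observations enter the variant's likelihood.
likelihood_waves <- function(variant, n_waves = 3L) {
  variant <- as_variant(variant)
  if (variant$has_lag) 2:n_waves else 1:n_waves
}
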