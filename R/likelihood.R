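#' Reference-category softmax
#'
#' Maps a matrix of log-scale cell means `log(mu_itj)` (column 1 the
#' reference, identically 0) to level probabilities
#' `P_itj = mu_itj / sum_j mu_itj`. Computed with row-max subtraction so
#' large linear predictors do not overflow; by construction
#' `log(P_itj / P_it1) = log(mu_itj)` exactly.
#'
#' @param logmu numeric matrix (rows = observations, columns = levels) or a
#'   single vector of log means.
#' @return matrix (or vector) of probabilities, rows summing to 1.
#' @export
#' @examples
#' category_probs(c(0, log(2), 0, 0, 0, 0))  # (1/7, 2/7, 1/7, ...)
category_probs <- function(logmu) {
  vec <- is.null(dim(logmu))
  if (vec) logmu <- matrix(logmu, nrow = 1L)
  if (!all(is.finite(logmu))) stop("non-finite linear predictor")
  m <- logmu[, 1L]
  for (k in seq_len(ncol(logmu))[-1L]) m <- pmax(m, logmu[, k])
  e <- exp(logmu - m)
  P <- e / rowSums(e)
  if (vec) drop(P) else P
}

# Linear predictor matrix eta (n x L, column 1 zero) for a design and a
# parameter state. state: list(beta p x K, gamma (5 x K | 5 x K x 2 | NULL),
# alpha (N x K | NULL)).
compute_eta <- function(design, state) {
  n <- length(design$y)
  eta <- matrix(0, n, design$L)
  eta[, -1L] <- design$X %*% state$beta
  if (design$variant$has_lag && !is.null(state$gamma)) {
    if (design$variant$lag_time_varying) {
      for (w in 2:design$n_waves) {
        rows <- design$wave == w
        eta[rows, -1L] <- eta[rows, -1L] +
          design$Z[rows, , drop = FALSE] %*% state$gamma[, , w - 1L]
      }
    } else {
      eta[, -1L] <- eta[, -1L] + design$Z %*% state$gamma
    }
  }
  if (design$variant$has_random_effect && !is.null(state$alpha))
    eta[, -1L] <- eta[, -1L] + state$alpha[design$patient, , drop = FALSE]
  eta
}

#' Multinomial log-likelihood of a parameter state
#'
#' Sum over observations of `log P_it,level`, each observation a single
#' categorical draw (`n_it = 1`). Optionally restricted to a subset of
#' waves, which is how the wave-restricted deviance behind DIC* is obtained.
#'
#' @param design a [build_design()] result.
#' @param state parameter state (`beta`, `gamma`, `alpha` as documented in
#'   [initialize_state()]).
#' @param waves `NULL` for all rows in the design, or an integer subset of
#'   waves.
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(design, state, waves = NULL) {
  eta <- compute_eta(design, state)
  if (is.null(waves)) {
    cpp_loglik(eta, design$y)
  } else {
    keep <- design$wave %in% waves
    cpp_loglik(eta[keep, , drop = FALSE], design$y[keep])
  }
}

#' Deviance of a parameter state
#'
#' `-2` times [log_likelihood()].
#' @inheritParams log_likelihood
#' @return scalar deviance (nonnegative, since each `log P <= 0`).
#' @export
deviance_state <- function(design, state, waves = NULL) {
  -2 * log_likelihood(design, state, waves)
}

# Per-wave deviance contributions (named by wave), used to track full and
# wave-{2,3}-restricted deviances from a single eta evaluation.
deviance_by_wave <- function(design, eta) {
  waves <- sort(unique(design$wave))
  ll <- cpp_loglik_group(eta, design$y, match(design$wave, waves),
                         length(waves))
  stats::setNames(-2 * ll, waves)
}
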