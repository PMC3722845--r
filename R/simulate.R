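# Draw one categorical outcome per row of a probability matrix (rows sum to 1).
sample_categorical <- function(P) {
  u <- stats::runif(nrow(P))
  cum <- t(apply(P, 1, cumsum))
  1L + rowSums(u > cum + 1e-15)
}

# Matrix square root for a PSD covariance (handles zero / rank-deficient Sigma).
psd_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Simulate a sedation panel from known ground truth
#'
#' Generates one Ramsay level per patient per wave. Wave 1 is drawn from the
#' truth's baseline multinomial (or from the covariate model, see
#' [truth_record()]); later waves are drawn from the variant's linear
#' predictor, including lag terms computed from the previously simulated
#' level and patient random intercepts drawn once and reused across waves.
#'
#' @param cohort cohort table from [generate_cohort()].
#' @param truth a [truth_record()].
#' @param seed RNG seed.
#' @return `data.frame` of class `sed_panel` with columns `patient_id`,
#'   `wave`, `level`.
#' @export
#' @examples
#' coh <- generate_cohort(20, c(5, 5, 5, 5), seed = 1)
#' tr <- truth_record(3, beta = 0, gamma = 0, Sigma = 1)
#' pan <- simulate_panel(coh, tr, seed = 2)
simulate_panel <- function(cohort, truth, seed = 1L) {
  stopifnot(inherits(truth, "sed_truth"))
  validate_cohort(cohort)
  set.seed(as.integer(seed))

  variant <- truth$variant
  if (variant$has_lag && is.null(truth$baseline) && truth$wave1 == "baseline")
    stop("lag variant needs wave-1 baseline probabilities")

  ord <- order(cohort$patient_id, cohort$wave)
  cohort <- cohort[ord, , drop = FALSE]
  Xall <- covariate_matrix(cohort, truth$include_intercept, truth$standardize)
  upid <- unique(cohort$patient_id)
  N <- length(upid)
  pidx <- match(cohort$patient_id, upid)
  n_waves <- max(cohort$wave)
  K <- 5L

  alpha <- matrix(0, N, K)
  if (variant$has_random_effect && any(truth$Sigma != 0))
    alpha <- matrix(stats::rnorm(N * K), N, K) %*% psd_sqrt(truth$Sigma)

  level <- matrix(0L, N, n_waves)
  for (w in seq_len(n_waves)) {
    rows <- which(cohort$wave == w)
    rows <- rows[order(pidx[rows])]          # align to patient order 1..N
    if (w == 1L && truth$wave1 == "baseline") {
      P <- matrix(truth$baseline, N, 6L, byrow = TRUE)
    } else {
      eta <- cbind(0, Xall[rows, , drop = FALSE] %*% truth$beta)
      if (variant$has_lag && w >= 2L) {
        prev <- level[, w - 1L]
        Zw <- matrix(0, N, K)
        hot <- prev >= 2L
        Zw[cbind(which(hot), prev[hot] - 1L)] <- 1
        g <- if (variant$lag_time_varying) truth$gamma[, , w - 1L] else truth$gamma
        eta[, 2:6] <- eta[, 2:6] + Zw %*% g
      }
      if (variant$has_random_effect) eta[, 2:6] <- eta[, 2:6] + alpha
      P <- category_probs(eta)
    }
    level[, w] <- sample_categorical(P)
  }

  out <- data.frame(
    patient_id = rep(upid, each = n_waves),
    wave = rep(seq_len(n_waves), times = N),
    level = as.integer(t(level)))
  class(out) <- c("sed_panel", "data.frame")
  attr(out, "alpha") <- alpha
  out
}
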