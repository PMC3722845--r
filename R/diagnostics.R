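# Split-Rhat for one parameter: chains are split in half and the classic
# potential-scale-reduction factor is computed over the resulting half-chains.
split_rhat <- function(x, chain) {
  halves <- list()
  for (ch in unique(chain)) {
    v <- x[chain == ch]
    m <- length(v) %/% 2L
    if (m < 2L) return(NA_real_)
    halves <- c(halves, list(v[seq_len(m)], v[m + seq_len(m)]))
  }
  m <- length(halves); n <- length(halves[[1]])
  mu <- vapply(halves, mean, numeric(1))
  s2 <- vapply(halves, stats::var, numeric(1))
  W <- mean(s2)
  B <- n * stats::var(mu)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Effective sample size via autocovariances with Geyer's initial-monotone
# truncation, summed over chains.
ess_one <- function(x) {
  n <- length(x)
  if (n < 4L || stats::var(x) == 0) return(NA_real_)
  ac <- stats::acf(x, lag.max = min(n - 2L, 500L), plot = FALSE)$acf[, 1, 1]
  # Geyer pair sums rho_{2k} + rho_{2k+1} (ac[1] is lag 0): stop at the
  # first nonpositive pair, enforce monotone decrease
  P <- c()
  k <- 1L
  while (k + 1L <= length(ac)) {
    s <- ac[k] + ac[k + 1L]
    if (s <= 0) break
    P <- c(P, s)
    k <- k + 2L
  }
  if (!length(P)) return(n)
  P <- cummin(P)
  n / max(2 * sum(P) - 1, 1e-12)
}

ess <- function(x, chain) {
  vals <- vapply(unique(chain), function(ch) ess_one(x[chain == ch]), numeric(1))
  if (all(is.na(vals))) NA_real_ else sum(vals, na.rm = TRUE)
}

#' Convergence diagnostics for a fit
#'
#' Split-Rhat and effective sample size per monitored parameter. Requires at
#' least two chains (for a meaningful Rhat) and at least 100 retained draws.
#' Parameters with Rhat above the threshold, or with an undefined Rhat
#' (e.g. constant chains), are flagged.
#'
#' @param fit a `sed_fit` run with `chains >= 2`.
#' @param rhat_threshold flagging threshold (default 1.05).
#' @return `data.frame` with columns `parameter`, `rhat`, `ess`, `flagged`.
#' @export
convergence_diagnostics <- function(fit, rhat_threshold = 1.05) {
  stopifnot(inherits(fit, "sed_fit"))
  if (length(unique(fit$chain)) < 2L)
    stop("split-Rhat needs at least 2 chains")
  if (nrow(fit$draws) < 100L)
    stop("too few retained draws for diagnostics (need >= 100)")
  rh <- apply(fit$draws, 2, split_rhat, chain = fit$chain)
  es <- apply(fit$draws, 2, ess, chain = fit$chain)
  data.frame(parameter = colnames(fit$draws),
             rhat = unname(rh), ess = unname(es),
             flagged = is.na(rh) | rh > rhat_threshold,
             row.names = NULL)
}
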