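design_level_labels <- function(design) {
  if (is.null(design$contrast)) free_level_names() else paste0("Sed", design$contrast)
}

#' Initial parameter state
#'
#' Deterministic default start: all coefficients and random intercepts at
#' zero, random-effect variances at 1. A positive `jitter` adds a normal
#' offset to every coefficient, giving overdispersed starts for multi-chain
#' diagnostics.
#'
#' @param design a [build_design()] result.
#' @param priors a [prior_spec()].
#' @param seed optional seed for the jitter.
#' @param jitter sd of the start offset (0 = deterministic).
#' @return list with elements `beta`, `gamma`, `alpha`, `Sigma` (the latter
#'   two `NULL` for variants without random effects). `Sigma` is a list with
#'   variances `v` (per non-reference level) and, in paired mode, the
#'   off-diagonal covariance `c`.
#' @export
initialize_state <- function(design, priors = prior_spec(), seed = NULL,
                             jitter = 0) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  v <- design$variant
  K <- design$K
  p <- ncol(design$X)
  lvl <- design_level_labels(design)
  beta <- matrix(0, p, K, dimnames = list(colnames(design$X), lvl))
  gamma <- NULL
  if (v$has_lag) {
    nl <- ncol(design$Z)
    if (v$lag_time_varying) {
      gamma <- array(0, c(nl, K, design$n_waves - 1L),
                     dimnames = list(colnames(design$Z), lvl,
                                     paste0("wave", 2:design$n_waves)))
    } else {
      gamma <- matrix(0, nl, K,
                      dimnames = list(colnames(design$Z), lvl))
    }
  }
  alpha <- NULL; Sigma <- NULL
  if (v$has_random_effect) {
    alpha <- matrix(0, design$n_patients, K)
    Sigma <- list(v = rep(1, K), c = 0)
  }
  if (jitter > 0) {
    beta <- beta + stats::rnorm(length(beta), 0, jitter)
    if (!is.null(gamma)) gamma <- gamma + stats::rnorm(length(gamma), 0, jitter)
  }
  list(beta = beta, gamma = gamma, alpha = alpha, Sigma = Sigma)
}

# Gibbs draw of a random-effect variance from its truncated inverse-gamma
# full conditional under a Uniform(0, bound) prior (on the variance or the
# sd scale). Returns NA when the conditional shape is nonpositive (N <= 2
# on the variance scale), in which case the caller falls back to Metropolis.
draw_sigma_gibbs <- function(S, N, sigma_max, sigma_scale) {
  if (sigma_scale == "variance") {
    a <- N / 2 - 1; vmax <- sigma_max
  } else {
    a <- (N - 1) / 2; vmax <- sigma_max^2
  }
  b <- S / 2
  if (a <= 0 || b <= 0) return(NA_real_)
  # precision 1/v ~ Gamma(a, rate = b) truncated to (1/vmax, Inf)
  pu <- stats::pgamma(1 / vmax, a, rate = b, lower.tail = FALSE)
  if (pu <= 0) return(vmax * (1 - 1e-10))
  q <- stats::runif(1, 0, pu)
  1 / stats::qgamma(q, a, rate = b, lower.tail = FALSE)
}

# log target of a variance v under Uniform(0, bound) prior given sum of
# squares S over N effects (used by the Metropolis fallback).
sigma_logpost <- function(v, S, N, sigma_max, sigma_scale) {
  if (sigma_scale == "variance") {
    if (v <= 0 || v >= sigma_max) return(-Inf)
    -N / 2 * log(v) - S / (2 * v)
  } else {
    if (v <= 0 || v >= sigma_max^2) return(-Inf)
    -(N + 1) / 2 * log(v) - S / (2 * v)
  }
}

run_chain <- function(design, priors, settings, chain_id = 1L) {
  set.seed(settings$seed + 1000L * (chain_id - 1L))
  vr <- design$variant
  K <- design$K; p <- ncol(design$X); n <- length(design$y)
  N <- design$n_patients
  X <- design$X; Z <- design$Z; y <- design$y; pat <- design$patient
  lw <- settings$likelihood_weight
  has_ll <- lw > 0
  re <- vr$has_random_effect
  tv <- vr$lag_time_varying
  n_lag <- if (vr$has_lag) ncol(Z) else 0L
  paired <- re && priors$sigma_mode == "paired" && K >= 2L
  pair_idx <- if (paired) priors$pair - 1L else integer(0)  # K-indexing (level j -> j-1)

  waves_present <- sort(unique(design$wave))
  wave_idx <- match(design$wave, waves_present)
  nwp <- length(waves_present)
  rows_w <- lapply(waves_present, function(w) which(design$wave == w))
  names(rows_w) <- waves_present

  st <- initialize_state(design, priors, jitter = settings$jitter)
  if (!is.null(settings$init))
    for (nm in intersect(names(settings$init), names(st)))
      st[[nm]] <- settings$init[[nm]]
  beta <- st$beta + 0                       # force unique copies: the C++
  alpha <- st$alpha                         # sweep updates them in place
  sig_v <- if (re) st$Sigma$v else NULL
  sig_c <- if (re) st$Sigma$c else NULL
  # gamma kept as a list of slice matrices (one per wave for time-varying
  # variants) so each slice can be handed to the in-place C++ sweep
  if (vr$has_lag) {
    if (tv) {
      n_slice <- design$n_waves - 1L
      g_slices <- lapply(seq_len(n_slice), function(s) st$gamma[, , s] + 0)
      g_rows <- lapply(seq_len(n_slice), function(s)
        rows_w[[as.character(s + 1L)]] - 1L)   # 0-based for C++
    } else {
      g_slices <- list(st$gamma + 0)
      g_rows <- list(integer(0))
    }
  } else { g_slices <- NULL; g_rows <- NULL }
  gamma_now <- function() {
    if (!vr$has_lag) return(NULL)
    if (tv) array(unlist(g_slices), c(n_lag, K, length(g_slices)))
    else g_slices[[1]]
  }

  eta <- compute_eta(design, list(beta = beta, gamma = gamma_now(),
                                  alpha = alpha))
  if (has_ll && !is.finite(cpp_loglik(eta, y)))
    stop("non-finite log-likelihood at initialization")

  ls_beta <- matrix(log(0.2), p, K)
  ls_gamma <- if (vr$has_lag)
    lapply(g_slices, function(g) matrix(log(0.2), nrow(g), ncol(g))) else NULL
  ls_alpha <- if (re) matrix(log(0.5), N, K) else NULL
  ls_pair <- c(log(0.5), log(0.5), log(0.3))  # v1, v2, c proposals (paired mode)

  lvl <- design_level_labels(design)
  nm_beta <- as.vector(outer(rownames(beta), lvl,
                             function(a, b) paste("beta", a, b, sep = ".")))
  nm_gamma <- character(0)
  if (vr$has_lag) {
    znm <- colnames(Z)
    if (tv) {
      nm_gamma <- as.vector(vapply(paste0("wave", 2:design$n_waves), function(w)
        as.vector(outer(znm, lvl,
                        function(a, b) paste("gamma", w, a, b, sep = "."))),
        character(n_lag * K)))
    } else {
      nm_gamma <- as.vector(outer(znm, lvl,
                                  function(a, b) paste("gamma", a, b, sep = ".")))
    }
  }
  nm_sig <- character(0)
  if (re) {
    nm_sig <- paste0("Sigma.", lvl)
    if (paired) nm_sig <- c(nm_sig,
                            paste0("Sigma.cov.", lvl[pair_idx[1]], ".", lvl[pair_idx[2]]))
  }
  par_names <- c(nm_beta, nm_gamma, nm_sig)

  n_keep <- (settings$n_iter - settings$burn_in) %/% settings$thin
  draws <- matrix(NA_real_, n_keep, length(par_names),
                  dimnames = list(NULL, par_names))
  dev_wave <- matrix(NA_real_, n_keep, nwp,
                     dimnames = list(NULL, paste0("wave", waves_present)))
  alpha_sum <- if (re) matrix(0, N, K) else NULL
  alpha_draws <- if (re && settings$store_alpha)
    matrix(NA_real_, n_keep, N * K) else NULL

  acc <- c(beta = 0, gamma = 0, alpha = 0, Sigma = 0)
  try_n <- c(beta = 0, gamma = 0, alpha = 0, Sigma = 0)
  tgt <- settings$target_accept
  burn <- settings$burn_in
  kept <- 0L

  # alpha log prior density difference for column j (vectorised over patients)
  alpha_dlp <- function(j, a_new, a_old) {
    if (paired && j %in% pair_idx) {
      o <- if (j == pair_idx[1]) pair_idx[2] else pair_idx[1]
      vo <- sig_v[o]; vj <- sig_v[j]
      m <- (sig_c / vo) * alpha[, o]
      vc <- max(vj - sig_c^2 / vo, 1e-12)
      ((a_old - m)^2 - (a_new - m)^2) / (2 * vc)
    } else {
      (a_old^2 - a_new^2) / (2 * sig_v[j])
    }
  }

  pair_logpost <- function(v1, v2, cc, S11, S22, S12) {
    det <- v1 * v2 - cc^2
    if (v1 <= 0 || v2 <= 0 || det <= 0) return(-Inf)
    if (priors$sigma_scale == "variance") {
      if (v1 >= priors$sigma_max || v2 >= priors$sigma_max) return(-Inf)
      pr <- -0.5 * (log(v1) + log(v2))        # conditional-uniform off-diagonal
    } else {
      if (v1 >= priors$sigma_max^2 || v2 >= priors$sigma_max^2) return(-Inf)
      pr <- -(log(v1) + log(v2))              # plus uniform-sd Jacobian
    }
    quad <- (v2 * S11 - 2 * cc * S12 + v1 * S22) / det
    -N / 2 * log(det) - 0.5 * quad + pr
  }

  for (it in seq_len(settings$n_iter)) {
    adapting <- settings$adapt && it <= burn
    gain <- if (adapting) min(0.5, 3 * it^(-0.6)) else 0
    post <- it > burn

    ## beta: element-wise random walk (C++ sweep, eta updated in place)
    nacc <- cpp_sweep_block(eta, y, X, beta, ls_beta, integer(0),
                            lw, priors$beta_var, gain, tgt)
    if (post) { acc["beta"] <- acc["beta"] + nacc; try_n["beta"] <- try_n["beta"] + p * K }

    ## gamma: element-wise random walk (per wave slice when time-varying)
    if (vr$has_lag) {
      for (s in seq_along(g_slices)) {
        nacc <- cpp_sweep_block(eta, y, Z, g_slices[[s]], ls_gamma[[s]],
                                g_rows[[s]], lw, priors$gamma_var, gain, tgt)
        if (post) { acc["gamma"] <- acc["gamma"] + nacc; try_n["gamma"] <- try_n["gamma"] + n_lag * K }
      }
    }

    ## alpha: per-patient vectorised random walk, one level column at a time
    if (re) {
      pll <- if (has_ll) cpp_loglik_group(eta, y, pat, N) else numeric(N)
      for (j in seq_len(K)) {
        ej <- j + 1L
        eps <- exp(ls_alpha[, j]) * stats::rnorm(N)
        a_new <- alpha[, j] + eps
        newcol <- eta[, ej] + eps[pat]
        pll_new <- if (has_ll) cpp_loglik_group_upd(eta, y, ej, newcol, pat, N)
                   else numeric(N)
        logr <- lw * (pll_new - pll) + alpha_dlp(j, a_new, alpha[, j])
        a_ok <- log(stats::runif(N)) < logr
        if (any(a_ok)) {
          alpha[a_ok, j] <- a_new[a_ok]
          racc <- a_ok[pat]
          eta[racc, ej] <- newcol[racc]
          pll[a_ok] <- pll_new[a_ok]
        }
        if (adapting) ls_alpha[, j] <- ls_alpha[, j] + gain * (a_ok - tgt)
        if (post) { acc["alpha"] <- acc["alpha"] + sum(a_ok); try_n["alpha"] <- try_n["alpha"] + N }
      }

      ## Sigma
      diag_cols <- setdiff(seq_len(K), pair_idx)
      for (j in diag_cols) {
        S <- sum(alpha[, j]^2)
        if (S < 1e-300) next
        vnew <- draw_sigma_gibbs(S, N, priors$sigma_max, priors$sigma_scale)
        if (is.na(vnew)) {  # Metropolis fallback on log variance (tiny N)
          prop <- sig_v[j] * exp(0.5 * stats::rnorm(1))
          logr <- sigma_logpost(prop, S, N, priors$sigma_max, priors$sigma_scale) -
            sigma_logpost(sig_v[j], S, N, priors$sigma_max, priors$sigma_scale) +
            log(prop) - log(sig_v[j])
          if (is.finite(logr) && log(stats::runif(1)) < logr) vnew <- prop
          else vnew <- sig_v[j]
        }
        if (post) { acc["Sigma"] <- acc["Sigma"] + (vnew != sig_v[j]); try_n["Sigma"] <- try_n["Sigma"] + 1 }
        sig_v[j] <- vnew
      }
      if (paired) {
        S11 <- sum(alpha[, pair_idx[1]]^2)
        S22 <- sum(alpha[, pair_idx[2]]^2)
        S12 <- sum(alpha[, pair_idx[1]] * alpha[, pair_idx[2]])
        cur_lp <- pair_logpost(sig_v[pair_idx[1]], sig_v[pair_idx[2]], sig_c,
                               S11, S22, S12)
        for (comp in 1:3) {
          prop <- c(sig_v[pair_idx[1]], sig_v[pair_idx[2]], sig_c)
          prop[comp] <- prop[comp] + exp(ls_pair[comp]) * stats::rnorm(1)
          lp_new <- pair_logpost(prop[1], prop[2], prop[3], S11, S22, S12)
          a_ok <- is.finite(lp_new) && log(stats::runif(1)) < lp_new - cur_lp
          if (a_ok) {
            sig_v[pair_idx[1]] <- prop[1]; sig_v[pair_idx[2]] <- prop[2]
            sig_c <- prop[3]; cur_lp <- lp_new
          }
          if (adapting) ls_pair[comp] <- ls_pair[comp] + gain * ((a_ok) - tgt)
          if (post) { acc["Sigma"] <- acc["Sigma"] + a_ok; try_n["Sigma"] <- try_n["Sigma"] + 1 }
        }
      }
    }

    ## record
    if (post && (it - burn) %% settings$thin == 0L) {
      kept <- kept + 1L
      row <- c(beta, if (vr$has_lag) unlist(g_slices),
               if (re) sig_v, if (paired) sig_c)
      draws[kept, ] <- row
      dev_wave[kept, ] <- -2 * cpp_loglik_group(eta, y, wave_idx, nwp)
      if (re) {
        alpha_sum <- alpha_sum + alpha
        if (settings$store_alpha) alpha_draws[kept, ] <- alpha
      }
    }
  }

  list(draws = draws[seq_len(kept), , drop = FALSE],
       dev_wave = dev_wave[seq_len(kept), , drop = FALSE],
       alpha_mean = if (re) alpha_sum / max(kept, 1L) else NULL,
       alpha_draws = if (re && settings$store_alpha)
         alpha_draws[seq_len(kept), , drop = FALSE] else NULL,
       accept = ifelse(try_n > 0, acc / pmax(try_n, 1), NA_real_))
}

#' Run the Metropolis-within-Gibbs sampler
#'
#' Posterior simulation for any model variant. Coefficients (`beta`, `gamma`)
#' are updated by element-wise adaptive random-walk Metropolis, patient
#' random intercepts by vectorised per-patient Metropolis, and diagonal
#' random-effect variances by an exact Gibbs draw from their truncated
#' inverse-gamma full conditional under the Uniform(0, 100) prior (the
#' paired 2x2 covariance block, when enabled, is updated by Metropolis on
#' its bounded support). Proposal-scale adaptation runs during burn-in only.
#' Per-wave deviances are recorded for every retained draw, which is what
#' the DIC and wave-restricted DIC* computations consume.
#'
#' @param design a [build_design()] result.
#' @param priors a [prior_spec()].
#' @param settings an [mcmc_settings()].
#' @return object of class `sed_fit`: `draws` (retained draws x named
#'   parameters, chains stacked), `chain` (chain index per row), `deviance`
#'   (per-draw deviance over the variant's likelihood waves), `dev_wave`
#'   (per-draw per-wave deviance), `alpha_mean` (posterior-mean random
#'   intercepts), `accept` (post-burn-in acceptance rates per block),
#'   `design`, `priors`, `settings`.
#' @export
run_sampler <- function(design, priors = prior_spec(),
                        settings = mcmc_settings()) {
  stopifnot(inherits(design, "sed_design"), inherits(priors, "prior_spec"),
            inherits(settings, "mcmc_settings"))
  res <- vector("list", settings$chains)
  for (ch in seq_len(settings$chains)) res[[ch]] <- run_chain(design, priors, settings, ch)
  draws <- do.call(rbind, lapply(res, `[[`, "draws"))
  dev_wave <- do.call(rbind, lapply(res, `[[`, "dev_wave"))
  chain <- rep(seq_len(settings$chains),
               vapply(res, function(r) nrow(r$draws), integer(1)))
  alpha_mean <- NULL
  if (design$variant$has_random_effect) {
    alpha_mean <- Reduce(`+`, lapply(res, `[[`, "alpha_mean")) / settings$chains
    rownames(alpha_mean) <- design$patient_ids
    colnames(alpha_mean) <- design_level_labels(design)
  }
  alpha_draws <- if (settings$store_alpha && design$variant$has_random_effect)
    do.call(rbind, lapply(res, `[[`, "alpha_draws")) else NULL
  accept <- Reduce(`+`, lapply(res, `[[`, "accept")) / settings$chains
  out <- list(draws = draws, chain = chain,
              deviance = rowSums(dev_wave), dev_wave = dev_wave,
              alpha_mean = alpha_mean, alpha_draws = alpha_draws,
              accept = accept, design = design, priors = priors,
              settings = settings, variant = design$variant)
  class(out) <- "sed_fit"
  out
}

#' Fit a model variant to a sedation panel
#'
#' Convenience wrapper: builds the design for the requested variant (and
#' optional per-contrast mode) and runs [run_sampler()].
#'
#' @inheritParams build_design
#' @param priors a [prior_spec()].
#' @param settings an [mcmc_settings()].
#' @return a `sed_fit`; see [run_sampler()].
#' @export
fit_variant <- function(panel, cohort, variant, contrast = NULL,
                        priors = prior_spec(), settings = mcmc_settings(),
                        include_intercept = FALSE, standardize = FALSE,
                        scaling = NULL) {
  design <- build_design(panel, cohort, variant, contrast = contrast,
                         include_intercept = include_intercept,
                         standardize = standardize, scaling = scaling)
  run_sampler(design, priors, settings)
}

#' @export
print.sed_fit <- function(x, ...) {
  cat(sprintf(
    "Posterior fit: variant %d, %d retained draws (%d chain%s), %d parameters\n",
    x$variant$id, nrow(x$draws), x$settings$chains,
    if (x$settings$chains > 1) "s" else "", ncol(x$draws)))
  cat("Mean deviance:", round(mean(x$deviance), 2), "\n")
  invisible(x)
}

# Posterior-mean parameter state of a fit (element-wise means of the
# retained draws, including the running posterior means of the random
# intercepts), used as the plug-in state for Dhat.
mean_state <- function(fit) {
  st <- vec_to_state(fit$design, colMeans(fit$draws))
  st$alpha <- fit$alpha_mean
  st
}

# Reshape one flattened draw (named vector in the draws-column layout) back
# into beta / gamma matrices and the Sigma diagonal.
vec_to_state <- function(design, cm) {
  vr <- design$variant
  K <- design$K; p <- ncol(design$X)
  lvl <- design_level_labels(design)
  beta <- matrix(cm[seq_len(p * K)], p, K,
                 dimnames = list(colnames(design$X), lvl))
  off <- p * K
  gamma <- NULL
  if (vr$has_lag) {
    nl <- ncol(design$Z)
    if (vr$lag_time_varying) {
      ng <- nl * K * (design$n_waves - 1L)
      gamma <- array(cm[off + seq_len(ng)], c(nl, K, design$n_waves - 1L),
                     dimnames = list(colnames(design$Z), lvl,
                                     paste0("wave", 2:design$n_waves)))
      off <- off + ng
    } else {
      gamma <- matrix(cm[off + seq_len(nl * K)], nl, K,
                      dimnames = list(colnames(design$Z), lvl))
      off <- off + nl * K
    }
  }
  sigma_v <- NULL
  if (vr$has_random_effect) {
    nms <- paste0("Sigma.", lvl)
    if (all(nms %in% names(cm))) sigma_v <- unname(cm[nms])
  }
  list(beta = beta, gamma = gamma, alpha = NULL, sigma_v = sigma_v)
}
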