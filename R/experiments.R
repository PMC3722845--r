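#' Build a small custom design (toy-model helper)
#'
#' Wraps arbitrary response/covariate/lag matrices into the design structure
#' the sampler consumes, for small validation models (e.g. a two-level,
#' two-parameter logistic toy whose posterior can be integrated on a grid).
#'
#' @param y integer responses in 1..L.
#' @param X covariate matrix (named columns).
#' @param Z lag-indicator matrix (named columns) or `NULL`.
#' @param patient 1-based patient index per row.
#' @param wave wave per row.
#' @param variant variant id or spec.
#' @param L number of response levels.
#' @param contrast optional contrast label.
#' @return a `sed_design`.
#' @export
toy_design <- function(y, X, Z = NULL, patient = seq_along(y),
                       wave = rep(2L, length(y)), variant = 2L, L = 2L,
                       contrast = if (L == 2L) 2L else NULL) {
  variant <- as_variant(variant)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    if (is.null(colnames(Z))) colnames(Z) <- paste0("prev", seq_len(ncol(Z)))
  }
  upat <- sort(unique(patient))
  out <- list(y = as.integer(y), X = X, Z = Z,
              patient = match(patient, upat), patient_id = patient,
              patient_ids = upat, wave = as.integer(wave),
              L = as.integer(L), K = as.integer(L) - 1L,
              n_patients = length(upat), n_waves = max(wave),
              variant = variant, contrast = contrast,
              include_intercept = FALSE, standardize = FALSE, scaling = NULL)
  class(out) <- "sed_design"
  out
}

#' Grid-quadrature posterior means for the two-parameter logistic toy
#'
#' Independent oracle for sampler validation: a two-level response with one
#' covariate effect and one lag effect reduces to logistic regression with
#' two coefficients; under normal priors the posterior mean is computed by
#' deterministic quadrature on a dense grid (no MCMC anywhere). The
#' likelihood is written out directly here, independently of the package's
#' likelihood kernel.
#'
#' @param x,z,y covariate, lag indicator and response (1/2) vectors.
#' @param prior_var normal prior variance of both coefficients.
#' @param half half-width of the grid around 0.
#' @param n grid points per dimension.
#' @return named numeric vector: posterior means of the `x` and `z`
#'   coefficients.
#' @export
logistic_grid_means <- function(x, z, y, prior_var = 1000, half = 10,
                                n = 401L) {
  g <- seq(-half, half, length.out = n)
  s <- as.integer(y == 2L)
  # pool observations sharing an (x, z) value pair, then accumulate the
  # log posterior over the grid one pooled cell at a time
  key <- paste(x, z)
  lp <- -outer(g^2, g^2, "+") / (2 * prior_var)
  for (k in unique(key)) {
    rows <- key == k
    E <- outer(g * x[rows][1], g * z[rows][1], "+")
    lp <- lp + sum(s[rows]) * E - sum(rows) * log1p(exp(E))
  }
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  c(x = sum(rowSums(w) * g), z = sum(colSums(w) * g))
}

#' Quadrature-versus-MCMC check on the logistic toy
#'
#' Simulates the small two-parameter model (8 patients, 2 response levels,
#' 2 waves with a lagged indicator), computes exact posterior means by grid
#' quadrature, runs the package sampler on the identical design, and
#' returns both sets of means and their maximum absolute difference.
#'
#' @param seed RNG seed.
#' @param n_iter,burn_in sampler effort.
#' @return list with `quadrature`, `mcmc`, `max_abs_diff`.
#' @export
quadrature_check <- function(seed = 1L, n_iter = 200000L, burn_in = 5000L) {
  set.seed(seed)
  n_pat <- 8L
  x <- rep(stats::rbinom(n_pat, 1L, 0.5), each = 2L)   # waves 2,3 per patient
  z <- stats::rbinom(2L * n_pat, 1L, 0.5)              # previous level == 2
  eta <- 0.8 * x + 1.0 * z
  y <- 1L + stats::rbinom(2L * n_pat, 1L, stats::plogis(eta))

  quad <- logistic_grid_means(x, z, y)

  design <- toy_design(y, X = cbind(x = x), Z = cbind(prevSed2 = z),
                       patient = rep(seq_len(n_pat), each = 2L),
                       wave = rep(c(2L, 3L), n_pat), variant = 2L)
  fit <- run_sampler(design, prior_spec(),
                     mcmc_settings(n_iter = n_iter, burn_in = burn_in,
                                   seed = seed + 1L))
  mc <- colMeans(fit$draws)[c("beta.x.Sed2", "gamma.prevSed2.Sed2")]
  list(quadrature = quad, mcmc = mc,
       max_abs_diff = max(abs(unname(quad) - unname(mc))))
}

# Fixed ground-truth coefficient patterns used by the simulation
# experiments: modest, varied effects on the standardized-design scale.
recovery_truth <- function(variant = 3L) {
  p <- length(design_colnames(FALSE))
  beta <- matrix(rep_len(c(0.6, -0.4, 0, 0.8, -0.7, 0.3), p * 5L), p, 5L)
  gamma <- matrix(0, 5L, 5L)
  diag(gamma) <- 1.2
  gamma[cbind(1:4, 2:5)] <- 0.4
  truth_record(variant, beta = beta, gamma = gamma, Sigma = 0.5,
               include_intercept = FALSE, standardize = TRUE)
}

#' Parameter-recovery experiment
#'
#' Simulates panels from a known variant-3 truth (covariate effects, lag
#' effects, diagonal random-effect covariance), refits the same variant,
#' and reports how often the central 95% credible intervals cover the true
#' coefficient values, pooled over replicates.
#'
#' @param n_reps replicate simulations.
#' @param n_patients cohort size per replicate (split evenly over groups,
#'   remainder to group C).
#' @param settings [mcmc_settings()] for each fit.
#' @param seed base seed; replicate r derives its seeds from `seed + r`.
#' @return list with `coverage` (pooled over beta and gamma), `per_rep`
#'   coverage vector, `n_params`, and the `truth` used.
#' @export
recovery_experiment <- function(n_reps = 5L, n_patients = 500L,
                                settings = mcmc_settings(n_iter = 10000L,
                                                         burn_in = 1000L),
                                seed = 1L) {
  truth <- recovery_truth(3L)
  truth_vec <- c(stats::setNames(
    as.vector(truth$beta),
    as.vector(outer(rownames(truth$beta), colnames(truth$beta),
                    function(a, b) paste("beta", a, b, sep = ".")))),
    stats::setNames(
      as.vector(truth$gamma),
      as.vector(outer(rownames(truth$gamma), colnames(truth$gamma),
                      function(a, b) paste("gamma", a, b, sep = ".")))))
  gs <- rep(n_patients %/% 4L, 4L)
  gs[4] <- gs[4] + n_patients - sum(gs)
  per_rep <- numeric(n_reps)
  covered_all <- 0L; total_all <- 0L
  for (r in seq_len(n_reps)) {
    coh <- generate_cohort(n_patients, gs, seed = seed + r)
    pan <- simulate_panel(coh, truth, seed = seed + 100L + r)
    st <- settings; st$seed <- as.integer(seed + 200L + r)
    fit <- fit_variant(pan, coh, 3L, priors = prior_spec(), settings = st,
                       include_intercept = FALSE, standardize = TRUE)
    s <- summarize_draws(fit)
    i <- match(names(truth_vec), s$variable)
    stopifnot(!anyNA(i))
    cov <- truth_vec >= s$q2.5[i] & truth_vec <= s$q97.5[i]
    per_rep[r] <- mean(cov)
    covered_all <- covered_all + sum(cov)
    total_all <- total_all + length(cov)
  }
  list(coverage = covered_all / total_all, per_rep = per_rep,
       n_params = length(truth_vec), truth = truth)
}

#' Model-discrimination experiment
#'
#' Repeatedly simulates data whose generating process favours a known
#' variant family and checks which fitted variant wins on the
#' wave-restricted criterion DIC*:
#'
#' * `"lag_free"`: truth is variant 1 (covariate + random effects, no lag
#'   dynamics); a win means variant 1 attains the minimum DIC* among all
#'   five fitted variants.
#' * `"wave_varying"`: truth is variant 4 with strongly different lag
#'   effects at waves 2 and 3; a win means the better of variants 4/5 beats
#'   the better of variants 2/3 on DIC*.
#'
#' @param kind `"lag_free"` or `"wave_varying"`.
#' @param n_reps replicates.
#' @param n_patients cohort size per replicate.
#' @param settings [mcmc_settings()] per fit.
#' @param seed base seed.
#' @return list with `wins`, `n_reps`, and per-replicate DIC* tables.
#' @export
discrimination_experiment <- function(kind = c("lag_free", "wave_varying"),
                                      n_reps = 10L, n_patients = 150L,
                                      settings = mcmc_settings(
                                        n_iter = 2000L, burn_in = 500L),
                                      seed = 1L) {
  kind <- match.arg(kind)
  p <- length(design_colnames(FALSE))
  if (kind == "lag_free") {
    beta <- matrix(rep_len(c(0.8, -0.6, 0.4, 0, -0.8, 0.5), p * 5L), p, 5L)
    truth <- truth_record(1L, beta = beta, Sigma = 1,
                          include_intercept = FALSE, standardize = TRUE)
    fit_ids <- 1:5
  } else {
    g2 <- matrix(0, 5L, 5L); diag(g2) <- 2.5
    g3 <- matrix(0, 5L, 5L); g3[cbind(1:5, c(2:5, 1))] <- 2.5  # shifted target
    gamma <- array(c(g2, g3), c(5L, 5L, 2L))
    beta <- matrix(rep_len(c(0.5, -0.4, 0.3), p * 5L), p, 5L)
    truth <- truth_record(4L, beta = beta, gamma = gamma,
                          include_intercept = FALSE, standardize = TRUE)
    fit_ids <- 2:5
  }
  gs <- rep(n_patients %/% 4L, 4L)
  gs[4] <- gs[4] + n_patients - sum(gs)
  wins <- 0L
  tables <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    coh <- generate_cohort(n_patients, gs, seed = seed + r)
    pan <- simulate_panel(coh, truth, seed = seed + 100L + r)
    fits <- lapply(fit_ids, function(v) {
      st <- settings; st$seed <- as.integer(seed + 200L + 10L * r + v)
      fit_variant(pan, coh, v, priors = prior_spec(), settings = st,
                  include_intercept = FALSE, standardize = TRUE)
    })
    tab <- suppressWarnings(compare_variants(fits, sort_by = NA, focus = "marginal"))
    tables[[r]] <- tab
    star <- stats::setNames(tab$DIC_star, tab$variant)
    if (kind == "lag_free") {
      wins <- wins + (which.min(star) == match("1", names(star)))
    } else {
      wins <- wins + (min(star[c("4", "5")]) < min(star[c("2", "3")]))
    }
  }
  list(kind = kind, wins = as.integer(wins), n_reps = n_reps,
       tables = tables)
}
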