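#' Names of the covariate design columns
#'
#' Drug group enters as dummies for C, D and L with M as the reference; the
#' remaining covariates enter as given. Used to line up ground-truth
#' coefficient matrices with the design matrix.
#'
#' @param include_intercept add a leading `(Intercept)` column.
#' @return character vector of column names.
#' @export
design_colnames <- function(include_intercept = FALSE) {
  nm <- c("groupC", "groupD", "groupL", "age_months", "weight_kg",
          "sex", "disease", "test", "comp", "sbp", "pul", "osat")
  if (include_intercept) c("(Intercept)", nm) else nm
}

level_names <- function(levels = 6L) paste0("Sed", seq_len(levels))
free_level_names <- function(levels = 6L) paste0("Sed", 2:levels)
lag_rownames <- function(levels = 6L) paste0("prevSed", 2:levels)

#' Ground-truth parameter record for simulation
#'
#' Bundles a variant id with the full parameter set needed to simulate
#' sedation panels: per-level coefficient matrix `beta`, lag-effect matrix
#' `gamma` (constant, or one slice per wave for wave-varying variants),
#' random-effect covariance `Sigma`, and the wave-1 baseline level
#' probabilities. Reference-level (Sed1) entries are implicitly zero and are
#' not stored.
#'
#' @param variant variant id in 1..5 or a [variant_spec()].
#' @param beta numeric `p x 5` matrix (columns Sed2..Sed6) or a single number
#'   recycled; rows must match [design_colnames()] for the chosen intercept
#'   setting.
#' @param gamma lag effects: `5 x 5` matrix (rows prevSed2..prevSed6, columns
#'   Sed2..Sed6) for variants 2/3, or a `5 x 5 x 2` array (slices = waves 2,3)
#'   for variants 4/5; single numbers are recycled. Ignored for variant 1.
#' @param Sigma random-effect covariance: a scalar or length-5 vector of
#'   variances (diagonal), or a full `5 x 5` positive semi-definite matrix.
#'   Ignored (forced to 0) for variants without random effects.
#' @param baseline wave-1 level probabilities, length 6, summing to 1.
#'   The lag variants condition on wave 1, which is therefore generated from
#'   this free multinomial (default uniform).
#' @param include_intercept,standardize design-construction flags; simulation
#'   and fitting must use the same values for coefficients to be comparable.
#' @param wave1 `"baseline"` draws wave 1 from `baseline`; `"model"` draws it
#'   from the variant's covariate linear predictor (only meaningful for
#'   variant 1, whose likelihood covers wave 1).
#' @return a list of class `sed_truth`.
#' @export
truth_record <- function(variant, beta = 0, gamma = 0, Sigma = 0,
                         baseline = rep(1 / 6, 6),
                         include_intercept = FALSE, standardize = FALSE,
                         wave1 = c("baseline", "model")) {
  variant <- as_variant(variant)
  wave1 <- match.arg(wave1)
  K <- 5L
  p <- length(design_colnames(include_intercept))

  if (length(beta) == 1L) beta <- matrix(beta, p, K)
  beta <- as.matrix(beta)
  if (!all(dim(beta) == c(p, K)))
    stop(sprintf("beta must be %d x %d for this design", p, K))
  dimnames(beta) <- list(design_colnames(include_intercept), free_level_names())

  if (variant$has_lag) {
    if (variant$lag_time_varying) {
      if (length(gamma) == 1L) gamma <- array(gamma, c(K, K, 2L))
      if (is.matrix(gamma)) gamma <- array(rep(gamma, 2L), c(K, K, 2L))
      if (!all(dim(gamma) == c(K, K, 2L)))
        stop("gamma must be a 5 x 5 x 2 array for wave-varying variants")
      dimnames(gamma) <- list(lag_rownames(), free_level_names(),
                              paste0("wave", 2:3))
    } else {
      if (length(gamma) == 1L) gamma <- matrix(gamma, K, K)
      gamma <- as.matrix(gamma)
      if (!all(dim(gamma) == c(K, K)))
        stop("gamma must be a 5 x 5 matrix for constant-lag variants")
      dimnames(gamma) <- list(lag_rownames(), free_level_names())
    }
  } else gamma <- NULL

  if (variant$has_random_effect) {
    if (is.matrix(Sigma)) {
      if (!all(dim(Sigma) == c(K, K)) || !isSymmetric(unname(Sigma)))
        stop("Sigma matrix must be symmetric 5 x 5")
      ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < -1e-8) stop("Sigma must be positive semi-definite")
    } else {
      Sigma <- diag(rep(Sigma, length.out = K), K)
    }
    if (any(diag(Sigma) < 0)) stop("Sigma diagonal entries must be >= 0")
  } else Sigma <- diag(0, K)
  dimnames(Sigma) <- list(free_level_names(), free_level_names())

  baseline <- as.numeric(baseline)
  if (length(baseline) != 6L || any(baseline < 0) ||
      abs(sum(baseline) - 1) > 1e-8)
    stop("baseline must be 6 nonnegative probabilities summing to 1")

  out <- list(variant = variant, beta = beta, gamma = gamma, Sigma = Sigma,
              baseline = baseline, include_intercept = include_intercept,
              standardize = standardize, wave1 = wave1)
  class(out) <- "sed_truth"
  out
}

#' @export
print.sed_truth <- function(x, ...) {
  cat(sprintf("Ground truth for variant %d (%d covariates%s)\n",
              x$variant$id, nrow(x$beta),
              if (x$include_intercept) ", with intercept" else ""))
  invisible(x)
}
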