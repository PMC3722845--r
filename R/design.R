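# Covariate matrix for the long cohort rows (one row per patient x wave),
# in the cohort's row order. Group enters as C/D/L dummies with M reference.
covariate_matrix <- function(cohort, include_intercept = FALSE,
                             standardize = FALSE, scaling = NULL) {
  validate_cohort(cohort)
  g <- as.character(cohort$group)
  X <- cbind(
    groupC = as.numeric(g == "C"),
    groupD = as.numeric(g == "D"),
    groupL = as.numeric(g == "L"),
    age_months = cohort$age_months,
    weight_kg  = cohort$weight_kg,
    sex = cohort$sex, disease = cohort$disease,
    test = cohort$test, comp = cohort$comp,
    sbp = cohort$sbp, pul = cohort$pul, osat = cohort$osat)
  if (standardize) {
    cont <- c("age_months", "weight_kg", "sbp", "pul", "osat")
    if (is.null(scaling)) {
      scaling <- list(center = colMeans(X[, cont, drop = FALSE]),
                      scale = apply(X[, cont, drop = FALSE], 2, stats::sd))
      scaling$scale[scaling$scale == 0] <- 1
    }
    X[, cont] <- sweep(sweep(X[, cont, drop = FALSE], 2, scaling$center),
                       2, scaling$scale, "/")
  }
  if (include_intercept) X <- cbind(`(Intercept)` = 1, X)
  attr(X, "scaling") <- scaling
  X
}

#' Build the model design from a sedation panel and cohort
#'
#' Assembles the response vector, covariate matrix `X` and lag-indicator
#' matrix `Z` for a model variant. For lag variants only waves 2..T yield
#' rows (wave 1 is conditioned on); variant 1 uses all waves. The lag
#' indicators one-hot encode the previous wave's observed level over levels
#' 2..6, with previous level 1 (the reference) coding as all zeros.
#'
#' @param panel `data.frame` with `patient_id`, `wave`, `level` (1..6).
#' @param cohort a cohort table as from [generate_cohort()].
#' @param variant variant id or [variant_spec()].
#' @param contrast `NULL` for the joint 6-level model, or a level `j` in 2..6
#'   for the per-contrast mode: the model of level `j` versus level 1 fitted
#'   on the subset of observations with level in `{1, j}` (the bookkeeping
#'   behind per-effect DIC tables).
#' @param include_intercept,standardize design flags; see [truth_record()].
#' @param scaling optional precomputed standardization (centers/scales), so a
#'   fit design can reuse the scaling of the data it was simulated from.
#' @return a list of class `sed_design`: `y` (response recoded 1..L), `X`,
#'   `Z` (or `NULL`), `patient` (1-based patient index), `patient_id`,
#'   `wave`, `L` (number of response levels used), `K = L - 1`,
#'   `n_patients`, `variant`, `contrast`.
#' @export
build_design <- function(panel, cohort, variant, contrast = NULL,
                         include_intercept = FALSE, standardize = FALSE,
                         scaling = NULL) {
  variant <- as_variant(variant)
  validate_panel(panel)
  validate_cohort(cohort)
  if (!all(panel$patient_id %in% cohort$patient_id))
    stop("panel contains patient_ids absent from the cohort")

  ord <- order(panel$patient_id, panel$wave)
  panel <- panel[ord, , drop = FALSE]
  key_c <- paste(cohort$patient_id, cohort$wave)
  key_p <- paste(panel$patient_id, panel$wave)
  m <- match(key_p, key_c)
  if (anyNA(m)) stop("cohort is missing rows for some (patient, wave) pairs")
  Xall <- covariate_matrix(cohort, include_intercept, standardize, scaling)
  scaling <- attr(Xall, "scaling")
  Xall <- Xall[m, , drop = FALSE]

  n_waves <- max(panel$wave)
  if (variant$has_lag) {
    keep <- panel$wave >= 2L
    prev_key <- paste(panel$patient_id, panel$wave - 1L)
    pm <- match(prev_key[keep], key_p)
    if (anyNA(pm))
      stop("lag variant requires the previous wave for every row at waves >= 2")
    prev_level <- panel$level[pm]
    Z <- matrix(0, sum(keep), 5L,
                dimnames = list(NULL, lag_rownames()))
    hot <- prev_level >= 2L
    Z[cbind(which(hot), prev_level[hot] - 1L)] <- 1
  } else {
    keep <- rep(TRUE, nrow(panel))
    Z <- NULL
  }

  y <- panel$level[keep]
  X <- Xall[keep, , drop = FALSE]
  pid <- panel$patient_id[keep]
  wave <- panel$wave[keep]

  L <- 6L
  if (!is.null(contrast)) {
    contrast <- as.integer(contrast)
    if (contrast < 2L || contrast > 6L)
      stop("contrast must be a level in 2..6")
    sub <- y %in% c(1L, contrast)
    y <- ifelse(y[sub] == 1L, 1L, 2L)
    X <- X[sub, , drop = FALSE]
    if (!is.null(Z)) Z <- Z[sub, , drop = FALSE]
    pid <- pid[sub]
    wave <- wave[sub]
    L <- 2L
  }

  upid <- sort(unique(pid))
  out <- list(y = as.integer(y), X = X, Z = Z,
              patient = match(pid, upid), patient_id = pid,
              patient_ids = upid, wave = as.integer(wave),
              L = L, K = L - 1L, n_patients = length(upid),
              n_waves = n_waves, variant = variant, contrast = contrast,
              include_intercept = include_intercept,
              standardize = standardize, scaling = scaling)
  class(out) <- "sed_design"
  out
}

#' @export
print.sed_design <- function(x, ...) {
  cat(sprintf(
    "Design for variant %d%s: %d rows, %d patients, %d covariates, %d levels\n",
    x$variant$id,
    if (is.null(x$contrast)) "" else sprintf(" (contrast Sed%d vs Sed1)", x$contrast),
    length(x$y), x$n_patients, ncol(x$X), x$L))
  invisible(x)
}

validate_panel <- function(panel) {
  need <- c("patient_id", "wave", "level")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("panel is missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!(panel$level %in% 1:6))
  if (length(bad))
    stop("panel rows with level outside 1..6: ",
         paste(utils::head(bad, 5), collapse = ", "))
  key <- paste(panel$patient_id, panel$wave)
  if (anyDuplicated(key))
    stop("panel has duplicate (patient_id, wave) rows")
  invisible(panel)
}
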