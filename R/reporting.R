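# Batch-means Monte Carlo standard error of the mean, with floor(sqrt(n))
# batches (trailing remainder dropped).
mc_error_batch <- function(x) {
  n <- length(x)
  if (n < 4L) return(NA_real_)
  nb <- floor(sqrt(n))
  bs <- n %/% nb
  m <- vapply(seq_len(nb), function(b) mean(x[((b - 1) * bs + 1):(b * bs)]),
              numeric(1))
  stats::sd(m) / sqrt(nb)
}

#' Posterior summary table
#'
#' One row per monitored parameter with posterior mean, sd, batch-means MC
#' error, 2.5/50/97.5 percentiles, the start iteration and retained sample
#' size, and a significance flag set when the central 95% interval excludes
#' zero (the convention used to bold entries in the study's tables).
#'
#' @param fit a `sed_fit`, or a numeric matrix of draws with named columns.
#' @param start,sample echoed table columns; taken from the fit's settings
#'   when a `sed_fit` is given.
#' @return `data.frame` with columns `variable`, `mean`, `sd`, `mc_error`,
#'   `q2.5`, `median`, `q97.5`, `start`, `sample`, `significant`.
#' @export
summarize_draws <- function(fit, start = NULL, sample = NULL) {
  if (inherits(fit, "sed_fit")) {
    draws <- fit$draws
    if (is.null(start)) start <- fit$settings$burn_in + 1L
  } else {
    draws <- as.matrix(fit)
  }
  if (!nrow(draws)) stop("empty chain")
  if (is.null(start)) start <- 1L
  if (is.null(sample)) sample <- nrow(draws)
  q <- t(apply(draws, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
               names = FALSE))
  out <- data.frame(
    variable = colnames(draws),
    mean = colMeans(draws),
    sd = apply(draws, 2, stats::sd),
    mc_error = apply(draws, 2, mc_error_batch),
    q2.5 = q[, 1], median = q[, 2], q97.5 = q[, 3],
    start = start, sample = sample,
    row.names = NULL)
  out$significant <- out$q2.5 > 0 | out$q97.5 < 0
  out
}

format_cell <- function(mean, lo, hi, signif = FALSE, digits = 3) {
  cell <- sprintf("%.*f (%.*f; %.*f)", digits, mean, digits, lo, digits, hi)
  if (signif) paste0(cell, "*") else cell
}

#' Parse a formatted posterior cell back into numbers
#'
#' Inverse of the "mean (q2.5; q97.5)" cell format used by
#' [contrast_table()]; a trailing `*` marks significance.
#'
#' @param cell character cell.
#' @return named numeric vector `mean`, `q2.5`, `q97.5` with attribute
#'   `significant`.
#' @export
parse_cell <- function(cell) {
  sig <- grepl("\\*$", cell)
  nums <- as.numeric(regmatches(cell, gregexpr("-?[0-9.]+", cell))[[1]])
  out <- c(mean = nums[1], q2.5 = nums[2], q97.5 = nums[3])
  attr(out, "significant") <- sig
  out
}

#' Cross-variant posterior comparison table for one contrast
#'
#' Wide table of "mean (q2.5; q97.5)" cells, rows = covariate effects
#' followed by lagged-level effects, columns = the supplied fits. For a
#' joint 6-level fit the requested contrast's column block is extracted;
#' per-contrast fits must match the requested contrast. Variants without a
#' lag term leave the lag rows empty; wave-varying variants get one lag row
#' block per wave.
#'
#' @param fits named list of `sed_fit` objects on the same data (names
#'   become column labels; defaults to `Model <variant>`).
#' @param contrast response level `j`; cells describe effects on
#'   `log(P(Sed j)/P(Sed1))`.
#' @param digits formatting digits.
#' @return `data.frame`, first column `variable`, one column per fit;
#'   unavailable cells are `""`.
#' @export
contrast_table <- function(fits, contrast = 6L, digits = 3) {
  stopifnot(length(fits) >= 1)
  contrast <- as.integer(contrast)
  lvl <- paste0("Sed", contrast)
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f)
      paste("Model", f$variant$id), character(1))
  sig <- vapply(fits, function(f) digest_y(f$design), character(1))
  if (length(unique(sig)) != 1L) stop("fits were not computed on the same data")

  covars <- rownames(mean_state(fits[[1]])$beta)
  lagrows_const <- paste0("Sed-level (t-1) [", lag_rownames(), "]")
  lagrows_tv <- unlist(lapply(2:3, function(w)
    paste0("Sed-level (", w, ", t-1) [", lag_rownames(), "]")))
  vars <- c(covars, lagrows_const, lagrows_tv)
  tab <- data.frame(variable = vars, stringsAsFactors = FALSE)

  for (nmf in names(fits)) {
    f <- fits[[nmf]]
    if (!is.null(f$design$contrast) && f$design$contrast != contrast)
      stop(sprintf("fit '%s' is a per-contrast fit for Sed%d, not Sed%d",
                   nmf, f$design$contrast, contrast))
    s <- summarize_draws(f)
    col <- rep("", length(vars))
    pick <- function(pname) {
      i <- match(pname, s$variable)
      if (is.na(i)) return("")
      format_cell(s$mean[i], s$q2.5[i], s$q97.5[i], s$significant[i], digits)
    }
    tgt_lvl <- if (is.null(f$design$contrast)) lvl else paste0("Sed", f$design$contrast)
    for (i in seq_along(covars))
      col[i] <- pick(paste("beta", covars[i], tgt_lvl, sep = "."))
    if (f$variant$has_lag && !f$variant$lag_time_varying) {
      for (i in seq_along(lag_rownames()))
        col[length(covars) + i] <-
          pick(paste("gamma", lag_rownames()[i], tgt_lvl, sep = "."))
    }
    if (f$variant$has_lag && f$variant$lag_time_varying) {
      off <- length(covars) + length(lag_rownames())
      for (w in 2:3) for (i in seq_along(lag_rownames()))
        col[off + (w - 2) * 5 + i] <-
          pick(paste("gamma", paste0("wave", w), lag_rownames()[i], tgt_lvl,
                     sep = "."))
    }
    tab[[nmf]] <- col
  }
  # drop all-empty rows (e.g. lag blocks when no fitted variant uses them)
  keep <- rowSums(tab[, -1, drop = FALSE] != "") > 0
  tab[keep | seq_along(vars) <= length(covars), , drop = FALSE]
}
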