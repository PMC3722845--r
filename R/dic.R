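#' Assemble DIC from deviance draws and a plug-in deviance
#'
#' `Dbar` is the posterior mean deviance, `Dhat` the deviance at the
#' posterior-mean parameters, `pD = Dbar - Dhat` the effective number of
#' parameters, and `DIC = Dbar + pD = 2 Dbar - Dhat`.
#'
#' @param deviances numeric vector of per-draw deviances.
#' @param dev_at_mean deviance at the posterior-mean parameter state.
#' @return list with `Dbar`, `Dhat`, `pD`, `DIC`.
#' @export
dic_from_deviances <- function(deviances, dev_at_mean) {
  if (!length(deviances)) stop("empty deviance chain")
  Dbar <- mean(deviances)
  pD <- Dbar - dev_at_mean
  list(Dbar = Dbar, Dhat = dev_at_mean, pD = pD, DIC = Dbar + pD)
}

#' Deviance Information Criterion of a fit
#'
#' Computes DIC from a fitted chain, either over all waves in the variant's
#' likelihood or restricted to waves 2 and 3 (the wave-restricted criterion,
#' DIC*, which puts variants with and without a lag term on the same
#' likelihood support). Two deviance focuses are supported:
#'
#' * `"patient"` (default, the WinBUGS-style focus on all sampled nodes):
#'   the per-draw conditional deviance given the sampled random intercepts;
#'   `Dhat` plugs in the element-wise posterior-mean state including the
#'   posterior means of the intercepts.
#' * `"marginal"`: the random intercepts are integrated out of the
#'   likelihood by Monte Carlo (common standard-normal draws shared across
#'   parameter draws), so the deviance is a function of `beta`, `gamma` and
#'   `Sigma` only. This is the focus to use when comparing variants with
#'   different random-effect structures: the conditional deviance rewards
#'   per-patient overfitting and is not comparable across such variants.
#'   For variants without random effects the two focuses coincide.
#'
#' @param fit a `sed_fit`.
#' @param waves `"all"` or `"23"`.
#' @param focus `"patient"` or `"marginal"`.
#' @param mc_draws Monte Carlo points per patient for the marginal focus.
#' @param max_draws number of (evenly spaced) retained draws used for the
#'   marginal `Dbar` (the conditional `Dbar` always uses every draw).
#' @param mc_seed seed of the shared Monte Carlo draws; the global RNG
#'   state is saved and restored.
#' @return list of class `dic_result` with `Dbar`, `Dhat`, `pD`, `DIC`,
#'   plus `waves`, `variant`, `contrast`, `focus`, `note`.
#' @export
compute_dic <- function(fit, waves = c("all", "23"),
                        focus = c("patient", "marginal"),
                        mc_draws = 128L, max_draws = 200L, mc_seed = 1L) {
  stopifnot(inherits(fit, "sed_fit"))
  waves <- match.arg(waves)
  focus <- match.arg(focus)
  design <- fit$design
  present <- as.integer(sub("wave", "", colnames(fit$dev_wave)))
  note <- NULL
  if (waves == "23") {
    use <- present[present >= 2L]
    if (identical(use, present))
      note <- "likelihood already restricted to waves 2,3 (lag variant); DIC* equals DIC"
  } else use <- present
  if (focus == "patient") {
    devs <- rowSums(fit$dev_wave[, present %in% use, drop = FALSE])
    dhat <- deviance_state(design, mean_state(fit), waves = use)
  } else {
    re <- design$variant$has_random_effect
    M <- if (re) as.integer(mc_draws) else 1L
    if (exists(".Random.seed", envir = globalenv()))
      old_seed <- get(".Random.seed", envir = globalenv()) else old_seed <- NULL
    set.seed(as.integer(mc_seed))
    Zm <- matrix(stats::rnorm(M * design$K), M, design$K)
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
    use_row <- design$wave %in% use
    mdev <- function(v) {
      stt <- vec_to_state(design, v)
      eta0 <- compute_eta(design, list(beta = stt$beta, gamma = stt$gamma,
                                       alpha = NULL))
      sd_k <- if (re) sqrt(pmax(stt$sigma_v, 0)) else rep(0, design$K)
      cpp_marginal_dev(eta0, design$y, design$patient, design$n_patients,
                       sd_k, Zm, use_row)
    }
    sub <- unique(round(seq(1, nrow(fit$draws),
                            length.out = min(max_draws, nrow(fit$draws)))))
    devs <- vapply(sub, function(r) mdev(fit$draws[r, ]), numeric(1))
    dhat <- mdev(colMeans(fit$draws))
  }
  out <- dic_from_deviances(devs, dhat)
  out$waves <- use
  out$variant <- design$variant$id
  out$contrast <- design$contrast
  out$focus <- focus
  out$note <- note
  class(out) <- "dic_result"
  out
}

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf(
    "Variant %d%s, waves {%s}: Dbar = %.2f, Dhat = %.2f, pD = %.2f, DIC = %.2f\n",
    x$variant,
    if (is.null(x$contrast)) "" else sprintf(" (Sed%d vs Sed1)", x$contrast),
    paste(x$waves, collapse = ","), x$Dbar, x$Dhat, x$pD, x$DIC))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Compare model variants by DIC and DIC*
#'
#' Builds the cross-variant comparison table (one row per fit, columns DIC
#' and wave-restricted DIC*). DIC over all waves is not comparable between
#' variant 1 (which models wave 1) and the lag variants (which condition on
#' it); a warning flags this whenever both kinds are present — DIC* is the
#' comparable column.
#'
#' @param fits list of `sed_fit` objects fitted to the same data.
#' @param sort_by column used to order the table (`"DIC_star"` default,
#'   or `"DIC"`, or `NA` to keep input order).
#' @param focus,... passed to [compute_dic()]; use `focus = "marginal"` when
#'   the fits mix random-effect structures.
#' @return `data.frame` with columns `variant`, `contrast`, `Dbar`, `Dhat`,
#'   `pD`, `DIC`, `Dbar_star`, `Dhat_star`, `pD_star`, `DIC_star`.
#' @export
compare_variants <- function(fits, sort_by = "DIC_star", focus = "patient", ...) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, logical(1), "sed_fit")))
  # all fits must come from the same panel: compare the wave-2,3 responses,
  # which every variant's design contains
  sig <- vapply(fits, function(f) digest_y(f$design), character(1))
  if (length(unique(sig)) != 1L)
    stop("fits were not computed on the same data")
  ctr <- unique(vapply(fits, function(f)
    if (is.null(f$design$contrast)) 0L else f$design$contrast, integer(1)))
  if (length(ctr) != 1L)
    stop("fits mix joint and per-contrast modes")
  rows <- lapply(fits, function(f) {
    d <- compute_dic(f, "all", focus = focus, ...)
    ds <- compute_dic(f, "23", focus = focus, ...)
    data.frame(variant = d$variant,
               contrast = if (is.null(d$contrast)) NA_integer_ else d$contrast,
               Dbar = d$Dbar, Dhat = d$Dhat, pD = d$pD, DIC = d$DIC,
               Dbar_star = ds$Dbar, Dhat_star = ds$Dhat,
               pD_star = ds$pD, DIC_star = ds$DIC)
  })
  tab <- do.call(rbind, rows)
  kinds <- vapply(fits, function(f) f$design$variant$has_lag, logical(1))
  if (length(unique(kinds)) > 1L)
    warning("DIC over all waves mixes likelihood supports (variant 1 models ",
            "wave 1, lag variants condition on it); compare on DIC_star")
  if (!is.na(sort_by) && sort_by %in% names(tab))
    tab <- tab[order(tab[[sort_by]]), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

# Stable fingerprint of the wave-2,3 part of a design's response (rows are
# sorted by patient and wave in every design), used to check that compared
# fits share one dataset.
digest_y <- function(design) {
  keep <- design$wave >= 2L
  yk <- design$y[keep]
  paste(sum(yk * (seq_along(yk) %% 97L + 1L)), length(yk))
}
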