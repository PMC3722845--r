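panel_columns <- c("patient_id", "wave", "level", "group", "age_months",
                   "weight_kg", "sex", "disease", "test", "comp",
                   "sbp", "pul", "osat")

#' Write a cohort and panel as one long-format CSV
#'
#' The canonical exchange format: one row per patient x wave with the
#' response level and all covariates, header `patient_id, wave, level,
#' group, age_months, weight_kg, sex, disease, test, comp, sbp, pul, osat`.
#'
#' @param cohort cohort table.
#' @param panel sedation panel.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(cohort, panel, path) {
  validate_cohort(cohort); validate_panel(panel)
  key_c <- paste(cohort$patient_id, cohort$wave)
  key_p <- paste(panel$patient_id, panel$wave)
  m <- match(key_c, key_p)
  if (anyNA(m)) stop("panel is missing rows for some cohort (patient, wave)")
  out <- cbind(cohort[, c("patient_id", "wave")],
               level = panel$level[m],
               cohort[, setdiff(names(cohort), c("patient_id", "wave"))])
  out <- out[order(out$patient_id, out$wave), panel_columns]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a combined sedation CSV
#'
#' Validates and splits the long-format CSV written by [write_panel()] into
#' a cohort table and a sedation panel. Duplicate (patient, wave) rows and
#' levels outside 1..6 are rejected with the offending row numbers; unknown
#' extra columns produce a warning and are dropped.
#'
#' @param path CSV path.
#' @return list with elements `cohort` and `panel`.
#' @export
read_panel <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(panel_columns, names(raw))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  extra <- setdiff(names(raw), panel_columns)
  if (length(extra))
    warning("ignoring unknown columns: ", paste(extra, collapse = ", "))
  raw <- raw[, panel_columns]
  lev <- suppressWarnings(as.integer(raw$level))
  bad <- which(is.na(lev) | lev < 1L | lev > 6L)
  if (length(bad))
    stop("level outside 1..6 in rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  raw$level <- lev
  key <- paste(raw$patient_id, raw$wave)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (patient_id, wave) rows: ",
         paste(utils::head(dup, 10), collapse = ", "))
  raw <- raw[order(raw$patient_id, raw$wave), , drop = FALSE]
  cohort <- raw[, setdiff(panel_columns, "level")]
  cohort$group <- factor(cohort$group, levels = c("M", "D", "L", "C"))
  if (anyNA(cohort$group)) stop("group must be one of M, D, L, C")
  class(cohort) <- c("sed_cohort", "data.frame")
  panel <- raw[, c("patient_id", "wave", "level")]
  class(panel) <- c("sed_panel", "data.frame")
  rownames(cohort) <- rownames(panel) <- NULL
  list(cohort = cohort, panel = panel)
}

#' Write a ground-truth record as JSON
#' @param truth a [truth_record()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sed_truth"))
  obj <- list(variant = truth$variant$id,
              beta = truth$beta,
              gamma = truth$gamma,
              Sigma = truth$Sigma,
              baseline = truth$baseline,
              include_intercept = truth$include_intercept,
              standardize = truth$standardize,
              wave1 = truth$wave1)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' End-to-end pipeline: read/simulate, fit, diagnose, compare, summarise
#'
#' Runs the full analysis for one configuration and writes the artifact
#' directory: `draws.csv` (retained draws), `summary.csv` (posterior
#' summaries), `dic.csv` (DIC and DIC*), `diagnostics.csv` (when at least
#' two chains were run), and `manifest.json` (settings, seed, acceptance
#' rates). Fully deterministic given the seed. On failure a `FAILED` marker
#' file with the error message is left next to any partial outputs.
#'
#' @param config list with elements `data` (path to a combined CSV),
#'   `variant` (1..5), `out` (output directory), and optionally `contrast`,
#'   `priors` ([prior_spec()]), `settings` ([mcmc_settings()]),
#'   `include_intercept`, `standardize`.
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  need <- c("data", "variant", "out")
  miss <- setdiff(need, names(config))
  if (length(miss)) stop("config is missing: ", paste(miss, collapse = ", "))
  if (!file.exists(config$data)) stop("data file not found: ", config$data)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok) writeLines(geterrmessage(),
                              file.path(config$out, "FAILED")), add = TRUE)

  priors <- config$priors %||% prior_spec()
  settings <- config$settings %||% mcmc_settings()
  dat <- read_panel(config$data)
  fit <- fit_variant(dat$panel, dat$cohort, config$variant,
                     contrast = config$contrast %||% NULL,
                     priors = priors, settings = settings,
                     include_intercept = isTRUE(config$include_intercept),
                     standardize = isTRUE(config$standardize))
  utils::write.csv(cbind(chain = fit$chain, as.data.frame(fit$draws),
                         deviance = fit$deviance),
                   file.path(config$out, "draws.csv"), row.names = FALSE)
  utils::write.csv(summarize_draws(fit),
                   file.path(config$out, "summary.csv"), row.names = FALSE)
  d <- compute_dic(fit, "all"); ds <- compute_dic(fit, "23")
  utils::write.csv(data.frame(variant = d$variant,
                              Dbar = d$Dbar, Dhat = d$Dhat, pD = d$pD,
                              DIC = d$DIC, DIC_star = ds$DIC,
                              pD_star = ds$pD),
                   file.path(config$out, "dic.csv"), row.names = FALSE)
  if (settings$chains >= 2L && nrow(fit$draws) >= 100L)
    utils::write.csv(convergence_diagnostics(fit),
                     file.path(config$out, "diagnostics.csv"),
                     row.names = FALSE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("sedbayes")),
    data = normalizePath(config$data),
    variant = as_variant(config$variant)$id,
    contrast = config$contrast %||% NA,
    include_intercept = isTRUE(config$include_intercept),
    standardize = isTRUE(config$standardize),
    priors = unclass(priors),
    settings = unclass(settings),
    accept = as.list(fit$accept))
  jsonlite::write_json(manifest, file.path(config$out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  ok <- TRUE
  invisible(config$out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
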