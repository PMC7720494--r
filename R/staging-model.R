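#' Fit the complete modified-N staging model on a training cohort
#'
#' Runs the whole derivation on one cohort: (1) a multivariate Cox fit of
#' the positive- and negative-node counts (optionally adjusted for further
#' covariates), (2) delta-HR weights and the ratio coefficient, (3) the
#' per-patient re-adjusted N ratio, and (4) the minimum-p log-rank scan for
#' the two stage cutpoints. The returned model is self-contained: it can
#' stage any cohort via [stage_cohort()] and round-trips through
#' [write_staging_model()] / [read_staging_model()], which is the unit of
#' train-to-validation transfer.
#'
#' @param data Training cohort.
#' @param adjust_for Extra covariate columns entering the Cox fit alongside
#'   the node counts (their coefficients are estimated but do not enter the
#'   weights).
#' @param pln,nln,time,event Column names.
#' @param config An [nratio_config()].
#' @param min_group_frac,max_cutpoints Scan constraints, see [scan_cutpoints()].
#' @return An `nratio_model`: `weights`, `cutoffs`, `config`, `scan`
#'   (the full [scan_cutpoints()] result), `cox` (the `cox_fit`), and `n_train`.
#' @export
fit_staging_model <- function(data, adjust_for = character(),
                              pln = "n_pln", nln = "n_nln",
                              time = "survival_months", event = "event",
                              config = nratio_config(),
                              min_group_frac = 0.05, max_cutpoints = 100L) {
  assert_cols(data, c(pln, nln, time, event), "training cohort")
  cox <- fit_cox(data, c(pln, nln, adjust_for), mode = "multivariate",
                 time = time, event = event)
  tab <- tidy(cox)
  hr_pln <- tab$hazard_ratio[tab$term == pln]
  hr_nln <- tab$hazard_ratio[tab$term == nln]
  assert_that(length(hr_pln) == 1 && length(hr_nln) == 1 &&
                is.finite(hr_pln) && is.finite(hr_nln),
              "Cox fit did not yield finite hazard ratios for both node counts")
  weights <- nratio_weights(hr_pln, hr_nln)

  staged <- add_n_ratio(data, weights, config, pln = pln, nln = nln)
  scan <- scan_cutpoints(staged, ratio = "n_ratio", time = time, event = event,
                         min_group_frac = min_group_frac,
                         max_cutpoints = max_cutpoints)

  structure(
    list(weights = weights, cutoffs = scan$cutoffs, config = config,
         scan = scan, cox = cox, n_train = nrow(data),
         columns = list(pln = pln, nln = nln, time = time, event = event)),
    class = "nratio_model"
  )
}

#' Stage a cohort with a fitted staging model
#'
#' @param data Cohort to stage (any cohort with the model's node-count
#'   columns; typically the validation split).
#' @param model An `nratio_model` from [fit_staging_model()] or
#'   [read_staging_model()].
#' @return `data` with `n_ratio` and `modified_stage` columns appended.
#' @export
stage_cohort <- function(data, model) {
  assert_that(inherits(model, "nratio_model"), "model must be an nratio_model")
  staged <- add_n_ratio(data, model$weights, model$config,
                        pln = model$columns$pln, nln = model$columns$nln)
  dplyr::mutate(staged, modified_stage = assign_stage(.data$n_ratio, model$cutoffs))
}

#' @export
print.nratio_model <- function(x, ...) {
  cat(sprintf("<nratio_model> trained on %d patients\n", x$n_train))
  print(x$weights)
  print(x$cutoffs)
  if (!is.null(x$scan$grid)) {
    cat(sprintf("  scan: min p = %.3g over %d feasible pairs\n",
                x$scan$p_min, nrow(x$scan$grid)))
  } else {
    cat(sprintf("  scan (reloaded summary): min p = %.3g\n", x$scan$p_min))
  }
  invisible(x)
}

#' @export
tidy.nratio_model <- function(x, ...) {
  tibble::tibble(
    quantity = c("hr_pln", "hr_nln", "delta_pos", "delta_neg", "n_ratio_coef",
                 "c1", "c2"),
    value = c(x$weights$hr_pln, x$weights$hr_nln, x$weights$delta_pos,
              x$weights$delta_neg, x$weights$coef, x$cutoffs$c1, x$cutoffs$c2)
  )
}

#' @export
glance.nratio_model <- function(x, ...) {
  tibble::tibble(
    n_train = x$n_train,
    hr_pln = x$weights$hr_pln, hr_nln = x$weights$hr_nln,
    n_ratio_coef = x$weights$coef,
    c1 = x$cutoffs$c1, c2 = x$cutoffs$c2,
    scan_p_min = x$scan$p_min,
    scan_p_miller_siegmund = x$scan$p_miller_siegmund
  )
}

#' Serialize a staging model to JSON
#'
#' Writes the weights, cutoffs, zero-count configuration and scan summary to
#' a JSON file that [read_staging_model()] can reload; the file carries
#' everything needed to stage new patients, so it is the transferable unit
#' between the training and validation populations.
#'
#' @param model An `nratio_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_staging_model <- function(model, path) {
  assert_that(inherits(model, "nratio_model"), "model must be an nratio_model")
  payload <- list(
    format = "nodalratio/staging-model",
    version = 1L,
    weights = model$weights[c("hr_pln", "hr_nln", "delta_pos", "delta_neg", "coef")],
    cutoffs = list(c1 = model$cutoffs$c1, c2 = model$cutoffs$c2,
                   convention = model$cutoffs$convention),
    config = list(zero_substitute = model$config$zero_substitute,
                  both_zero_value = model$config$both_zero_value,
                  pln_zero_policy = model$config$pln_zero_policy),
    columns = model$columns,
    n_train = model$n_train,
    scan = list(p_min = model$scan$p_min,
                p_miller_siegmund = model$scan$p_miller_siegmund,
                chi_square = model$scan$chi_square,
                min_group_frac = model$scan$min_group_frac,
                n_staged = model$scan$n_staged,
                n_zero = model$scan$n_zero)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Reload a staging model serialized by [write_staging_model()]
#'
#' @param path JSON path.
#' @return An `nratio_model` capable of staging cohorts. The Cox fit and the
#'   full scan grid are not serialized; only the scan summary is restored.
#' @export
read_staging_model <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  assert_that(identical(payload$format, "nodalratio/staging-model"),
              "not a staging-model JSON file")
  weights <- nratio_weights(payload$weights$hr_pln, payload$weights$hr_nln)
  config <- nratio_config(zero_substitute = payload$config$zero_substitute,
                          pln_zero_policy = payload$config$pln_zero_policy)
  structure(
    list(weights = weights,
         cutoffs = stage_cutoffs(payload$cutoffs$c1, payload$cutoffs$c2),
         config = config,
         scan = payload$scan,
         cox = NULL,
         n_train = payload$n_train,
         columns = payload$columns),
    class = "nratio_model"
  )
}
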