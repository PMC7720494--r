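#' Fit Cox proportional-hazards models to a cohort
#'
#' Fits either one multivariate model over all `covariates` or a series of
#' univariate models (one per covariate), with Efron handling of tied event
#' times — survival is recorded in whole months, so ties are the norm.
#' Estimation is delegated to [survival::coxph()] (Newton-Raphson,
#' coefficient tolerance 1e-9, at most 100 iterations); this package wraps
#' it in a tidy result.
#'
#' @param data Cohort data frame.
#' @param covariates Character vector of covariate column names (numeric or
#'   categorical; factors are expanded to model terms).
#' @param mode `"multivariate"` (default) or `"univariate"`.
#' @param time,event Column names of the follow-up time and event indicator.
#' @return A `cox_fit` object. `tidy()` gives one row per model term:
#'   `model`, `term`, `estimate` (log-hazard), `hazard_ratio`, `std_error`,
#'   `conf_low`/`conf_high` (95% Wald, HR scale), `p_value` (Wald), and
#'   `non_identifiable` for terms dropped as singular. `glance()` gives
#'   `n`, `n_events`, and the multivariate partial log-likelihood.
#' @export
fit_cox <- function(data, covariates, mode = c("multivariate", "univariate"),
                    time = "survival_months", event = "event") {
  mode <- match.arg(mode)
  assert_cols(data, c(time, event, covariates), "cohort")
  assert_that(length(covariates) >= 1, "at least one covariate is required")
  assert_that(sum(data[[event]] == 1, na.rm = TRUE) >= 1,
              "degenerate data: no events in cohort, Cox model cannot be fit")

  fit_one <- function(covs, label) {
    f <- as.formula(sprintf(
      "survival::Surv(%s, %s) ~ %s",
      time, event, paste(sprintf("`%s`", covs), collapse = " + ")
    ))
    fit <- withCallingHandlers(
      survival::coxph(f, data = data, ties = "efron",
                      control = survival::coxph.control(eps = 1e-9, iter.max = 100)),
      warning = function(w) {
        if (grepl("singular|infinite|not converge|beta may be infinite",
                  conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    s <- summary(fit)
    coefs <- s$coefficients
    ci <- s$conf.int
    tibble::tibble(
      model = label,
      term = rownames(coefs),
      estimate = unname(coefs[, "coef"]),
      hazard_ratio = unname(coefs[, "exp(coef)"]),
      std_error = unname(coefs[, "se(coef)"]),
      conf_low = unname(ci[, "lower .95"]),
      conf_high = unname(ci[, "upper .95"]),
      p_value = unname(coefs[, "Pr(>|z|)"]),
      non_identifiable = unname(is.na(coefs[, "coef"]))
    )
  }

  if (mode == "multivariate") {
    table <- fit_one(covariates, "multivariate")
    f_full <- as.formula(sprintf(
      "survival::Surv(%s, %s) ~ %s",
      time, event, paste(sprintf("`%s`", covariates), collapse = " + ")
    ))
    fit_full <- survival::coxph(f_full, data = data, ties = "efron",
                                control = survival::coxph.control(eps = 1e-9, iter.max = 100))
    loglik <- fit_full$loglik[length(fit_full$loglik)]
    n_events <- fit_full$nevent
    n_used <- fit_full$n
  } else {
    table <- purrr::map_dfr(covariates, function(cv) fit_one(cv, cv))
    loglik <- NA_real_
    n_events <- sum(data[[event]] == 1, na.rm = TRUE)
    n_used <- nrow(data)
  }

  structure(
    list(table = table, mode = mode, n = n_used, n_events = n_events,
         loglik = loglik, time = time, event = event),
    class = "cox_fit"
  )
}

#' @export
tidy.cox_fit <- function(x, ...) x$table

#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(n = x$n, n_events = x$n_events, loglik = x$loglik, mode = x$mode)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> %s model, n = %d, events = %d\n", x$mode, x$n, x$n_events))
  print(x$table, ...)
  invisible(x)
}

#' Write a Cox fit as a tidy CSV table
#'
#' One row per model term (term, coefficient, HR, CI, p), mirroring the
#' layout of a published uni-/multivariate Cox regression table.
#'
#' @param fit A `cox_fit` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cox_table <- function(fit, path) {
  assert_that(inherits(fit, "cox_fit"), "fit must be a cox_fit object")
  readr::write_csv(tidy(fit), path)
  invisible(path)
}
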