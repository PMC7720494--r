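#' Random train/validation split of a cohort
#'
#' Partitions a cohort into disjoint training and validation sets, either
#' with an exact target size (`round(fraction * n)` training records, the
#' default — published split sizes of near-equal halves imply exact
#' randomization) or by independent Bernoulli assignment.
#'
#' @param data Cohort data frame (>= 2 records).
#' @param fraction Target training fraction in (0, 1).
#' @param seed Integer seed; the split is deterministic given `seed`.
#' @param mode `"exact"` or `"bernoulli"`.
#' @return A `cohort_split` list: `train`, `validation`, `seed`, `fraction`,
#'   `mode`. Train and validation are disjoint and their union is the input.
#' @export
split_cohort <- function(data, fraction = 0.5, seed = 1L,
                         mode = c("exact", "bernoulli")) {
  mode <- match.arg(mode)
  assert_that(is.data.frame(data) && nrow(data) >= 2,
              "empty input: need at least 2 records to split")
  assert_that(fraction > 0 && fraction < 1, "fraction must lie in (0, 1)")
  n <- nrow(data)
  in_train <- withr::with_seed(as.integer(seed), {
    if (mode == "exact") {
      idx <- sample.int(n, size = round(fraction * n))
      seq_len(n) %in% idx
    } else {
      runif(n) < fraction
    }
  })
  structure(
    list(train = data[in_train, , drop = FALSE],
         validation = data[!in_train, , drop = FALSE],
         seed = as.integer(seed), fraction = fraction, mode = mode),
    class = "cohort_split"
  )
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf("<cohort_split> %s split (fraction %.2f, seed %d): train %d / validation %d\n",
              x$mode, x$fraction, x$seed, nrow(x$train), nrow(x$validation)))
  invisible(x)
}

#' Cross-validate the modified staging across a train/validation pair
#'
#' Implements the validation design of the staging procedure: the staging
#' model (Cox weights and scan cutoffs) is fit on the training cohort only
#' and then frozen; both cohorts are staged with it, and each is summarised
#' by per-stage Kaplan-Meier curves and a k-group log-rank test across the
#' occupied stages.
#'
#' @param train,validation Cohort data frames, both non-empty with events.
#' @param ... Passed to [fit_staging_model()] (e.g. `adjust_for`,
#'   `min_group_frac`, `config`).
#' @return A `cv_report`: `model`, staged `train` and `validation` tibbles,
#'   `logrank` (tibble of cohort, chi_square, df, p_value), and `km`
#'   (stacked per-stage KM curves with `cohort` and `group` columns).
#' @export
crossvalidate_staging <- function(train, validation, ...) {
  assert_that(is.data.frame(train) && nrow(train) > 0, "empty input: training cohort")
  assert_that(is.data.frame(validation) && nrow(validation) > 0,
              "empty input: validation cohort")
  model <- tryCatch(
    fit_staging_model(train, ...),
    error = function(e) {
      abort(sprintf("staging-model fit on the training cohort failed: %s",
                    conditionMessage(e)))
    }
  )
  tcol <- model$columns$time
  ecol <- model$columns$event

  staged <- list(train = stage_cohort(train, model),
                 validation = stage_cohort(validation, model))
  logrank <- purrr::imap_dfr(staged, function(d, nm) {
    d <- dplyr::filter(d, !is.na(.data$modified_stage))
    d$modified_stage <- droplevels(d$modified_stage)
    res <- logrank_test(d, "modified_stage", time = tcol, event = ecol)
    dplyr::bind_cols(tibble::tibble(cohort = nm), tibble::as_tibble(res))
  })
  km <- purrr::imap_dfr(staged, function(d, nm) {
    d <- dplyr::filter(d, !is.na(.data$modified_stage))
    curves <- km_by_group(d, "modified_stage", time = tcol, event = ecol)
    dplyr::bind_cols(tibble::tibble(cohort = nm), curves)
  })

  structure(
    list(model = model, train = staged$train, validation = staged$validation,
         logrank = logrank, km = km),
    class = "cv_report"
  )
}

#' @export
tidy.cv_report <- function(x, ...) x$logrank

#' @export
glance.cv_report <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$model),
    tibble::tibble(
      p_logrank_train = x$logrank$p_value[x$logrank$cohort == "train"],
      p_logrank_validation = x$logrank$p_value[x$logrank$cohort == "validation"]
    )
  )
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report>\n")
  print(x$model)
  print(x$logrank)
  invisible(x)
}

#' @export
autoplot.cv_report <- function(object, ...) {
  anchors <- dplyr::distinct(object$km, .data$cohort, .data$group) |>
    dplyr::mutate(time = 0, survival = 1)
  ggplot2::ggplot(object$km,
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = factor(.data$group))) +
    ggplot2::geom_step(data = dplyr::bind_rows(anchors, object$km)) +
    ggplot2::facet_wrap(~cohort) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Survival probability", colour = "Modified N") +
    ggplot2::theme_minimal()
}

# one ROC curve for an ordinal score against a binary outcome; thresholds are
# the distinct score values, predictions "score >= threshold"
roc_curve_ordinal <- function(score, outcome) {
  pos <- sum(outcome == 1)
  neg <- sum(outcome == 0)
  thr <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(score >= t & outcome == 1) / pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(score >= t & outcome == 0) / neg, numeric(1))
  tibble::tibble(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}

#' Compare two ordinal staging systems by ROC against vital status
#'
#' Treats each staging as an ordinal score for the binary death outcome
#' (vital status at end of follow-up; censoring times are ignored, matching
#' the conventional fixed-endpoint ROC used to compare staging systems) and
#' computes each system's ROC curve and trapezoidal AUC. With midpoint
#' handling of ties the trapezoidal AUC equals the rank-sum (concordance)
#' estimator.
#'
#' @param data Staged cohort.
#' @param modified,comparator Column names of the two ordinal stage columns
#'   (ordered factors or numeric codes).
#' @param event Column name of the binary death outcome.
#' @return A `roc_comparison`: `auc` (tibble of system, auc), `curves`
#'   (tibble of system, threshold, fpr, tpr; each curve runs from (0,0) to
#'   (1,1)), and the outcome convention string.
#' @export
roc_compare <- function(data, modified = "modified_stage", comparator = "ajcc_n",
                        event = "event") {
  assert_cols(data, c(modified, comparator, event))
  outcome <- data[[event]]
  assert_that(all(outcome %in% c(0, 1)), "outcome must be binary 0/1")
  assert_that(length(unique(outcome)) == 2,
              "degenerate data: ROC needs both deaths and survivors")
  as_score <- function(x) if (is.numeric(x)) x else as.numeric(factor(x, ordered = TRUE))

  systems <- list(modified = as_score(data[[modified]]),
                  comparator = as_score(data[[comparator]]))
  curves <- purrr::imap_dfr(systems, function(s, nm) {
    dplyr::bind_cols(tibble::tibble(system = nm), roc_curve_ordinal(s, outcome))
  })
  auc <- curves |>
    dplyr::group_by(.data$system) |>
    dplyr::summarise(auc = trapezoid_auc(.data$fpr, .data$tpr), .groups = "drop")

  structure(
    list(auc = auc, curves = curves,
         auc_modified = auc$auc[auc$system == "modified"],
         auc_comparator = auc$auc[auc$system == "comparator"],
         outcome = "vital status at end of follow-up (censoring time ignored)"),
    class = "roc_comparison"
  )
}

#' @export
tidy.roc_comparison <- function(x, ...) x$curves

#' @export
glance.roc_comparison <- function(x, ...) {
  tibble::tibble(auc_modified = x$auc_modified, auc_comparator = x$auc_comparator)
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf("<roc_comparison> AUC modified = %.3f, comparator = %.3f (outcome: %s)\n",
              x$auc_modified, x$auc_comparator, x$outcome))
  invisible(x)
}

#' @export
autoplot.roc_comparison <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr, colour = .data$system)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate") +
    ggplot2::theme_minimal()
}
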