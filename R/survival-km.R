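#' Kaplan-Meier product-limit estimate
#'
#' First-party product-limit estimator. At each distinct observed time the
#' step is `1 - d/n` with `d` events among `n` at risk; censored subjects
#' tied with events at the same time are counted as at risk for that time
#' (standard convention: events precede censorings at a tied time).
#'
#' @param data Data frame of one row per subject.
#' @param time,event Column names of follow-up time (>= 0) and event
#'   indicator (1 = event, 0 = censored).
#' @return A `km_curve` tibble with one row per distinct observed time:
#'   `time`, `n_risk`, `n_event`, `n_censor`, `survival`. The curve starts
#'   implicitly at S(0) = 1; with no censoring it equals one minus the
#'   empirical CDF at every event time.
#' @export
km_estimate <- function(data, time = "survival_months", event = "event") {
  assert_cols(data, c(time, event))
  times <- data[[time]]
  events <- data[[event]]
  check_surv_inputs(times, events)

  u <- sort(unique(times))
  ti <- match(times, u)
  d <- tabulate(ti[events == 1], nbins = length(u))
  cns <- tabulate(ti[events == 0], nbins = length(u))
  n_risk <- rev(cumsum(rev(d + cns)))
  surv <- cumprod(1 - d / n_risk)

  out <- tibble::tibble(
    time = u, n_risk = n_risk, n_event = d, n_censor = cns, survival = surv
  )
  class(out) <- c("km_curve", class(out))
  attr(out, "n") <- length(times)
  out
}

#' Kaplan-Meier curves by group
#'
#' Convenience wrapper computing one [km_estimate()] per level of a grouping
#' column, stacked into a single tibble for plotting or reporting.
#'
#' @inheritParams km_estimate
#' @param group Column name of the grouping variable.
#' @return A tibble with a `group` column followed by the `km_curve` columns.
#' @export
km_by_group <- function(data, group, time = "survival_months", event = "event") {
  assert_cols(data, c(group, time, event))
  g <- data[[group]]
  purrr::map_dfr(split(data, g), function(d) {
    curve <- km_estimate(d, time = time, event = event)
    dplyr::bind_cols(tibble::tibble(group = d[[group]][1]), tibble::as_tibble(curve))
  })
}

#' @export
autoplot.km_curve <- function(object, ...) {
  df <- step_expand(tibble::as_tibble(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Survival probability") +
    ggplot2::theme_minimal()
}

# prepend the S(0) = 1 anchor so geom_step starts at the origin
step_expand <- function(df) {
  dplyr::bind_rows(
    tibble::tibble(time = 0, n_risk = NA_real_, n_event = NA_real_,
                   n_censor = NA_real_, survival = 1),
    df
  )
}

#' Plot Kaplan-Meier curves for a staged cohort
#'
#' @inheritParams km_by_group
#' @return A ggplot object of step curves, one per group.
#' @export
plot_km <- function(data, group, time = "survival_months", event = "event") {
  curves <- km_by_group(data, group, time = time, event = event)
  anchors <- dplyr::distinct(curves, .data$group) |>
    dplyr::mutate(time = 0, survival = 1)
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$time, y = .data$survival,
                               colour = factor(.data$group))) +
    ggplot2::geom_step(data = dplyr::bind_rows(anchors, curves)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Survival probability", colour = group) +
    ggplot2::theme_minimal()
}
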