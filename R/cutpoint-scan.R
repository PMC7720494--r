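#' Minimum-p-value scan for the two stage cutpoints
#'
#' Enumerates candidate cutpoint pairs (c1, c2) drawn from the distinct
#' observed re-adjusted ratios of staged patients (ratio > 0; patients with
#' ratio 0 are fixed at N0 and excluded from the scan, as in X-tile-style
#' optimal-cutpoint searches). For every feasible pair — each of the three
#' groups `(0,c1]`, `(c1,c2]`, `(c2,Inf)` at least `min_group_frac` of the
#' staged patients — the 3-group log-rank statistic is computed, and the
#' pair with the smallest p-value is selected.
#'
#' Ties in the minimum p (within 1e-12) are broken by the larger smallest
#' group, then by the lexicographically smaller (c1, c2). The selected
#' minimum p is reported raw (as is conventional for this procedure) along
#' with a Miller-Siegmund-corrected p for information; the correction is
#' the single-cutpoint formula evaluated at `min_group_frac` and is an
#' approximation for the two-cutpoint scan.
#'
#' When the staged patients carry more than `max_cutpoints` distinct ratio
#' values, the candidate set is thinned to an evenly spaced subset of the
#' observed values (the scan is quadratic in the number of candidates).
#'
#' @param data Data frame with ratio, time and event columns.
#' @param ratio,time,event Column names.
#' @param min_group_frac Minimum fraction of staged patients per group.
#' @param max_cutpoints Cap on the number of candidate cut values.
#' @return A `cutpoint_scan` object: `grid` (tibble of `c1`, `c2`, `n1`,
#'   `n2`, `n3`, `chi_square`, `p_value` over all feasible pairs), `cutoffs`
#'   (a [stage_cutoffs()]), `p_min`, `p_miller_siegmund`, `chi_square`,
#'   plus the constraint settings and staged/zero patient counts.
#' @export
scan_cutpoints <- function(data, ratio = "n_ratio", time = "survival_months",
                           event = "event", min_group_frac = 0.05,
                           max_cutpoints = 100L) {
  assert_cols(data, c(ratio, time, event))
  assert_that(min_group_frac > 0 && min_group_frac < 1/3,
              "min_group_frac must lie in (0, 1/3)")
  r_all <- data[[ratio]]
  assert_that(all(!is.na(r_all)) && all(r_all >= 0), "ratios must be non-missing and >= 0")
  staged <- r_all > 0
  n_zero <- sum(!staged)
  r <- r_all[staged]
  times <- data[[time]][staged]
  events <- data[[event]][staged]
  check_surv_inputs(times, events)
  assert_that(sum(events) >= 1, "degenerate data: no events among staged patients")

  cand <- sort(unique(r))
  assert_that(length(cand) >= 3,
              "degenerate data: need at least 3 distinct positive ratio values to place two cutpoints")
  if (length(cand) > max_cutpoints) {
    keep <- unique(round(seq(1, length(cand), length.out = max_cutpoints)))
    cand <- cand[keep]
  }
  m <- length(cand)
  n_staged <- length(r)
  min_size <- max(1, ceiling(min_group_frac * n_staged))

  # membership index: g = smallest candidate index i with r <= cand[i]
  g <- findInterval(r, cand, left.open = TRUE) + 1L
  sz <- cumsum(tabulate(g, nbins = m))          # patients with ratio <= cand[i]

  # prefix event / at-risk matrices over event times x candidate index
  u <- sort(unique(times[events == 1]))
  D <- length(u)
  ev <- events == 1
  ti <- match(times, u)
  dmat <- matrix(as.numeric(table(factor(ti[ev], levels = seq_len(D)),
                                  factor(g[ev], levels = seq_len(m)))), D, m)
  E <- t(apply(dmat, 1, cumsum))                # events at u_t with ratio <= cand[i]
  if (D == 1) E <- matrix(E, 1, m)
  b <- findInterval(times, u)
  cnt <- matrix(as.numeric(table(factor(b, levels = 0:D),
                                 factor(g, levels = seq_len(m)))), D + 1, m)
  cnt <- t(apply(cnt, 1, cumsum))
  if (D == 0) abort("degenerate data: no event times among staged patients")
  A <- apply(cnt[-1, , drop = FALSE], 2, function(col) rev(cumsum(rev(col))))
  A <- matrix(A, D, m)                          # at risk at u_t with ratio <= cand[i]

  n_tot <- A[, m]
  d_tot <- E[, m]
  cfac <- ifelse(n_tot > 1, d_tot * (n_tot - d_tot) / (n_tot - 1), 0)
  e_frac <- ifelse(n_tot > 0, d_tot / n_tot, 0)

  rows <- list()
  best_frac <- 0
  idx <- 0L
  for (i in seq_len(m - 2L)) {
    for (j in seq.int(i + 1L, m - 1L)) {
      n1s <- sz[i]; n2s <- sz[j] - sz[i]; n3s <- n_staged - sz[j]
      best_frac <- max(best_frac, min(n1s, n2s, n3s) / n_staged)
      if (n1s < min_size || n2s < min_size || n3s < min_size) next
      n1 <- A[, i]; n2 <- A[, j] - A[, i]
      d1 <- E[, i]; d2 <- E[, j] - E[, i]
      p1 <- ifelse(n_tot > 0, n1 / n_tot, 0)
      p2 <- ifelse(n_tot > 0, n2 / n_tot, 0)
      oe1 <- sum(d1 - e_frac * n1)
      oe2 <- sum(d2 - e_frac * n2)
      v11 <- sum(cfac * p1 * (1 - p1))
      v22 <- sum(cfac * p2 * (1 - p2))
      v12 <- -sum(cfac * p1 * p2)
      det <- v11 * v22 - v12 * v12
      if (!is.finite(det) || det <= 1e-300) next
      stat <- (oe1^2 * v22 - 2 * oe1 * oe2 * v12 + oe2^2 * v11) / det
      stat <- max(0, stat)
      idx <- idx + 1L
      rows[[idx]] <- c(cand[i], cand[j], n1s, n2s, n3s, stat)
    }
  }
  if (idx == 0L) {
    abort(sprintf(
      "constraint error: no feasible cutpoint pair at min_group_frac = %.3g (tightest feasible fraction is %.3g)",
      min_group_frac, best_frac))
  }
  grid <- do.call(rbind, rows)
  grid <- tibble::tibble(
    c1 = grid[, 1], c2 = grid[, 2],
    n1 = as.integer(grid[, 3]), n2 = as.integer(grid[, 4]), n3 = as.integer(grid[, 5]),
    chi_square = grid[, 6],
    p_value = pchisq(grid[, 6], df = 2, lower.tail = FALSE)
  )

  p_min <- min(grid$p_value)
  tied <- which(grid$p_value <= p_min + 1e-12)
  if (length(tied) > 1) {
    min_sz <- pmin(grid$n1[tied], pmin(grid$n2[tied], grid$n3[tied]))
    tied <- tied[min_sz == max(min_sz)]
    if (length(tied) > 1) {
      ord <- order(grid$c1[tied], grid$c2[tied])
      tied <- tied[ord[1]]
    }
  }
  sel <- tied[1]

  structure(
    list(
      grid = grid,
      cutoffs = stage_cutoffs(grid$c1[sel], grid$c2[sel]),
      chi_square = grid$chi_square[sel],
      p_min = grid$p_value[sel],
      p_miller_siegmund = miller_siegmund_p(grid$p_value[sel], min_group_frac),
      min_group_frac = min_group_frac,
      max_cutpoints = max_cutpoints,
      n_staged = n_staged,
      n_zero = n_zero,
      n_candidates = m
    ),
    class = "cutpoint_scan"
  )
}

# Miller & Siegmund small-epsilon correction for a minimum-p cutpoint search:
# informational approximation (derived for one cutpoint) reported next to the
# raw minimum p.
miller_siegmund_p <- function(p_min, eps) {
  if (!is.finite(p_min) || p_min >= 1) return(1)
  if (p_min <= 0) return(0)
  z <- qnorm(1 - p_min / 2)
  if (!is.finite(z)) return(p_min)
  if (z <= 0) return(1)
  p <- dnorm(z) * (z - 1 / z) * log((1 - eps)^2 / eps^2) + 4 * dnorm(z) / z
  min(1, max(p_min, p))
}

#' @export
tidy.cutpoint_scan <- function(x, ...) x$grid

#' @export
glance.cutpoint_scan <- function(x, ...) {
  tibble::tibble(
    c1 = x$cutoffs$c1, c2 = x$cutoffs$c2,
    chi_square = x$chi_square, p_min = x$p_min,
    p_miller_siegmund = x$p_miller_siegmund,
    n_staged = x$n_staged, n_zero = x$n_zero,
    n_candidates = x$n_candidates, min_group_frac = x$min_group_frac
  )
}

#' @export
print.cutpoint_scan <- function(x, ...) {
  cat(sprintf(
    "<cutpoint_scan> %d feasible pairs over %d candidates (%d staged, %d at ratio 0)\n",
    nrow(x$grid), x$n_candidates, x$n_staged, x$n_zero))
  cat(sprintf("  selected (c1, c2) = (%.4g, %.4g); chi2 = %.2f, min p = %.3g (Miller-Siegmund %.3g)\n",
              x$cutoffs$c1, x$cutoffs$c2, x$chi_square, x$p_min, x$p_miller_siegmund))
  invisible(x)
}

#' @export
autoplot.cutpoint_scan <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$c1, y = .data$c2,
                               fill = -log10(.data$p_value))) +
    ggplot2::geom_tile() +
    ggplot2::annotate("point", x = object$cutoffs$c1, y = object$cutoffs$c2,
                      shape = 4, size = 3) +
    ggplot2::labs(x = "c1", y = "c2", fill = "-log10 p") +
    ggplot2::theme_minimal()
}

#' Export a scan grid as CSV
#'
#' @param scan A `cutpoint_scan` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_scan_grid <- function(scan, path) {
  assert_that(inherits(scan, "cutpoint_scan"), "scan must be a cutpoint_scan object")
  readr::write_csv(scan$grid, path)
  invisible(path)
}
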