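#' K-group log-rank test
#'
#' First-party log-rank (Mantel-Cox) test for equality of survival across
#' two or more groups. At each distinct event time the observed events per
#' group are compared with their hypergeometric expectation given the risk
#' sets; the variance uses the usual multivariate hypergeometric form with
#' the `d(n-d)/(n-1)` tie factor (times with fewer than two subjects at risk
#' contribute no variance). The statistic is the quadratic form over the
#' first k-1 groups and is chi-square with k-1 degrees of freedom under the
#' null.
#'
#' @param data Data frame of one row per subject.
#' @param group Column name of the group labels.
#' @param time,event Column names of follow-up time and event indicator.
#' @return A `logrank_test` tibble: `chi_square`, `df`, `p_value`, `n`,
#'   `n_events`, `n_groups`.
#' @export
logrank_test <- function(data, group, time = "survival_months", event = "event") {
  assert_cols(data, c(group, time, event))
  times <- data[[time]]
  events <- data[[event]]
  check_surv_inputs(times, events)
  g <- as.integer(factor(data[[group]]))
  k <- max(g)
  assert_that(k >= 2, "degenerate data: log-rank test needs at least 2 non-empty groups")
  assert_that(sum(events) >= 1, "degenerate data: log-rank test needs at least 1 event")

  res <- logrank_core(times, events, g, k)
  out <- tibble::tibble(
    chi_square = res$stat, df = k - 1L,
    p_value = pchisq(res$stat, df = k - 1, lower.tail = FALSE),
    n = length(times), n_events = sum(events), n_groups = k
  )
  class(out) <- c("logrank_test", class(out))
  out
}

# O-E / V quadratic form over groups 1..k-1; shared by logrank_test and the
# brute-force path of the cutpoint scan.
logrank_core <- function(times, events, g, k) {
  u <- sort(unique(times[events == 1]))
  D <- length(u)
  ti <- match(times, u)                       # NA for times not at any event time

  # events per (event time, group)
  dmat <- matrix(0, D, k)
  ev <- events == 1
  if (any(ev)) {
    tab <- table(factor(ti[ev], levels = seq_len(D)), factor(g[ev], levels = seq_len(k)))
    dmat <- matrix(as.numeric(tab), D, k)
  }
  # at-risk per (event time, group): subjects with observed time >= u_t
  b <- findInterval(times, u)                 # number of event times <= time
  nmat <- matrix(0, D, k)
  cnt <- table(factor(b, levels = 0:D), factor(g, levels = seq_len(k)))
  cnt <- matrix(as.numeric(cnt), D + 1, k)
  for (j in seq_len(k)) {
    nmat[, j] <- rev(cumsum(rev(cnt[-1, j])))
  }

  n_tot <- rowSums(nmat)
  d_tot <- rowSums(dmat)
  ok <- n_tot > 0
  e_frac <- ifelse(ok, d_tot / n_tot, 0)
  cfac <- ifelse(n_tot > 1, d_tot * (n_tot - d_tot) / (n_tot - 1), 0)

  oe <- numeric(k - 1)
  V <- matrix(0, k - 1, k - 1)
  p <- nmat / ifelse(n_tot > 0, n_tot, 1)     # group at-risk proportions
  for (i in seq_len(k - 1)) {
    oe[i] <- sum(dmat[, i] - e_frac * nmat[, i])
    for (j in seq_len(k - 1)) {
      delta <- as.numeric(i == j)
      V[i, j] <- sum(cfac * p[, i] * (delta - p[, j]))
    }
  }
  stat <- tryCatch(
    drop(crossprod(oe, solve(V, oe))),
    error = function(e) {
      # singular variance (e.g. identical groups with no variation): use a
      # pseudo-inverse so degenerate comparisons yield a finite statistic
      sv <- svd(V)
      pos <- sv$d > max(sv$d) * 1e-12
      if (!any(pos)) return(0)
      Vinv <- sv$v[, pos, drop = FALSE] %*%
        (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
      drop(crossprod(oe, Vinv %*% oe))
    }
  )
  list(stat = max(0, stat), oe = oe, V = V)
}
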