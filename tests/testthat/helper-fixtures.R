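# Shared fixtures and independent oracles used across the suite.

# tiny survival fixture as a tibble
surv_df <- function(times, events, ...) {
  tibble::tibble(survival_months = times, event = events, ...)
}

# small random cohort with few distinct positive ratios, for scan-oracle work
random_scan_cohort <- function(n, seed) {
  withr::with_seed(seed, {
    n_pln <- sample(0:6, n, replace = TRUE, prob = c(4, 3, 2, 2, 1, 1, 1))
    n_nln <- sample(1:12, n, replace = TRUE)
    ratio <- readjusted_n_ratio(n_pln, n_nln, nratio_weights(1.064, 0.962))
    t_death <- rexp(n, rate = 0.05 * exp(0.8 * log1p(ratio)))
    censor <- runif(n, 0, 60)
    tibble::tibble(
      survival_months = pmax(1, ceiling(pmin(t_death, censor))),
      event = as.integer(t_death <= censor),
      n_ratio = ratio
    )
  })
}

# Independent brute-force cutpoint search: exhaustive double loop over all
# distinct positive ratio values, 3-group log-rank via logrank_test, same
# feasibility and tie-break rules as the spec'd selection.
brute_force_scan <- function(data, min_group_frac = 0.05,
                             ratio = "n_ratio", time = "survival_months",
                             event = "event") {
  staged <- data[data[[ratio]] > 0, , drop = FALSE]
  r <- staged[[ratio]]
  cand <- sort(unique(r))
  m <- length(cand)
  n_staged <- nrow(staged)
  min_size <- max(1, ceiling(min_group_frac * n_staged))
  best <- NULL
  for (i in seq_len(m - 2)) {
    for (j in seq.int(i + 1, m - 1)) {
      g <- ifelse(r <= cand[i], 1L, ifelse(r <= cand[j], 2L, 3L))
      sizes <- tabulate(g, 3)
      if (any(sizes < min_size)) next
      d <- staged
      d$grp <- g
      res <- logrank_test(d, "grp", time = time, event = event)
      row <- list(c1 = cand[i], c2 = cand[j], p = res$p_value,
                  min_size = min(sizes))
      if (is.null(best) ||
          row$p < best$p - 1e-12 ||
          (abs(row$p - best$p) <= 1e-12 &&
           (row$min_size > best$min_size ||
            (row$min_size == best$min_size &&
             (row$c1 < best$c1 || (row$c1 == best$c1 && row$c2 < best$c2)))))) {
        best <- row
      }
    }
  }
  best
}

# rank-sum (concordance) AUC oracle by exhaustive pair enumeration
rank_sum_auc <- function(score, outcome) {
  pos <- score[outcome == 1]
  neg <- score[outcome == 0]
  tot <- 0
  for (p in pos) {
    tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  }
  tot / (length(pos) * length(neg))
}
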