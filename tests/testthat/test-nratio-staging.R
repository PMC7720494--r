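test_that("delta-HR distances reproduce the published worked values", {
  expect_equal(nratio_delta_hr(1.064), 0.064, tolerance = 1e-12)
  expect_equal(nratio_delta_hr(0.962), 0.038, tolerance = 1e-12)
  expect_equal(nratio_delta_hr(1), 0)
  expect_error(nratio_delta_hr(0), "domain error")
  expect_error(nratio_delta_hr(-0.5), "domain error")
})

test_that("the weighting coefficient is the quotient of the two distances", {
  expect_equal(nratio_weight(0.064, 0.038), 0.064 / 0.038, tolerance = 1e-12)
  expect_equal(nratio_weight(0.5, 0.5), 1)
  expect_equal(nratio_weight(0, 0.038), 0)
  expect_error(nratio_weight(0.064, 0), "degenerate weight")
  w <- nratio_weights(1.064, 0.962)
  expect_equal(w$coef, 0.064 / 0.038, tolerance = 1e-9)
})

test_that("zero-count rules follow the stated conventions", {
  w <- nratio_weights(1.064, 0.962)
  expect_equal(readjusted_n_ratio(0, 0, w), 0)
  # single zero: substitute 0.0001 before dividing
  expect_equal(readjusted_n_ratio(0, 20, w), w$coef * 1e-4 / 20, tolerance = 1e-12)
  expect_equal(readjusted_n_ratio(3, 0, w), w$coef * 3 / 1e-4, tolerance = 1e-12)
  expect_equal(readjusted_n_ratio(5, 5, 1), 1)
  expect_error(readjusted_n_ratio(-1, 2, w), "domain error")
  expect_error(readjusted_n_ratio(1.5, 2, w), "domain error")
})

test_that("the clinical zero policy maps node-negative patients to ratio 0", {
  w <- nratio_weights(1.064, 0.962)
  clin <- nratio_config(pln_zero_policy = "clinical")
  expect_equal(readjusted_n_ratio(0, 20, w, clin), 0)
  expect_equal(readjusted_n_ratio(0, 0, w, clin), 0)
  # non-zero counts are unaffected by the policy
  expect_equal(readjusted_n_ratio(4, 8, w, clin), readjusted_n_ratio(4, 8, w))
})

test_that("the ratio is scale-invariant in the two counts", {
  w <- nratio_weights(1.08, 0.95)
  for (kmul in c(2L, 3L, 7L)) {
    expect_equal(readjusted_n_ratio(3L * kmul, 11L * kmul, w),
                 readjusted_n_ratio(3L, 11L, w), tolerance = 1e-12)
  }
})

test_that("stage assignment honours the left-open right-closed intervals", {
  cuts <- stage_cutoffs(0.08, 0.63)
  expect_equal(as.character(assign_stage(c(0, 0.05, 0.08, 0.2, 0.63, 0.6300001), cuts)),
               c("N0", "N1", "N1", "N2", "N2", "N3"))
  expect_error(assign_stage(-0.1, cuts), "domain error")
  expect_error(stage_cutoffs(0.63, 0.08), "c1 < c2")
  expect_error(stage_cutoffs(0, 0.5), "c1 < c2|0 < c1")
})

test_that("stage assignment is monotone in the ratio", {
  cuts <- stage_cutoffs(0.08, 0.63)
  r <- sort(withr::with_seed(1, c(0, runif(200, 0, 2))))
  stages <- assign_stage(r, cuts)
  expect_true(all(diff(as.integer(stages)) >= 0))
})

test_that("the scan recovers cutpoints bracketing constructed survival strata", {
  # three 20-patient strata with ratio bands [0.02,0.08], [0.2,0.4], [0.8,2]
  # and non-overlapping survival around medians 40 / 20 / 5 months: the
  # minimum-p pair must sit in the gaps between the bands
  d <- tibble::tibble(
    n_ratio = c(seq(0.02, 0.08, length.out = 20),
                seq(0.2, 0.4, length.out = 20),
                seq(0.8, 2, length.out = 20)),
    survival_months = c(seq(31, 50), seq(11, 30), rep(1:10, each = 2)),
    event = 1L
  )
  scan <- scan_cutpoints(d, min_group_frac = 0.1)
  expect_gte(scan$cutoffs$c1, 0.02)
  expect_lt(scan$cutoffs$c1, 0.2)
  expect_gte(scan$cutoffs$c2, 0.4)
  expect_lt(scan$cutoffs$c2, 0.8)
  expect_lt(scan$p_min, 1e-4)
  expect_gte(scan$p_miller_siegmund, scan$p_min)
})

test_that("the scan equals the exhaustive brute-force search", {
  for (seed in 1:6) {
    d <- random_scan_cohort(n = 120, seed = seed)
    scan <- scan_cutpoints(d, min_group_frac = 0.08)
    oracle <- brute_force_scan(d, min_group_frac = 0.08)
    expect_equal(scan$cutoffs$c1, oracle$c1)
    expect_equal(scan$cutoffs$c2, oracle$c2)
    expect_equal(scan$p_min, oracle$p, tolerance = 1e-8)
  }
})

test_that("the selected pair attains the grid minimum and sane group sizes", {
  d <- random_scan_cohort(n = 200, seed = 11)
  scan <- scan_cutpoints(d, min_group_frac = 0.1)
  expect_equal(scan$p_min, min(scan$grid$p_value))
  sel <- dplyr::filter(scan$grid, .data$c1 == scan$cutoffs$c1,
                       .data$c2 == scan$cutoffs$c2)
  n_staged <- scan$n_staged
  expect_gte(min(sel$n1, sel$n2, sel$n3), ceiling(0.1 * n_staged))
  expect_equal(sel$n1 + sel$n2 + sel$n3, n_staged)
})

test_that("scaling all ratios scales the cutoffs and keeps memberships", {
  d <- random_scan_cohort(n = 150, seed = 21)
  scan1 <- scan_cutpoints(d, min_group_frac = 0.08)
  d2 <- dplyr::mutate(d, n_ratio = n_ratio * 3.7)
  scan2 <- scan_cutpoints(d2, min_group_frac = 0.08)
  expect_equal(scan2$cutoffs$c1, 3.7 * scan1$cutoffs$c1, tolerance = 1e-9)
  expect_equal(scan2$cutoffs$c2, 3.7 * scan1$cutoffs$c2, tolerance = 1e-9)
  s1 <- assign_stage(d$n_ratio, scan1$cutoffs)
  s2 <- assign_stage(d2$n_ratio, scan2$cutoffs)
  expect_identical(s1, s2)
})

test_that("degenerate scans raise constraint errors", {
  # all staged ratios tied at one value: no 3-way split exists
  d <- tibble::tibble(n_ratio = rep(0.4, 30),
                      survival_months = rep(c(3, 9), 15),
                      event = 1L)
  expect_error(scan_cutpoints(d), "distinct")

  # feasible split impossible at this minimum fraction: error reports the
  # tightest achievable fraction
  d2 <- tibble::tibble(
    n_ratio = c(rep(0.1, 28), 0.5, 0.9),
    survival_months = ceiling(seq(1, 30)),
    event = 1L
  )
  expect_error(scan_cutpoints(d2, min_group_frac = 0.2), "tightest feasible")
})

test_that("staging models round-trip through JSON and stage identically", {
  co <- simulate_cohort(cohort_config(n_patients = 1500, seed = 13,
                                      log_hr_per_pln = log(1.15),
                                      log_hr_per_nln = log(0.93)))
  model <- fit_staging_model(co)
  path <- tempfile(fileext = ".json")
  write_staging_model(model, path)
  reloaded <- read_staging_model(path)
  expect_equal(reloaded$weights$coef, model$weights$coef, tolerance = 1e-12)
  expect_equal(reloaded$cutoffs$c1, model$cutoffs$c1, tolerance = 1e-12)
  s1 <- stage_cohort(co, model)
  s2 <- stage_cohort(co, reloaded)
  expect_identical(s1$modified_stage, s2$modified_stage)
  expect_equal(tidy(model)$value[tidy(model)$quantity == "n_ratio_coef"],
               model$weights$coef)
})
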