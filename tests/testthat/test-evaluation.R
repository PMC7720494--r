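test_that("exact splits hit the target sizes and partition the cohort", {
  co <- simulate_cohort(cohort_config(n_patients = 100, seed = 3))
  sp <- split_cohort(co, fraction = 0.5, seed = 8)
  expect_equal(nrow(sp$train), 50)
  expect_equal(nrow(sp$validation), 50)
  expect_length(intersect(sp$train$id, sp$validation$id), 0)
  expect_setequal(c(sp$train$id, sp$validation$id), co$id)
})

test_that("splits are deterministic under a seed", {
  co <- simulate_cohort(cohort_config(n_patients = 200, seed = 3))
  sp1 <- split_cohort(co, seed = 5)
  sp2 <- split_cohort(co, seed = 5)
  expect_identical(sp1$train, sp2$train)
  sp3 <- split_cohort(co, seed = 6)
  expect_false(identical(sp1$train$id, sp3$train$id))
})

test_that("Bernoulli splits concentrate near the target fraction", {
  co <- simulate_cohort(cohort_config(n_patients = 2000, seed = 4))
  diffs <- vapply(1:100, function(s) {
    sp <- split_cohort(co, seed = s, mode = "bernoulli")
    abs(nrow(sp$train) - nrow(sp$validation))
  }, numeric(1))
  # |train - valid| ~ |2*Binom(2000, .5) - 2000|; sd ~ 45, so < 150 nearly always
  expect_gte(mean(diffs < 150), 0.95)
  expect_error(split_cohort(co[0, ]), "at least 2")
  expect_error(split_cohort(co, fraction = 1.5), "\\(0, 1\\)")
})

test_that("cross-validation fits on training only and freezes the model", {
  co <- simulate_cohort(cohort_config(n_patients = 2000, seed = 17,
                                      log_hr_per_pln = log(1.15),
                                      log_hr_per_nln = log(0.93)))
  sp <- split_cohort(co, seed = 2)
  cv1 <- crossvalidate_staging(sp$train, sp$validation)

  # mutating every validation outcome must not change the staging model
  mutated <- sp$validation
  mutated$event <- 1L - mutated$event
  mutated$survival_months <- rev(mutated$survival_months)
  cv2 <- crossvalidate_staging(sp$train, mutated)
  p1 <- tempfile(fileext = ".json"); p2 <- tempfile(fileext = ".json")
  write_staging_model(cv1$model, p1)
  write_staging_model(cv2$model, p2)
  expect_identical(readLines(p1), readLines(p2))

  # staged outputs carry ratios and stages for every record
  expect_true(all(!is.na(cv1$validation$n_ratio)))
  expect_true(all(levels(cv1$validation$modified_stage) == c("N0", "N1", "N2", "N3")))
  expect_equal(nrow(cv1$logrank), 2)
})

test_that("cross-validation errors are surfaced with training context", {
  train <- tibble::tibble(
    survival_months = ceiling(seq(1, 40)), event = 1L,
    n_pln = 0L, n_nln = rep(10L, 40)
  )
  # all ratios identical -> the scan cannot place two cutpoints
  expect_error(
    crossvalidate_staging(train, train, config = nratio_config()),
    "training cohort failed"
  )
  expect_error(crossvalidate_staging(train[0, ], train), "empty input")
})

test_that("ROC handles perfect, null, and hand-countable orderings", {
  # perfect ordering: every death scored above every survivor
  d <- tibble::tibble(modified_stage = c(3, 3, 2, 1, 0, 0),
                      ajcc_n = c(3, 2, 3, 1, 0, 0),
                      event = c(1, 1, 1, 0, 0, 0))
  roc <- roc_compare(d)
  expect_equal(roc$auc_modified, 1)

  # permuted stage labels carry no information
  co <- simulate_cohort(cohort_config(n_patients = 5000, seed = 23))
  co$modified_stage <- withr::with_seed(1, sample(co$ajcc_n))
  roc_null <- roc_compare(co)
  expect_lt(abs(roc_null$auc_modified - 0.5), 0.03)

  # 8-patient fixture: AUC equals the exhaustive rank-sum oracle
  d8 <- tibble::tibble(
    modified_stage = c(0, 1, 1, 2, 2, 3, 0, 3),
    ajcc_n = c(0, 0, 1, 2, 1, 3, 2, 2),
    event = c(0, 0, 1, 0, 1, 1, 0, 1)
  )
  roc8 <- roc_compare(d8)
  expect_equal(roc8$auc_modified, rank_sum_auc(d8$modified_stage, d8$event),
               tolerance = 1e-12)
  expect_equal(roc8$auc_comparator, rank_sum_auc(d8$ajcc_n, d8$event),
               tolerance = 1e-12)

  # degenerate single-class outcome
  d_one <- dplyr::mutate(d8, event = 1)
  expect_error(roc_compare(d_one), "degenerate")
})

test_that("trapezoidal AUC equals the concordance estimator on random fixtures", {
  for (seed in 1:10) {
    d <- withr::with_seed(seed, tibble::tibble(
      modified_stage = sample(0:3, 60, replace = TRUE),
      ajcc_n = sample(0:3, 60, replace = TRUE),
      event = rbinom(60, 1, 0.5)
    ))
    if (length(unique(d$event)) < 2) next
    roc <- roc_compare(d)
    expect_equal(roc$auc_modified, rank_sum_auc(d$modified_stage, d$event),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  d <- withr::with_seed(2, tibble::tibble(
    modified_stage = sample(0:3, 300, replace = TRUE, prob = c(2, 3, 2, 1)),
    ajcc_n = sample(0:3, 300, replace = TRUE),
    event = rbinom(300, 1, 0.6)
  ))
  roc <- roc_compare(d)
  ref <- as.numeric(pROC::auc(pROC::roc(d$event, d$modified_stage,
                                        quiet = TRUE, direction = "<")))
  expect_equal(roc$auc_modified, ref, tolerance = 1e-10)
})

test_that("ROC curves run from (0,0) to (1,1) and integrate to their AUC", {
  d <- withr::with_seed(6, tibble::tibble(
    modified_stage = sample(0:3, 100, replace = TRUE),
    ajcc_n = sample(0:3, 100, replace = TRUE),
    event = rbinom(100, 1, 0.5)
  ))
  roc <- roc_compare(d)
  for (sys in c("modified", "comparator")) {
    cur <- dplyr::filter(roc$curves, .data$system == sys)
    expect_equal(c(cur$fpr[1], cur$tpr[1]), c(0, 0))
    expect_equal(c(cur$fpr[nrow(cur)], cur$tpr[nrow(cur)]), c(1, 1))
    expect_true(all(diff(cur$fpr) >= 0) && all(diff(cur$tpr) >= 0))
  }
})
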