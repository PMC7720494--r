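make_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path, na = "")
  path
}

fixture_df <- tibble::tibble(
  id = c("a", "b", "c"),
  survival_months = c(12, 3, 40),
  event = c(1, 1, 0),
  n_pln = c(2, NA, 0),
  n_nln = c(10, 5, 18),
  ajcc_n = c(1, 0, 0),
  age = c(60, 72, 55),
  sex = c("male", "female", "male"),
  race = c("white", "black", "white"),
  tumor_site = c("thoracic", "abdominal", "thoracic"),
  tumor_size = c(300, 410, 250),
  grade = c("II", "III", "I"),
  ajcc_group = c("II", "III", "I"),
  radiation_sequence = c("none", "after_surgery", "none"),
  met_bone = c(0, 0, 0), met_brain = c(0, 0, 0),
  met_liver = c(0, 1, 0), met_lung = c(0, 0, 0),
  surgery_flag = c(1, 1, 1),
  cause_specific = c(1, 1, 1)
)

test_that("a delimited case listing round-trips into a cohort", {
  path <- make_fixture_csv(fixture_df)
  co <- read_cohort(path)
  expect_equal(nrow(co), 3)
  expect_identical(co$id, c("a", "b", "c"))      # row order preserved
  expect_true(is.na(co$n_pln[2]))                # blank node count -> missing
  expect_equal(co$survival_months, c(12, 3, 40))
  expect_identical(attr(co, "provenance"), path)
})

test_that("field_map renames produce the same cohort as standard names", {
  renamed <- dplyr::rename(fixture_df, `Regional nodes positive` = n_pln,
                           `Survival months` = survival_months)
  path_std <- make_fixture_csv(fixture_df)
  path_ren <- make_fixture_csv(renamed)
  co_std <- read_cohort(path_std)
  co_ren <- read_cohort(path_ren, field_map = c(
    n_pln = "Regional nodes positive", survival_months = "Survival months"
  ))
  attr(co_std, "provenance") <- attr(co_ren, "provenance") <- NULL
  expect_equal(co_std, co_ren[names(co_std)])
})

test_that("schema errors name the missing column and empty files are rejected", {
  path <- make_fixture_csv(fixture_df)
  expect_error(read_cohort(path, field_map = c(n_pln = "NoSuchColumn")),
               "NoSuchColumn")
  empty <- make_fixture_csv(fixture_df[0, ])
  expect_error(read_cohort(empty), "empty")
  expect_error(read_cohort(tempfile()), "not found")
})

test_that("unparseable numerics and unknown codes become missing", {
  df <- fixture_df
  df$n_nln <- c("7", "Unknown", "not-a-number")
  path <- make_fixture_csv(df)
  co <- read_cohort(path)
  expect_equal(co$n_nln, c(7, NA, NA))
})

test_that("inclusion criteria retain the right records and tally by first failure", {
  # 10 records: 1 non-surgical (also missing a node count -> tallied as
  # no_surgery, the first listed criterion), 2 with unclear node counts,
  # 1 death from another cause, 6 eligible
  co <- tibble::tibble(
    id = as.character(1:10),
    survival_months = rep(10, 10),
    event = c(1, 1, 0, 1, 1, 1, 0, 1, 1, 1),
    n_pln = c(2, NA, 1, 0, 3, 4, 1, 2, 0, 1),
    n_nln = c(8, 9, NA, 12, 7, 11, 9, 6, 10, 8),
    surgery_flag = c(1, 1, 1, 0, 1, 1, 1, 1, 1, 1),
    cause_specific = c(1, 1, 1, 1, 0, 1, 1, 1, 1, 1)
  )
  # records 2 and 3 unclear_ln, record 4 no_surgery, record 5 other_cause
  res <- apply_inclusion_criteria(co)
  expect_equal(res$n_retained, 6)
  expect_identical(res$cohort$id, c("1", "6", "7", "8", "9", "10"))
  tally <- setNames(res$exclusions$n_excluded, res$exclusions$criterion)
  expect_equal(tally[["no_surgery"]], 1)
  expect_equal(tally[["unclear_ln"]], 2)
  expect_equal(tally[["other_cause"]], 1)
  expect_equal(res$n_retained + sum(res$exclusions$n_excluded), res$n_input)
})

test_that("a record failing several criteria is tallied under the first", {
  co <- tibble::tibble(
    survival_months = 5, event = 1, n_pln = NA_real_, n_nln = 4,
    surgery_flag = 0, cause_specific = 0
  )
  res <- apply_inclusion_criteria(co)
  tally <- setNames(res$exclusions$n_excluded, res$exclusions$criterion)
  expect_equal(tally[["no_surgery"]], 1)
  expect_equal(sum(res$exclusions$n_excluded), 1)
})

test_that("filtering is idempotent and empty cohorts pass through", {
  co <- simulate_cohort(cohort_config(n_patients = 50, seed = 2))
  co$surgery_flag[1:5] <- 0L
  once <- apply_inclusion_criteria(co)
  twice <- apply_inclusion_criteria(once$cohort)
  expect_equal(once$cohort, twice$cohort)
  expect_equal(sum(twice$exclusions$n_excluded), 0)

  res0 <- apply_inclusion_criteria(co[0, ])
  expect_equal(nrow(res0$cohort), 0)
  expect_equal(sum(res0$exclusions$n_excluded), 0)
})

test_that("retained plus tallied exclusions always partition the input", {
  for (seed in 1:5) {
    co <- withr::with_seed(seed, {
      d <- simulate_cohort(cohort_config(n_patients = 200, seed = seed))
      d$surgery_flag <- rbinom(200, 1, 0.9)
      d$cause_specific <- rbinom(200, 1, 0.85)
      d$n_pln[sample(200, 20)] <- NA
      d
    })
    res <- apply_inclusion_criteria(co)
    expect_equal(res$n_retained + sum(res$exclusions$n_excluded), 200)
  }
})
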