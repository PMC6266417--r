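test_that("design validation enforces the study invariants", {
  expect_error(study_design(n_subjects = 1))
  expect_error(study_design(sessions = c(1, 3)))
  expect_error(study_design(cycle_length_days = 20))
  expect_error(study_design(sessions = c(25, 30), cycle_length_days = 28),
               "more sessions than distinct cycle days")
})

test_that("null effects with zero noise give constant per-subject outcomes", {
  d <- generate_cycle_dataset(
    study_design(seed = 3),
    list(effect_spec("Y", 50, subject_sd = 4, noise_cv = 0)))
  spread <- tapply(d$Y, d$subject_id, function(x) diff(range(x)))
  expect_true(all(spread == 0))
  # but subjects differ (between-subject variance present)
  expect_gt(length(unique(round(tapply(d$Y, d$subject_id, mean), 8))), 1)
})

test_that("a linear 0.01 l/day effect is recovered exactly by per-subject OLS", {
  d <- generate_cycle_dataset(
    study_design(seed = 4),
    list(effect_spec("ECW", 13.5, subject_sd = 1, noise_cv = 0,
                     cycle = cycle_linear(0.01))))
  for (s in split(d, d$subject_id)) {
    slope <- stats::coef(stats::lm(ECW ~ cycle_day, data = s))[2]
    expect_equal(unname(slope), 0.01, tolerance = 1e-10)
  }
})

test_that("a sinusoidal effect spans its peak-to-trough range on the full grid", {
  a <- 0.7
  d <- generate_cycle_dataset(
    study_design(n_subjects = 2, sessions = c(28, 28), seed = 6),
    list(effect_spec("Y", 10, subject_sd = 0, noise_cv = 0,
                     cycle = cycle_sin(a))))
  # oracle: direct evaluation of the effect at the generated days
  expected <- a * sin(2 * pi * d$cycle_day / 28)
  expect_equal(d$Y - 10, expected, tolerance = 1e-12)
  expect_equal(diff(range(d$Y)), 2 * a, tolerance = 1e-12)
})

test_that("each subject is tested on distinct days within one cycle", {
  d <- generate_cycle_dataset(study_design(seed = 9),
                              default_study_effects())
  for (s in split(d, d$subject_id)) {
    expect_false(any(duplicated(s$test_date)))
    expect_true(all(s$test_date >= s$menses_onset_prev[1]))
    expect_true(all(s$test_date < s$menses_onset_next[1]))
    expect_true(all(s$cycle_day %in% 1:28))
    expect_true(nrow(s) >= 12 && nrow(s) <= 14)
  }
})

test_that("identical seeds reproduce the dataset bit for bit", {
  d1 <- generate_cycle_dataset(study_design(seed = 11))
  d2 <- generate_cycle_dataset(study_design(seed = 11))
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  d3 <- generate_cycle_dataset(study_design(seed = 12))
  expect_false(identical(d1$BM, d3$BM))
})

test_that("within-subject CV matches the specified noise_cv at stress scale", {
  cv <- 0.01
  d <- generate_cycle_dataset(
    study_design(n_subjects = 200, sessions = c(13, 13), seed = 21),
    list(effect_spec("Y", 50, subject_sd = 2, noise_cv = cv)))
  emp <- mean(tapply(d$Y, d$subject_id, function(x) stats::sd(x) / mean(x)))
  expect_equal(emp, cv, tolerance = 0.15)
})

test_that("study CSV round trip preserves values and dates", {
  d <- generate_cycle_dataset(study_design(seed = 2), default_study_effects())
  path <- withr::local_tempfile(fileext = ".csv")
  write_study_csv(d, path)
  d2 <- read_study_csv(path)
  expect_equal(d2$BM, d$BM, tolerance = 1e-10)
  expect_identical(d2$test_date, d$test_date)
  expect_identical(d2$cycle_day, d$cycle_day)
})
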