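test_that("identical seeds give bit-identical streams and cohorts", {
  cfg <- four_state_config(seed = 99)
  a <- simulate_subject_stream(cfg)
  b <- simulate_subject_stream(cfg)
  expect_identical(a$samples, b$samples)
  expect_identical(a$clean, b$clean)
  expect_identical(a$labels, b$labels)
  c1 <- simulate_cohort(seed = 7)
  c2 <- simulate_cohort(seed = 7)
  expect_identical(c1, c2)
  # a different seed changes the draw
  expect_false(identical(a$samples$adc12,
                         simulate_subject_stream(four_state_config(seed = 100))$samples$adc12))
})

test_that("the simulator does not disturb the caller's RNG stream", {
  set.seed(1234)
  r1 <- runif(3)
  set.seed(1234)
  invisible(simulate_subject_stream(simulator_config(seed = 5, duration_s = 10, calibration_window_s = 0)))
  r2 <- runif(3)
  expect_identical(r1, r2)
})

test_that("a degenerate configuration yields a constant baseline stream", {
  cfg <- simulator_config(seed = 1, duration_s = 20, noise_sd = 0,
                          scr_rate_per_min = 0, drift_per_min = 0,
                          calibration_window_s = 0)
  sim <- simulate_subject_stream(cfg)
  # no_stress tonic elevation sits at 20% of the dynamic range
  expected <- cfg$baseline_adc12 + 0.2 * cfg$dynamic_range_adc12
  expect_true(all(sim$samples$adc12 == round(expected)))
  expect_equal(sim$clean, rep(expected, nrow(sim$samples)))
  expect_true(all(sim$labels == "No stress"))
})

test_that("sensor noise is zero-mean at the CLT scale and counts stay 12-bit", {
  cfg <- simulator_config(seed = 8, duration_s = 1000, noise_sd = 10,
                          scr_rate_per_min = 0, drift_per_min = 0,
                          calibration_window_s = 0)
  sim <- simulate_subject_stream(cfg)
  n <- nrow(sim$samples)
  expect_equal(n, 10000L)
  resid <- sim$samples$adc12 - sim$clean
  expect_lt(abs(mean(resid)), 3 * cfg$noise_sd / 100)
  expect_true(all(sim$samples$adc12 >= 0 & sim$samples$adc12 <= 4095))
  expect_equal(length(sim$clean), n)
  expect_equal(length(sim$labels), n)
})

test_that("stress states raise the clean signal above rest", {
  for (seed in 1:50) {
    sim <- simulate_subject_stream(four_state_config(seed = seed, noise_sd = 0))
    high <- sim$labels == "High stress"
    rest <- sim$labels == "No stress"
    expect_gt(mean(sim$clean[high]), mean(sim$clean[rest]))
  }
})

test_that("schedules outside the stream or overlapping are rejected", {
  expect_error(simulator_config(duration_s = 100, stress_state_schedule =
    data.frame(start_s = 50, end_s = 150, level = "high")),
    "within")
  expect_error(simulator_config(duration_s = 100, stress_state_schedule =
    data.frame(start_s = 10, end_s = 50, level = "high")),
    "within")  # starts inside the default 30 s calibration window
  expect_error(simulator_config(duration_s = 200, stress_state_schedule =
    data.frame(start_s = c(40, 60), end_s = c(80, 100),
               level = c("high", "minor"))),
    "non-overlapping")
  expect_error(simulator_config(duration_s = 200, stress_state_schedule =
    data.frame(start_s = 40, end_s = 80, level = "panic")),
    "levels")
})

test_that("the cohort generator emits subjects x samples records in-band", {
  cohort <- simulate_cohort(n_subjects = 32, samples_per_subject = 20, seed = 2)
  expect_equal(nrow(cohort), 640L)
  expect_equal(nlevels(cohort$subject), 32L)
  # every draw classifies back to its assigned band
  expect_true(all(classify_stress(cohort$gsr_norm) == cohort$level))
  # default assignment cycles the four bands, four subjects each
  expect_equal(as.integer(table(cohort$level)) / 20L, rep(8L, 4L))

  tiny <- simulate_cohort(n_subjects = 1, samples_per_subject = 1, seed = 3)
  expect_equal(nrow(tiny), 1L)

  wide <- cohort_to_table(cohort)
  expect_equal(dim(wide), c(20L, 32L))
  counts <- classify_table(wide)
  expect_equal(sum(as.matrix(counts)), 640L)
})

test_that("the bundled cohort fixture carries the printed readings", {
  tab <- load_table2_fixture()
  expect_equal(names(tab), sprintf("Person %d", 1:16))
  expect_equal(tab[["Person 1"]][1], 432)
  expect_equal(tab[["Person 16"]][1], 175)
  expect_equal(tab[["Person 4"]][10], 140)
  # Persons 1-4 carry 14 readings; 5-16 carry 13 (final row padded)
  expect_equal(colSums(!is.na(tab)), setNames(c(rep(14L, 4), rep(13L, 12)),
                                              names(tab)))
})
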