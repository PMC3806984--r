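test_that("one-third-octave centers follow the nominal base-10 series", {
  centers <- third_octave_centers(200, 10000)
  expect_length(centers, 18)
  expect_equal(centers[1], 200)
  expect_equal(centers[18], 10000)
  expect_true(all(diff(centers) > 0))
  # exact centers 1000 * 10^(m/10) agree with nominal rounding to < 1.3%
  m <- seq(-7, 10)
  exact <- 1000 * 10^(m / 10)
  expect_true(all(abs(exact - centers) / exact < 0.013))
  # edge cases
  expect_equal(third_octave_centers(1000, 1000), 1000)
  expect_error(third_octave_centers(500, 200), "fmin")
  expect_error(third_octave_centers(-1, 100), "positive")
})

test_that("SPL to pressure is exact at reference multiples and monotone", {
  expect_equal(spl_to_pressure(0), 2e-5)
  expect_equal(spl_to_pressure(60), 0.02)
  expect_equal(spl_to_pressure(80), 0.2)
  spl <- seq(-10, 120, by = 0.5)
  expect_true(all(diff(spl_to_pressure(spl)) > 0))
  expect_error(spl_to_pressure(Inf), "finite")
})

test_that("velocity/displacement conversion is the harmonic inverse pair", {
  expect_equal(velocity_to_displacement(2 * pi, 1), 1)
  expect_equal(velocity_to_displacement(0, 100), 0)
  v <- c(0.1, 3, 50)
  f <- c(200, 1000, 8000)
  d <- velocity_to_displacement(v, f)
  expect_equal(d * 2 * pi * f, v, tolerance = 1e-12)
  expect_error(velocity_to_displacement(1, 0), "> 0")
})

test_that("UDTF conversion divides by excitation pressure and is level-invariant", {
  rec <- tibble::tibble(frequency_hz = 1000, spl_db = 60,
                        displacement_mm = 0.02)
  expect_equal(to_udtf(rec)$udtf_mm_per_pa, 1.0)
  # same physical transfer function at 80 dB: displacement x10
  rec80 <- tibble::tibble(frequency_hz = 1000, spl_db = 80,
                          displacement_mm = 0.2)
  expect_equal(to_udtf(rec80)$udtf_mm_per_pa, to_udtf(rec)$udtf_mm_per_pa)
  expect_error(to_udtf(dplyr::mutate(rec, displacement_mm = 0)), "positive")
  # velocity-only records convert through the harmonic relation
  vrec <- tibble::tibble(frequency_hz = 100, spl_db = 60,
                         velocity_mm_s = 2 * pi * 100 * 0.01)
  expect_equal(to_udtf(vrec)$displacement_mm, 0.01)
})

test_that("log-normal aggregation reproduces hand-computed statistics", {
  samples <- tibble::tibble(
    frequency_hz = 500, subject_id = 1:3,
    udtf_mm_per_pa = 10^c(1, 2, 3))
  s <- aggregate_lognormal(samples)
  expect_equal(s$log_mean, 2)
  expect_equal(s$log_sd, 1)
  expect_equal(s$n_subjects, 3L)
  # fitted 10th/90th band: mean +/- 1.2816 sd on the log scale
  expect_equal(s$band_lower, 10^(2 + qnorm(0.1)), tolerance = 1e-6)
  expect_equal(s$band_upper, 10^(2 + qnorm(0.9)), tolerance = 1e-6)
  # all-equal samples -> zero spread
  eq <- aggregate_lognormal(dplyr::mutate(samples, udtf_mm_per_pa = 5))
  expect_equal(eq$log_sd, 0)
  expect_equal(eq$band_lower, eq$band_upper)
})

test_that("aggregation is invariant to ordering and shifts under rescaling", {
  set.seed(11)
  samples <- tibble::tibble(
    frequency_hz = rep(c(250, 500), each = 8),
    subject_id = rep(1:8, times = 2),
    udtf_mm_per_pa = exp(rnorm(16, -9, 0.5)))
  s1 <- aggregate_lognormal(samples)
  s2 <- aggregate_lognormal(samples[sample(nrow(samples)), ])
  expect_equal(tidy(s1), tidy(s2))
  s3 <- aggregate_lognormal(dplyr::mutate(samples,
                                          udtf_mm_per_pa = udtf_mm_per_pa * 7))
  expect_equal(s3$log_mean, s1$log_mean + log10(7), tolerance = 1e-12)
  expect_equal(s3$log_sd, s1$log_sd, tolerance = 1e-12)
})

test_that("fitted percentile band matches empirical quantiles at large n", {
  set.seed(21)
  n <- 10000
  samples <- tibble::tibble(
    frequency_hz = 1000, subject_id = seq_len(n),
    udtf_mm_per_pa = 10^rnorm(n, -4.5, 0.2))
  fit <- aggregate_lognormal(samples, method = "fitted")
  emp <- aggregate_lognormal(samples, method = "empirical")
  expect_equal(log10(fit$band_lower), log10(emp$band_lower), tolerance = 0.02)
  expect_equal(log10(fit$band_upper), log10(emp$band_upper), tolerance = 0.02)
})

test_that("schedule bookkeeping and record CSV round-trip", {
  sch <- tone_schedule()
  expect_equal(nrow(sch), 36)          # 18 centers x 2 levels
  expect_equal(attr(sch, "repetitions"), 20L)
  pop <- population_model()
  recs <- generate_subject(pop, "S1", sch, seed = 5)
  path <- tempfile(fileext = ".csv")
  write_records_csv(recs, path)
  back <- read_records_csv(path)
  expect_equal(back$displacement_mm, recs$displacement_mm, tolerance = 1e-12)
  expect_equal(back$frequency_hz, recs$frequency_hz)
})
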