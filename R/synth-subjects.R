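#' Population model for synthetic vibrometry subjects
#'
#' Describes a synthetic population of middle ears through a template
#' UDTF curve (flat low-frequency compliance, one dominant resonance,
#' asymptotic high-frequency roll-off) and log-normal variability:
#' each subject draws a level shift and a resonance-frequency shift on
#' the log10 scale, and every tone measurement carries multiplicative
#' (log-normal) noise whose SD shrinks as `1/sqrt(n_averaged)` under
#' repetition averaging.
#'
#' Defaults emulate the measurement conditions this package's comparison
#' stage targets: resonance near 1 kHz, flat compliance below it, roll-off
#' above, and inter-subject spreads large relative to the level effect
#' (subject level SD 0.2 log10 units, i.e. 4 dB).
#'
#' @param f0 Template resonance frequency, Hz.
#' @param compliance Low-frequency plateau, mm/Pa.
#' @param slope High-frequency asymptotic slope, dB/decade (negative).
#' @param q Resonance quality factor.
#' @param sigma_subject SD of the per-subject log10 level shift.
#' @param sigma_f0 SD of the per-subject log10 resonance shift.
#' @param sigma_noise SD of the per-measurement log10 noise (before
#'   repetition averaging).
#' @return A `population_model` object.
#' @export
population_model <- function(f0 = 1000, compliance = 3e-5, slope = -30,
                             q = 1.4, sigma_subject = 0.2, sigma_f0 = 0.05,
                             sigma_noise = 0.05) {
  if (f0 <= 0) abort("f0 must be > 0")
  if (any(c(sigma_subject, sigma_f0, sigma_noise) < 0)) {
    abort("sigmas must be >= 0")
  }
  structure(list(f0 = f0, compliance = compliance, slope = slope, q = q,
                 sigma_subject = sigma_subject, sigma_f0 = sigma_f0,
                 sigma_noise = sigma_noise),
            class = "population_model")
}

#' Template UDTF curve of the synthetic population
#'
#' A generalized second-order resonator magnitude
#' `compliance * ((1 - x^2)^2 + (x/q)^2)^(-s/80)` with `x = f/f0`:
#' flat at `compliance` for `f << f0`, peak near
#' `f0 * sqrt(1 - 1/(2 q^2))`, and an asymptotic roll-off of `slope`
#' dB/decade above `f0` (`slope = -40` recovers the classical resonator).
#'
#' @inheritParams population_model
#' @param freqs Frequencies in Hz.
#' @return A `udtf_spectrum` tibble.
#' @export
template_udtf <- function(freqs, f0 = 1000, compliance = 3e-5, slope = -30,
                          q = 1.4) {
  if (f0 <= 0) abort("f0 must be > 0")
  x <- freqs / f0
  new_udtf_spectrum(
    tibble(frequency_hz = freqs,
           magnitude_mm_per_pa = resonator_magnitude(freqs, f0, compliance,
                                                     slope, q),
           phase_rad = -atan2(x / q, 1 - x^2)),
    excitation = "synthetic resonator template", f0 = f0)
}

# magnitude law shared by template_udtf and the subject generator (the
# generator evaluates it on a tone grid with repeated frequencies)
resonator_magnitude <- function(freqs, f0, compliance, slope, q) {
  x <- freqs / f0
  compliance * ((1 - x^2)^2 + (x / q)^2)^(slope / 80)
}

# Deterministic per-subject seed sequence from a master seed.
subject_seed <- function(seed, subject_index) {
  as.integer((as.double(seed) * 1000003 + subject_index * 7919) %% 2147483647)
}

#' Generate one synthetic subject's measurement records
#'
#' Draws the subject's log10 level shift (`sigma_subject`) and log10
#' resonance shift (`sigma_f0`) once, then for every tone of the schedule
#' produces the displacement magnitude
#' `UDTF(f) * pressure(spl) * 10^eps`, with
#' `eps ~ Normal(0, sigma_noise / sqrt(n_averaged))` when repetition
#' averaging is modeled (`average_repeats = TRUE`, one record per tone),
#' or one record per repetition with full-SD noise otherwise.
#'
#' @param pop A [population_model()].
#' @param subject_id Identifier stored in the records.
#' @param schedule A [tone_schedule()].
#' @param seed Master seed; records are deterministic given
#'   `(seed, subject_id index)`.
#' @param subject_index Integer used for seed sequencing (defaults to a
#'   hash-free 1).
#' @param average_repeats Model the repetition average as a
#'   `1/sqrt(n)` noise reduction (default) instead of raw repeats.
#' @return A tibble of measurement records: `subject_id`, `frequency_hz`,
#'   `spl_db`, `displacement_mm`, `n_averaged`.
#' @export
generate_subject <- function(pop, subject_id, schedule = tone_schedule(),
                             seed = 1L, subject_index = 1L,
                             average_repeats = TRUE) {
  stopifnot(inherits(pop, "population_model"))
  reps <- attr(schedule, "repetitions") %||% 1L
  withr_seed <- subject_seed(seed, subject_index)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(withr_seed)

  shift_level <- rnorm(1, 0, pop$sigma_subject)
  shift_f0 <- rnorm(1, 0, pop$sigma_f0)
  f0_i <- pop$f0 * 10^shift_f0

  base <- as_tibble(schedule)
  base$udtf_true <- resonator_magnitude(
    base$frequency_hz, f0 = f0_i,
    compliance = pop$compliance * 10^shift_level,
    slope = pop$slope, q = pop$q)
  if (average_repeats) {
    eps <- rnorm(nrow(base), 0, pop$sigma_noise / sqrt(reps))
    out <- mutate(base,
                  subject_id = subject_id,
                  displacement_mm = .data$udtf_true *
                    spl_to_pressure(.data$spl_db) * 10^eps,
                  n_averaged = reps)
  } else {
    out <- tidyr::uncount(base, reps)
    eps <- rnorm(nrow(out), 0, pop$sigma_noise)
    out <- mutate(out,
                  subject_id = subject_id,
                  displacement_mm = .data$udtf_true *
                    spl_to_pressure(.data$spl_db) * 10^eps,
                  n_averaged = 1L)
  }
  select(out, "subject_id", "frequency_hz", "spl_db", "displacement_mm",
         "n_averaged")
}

#' Generate a synthetic measurement population
#'
#' Independent subjects via deterministic seed sequencing from one master
#' seed; record count is `n_subjects * tones` (averaged mode) or
#' `n_subjects * tones * repetitions` (raw-repeat mode).
#'
#' @inheritParams generate_subject
#' @param n_subjects Number of subjects (>= 1).
#' @return A tibble of measurement records for all subjects.
#' @export
generate_population <- function(pop, n_subjects, schedule = tone_schedule(),
                                seed = 1L, average_repeats = TRUE) {
  if (n_subjects < 1) abort("n_subjects must be >= 1")
  bind_rows(lapply(seq_len(n_subjects), function(i) {
    generate_subject(pop, subject_id = sprintf("S%03d", i),
                     schedule = schedule, seed = seed, subject_index = i,
                     average_repeats = average_repeats)
  }))
}
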