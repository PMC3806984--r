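#' One-third-octave band center frequencies
#'
#' Base-10 one-third-octave centers with standard preferred-number
#' (nominal) rounding: mantissas 1, 1.25, 1.6, 2, 2.5, 3.15, 4, 5, 6.3, 8
#' per decade. The exact centers `1000 * 10^(m/10)` agree with the
#' nominal values to better than 1.3%. The span 200 Hz-10 kHz contains
#' exactly 18 bands.
#'
#' @param fmin,fmax Inclusive range in Hz.
#' @return Nominal center frequencies within `[fmin, fmax]`.
#' @examples
#' length(third_octave_centers(200, 10000))  # 18
#' @export
third_octave_centers <- function(fmin, fmax) {
  if (!is.numeric(fmin) || !is.numeric(fmax) || fmin <= 0 || fmax <= 0) {
    abort("fmin and fmax must be positive")
  }
  if (fmin > fmax) abort("fmin must be <= fmax")
  mant <- c(1, 1.25, 1.6, 2, 2.5, 3.15, 4, 5, 6.3, 8)
  centers <- sort(as.vector(outer(mant, 10^(-1:6))))
  centers[centers >= fmin - 1e-9 & centers <= fmax + 1e-9]
}

#' Pure-tone measurement schedule
#'
#' The stimulation protocol: pure tones at one-third-octave centers, at
#' one or more sound pressure levels, each repeated and averaged.
#' Defaults reproduce the standard vibrometry protocol: 18 centers over
#' 200 Hz-10 kHz, 60 and 80 dB SPL, 20 repetitions per tone.
#'
#' @param center_frequencies Hz, strictly increasing.
#' @param levels dB SPL.
#' @param repetitions Repetitions averaged per tone (>= 1).
#' @return A `tone_schedule` object (tibble of the full tone grid plus
#'   attributes).
#' @export
tone_schedule <- function(center_frequencies = third_octave_centers(200, 10000),
                          levels = c(60, 80), repetitions = 20L) {
  if (any(diff(center_frequencies) <= 0)) {
    abort("center frequencies must be strictly increasing")
  }
  if (repetitions < 1) abort("repetitions must be >= 1")
  grid <- tidyr::expand_grid(frequency_hz = center_frequencies,
                             spl_db = levels)
  structure(grid, class = c("tone_schedule", class(tibble())),
            repetitions = as.integer(repetitions))
}

#' Sound pressure level to pressure
#'
#' `p = 20e-6 * 10^(spl/20)` Pa (RMS, reference 20 micropascal).
#'
#' @param spl Level(s) in dB SPL.
#' @return Pressure(s) in Pa.
#' @examples
#' spl_to_pressure(c(60, 80))  # 0.02, 0.2 Pa
#' @export
spl_to_pressure <- function(spl) {
  if (any(!is.finite(spl))) abort("spl must be finite")
  20e-6 * 10^(spl / 20)
}

#' Harmonic velocity-to-displacement conversion
#'
#' For a pure tone at frequency `f`, displacement magnitude is
#' `v / (2*pi*f)` — the steady-state relation used to convert vibrometer
#' velocity readings to displacements.
#'
#' @param v Velocity magnitude (mm/s; any length unit is preserved).
#' @param f Frequency in Hz (> 0).
#' @return Displacement in the same length unit as `v`.
#' @export
velocity_to_displacement <- function(v, f) {
  if (any(f <= 0)) abort("frequency must be > 0")
  v / (2 * pi * f)
}

#' Convert measurement records to UDTF samples
#'
#' Divides each displacement magnitude by the excitation pressure
#' (linearity assumption), yielding the umbo displacement transfer
#' function sample in mm/Pa. Records with a `velocity_mm_s` column (and
#' no displacement) are first converted via [velocity_to_displacement()].
#'
#' @param records Data frame with columns `frequency_hz`, `spl_db` and
#'   `displacement_mm` (or `velocity_mm_s`); extra columns pass through.
#' @return The input tibble with a `udtf_mm_per_pa` column appended.
#' @export
to_udtf <- function(records) {
  records <- as_tibble(records)
  if (!"displacement_mm" %in% names(records)) {
    if (!"velocity_mm_s" %in% names(records)) {
      abort("records need a displacement_mm or velocity_mm_s column")
    }
    records$displacement_mm <-
      velocity_to_displacement(records$velocity_mm_s, records$frequency_hz)
  }
  if (any(records$displacement_mm <= 0)) {
    abort("displacement magnitudes must be positive")
  }
  mutate(records,
         udtf_mm_per_pa = .data$displacement_mm /
           spl_to_pressure(.data$spl_db))
}

#' Log-normal population statistics of UDTF samples
#'
#' Per frequency: arithmetic mean and sample standard deviation (n-1) of
#' `log10` magnitudes across subjects (within-subject samples at a
#' frequency are first averaged on the log scale), plus percentile bands.
#' Bands come from the fitted normal-on-log quantiles
#' `mean +/- z * SD` (default) or from empirical quantiles.
#'
#' @param samples Data frame with `frequency_hz`, `udtf_mm_per_pa` and
#'   (optionally) `subject_id`.
#' @param probs Two band probabilities (default 10th/90th percentile).
#' @param method `"fitted"` (normal quantiles on the log scale) or
#'   `"empirical"`.
#' @param log_base `10` (default, dB-compatible) or `exp(1)`.
#' @return A tibble of class `population_summary`: `frequency_hz`,
#'   `log_mean`, `log_sd`, `n_subjects`, `band_lower`, `band_upper`
#'   (bands on the magnitude scale, mm/Pa).
#' @export
aggregate_lognormal <- function(samples, probs = c(0.1, 0.9),
                                method = c("fitted", "empirical"),
                                log_base = 10) {
  method <- match.arg(method)
  samples <- as_tibble(samples)
  if (!nrow(samples)) abort("no samples to aggregate")
  if (any(samples$udtf_mm_per_pa <= 0)) abort("magnitudes must be positive")
  if (length(probs) != 2L || probs[1] >= probs[2]) {
    abort("probs must be an increasing pair")
  }
  lg <- function(x) log(x, base = log_base)
  if (!"subject_id" %in% names(samples)) samples$subject_id <- 1L
  per_subject <- samples |>
    group_by(.data$frequency_hz, .data$subject_id) |>
    summarise(log_mag = mean(lg(.data$udtf_mm_per_pa)), .groups = "drop")
  out <- per_subject |>
    group_by(.data$frequency_hz) |>
    summarise(
      log_mean = mean(.data$log_mag),
      log_sd = if (dplyr::n() > 1) sd(.data$log_mag) else 0,
      n_subjects = dplyr::n(),
      q_lo = if (method[1] == "empirical")
        lg(stats::quantile(log_base^.data$log_mag, probs[1], names = FALSE))
      else NA_real_,
      q_hi = if (method[1] == "empirical")
        lg(stats::quantile(log_base^.data$log_mag, probs[2], names = FALSE))
      else NA_real_,
      .groups = "drop"
    )
  if (method == "fitted") {
    z <- qnorm(probs)
    out$band_lower <- log_base^(out$log_mean + z[1] * out$log_sd)
    out$band_upper <- log_base^(out$log_mean + z[2] * out$log_sd)
  } else {
    out$band_lower <- log_base^out$q_lo
    out$band_upper <- log_base^out$q_hi
  }
  out$q_lo <- out$q_hi <- NULL
  structure(arrange(out, .data$frequency_hz),
            class = c("population_summary", class(tibble())),
            probs = probs, method = method, log_base = log_base)
}

#' Read / write measurement record tables
#'
#' CSV layout `subject_id,frequency_hz,spl_db,displacement_mm,n_averaged`.
#'
#' @param records Measurement record tibble.
#' @param path CSV path.
#' @export
write_records_csv <- function(records, path) {
  cols <- c("subject_id", "frequency_hz", "spl_db", "displacement_mm",
            "n_averaged")
  utils::write.csv(as.data.frame(records)[, cols], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  as_tibble(utils::read.csv(path))
}
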