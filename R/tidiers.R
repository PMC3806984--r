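#' Tidy a UDTF spectrum
#'
#' @param x A `udtf_spectrum`.
#' @param ... Ignored.
#' @return A plain tibble with `frequency_hz`, `magnitude_mm_per_pa`,
#'   `phase_rad` and `magnitude_db` (dB re 1 mm/Pa).
#' @export
tidy.udtf_spectrum <- function(x, ...) {
  mutate(as_tibble(unclass(x)[c("frequency_hz", "magnitude_mm_per_pa",
                                "phase_rad")]),
         magnitude_db = 20 * log10(.data$magnitude_mm_per_pa))
}

#' @rdname tidy.udtf_spectrum
#' @return `glance()`: one row with frequency span, plateau level (mean
#'   magnitude over the lowest half-octave), the first resonance from
#'   [find_resonances()], and the peak magnitude.
#' @export
glance.udtf_spectrum <- function(x, ...) {
  res <- find_resonances(x)
  low <- x$frequency_hz <= min(x$frequency_hz) * 2^(1 / 2)
  tibble(
    n_freq = nrow(x),
    f_min_hz = min(x$frequency_hz),
    f_max_hz = max(x$frequency_hz),
    plateau_mm_per_pa = mean(x$magnitude_mm_per_pa[low]),
    first_resonance_hz = if (length(res)) res[1] else NA_real_,
    peak_mm_per_pa = max(x$magnitude_mm_per_pa)
  )
}

#' Tidy a population summary
#'
#' @param x A `population_summary`.
#' @param ... Ignored.
#' @return A plain tibble (one row per center frequency).
#' @export
tidy.population_summary <- function(x, ...) {
  as_tibble(unclass(x)[c("frequency_hz", "log_mean", "log_sd",
                         "n_subjects", "band_lower", "band_upper")])
}

#' @rdname tidy.population_summary
#' @export
glance.population_summary <- function(x, ...) {
  tibble(
    n_centers = nrow(x),
    n_subjects = max(x$n_subjects),
    mean_log_sd = mean(x$log_sd),
    band_probs = paste(attr(x, "probs"), collapse = "-"),
    method = attr(x, "method")
  )
}

#' Tidy a model-vs-measurement comparison
#'
#' @param x An `ear_comparison`.
#' @param ... Ignored.
#' @return A plain tibble of per-center rows.
#' @export
tidy.ear_comparison <- function(x, ...) {
  as_tibble(unclass(x)[c("frequency_hz", "model_mm_per_pa",
                         "measured_logmean", "band_lower", "band_upper",
                         "deviation_db")])
}

#' @rdname tidy.ear_comparison
#' @return `glance()`: one row with the divergence frequency, threshold,
#'   and deviation extremes.
#' @export
glance.ear_comparison <- function(x, ...) {
  tibble(
    divergence_hz = attr(x, "divergence_hz"),
    threshold_db = attr(x, "threshold_db"),
    max_abs_deviation_db = max(abs(x$deviation_db)),
    mean_deviation_db = mean(x$deviation_db)
  )
}
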