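#' Consistent nodal forces for uniform pressure on the membrane surface
#'
#' Integrates a uniform normal traction `p` over the tagged lateral
#' tympanic-membrane facets: each flat triangle contributes `p * A / 3`
#' along its (consistently oriented) normal to each of its three nodes,
#' acting medially (into the cone). When all facets share orientation the
#' resulting total force magnitude equals `p` times the projected
#' membrane area.
#'
#' @param system An [assemble_ear()] system (carries the mesh and dof map).
#' @param p Pressure in Pa.
#' @return Real load vector on the free dofs (N).
#' @export
pressure_load <- function(system, p = 1) {
  stopifnot(inherits(system, "fe_system"))
  mesh <- system$mesh
  if (is.null(mesh)) abort("system carries no mesh; assemble from an ear_mesh")
  facets <- mesh$tags$tm_lateral_surface
  if (is.null(facets) || !length(facets)) abort("tm_lateral_surface untagged")
  f_full <- numeric(system$ndof)
  nodes_m <- mesh$nodes * 1e-3
  for (e in facets) {
    el <- mesh$shell[e, ]
    nd <- c(el$n1, el$n2, el$n3)
    X <- nodes_m[nd, , drop = FALSE]
    nvec <- cross3(X[2, ] - X[1, ], X[3, ] - X[1, ])
    A2 <- sqrt(sum(nvec^2))
    fn <- -p * (A2 / 2) / 3 * (nvec / A2)     # medial push per node
    for (nn in nd) {
      ix <- system$dof_offset[nn] + 1:3
      f_full[ix] <- f_full[ix] + fn
    }
  }
  f_full[system$free]
}

#' Logarithmic frequency grid
#'
#' @param fmin,fmax Range in Hz.
#' @param points_per_decade Grid density (default 60).
#' @return Strictly increasing frequencies including both endpoints.
#' @export
udtf_freq_grid <- function(fmin = 200, fmax = 10000, points_per_decade = 60) {
  if (fmin <= 0 || fmax < fmin) abort("need 0 < fmin <= fmax")
  n <- max(2L, ceiling(log10(fmax / fmin) * points_per_decade) + 1L)
  10^seq(log10(fmin), log10(fmax), length.out = n)
}

#' Compute the umbo displacement transfer function (UDTF)
#'
#' Applies a uniform unit sound pressure to the lateral membrane surface,
#' solves the damped harmonic response at each frequency, and averages
#' the umbo-region response: per umbo node the magnitude of the complex
#' displacement component along the piston (footplate-normal, z) axis is
#' taken, then the arithmetic mean over nodes — conservative against
#' phase cancellation across the region. Reported in mm/Pa.
#'
#' @param mesh An `ear_mesh`, or `NULL` when `system` is supplied.
#' @param registry A [material_registry()] (or [material_preset()] output).
#' @param freqs Frequencies in Hz (default log grid, 60 points/decade over
#'   200 Hz-10 kHz).
#' @param system Optional pre-assembled `fe_system` (overrides
#'   `mesh`/`registry`).
#' @param direction `"normal"` for the z (piston) displacement component,
#'   `"total"` for the full vector magnitude.
#' @param p Excitation pressure in Pa; the spectrum is normalized by `p`,
#'   so it only matters for round-off (linearity makes it cancel).
#' @return A tibble of class `udtf_spectrum` with columns `frequency_hz`,
#'   `magnitude_mm_per_pa`, `phase_rad`, carrying excitation metadata as
#'   attributes.
#' @export
compute_udtf <- function(mesh = NULL, registry = material_registry(),
                         freqs = udtf_freq_grid(), system = NULL,
                         direction = c("normal", "total"), p = 1) {
  direction <- match.arg(direction)
  if (is.null(system)) {
    if (is.null(mesh)) abort("supply a mesh or a pre-assembled system")
    system <- assemble_ear(mesh, registry)
  }
  mesh <- system$mesh
  umbo <- mesh$tags$umbo_region
  if (!length(umbo)) abort("empty umbo region")
  load <- pressure_load(system, p)
  sol <- harmonic_solve(system, load, freqs)

  uz_rows <- vapply(umbo, function(nn) free_dof_index(system, nn, 3L),
                    integer(1))
  if (anyNA(uz_rows)) abort("umbo node is constrained")
  if (direction == "normal") {
    mags <- apply(abs(sol$u[uz_rows, , drop = FALSE]), 2, mean)
    mean_c <- colMeans(sol$u[uz_rows, , drop = FALSE])
  } else {
    rows3 <- lapply(umbo, function(nn)
      vapply(1:3, function(k) free_dof_index(system, nn, k), integer(1)))
    mags <- vapply(seq_along(freqs), function(i) {
      mean(vapply(rows3, function(r) sqrt(sum(abs(sol$u[r, i])^2)),
                  numeric(1)))
    }, numeric(1))
    mean_c <- colMeans(sol$u[vapply(rows3, `[`, integer(1), 3), , drop = FALSE])
  }
  out <- tibble(
    frequency_hz = freqs,
    magnitude_mm_per_pa = mags * 1e3 / p,
    phase_rad = Arg(mean_c)
  )
  new_udtf_spectrum(out,
                   excitation = sprintf("uniform %g Pa on tm_lateral_surface", p),
                   direction = direction,
                   n_free = system$n_free)
}

new_udtf_spectrum <- function(tbl, ...) {
  meta <- list(...)
  if (any(diff(tbl$frequency_hz) <= 0)) {
    abort("udtf_spectrum frequencies must be strictly increasing")
  }
  if (any(tbl$magnitude_mm_per_pa < 0)) abort("udtf magnitudes must be >= 0")
  structure(tbl, class = c("udtf_spectrum", class(tibble())),
            metadata = meta)
}

#' Locate resonance peaks of a UDTF spectrum
#'
#' Interior local maxima of the magnitude by three-point comparison,
#' refined by parabolic interpolation in (log10 f, log10 magnitude).
#'
#' @param spec A `udtf_spectrum` (or any data frame with `frequency_hz`
#'   and `magnitude_mm_per_pa`).
#' @return Ascending resonance frequencies in Hz (possibly empty).
#' @export
find_resonances <- function(spec) {
  f <- spec$frequency_hz
  m <- spec$magnitude_mm_per_pa
  if (length(f) < 3) abort("need at least 3 frequency points")
  peaks <- which(diff(sign(diff(m))) < 0) + 1L
  peaks <- peaks[m[peaks] > m[peaks - 1L] & m[peaks] >= m[peaks + 1L]]
  if (!length(peaks)) return(numeric(0))
  out <- vapply(peaks, function(i) {
    x <- log10(f[(i - 1):(i + 1)]); y <- log10(m[(i - 1):(i + 1)])
    d21 <- x[2] - x[1]; d32 <- x[3] - x[2]
    denom <- d21 * (y[3] - y[2]) - d32 * (y[2] - y[1])
    if (abs(denom) < .Machine$double.eps) return(f[i])
    xv <- x[2] - 0.5 * (d21^2 * (y[3] - y[2]) + d32^2 * (y[2] - y[1])) / denom
    10^max(min(xv, x[3]), x[1])
  }, numeric(1))
  sort(out)
}

#' Read / write UDTF spectra as CSV
#'
#' Column layout `frequency_hz,magnitude_mm_per_pa,phase_rad`.
#'
#' @param spec A `udtf_spectrum`.
#' @param path CSV path.
#' @export
write_udtf_csv <- function(spec, path) {
  utils::write.csv(as.data.frame(spec)[, c("frequency_hz",
                                           "magnitude_mm_per_pa",
                                           "phase_rad")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_udtf_csv
#' @export
read_udtf_csv <- function(path) {
  df <- utils::read.csv(path)
  new_udtf_spectrum(as_tibble(df), source = path)
}

#' @exportS3Method print udtf_spectrum
print.udtf_spectrum <- function(x, ...) {
  cat(sprintf("<udtf_spectrum> %d frequencies, %.4g-%.4g Hz\n",
              nrow(x), min(x$frequency_hz), max(x$frequency_hz)))
  NextMethod()
}
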