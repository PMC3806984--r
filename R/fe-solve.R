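#' Solve the damped harmonic response over a frequency list
#'
#' For each frequency `f` solves
#' `[K + i*Kloss + i*(2*pi*f)*C - (2*pi*f)^2*M] u = load`
#' by direct sparse factorization. The complex system is solved in its
#' equivalent real 2n-by-2n augmented form, one factorization per
#' frequency (no modal truncation).
#'
#' @param system An `fe_system` ([assemble_ear()] or [fe_system_raw()]).
#' @param load Complex (or real) load vector of length `system$n_free`,
#'   or a matrix with one column per load case.
#' @param freqs Frequencies in Hz (>= 0).
#' @return An object of class `harmonic_solution`: list with `frequencies`
#'   (Hz) and `u`, a complex matrix of size `n_free` x `length(freqs)`
#'   (displacement, m per load unit). Velocities are `2i*pi*f*u` via
#'   [solution_velocity()].
#' @export
harmonic_solve <- function(system, load, freqs) {
  stopifnot(inherits(system, "fe_system"))
  if (any(freqs < 0)) abort("frequencies must be >= 0")
  load <- as.vector(load)
  if (length(load) != system$n_free) {
    abort(sprintf("load has length %d; system has %d free dofs",
                  length(load), system$n_free))
  }
  n <- system$n_free
  u <- matrix(complex(real = NA_real_), n, length(freqs))
  rhs <- c(Re(load), Im(load))
  has_imag <- Matrix::nnzero(system$Kloss) > 0 || Matrix::nnzero(system$C) > 0
  for (i in seq_along(freqs)) {
    w <- 2 * pi * freqs[i]
    Ar <- system$K - w^2 * system$M
    Ai <- system$Kloss + w * system$C
    # symmetric diagonal equilibration: stiff mineralized dofs and the
    # near-massless drilling dofs span ~25 orders of magnitude
    d <- sqrt(abs(Matrix::diag(Ar)) + abs(Matrix::diag(Ai)))
    d[d == 0 | !is.finite(d)] <- 1
    Dm <- Matrix::Diagonal(n, 1 / d)
    Ars <- Dm %*% Ar %*% Dm
    if (has_imag) {
      Ais <- Dm %*% Ai %*% Dm
      Aug <- rbind(cbind(Ars, -Ais), cbind(Ais, Ars))
      sol <- try_solve(Aug, c(Re(load) / d, Im(load) / d), freqs[i])
      u[, i] <- complex(real = sol[seq_len(n)] / d,
                        imaginary = sol[n + seq_len(n)] / d)
    } else {
      sr <- try_solve(Ars, Re(load) / d, freqs[i]) / d
      si <- if (any(Im(load) != 0)) {
        try_solve(Ars, Im(load) / d, freqs[i]) / d
      } else {
        numeric(n)
      }
      u[, i] <- complex(real = sr, imaginary = si)
    }
  }
  structure(list(frequencies = freqs, u = u),
            class = "harmonic_solution")
}

try_solve <- function(A, b, f) {
  out <- tryCatch(as.vector(Matrix::solve(A, b)),
                  error = function(e) e)
  if (inherits(out, "error") || any(!is.finite(out))) {
    rc <- tryCatch(suppressWarnings(Matrix::rcond(as(A, "generalMatrix"))),
                   error = function(e) NA_real_)
    abort(sprintf(
      "singular harmonic system at f = %g Hz (undamped resonance?); reciprocal condition estimate %.3g",
      f, rc))
  }
  out
}

#' @rdname harmonic_solve
#' @param solution A `harmonic_solution`.
#' @return `solution_velocity()`: complex velocity matrix `2i*pi*f*u` (m/s).
#' @export
solution_velocity <- function(solution) {
  sweep(solution$u, 2, 2i * pi * solution$frequencies, `*`)
}

#' @exportS3Method print harmonic_solution
print.harmonic_solution <- function(x, ...) {
  cat(sprintf("<harmonic_solution> %d dofs x %d frequencies (%.4g-%.4g Hz)\n",
              nrow(x$u), length(x$frequencies),
              min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' Lowest undamped natural frequencies
#'
#' Solves the generalized symmetric eigenproblem `K v = (2*pi*f)^2 M v`
#' through the shifted-and-inverted dense form `(K + s*M)^{-1} M`, which
#' tolerates singular `K` (rigid-body modes come out at ~0 Hz) and
#' rotational-dof mass entries many orders below the translational ones.
#' Intended for verification fixtures, not for the full assembled ear.
#'
#' @param system An `fe_system` with positive-semidefinite `K` and
#'   positive-definite `M`.
#' @param n Number of frequencies to return (`n < n_free`).
#' @return Ascending natural frequencies in Hz.
#' @export
modal_frequencies <- function(system, n) {
  stopifnot(inherits(system, "fe_system"))
  if (n > system$n_free) abort("n must be <= number of free dofs")
  K <- as.matrix(system$K)
  M <- as.matrix(system$M)
  dM <- diag(M)
  if (any(dM <= 0)) abort("mass matrix not positive definite")
  # symmetric diagonal scaling: shell models mix membrane-stiff and
  # drilling/rotary-soft dofs over ~10 orders of magnitude
  d <- sqrt(pmax(abs(diag(K)), dM))
  d[d == 0] <- 1
  Ks <- K / tcrossprod(d)
  Ms <- M / tcrossprod(d)
  s <- max(mean(diag(Ks)) / mean(diag(Ms)) * 1e-8, 1e-300)
  Ainv <- solve(Ks + s * Ms, Ms, tol = 0)
  ev <- eigen(Ainv, only.values = TRUE)$values
  lam <- 1 / Re(ev[Mod(ev) > 0]) - s
  lam <- sort(pmax(lam, 0))
  sqrt(lam[seq_len(n)]) / (2 * pi)
}
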