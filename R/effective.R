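new_effective_hamiltonian <- function(matrix, construction, wr_hz,
                                      orientation = NULL, eigen_rad_s = NULL) {
  structure(
    list(matrix = matrix, construction = construction, wr_hz = wr_hz,
         orientation = orientation, eigen_rad_s = eigen_rad_s),
    class = "effective_hamiltonian"
  )
}

#' Floquet effective Hamiltonian up to a given order
#'
#' Builds the time-independent effective Hamiltonian of the rotor-periodic
#' Hamiltonian from the commutator expansion of single-mode Floquet theory:
#' first order \eqn{\hat H^{(0)}}, second order
#' \eqn{\frac{1}{2}\sum_{n\ne0} [\hat H^{(n)}, \hat H^{(-n)}]/(n\omega_r)},
#' third order
#' \eqn{\frac{1}{2}\sum_{n\ne0} [\hat H^{(n)}, [\hat H^{(0)}, \hat H^{(-n)}]]
#' /(n\omega_r)^2 + \frac{1}{3}\sum_{k,n\ne0} [\hat H^{(n)}, [\hat H^{(k)},
#' \hat H^{(-k-n)}]]/(nk\omega_r^2)} (components with \eqn{|k+n| > 2} vanish).
#' The order-k contribution scales exactly as \eqn{\omega_r^{-(k-1)}}.
#'
#' @param fh A [fourier_hamiltonian()].
#' @param wr_hz Spinning frequency in Hz (> 0).
#' @param max_order 1, 2 or 3.
#' @return An `effective_hamiltonian` (Hermitian matrix, rad s^-1) tagged
#'   `construction = "order<max_order>"`.
#' @export
floquet_effective <- function(fh, wr_hz, max_order = 2) {
  stopifnot(inherits(fh, "fourier_hamiltonian"))
  if (!is.numeric(wr_hz) || wr_hz <= 0) abort("`wr_hz` must be positive.")
  if (!max_order %in% 1:3) abort("`max_order` must be 1, 2 or 3.")
  wr <- 2 * pi * wr_hz  # rad/s
  h <- fh$h
  hm <- function(n) h[[as.character(n)]]
  H <- hm(0)
  if (max_order >= 2) {
    for (n in c(-2L, -1L, 1L, 2L)) {
      H <- H + .commutator(hm(n), hm(-n)) / (2 * n * wr)
    }
  }
  if (max_order >= 3) {
    for (n in c(-2L, -1L, 1L, 2L)) {
      H <- H + .commutator(hm(n), .commutator(hm(0), hm(-n))) / (2 * (n * wr)^2)
      for (k in c(-2L, -1L, 1L, 2L)) {
        # k = -n belongs to the first (H^(0) cross-term) sum; keeping it here
        # double-counts the shift cross terms and breaks the wr^-3 residual
        if (k + n == 0 || abs(k + n) > 2) next
        H <- H + .commutator(hm(n), .commutator(hm(k), hm(-k - n))) /
          (3 * n * k * wr^2)
      }
    }
  }
  new_effective_hamiltonian(.hermitize(H), paste0("order", max_order), wr_hz,
                            orientation = fh$orientation)
}

#' Rotor-period propagator by time slicing
#'
#' Time-ordered product of slice propagators over one rotor period
#' \eqn{\tau_r = 1/\nu_r} with midpoint sampling of the Hamiltonian; each
#' Hermitian slice is exponentiated through its spectral decomposition, so
#' the result is unitary to machine precision.
#'
#' @param fh A [fourier_hamiltonian()].
#' @param wr_hz Spinning frequency in Hz.
#' @param n_slices Number of time slices per rotor period (>= 4). The
#'   slicing defect decreases with the square of `n_slices`.
#' @return Complex unitary matrix.
#' @export
propagator <- function(fh, wr_hz, n_slices = 1000) {
  stopifnot(inherits(fh, "fourier_hamiltonian"))
  if (!is.numeric(wr_hz) || wr_hz <= 0) abort("`wr_hz` must be positive.")
  if (n_slices < 4) abort("`n_slices` must be at least 4.")
  if (n_slices < 64) {
    warn(sprintf("n_slices = %d is coarse; propagator may not be converged.",
                 as.integer(n_slices)))
  }
  cpp_propagator(unname(fh$h), wr_hz, as.integer(n_slices))
}

#' Exact effective Hamiltonian from the rotor-period propagator
#'
#' Back-calculates the time-independent Hamiltonian whose single-period
#' propagator equals `U`: \eqn{\bar H = (i/\tau_r) \ln U(\tau_r)}, using the
#' principal branch of the logarithm obtained from the complex Schur form of
#' the unitary. Eigenvalues (in Hz) lie in \eqn{(-\nu_r/2, +\nu_r/2]}; an
#' eigenphase within \eqn{10^{-6}\cdot 2\pi} of the branch cut raises a
#' warning.
#'
#' @param U Unitary propagator over one rotor period.
#' @param wr_hz Spinning frequency in Hz.
#' @param orientation Optional [rotor_orientation()] carried as metadata.
#' @return An `effective_hamiltonian` tagged `construction = "exact"`.
#' @export
exact_effective <- function(U, wr_hz, orientation = NULL) {
  du <- .frobenius(Conj(t(U)) %*% U - diag(nrow(U)))
  if (du > 1e-8 * nrow(U)) abort("`U` is not unitary.")
  res <- cpp_unitary_log(U, wr_hz)
  if (isTRUE(res$branch_risk)) {
    warn("An eigenphase lies near the branch cut of the logarithm; eigenvalues close to +/- wr/2 are ambiguous modulo wr.")
  }
  new_effective_hamiltonian(res$matrix, "exact", wr_hz,
                            orientation = orientation,
                            eigen_rad_s = as.numeric(res$eigen_rad_s))
}

#' One-call effective Hamiltonian for a system and orientation
#'
#' @param system A [spin_system()].
#' @param orientation A single [rotor_orientation()].
#' @param wr_hz Spinning frequency in Hz.
#' @param construction `"order1"`, `"order2"`, `"order3"` or `"exact"`.
#' @param n_slices Time slices per rotor period for `"exact"`.
#' @return An `effective_hamiltonian`.
#' @export
effective_hamiltonian <- function(system, orientation, wr_hz,
                                  construction = c("order2", "order3",
                                                   "order1", "exact"),
                                  n_slices = 1000) {
  construction <- match.arg(construction)
  fh <- fourier_hamiltonian(system, orientation)
  if (construction == "exact") {
    exact_effective(propagator(fh, wr_hz, n_slices), wr_hz,
                    orientation = orientation)
  } else {
    floquet_effective(fh, wr_hz, as.integer(sub("order", "", construction)))
  }
}

#' @export
print.effective_hamiltonian <- function(x, ...) {
  cat(sprintf(
    "<effective_hamiltonian> %s, dim %d, wr = %.4g kHz, ||H||_F/2pi = %.4g Hz\n",
    x$construction, nrow(x$matrix), x$wr_hz / 1e3,
    .frobenius(x$matrix) / (2 * pi)
  ))
  invisible(x)
}

#' Eigenvalues of an effective Hamiltonian as a tibble
#'
#' @param x An `effective_hamiltonian`.
#' @param ... Unused.
#' @return Tibble with `state` and `energy_hz` (ascending).
#' @export
tidy.effective_hamiltonian <- function(x, ...) {
  ev <- if (!is.null(x$eigen_rad_s)) sort(x$eigen_rad_s) else
    cpp_eig_herm(x$matrix)$values
  tibble::tibble(state = seq_along(ev), energy_hz = as.numeric(ev) / (2 * pi))
}

#' @export
glance.effective_hamiltonian <- function(x, ...) {
  tibble::tibble(
    construction = x$construction,
    wr_hz = x$wr_hz,
    dim = nrow(x$matrix),
    frobenius_hz = .frobenius(x$matrix) / (2 * pi),
    trace_hz = Re(sum(diag(x$matrix))) / (2 * pi)
  )
}
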