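#' Fourier components of the rotor-periodic Hamiltonian
#'
#' The MAS Hamiltonian of a homonuclear dipolar-coupled system is periodic
#' with the rotor frequency and carries five Fourier components
#' \eqn{\hat H^{(n)}}, \eqn{n = -2..2}:
#' \eqn{\hat H^{(0)} = \sum_p \omega_p \hat I_{pz}} (isotropic shifts only,
#' since the \eqn{m = 0} dipolar coefficient vanishes at the magic angle) and
#' \eqn{\hat H^{(n)} = \sum_{p<q} \omega^{(n)}_{pq} (2\hat I_{pz}\hat I_{qz}
#' - \hat I_{px}\hat I_{qx} - \hat I_{py}\hat I_{qy})} for \eqn{n \ne 0}.
#'
#' @param system A [spin_system()].
#' @param orientation A single [rotor_orientation()].
#' @return Object of class `fourier_hamiltonian`: list with `h` (five complex
#'   matrices, rad s^-1, named "-2".."2"), `n_spins`, `ops`, `orientation`.
#' @export
fourier_hamiltonian <- function(system, orientation) {
  stopifnot(inherits(system, "spin_system"))
  ctx <- .system_context(system)
  .fourier_hamiltonian_fast(
    ctx,
    orientation$alpha_deg * pi / 180,
    orientation$beta_deg * pi / 180,
    orientation$gamma_deg * pi / 180,
    orientation = orientation
  )
}

# Precomputed per-system objects reused across orientations.
.system_context <- function(system) {
  n <- nrow(system$spins)
  ops <- spin_operators(n)
  pair_ops <- .pair_dipolar_operators(ops, system$pairs)
  h0 <- matrix(0 + 0i, ops$dim, ops$dim)
  for (p in seq_len(n)) {
    h0 <- h0 + 2 * pi * system$spins$shift_hz[p] * ops$Iz[[p]]
  }
  list(system = system, ops = ops, pair_ops = pair_ops, h0 = h0,
       A = .pair_tensor_matrix(system))
}

.fourier_hamiltonian_fast <- function(ctx, alpha_rad, beta_rad, gamma_rad,
                                      orientation = NULL) {
  co <- .fourier_coefficients_all(ctx$A, alpha_rad, beta_rad, gamma_rad)
  dim <- ctx$ops$dim
  h <- vector("list", 5)
  names(h) <- as.character(-2:2)
  for (m in c(-2L, -1L, 1L, 2L)) {
    hm <- matrix(0 + 0i, dim, dim)
    for (k in seq_along(ctx$pair_ops)) {
      hm <- hm + co[k, m + 3] * ctx$pair_ops[[k]]
    }
    h[[as.character(m)]] <- hm
  }
  h[["0"]] <- ctx$h0
  structure(
    list(h = h, n_spins = nrow(ctx$system$spins), ops = ctx$ops,
         orientation = orientation),
    class = "fourier_hamiltonian"
  )
}

#' Evaluate the time-dependent Hamiltonian at a time point
#'
#' Reconstructs \eqn{\hat H(t) = \sum_n \hat H^{(n)} e^{i n \omega_r t}}.
#'
#' @param fh A [fourier_hamiltonian()].
#' @param wr_hz Spinning frequency in Hz.
#' @param t Time in seconds.
#' @return Complex Hermitian matrix in rad s^-1.
#' @export
hamiltonian_at <- function(fh, wr_hz, t) {
  stopifnot(inherits(fh, "fourier_hamiltonian"))
  ph <- exp(1i * (-2:2) * 2 * pi * wr_hz * t)
  Reduce(`+`, Map(function(h, z) h * z, fh$h, as.list(ph)))
}
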