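# Rotor-periodic Fourier coefficients of the dipolar couplings.
#
# The secular dipolar coupling of pair (p,q) in the laboratory frame is
#   omega_pq(t) = (delta_pq / 2) * P2(cos Theta_pq(t)),
# where Theta_pq(t) is the time-dependent angle between the internuclear
# vector and the static field. Expressed through three consecutive ZYZ Euler
# rotations -- (0, theta_pq, phi_pq): pair PAS -> PAS of pair (1,2);
# (alpha, beta, gamma): crystallite -> rotor frame; (-wr t, -theta_m, 0):
# rotor -> lab -- the coupling becomes a five-term Fourier series
# sum_m omega^(m) exp(i m wr t) whose m = 0 coefficient vanishes exactly at
# the magic angle.

#' Crystallite orientation in the rotor frame
#'
#' @param alpha_deg,beta_deg,gamma_deg ZYZ Euler angles (degrees) taking the
#'   crystallite frame (PAS of spin pair (1,2)) into the rotor-fixed frame.
#' @param weight Positive quadrature weight.
#' @return One-row tibble of class `rotor_orientation`.
#' @export
rotor_orientation <- function(alpha_deg, beta_deg, gamma_deg = 0, weight = 1) {
  if (any(weight <= 0)) abort("Orientation weights must be positive.")
  out <- tibble::tibble(
    alpha_deg = alpha_deg, beta_deg = beta_deg,
    gamma_deg = gamma_deg, weight = weight
  )
  class(out) <- c("rotor_orientation", class(out))
  out
}

# Pair-dependent part of the Fourier coefficients, precomputed once per
# system: row per pair, column per m1 in -2..2,
#   A[pq, m1] = (delta_pq / 2) * d^2_{0,m1}(theta_pq) * exp(-i m1 phi_pq)
.pair_tensor_matrix <- function(system) {
  th <- system$pairs$theta_deg * pi / 180
  ph <- system$pairs$phi_deg * pi / 180
  np <- nrow(system$pairs)
  A <- matrix(0 + 0i, np, 5)
  for (m1 in -2:2) {
    d0 <- vapply(th, function(b) .wigner_d_element(2, 0, m1, b), numeric(1))
    A[, m1 + 3] <- (system$pairs$delta_rad_s / 2) * d0 * exp(-1i * m1 * ph)
  }
  A
}

# All pairs at once: npairs x 5 complex matrix of omega^(m), m = -2..2 (rad/s)
.fourier_coefficients_all <- function(A, alpha_rad, beta_rad, gamma_rad) {
  tal <- exp(-1i * (-2:2) * alpha_rad)
  M <- (A * rep(tal, each = nrow(A))) %*% .wigner_d2_matrix(beta_rad)
  # d^2_{m,0}(-theta_m) = d^2_{0,m}(theta_m)
  dm0 <- vapply(-2:2, function(m) .wigner_d_element(2, 0, m, .const$theta_magic),
                numeric(1))
  lab <- dm0 * exp(-1i * (-2:2) * gamma_rad)
  M * rep(lab, each = nrow(A))
}

#' Fourier coefficients of one dipolar coupling under MAS
#'
#' The five coefficients \eqn{\omega^{(m)}_{pq}}, \eqn{m = -2..2}, of the
#' rotor-periodic dipolar coupling \eqn{\omega_{pq}(t) = \sum_m \omega^{(m)}
#' e^{i m \omega_r t}} for one pair of a spin system at a given crystallite
#' orientation. Conjugate symmetry \eqn{\omega^{(-m)} = \omega^{(m)*}} holds
#' and the \eqn{m = 0} coefficient vanishes at the magic angle.
#'
#' @param system A [spin_system()].
#' @param p,q Spin indices of the pair.
#' @param orientation A [rotor_orientation()] (one row).
#' @return Tibble with columns `m` (-2..2) and `omega_rad_s` (complex).
#' @export
dipolar_fourier_coefficients <- function(system, p, q, orientation) {
  stopifnot(inherits(system, "spin_system"))
  if (nrow(orientation) != 1) abort("`orientation` must be a single orientation.")
  idx <- which(system$pairs$p == min(p, q) & system$pairs$q == max(p, q))
  if (length(idx) != 1) abort("No such pair in the system.")
  A <- .pair_tensor_matrix(system)
  co <- .fourier_coefficients_all(
    A[idx, , drop = FALSE],
    orientation$alpha_deg * pi / 180,
    orientation$beta_deg * pi / 180,
    orientation$gamma_deg * pi / 180
  )
  tibble::tibble(m = -2:2, omega_rad_s = co[1, ])
}
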