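# Independent oracles used across the suite.

# Cartesian ZYZ rotation matrices (active).
rot_z <- function(a) rbind(c(cos(a), -sin(a), 0), c(sin(a), cos(a), 0), c(0, 0, 1))
rot_y <- function(b) rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
rot_euler <- function(a, b, g) rot_z(a) %*% rot_y(b) %*% rot_z(g)

theta_magic <- acos(1 / sqrt(3))

# Brute-force time trace of the dipolar coupling of pair (p,q): rotate the
# internuclear direction through the three frame transformations with plain
# 3x3 matrices and project onto the static field, omega(t) = (delta/2) *
# P2(cos Theta(t)). No Wigner elements involved.
oracle_coupling_trace <- function(system, p, q, alpha_deg, beta_deg, gamma_deg,
                                  nt = 256) {
  pr <- tidy(system)
  row <- pr[pr$p == min(p, q) & pr$q == max(p, q), ]
  th <- row$theta_deg * pi / 180
  ph <- row$phi_deg * pi / 180
  R12 <- rot_euler(0, th, ph) %*%
    rot_euler(alpha_deg * pi / 180, beta_deg * pi / 180, gamma_deg * pi / 180)
  ts <- (seq_len(nt) - 1) / nt   # fractions of a rotor period
  omega <- vapply(ts, function(u) {
    R <- R12 %*% rot_euler(-2 * pi * u, -theta_magic, 0)
    cth <- (t(c(0, 0, 1)) %*% R %*% c(0, 0, 1))[1, 1]
    row$delta_rad_s / 2 * (3 * cth^2 - 1) / 2
  }, numeric(1))
  list(t_frac = ts, omega = omega)
}

# Discrete Fourier coefficients of the oracle trace: omega(t) =
# sum_m c_m exp(i m wr t).
oracle_fourier <- function(system, p, q, alpha_deg, beta_deg, gamma_deg,
                           nt = 256) {
  tr <- oracle_coupling_trace(system, p, q, alpha_deg, beta_deg, gamma_deg, nt)
  vapply(-2:2, function(m) mean(tr$omega * exp(-1i * m * 2 * pi * tr$t_frac)),
         complex(1))
}

# Rank-2 reduced Wigner matrix by exponentiating the angular-momentum
# generator Jy for l = 2 (rows/cols ordered m = 2..-2).
oracle_wigner_d2 <- function(beta_rad) {
  jp <- matrix(0 + 0i, 5, 5)
  rownames(jp) <- colnames(jp) <- as.character(2:-2)
  for (m in -2:1) jp[as.character(m + 1), as.character(m)] <- sqrt(6 - m * (m + 1))
  Jy <- (jp - Conj(t(jp))) / (2i)
  ev <- eigen(Jy, symmetric = TRUE)
  Re(ev$vectors %*% diag(exp(-1i * beta_rad * ev$values)) %*% Conj(t(ev$vectors)))
}

frobenius <- function(m) sqrt(sum(Mod(m)^2))

herm_expm <- function(H, fac) {
  ev <- eigen(H, symmetric = TRUE)
  ev$vectors %*% diag(exp(fac * ev$values)) %*% Conj(t(ev$vectors))
}

eig_dist <- function(A, B) {
  sqrt(sum((sort(eigen(A, symmetric = TRUE, only.values = TRUE)$values) -
              sort(eigen(B, symmetric = TRUE, only.values = TRUE)$values))^2))
}

# Small randomized spin systems with a fixed seed: coordinates jittered off a
# grid so no two spins come closer than 1 A.
random_system <- function(n, seed, shifted = FALSE) {
  set.seed(seed)
  base <- rbind(c(0, 0, 0), c(0, 0, 1.8), c(2.8, 0, 0.5), c(2.5, 2.2, 1.2))
  xyz <- base[seq_len(n), , drop = FALSE] + matrix(runif(3 * n, -0.3, 0.3), n, 3)
  shifts <- if (shifted) round(runif(n, -0.5, 0.9), 2) else rep(0, n)
  spin_system(data.frame(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                         shift_ppm = shifts))
}
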