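#' Dipolar coupling anisotropy of a two-spin pair
#'
#' Point-dipole coupling anisotropy
#' \eqn{\delta = -2 (\mu_0/4\pi)\, \gamma_1 \gamma_2 \hbar / r^3}.
#' For two like spins (same sign of \eqn{\gamma}) the anisotropy is negative.
#'
#' @param distance Internuclear distance in Angstrom. Vectorised.
#' @param gamma1,gamma2 Gyromagnetic ratios in rad s^-1 T^-1; default proton.
#' @return Anisotropy in rad s^-1 (divide by `2*pi` for Hz).
#' @export
#' @examples
#' dipolar_anisotropy(1.75) / (2 * pi)  # about -44826 Hz
dipolar_anisotropy <- function(distance, gamma1 = gamma_proton(), gamma2 = gamma1) {
  if (any(!is.finite(distance)) || any(distance <= 0)) {
    abort("`distance` must be positive and finite (Angstrom).")
  }
  r <- distance * 1e-10
  -2 * .const$mu0_4pi * gamma1 * gamma2 * .const$hbar / r^3
}

# Orthonormal crystallite frame: z along r1 -> r2, x chosen so that the first
# spin not collinear with the (1,2) axis lies in the x-z half-plane (x >= 0
# for spin 3 in the paper-style planar systems).
.system_frame <- function(xyz) {
  ez <- xyz[2, ] - xyz[1, ]
  ez <- ez / sqrt(sum(ez^2))
  ex <- NULL
  if (nrow(xyz) >= 3) {
    for (k in 3:nrow(xyz)) {
      v <- xyz[k, ] - xyz[1, ]
      v <- v - sum(v * ez) * ez
      if (sqrt(sum(v^2)) > 1e-8) {
        ex <- v / sqrt(sum(v^2))
        break
      }
    }
  }
  if (is.null(ex)) {
    # collinear (or two-spin) system: any perpendicular axis will do
    trial <- if (abs(ez[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- trial - sum(trial * ez) * ez
    ex <- v / sqrt(sum(v^2))
  }
  ey <- c(
    ez[2] * ex[3] - ez[3] * ex[2],
    ez[3] * ex[1] - ez[1] * ex[3],
    ez[1] * ex[2] - ez[2] * ex[1]
  )
  rbind(ex = ex, ey = ey, ez = ez)
}

#' Build a homonuclear spin system from coordinates and shifts
#'
#' Constructs a spin system from a data frame of proton coordinates (Angstrom)
#' and isotropic chemical shifts (ppm). All pairwise dipolar anisotropies and
#' relative orientations are derived. The crystallite frame convention places
#' the z axis along the vector from spin 1 to spin 2 (so pair (1,2) has polar
#' angle `theta = 0`) and the x-z plane through the first non-collinear spin,
#' so planar systems have azimuth `phi` of 0 or 180 degrees.
#'
#' @param spins Data frame with columns `x`, `y`, `z` (Angstrom) and
#'   optionally `shift_ppm` (default 0).
#' @param larmor_hz Proton Larmor frequency in Hz, used for the ppm-to-Hz
#'   conversion of shifts.
#' @param gamma Gyromagnetic ratio of the (homonuclear) spins, rad s^-1 T^-1.
#' @return An object of class `spin_system` with elements `spins` (tibble:
#'   spin, x, y, z, shift_ppm, shift_hz), `pairs` (tibble: p, q, distance,
#'   delta_rad_s, delta_hz, theta_deg, phi_deg), `larmor_hz`, `gamma`,
#'   `frame` (3 x 3 crystallite axes).
#' @export
#' @examples
#' sys <- spin_system(data.frame(
#'   x = c(0, 0, 3), y = c(0, 0, 0), z = c(0, 1.75, 0)
#' ))
#' tidy(sys)
spin_system <- function(spins, larmor_hz = 1e9, gamma = gamma_proton()) {
  spins <- tibble::as_tibble(spins)
  if (!all(c("x", "y", "z") %in% names(spins))) {
    abort("`spins` must have columns x, y, z (Angstrom).")
  }
  if (!"shift_ppm" %in% names(spins)) spins$shift_ppm <- 0
  n <- nrow(spins)
  if (n < 2) abort("A spin system needs at least 2 spins.")
  xyz <- as.matrix(spins[, c("x", "y", "z")])
  storage.mode(xyz) <- "double"
  if (any(!is.finite(xyz))) abort("Spin positions must be finite.")
  if (!is.numeric(larmor_hz) || larmor_hz <= 0) abort("`larmor_hz` must be positive.")

  pr <- t(utils::combn(n, 2))
  dvec <- xyz[pr[, 2], , drop = FALSE] - xyz[pr[, 1], , drop = FALSE]
  dist <- sqrt(rowSums(dvec^2))
  if (any(dist < 0.5)) {
    abort("Two spins are closer than 0.5 Angstrom; coincident or degenerate geometry.")
  }

  frame <- .system_frame(xyz)
  u <- dvec / dist            # unit vectors, lab coordinates
  uc <- u %*% t(frame)        # crystallite-frame coordinates (ex, ey, ez)
  ct <- pmin(1, pmax(-1, uc[, 3]))
  theta <- acos(ct) * 180 / pi
  phi <- ifelse(
    abs(ct) > 1 - 1e-12, 0,
    (atan2(uc[, 2], uc[, 1]) * 180 / pi) %% 360
  )
  phi[phi > 360 - 1e-9] <- 0
  theta[theta < 1e-9] <- 0
  delta <- dipolar_anisotropy(dist, gamma)

  spins_tbl <- tibble::tibble(
    spin = seq_len(n),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    shift_ppm = as.numeric(spins$shift_ppm),
    shift_hz = as.numeric(spins$shift_ppm) * larmor_hz * 1e-6
  )
  pairs <- tibble::tibble(
    p = pr[, 1], q = pr[, 2],
    distance = dist,
    delta_rad_s = delta,
    delta_hz = delta / (2 * pi),
    theta_deg = theta,
    phi_deg = phi
  )
  structure(
    list(spins = spins_tbl, pairs = pairs, larmor_hz = larmor_hz,
         gamma = gamma, frame = frame),
    class = "spin_system"
  )
}

#' Relative orientation of a spin pair
#'
#' Polar and azimuthal angles of the internuclear vector from spin `p` to spin
#' `q` in the crystallite frame (z along the (1,2) direction).
#'
#' @param system A [spin_system()].
#' @param p,q Spin indices, `p != q`.
#' @return One-row tibble with `theta_deg` (polar, 0-180) and `phi_deg`
#'   (azimuth, 0-360).
#' @export
pair_orientation <- function(system, p, q) {
  stopifnot(inherits(system, "spin_system"))
  n <- nrow(system$spins)
  if (p == q) abort("`p` and `q` must differ.")
  if (!all(c(p, q) %in% seq_len(n))) abort("Spin index out of range.")
  if (p < q) {
    row <- dplyr::filter(system$pairs, .data$p == !!p, .data$q == !!q)
    tibble::tibble(theta_deg = row$theta_deg, phi_deg = row$phi_deg)
  } else {
    # reversed direction: antipodal point on the sphere
    row <- dplyr::filter(system$pairs, .data$p == !!q, .data$q == !!p)
    tibble::tibble(
      theta_deg = 180 - row$theta_deg,
      phi_deg = (row$phi_deg + 180) %% 360
    )
  }
}

#' @export
print.spin_system <- function(x, ...) {
  cat(sprintf(
    "<spin_system> %d protons, Larmor %.4g MHz\n",
    nrow(x$spins), x$larmor_hz / 1e6
  ))
  cat("Spins:\n")
  print(x$spins, n = Inf)
  cat("Dipolar pairs:\n")
  print(x$pairs, n = Inf)
  invisible(x)
}

#' Tidy a spin system into its pairwise couplings
#'
#' @param x A [spin_system()].
#' @param ... Unused.
#' @return The tibble of dipolar pairs.
#' @export
tidy.spin_system <- function(x, ...) x$pairs

#' One-row summary of a spin system
#'
#' @param x A [spin_system()].
#' @param ... Unused.
#' @export
glance.spin_system <- function(x, ...) {
  tibble::tibble(
    n_spins = nrow(x$spins),
    larmor_hz = x$larmor_hz,
    max_coupling_hz = max(abs(x$pairs$delta_hz)),
    max_shift_hz = max(abs(x$spins$shift_hz)),
    span_shift_hz = diff(range(x$spins$shift_hz))
  )
}
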