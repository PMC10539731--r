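# Built-in model spin systems: a strongly coupled CH2-like proton pair with
# one or two additional protons, used throughout the package's scans.

#' Three-proton model system (CH2 pair plus a remote proton)
#'
#' Spins at (0,0,0), (0,0,1.75) and (3,0,0) Angstrom: a strongly coupled
#' CH2-like pair (delta/2pi = -44.8 kHz) with a more distant third proton
#' (r13 = 3.00 A, r23 = 3.47 A, theta13 = 90 deg, theta23 = 120.26 deg).
#' The coordinates imply delta23/2pi = -5734 Hz; reference tabulations of
#' this geometry occasionally quote -5750 Hz for that pair, but the
#' constructor always derives couplings from the coordinates.
#'
#' @param shifts_ppm Isotropic shifts of the three spins (ppm).
#' @param larmor_hz Larmor frequency (Hz).
#' @return A [spin_system()].
#' @export
three_spin_system <- function(shifts_ppm = c(0, 0, 0), larmor_hz = 1e9) {
  spin_system(
    data.frame(
      x = c(0, 0, 3), y = c(0, 0, 0), z = c(0, 1.75, 0),
      shift_ppm = shifts_ppm
    ),
    larmor_hz = larmor_hz
  )
}

#' Four-proton model system
#'
#' The three-spin geometry of [three_spin_system()] extended by a fourth
#' proton at (3.5, 0, 2.0) Angstrom, giving couplings delta/2pi of -44826,
#' -8898, -3667, -5734, -5561 and -27420 Hz for the pairs (12), (13), (14),
#' (23), (24), (34).
#'
#' @inheritParams three_spin_system
#' @export
four_spin_system <- function(shifts_ppm = c(0, 0, 0, 0), larmor_hz = 1e9) {
  spin_system(
    data.frame(
      x = c(0, 0, 3, 3.5), y = c(0, 0, 0, 0), z = c(0, 1.75, 0, 2),
      shift_ppm = shifts_ppm
    ),
    larmor_hz = larmor_hz
  )
}

#' Phosphoserine-like three-proton system
#'
#' A CH2/CalphaH-style triangle with r12 = 1.60 A, r13 = r23 = 2.35 A and
#' apex angles of 70 degrees at spins 1 and 2, for studying
#' spinning-frequency-dependent line shifts. The default shifts are
#' synthetic, representative methylene/methine proton values (the geometry,
#' not the shift set, controls the shift-scan behavior).
#'
#' @param shifts_ppm Isotropic shifts (ppm); synthetic defaults.
#' @param larmor_hz Larmor frequency (Hz); default a 20 T field.
#' @export
phosphoserine_mimic_system <- function(shifts_ppm = c(4.4, 3.9, 4.1),
                                       larmor_hz = 8.515e8) {
  a <- 70 * pi / 180
  spin_system(
    data.frame(
      x = c(0, 0, 2.35 * sin(a)), y = c(0, 0, 0),
      z = c(0, 1.60, 2.35 * cos(a)),
      shift_ppm = shifts_ppm
    ),
    larmor_hz = larmor_hz
  )
}

#' All built-in demonstration systems
#'
#' @return Named list of [spin_system()] objects: the dipolar-only three- and
#'   four-spin systems, the two shifted three-spin variants (shifts 0/0/0.7
#'   ppm and -0.1/0.2/0.7 ppm at 1 GHz), and the phosphoserine-like mimic.
#' @export
demo_spin_systems <- function() {
  list(
    three_spin = three_spin_system(),
    three_spin_shifted_a = three_spin_system(shifts_ppm = c(0, 0, 0.7)),
    three_spin_shifted_b = three_spin_system(shifts_ppm = c(-0.1, 0.2, 0.7)),
    four_spin = four_spin_system(),
    phosphoserine_mimic = phosphoserine_mimic_system()
  )
}
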