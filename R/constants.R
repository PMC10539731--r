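# Physical constants (CODATA 2018) and fixed geometry.
# Internal angular-frequency unit is rad s^-1; user-facing I/O is Hz and ppm.

.const <- list(
  gamma_1H = 2.6752218744e8,    # proton gyromagnetic ratio, rad s^-1 T^-1
  hbar     = 1.054571817e-34,   # reduced Planck constant, J s
  mu0_4pi  = 1e-7,              # magnetic constant / 4 pi, T m A^-1
  theta_magic = acos(1 / sqrt(3))  # magic angle, rad (full double precision)
)

#' Proton gyromagnetic ratio
#'
#' @return The proton gyromagnetic ratio in rad s^-1 T^-1 (CODATA).
#' @export
#' @examples
#' gamma_proton()
gamma_proton <- function() .const$gamma_1H

#' Physical constants used by the package
#'
#' @return A tibble with one row per constant: name, value, unit.
#' @export
mas_constants <- function() {
  tibble::tibble(
    name = c("gamma_1H", "hbar", "mu0_4pi", "theta_magic"),
    value = c(.const$gamma_1H, .const$hbar, .const$mu0_4pi, .const$theta_magic),
    unit = c("rad s-1 T-1", "J s", "T m A-1", "rad")
  )
}
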