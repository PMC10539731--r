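# Rank-2 reduced Wigner rotation matrix elements d^2_{m,m'}(beta).
# Implemented through Wigner's closed-form sum (exact for any rank, used here
# at rank 2 only), with the Condon-Shortley phase convention:
#   d^l_{m,m'}(beta) = <l m| exp(-i beta Jy) |l m'>.

.wigner_d_element <- function(l, m, mp, beta_rad) {
  smin <- max(0, mp - m)
  smax <- min(l + mp, l - m)
  pref <- sqrt(factorial(l + m) * factorial(l - m) *
                 factorial(l + mp) * factorial(l - mp))
  c2 <- cos(beta_rad / 2)
  s2 <- sin(beta_rad / 2)
  out <- 0
  for (s in smin:smax) {
    out <- out + (-1)^(m - mp + s) /
      (factorial(l + mp - s) * factorial(s) *
         factorial(m - mp + s) * factorial(l - m - s)) *
      c2^(2 * l + mp - m - 2 * s) * s2^(m - mp + 2 * s)
  }
  pref * out
}

#' Rank-2 reduced Wigner rotation matrix element
#'
#' \eqn{d^2_{m,m'}(\beta)} in the Condon-Shortley convention
#' (\eqn{d^l_{m,m'}(\beta) = \langle l m| e^{-i\beta J_y} |l m'\rangle}).
#'
#' @param m,mp Row and column indices in -2..2.
#' @param beta_deg Rotation angle in degrees. Vectorised.
#' @return Dimensionless matrix element(s).
#' @export
#' @examples
#' reduced_wigner(0, 0, 54.7356103)  # vanishes at the magic angle
reduced_wigner <- function(m, mp, beta_deg) {
  if (length(m) != 1 || length(mp) != 1 ||
      m != round(m) || mp != round(mp) || abs(m) > 2 || abs(mp) > 2) {
    abort("`m` and `mp` must be single integers in -2..2.")
  }
  vapply(beta_deg * pi / 180, function(b) .wigner_d_element(2, m, mp, b),
         numeric(1))
}

# Full 5x5 reduced rotation matrix; element [m + 3, mp + 3] = d^2_{m,mp}(beta).
.wigner_d2_matrix <- function(beta_rad) {
  out <- matrix(0, 5, 5)
  for (m in -2:2) {
    for (mp in -2:2) {
      out[m + 3, mp + 3] <- .wigner_d_element(2, m, mp, beta_rad)
    }
  }
  out
}
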