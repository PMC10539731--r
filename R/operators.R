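# Spin-1/2 product operators on the Zeeman product basis.
# Spin 1 is the most significant factor: basis states are ordered
# |up..up>, ..., |down..down> with spin N toggling fastest.

.single_spin <- list(
  Ix = matrix(c(0, 0.5, 0.5, 0), 2, 2, byrow = TRUE) + 0i,
  Iy = matrix(c(0, -0.5i, 0.5i, 0), 2, 2, byrow = TRUE),
  Iz = diag(c(0.5, -0.5)) + 0i,
  Id = diag(2) + 0i
)

# Embed a single-spin operator at position p of an N-spin register.
.embed <- function(op, p, n) {
  out <- if (p == 1) op else diag(2^(p - 1)) + 0i
  if (p > 1) out <- kronecker(out, op)
  if (p < n) out <- kronecker(out, diag(2^(n - p)) + 0i)
  out
}

#' Product spin operators for an N-spin-1/2 system
#'
#' @param n Number of spins (dimension `2^n`).
#' @return List with per-spin operator lists `Ix`, `Iy`, `Iz` (each a list of
#'   length `n`), the totals `Fx`, `Fy`, `Fz`, the detection operator
#'   `Fminus = Fx - i Fy`, and `dim`.
#' @export
spin_operators <- function(n) {
  stopifnot(n >= 1, n == round(n))
  Ix <- lapply(seq_len(n), function(p) .embed(.single_spin$Ix, p, n))
  Iy <- lapply(seq_len(n), function(p) .embed(.single_spin$Iy, p, n))
  Iz <- lapply(seq_len(n), function(p) .embed(.single_spin$Iz, p, n))
  Fx <- Reduce(`+`, Ix)
  Fy <- Reduce(`+`, Iy)
  Fz <- Reduce(`+`, Iz)
  list(Ix = Ix, Iy = Iy, Iz = Iz, Fx = Fx, Fy = Fy, Fz = Fz,
       Fminus = Fx - 1i * Fy, dim = 2^n)
}

# Dipolar two-spin operators 2 IpzIqz - IpxIqx - IpyIqy, one per pair p < q,
# in the order of the system's pairs table.
.pair_dipolar_operators <- function(ops, pairs) {
  lapply(seq_len(nrow(pairs)), function(k) {
    p <- pairs$p[k]; q <- pairs$q[k]
    2 * ops$Iz[[p]] %*% ops$Iz[[q]] -
      ops$Ix[[p]] %*% ops$Ix[[q]] -
      ops$Iy[[p]] %*% ops$Iy[[q]]
  })
}

.commutator <- function(a, b) a %*% b - b %*% a

.frobenius <- function(m) sqrt(sum(Mod(m)^2))

.hermitize <- function(m) (m + Conj(t(m))) / 2
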