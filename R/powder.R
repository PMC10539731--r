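#' Deterministic equal-area powder orientations
#'
#' Low-discrepancy crystallite orientations covering the sphere with equal
#' areas: `cos(beta)` traverses a symmetric uniform grid while `alpha`
#' advances by the golden-ratio fraction of a turn (a ZCW-style Fibonacci
#' construction). The set is deterministic for a given count -- no random
#' numbers are involved. `gamma` is 0 by default; with `sample_gamma` each
#' (alpha, beta) point is replicated on a uniform `gamma` grid.
#'
#' @param count Number of (alpha, beta) points (>= 10).
#' @param sample_gamma Also sample the third Euler angle?
#' @param gamma_steps Number of uniform gamma steps when `sample_gamma`.
#' @return A [rotor_orientation()] tibble of class `orientation_set` with
#'   uniform weights summing to 1; attributes `scheme` and `count`.
#' @export
#' @examples
#' ori <- zcw_orientations(144)
#' sum(ori$weight)
zcw_orientations <- function(count, sample_gamma = FALSE, gamma_steps = 8) {
  if (count < 10) abort("`count` must be at least 10 for a meaningful powder average.")
  count <- as.integer(count)
  j <- seq_len(count) - 1L
  g <- (sqrt(5) - 1) / 2
  alpha <- 360 * ((j * g) %% 1)
  beta <- acos(2 * (j + 0.5) / count - 1) * 180 / pi
  gamma <- 0
  if (sample_gamma) {
    if (gamma_steps < 1) abort("`gamma_steps` must be at least 1.")
    gamma <- rep(seq(0, gamma_steps - 1) * 360 / gamma_steps, each = count)
    alpha <- rep(alpha, times = gamma_steps)
    beta <- rep(beta, times = gamma_steps)
  }
  out <- rotor_orientation(alpha, beta, gamma, weight = 1 / length(alpha))
  attr(out, "scheme") <- if (sample_gamma) "zcw-golden+gamma" else "zcw-golden"
  attr(out, "count") <- count
  class(out) <- c("orientation_set", class(out))
  out
}

#' Powder average of a per-orientation computation
#'
#' Applies `f` to every orientation and accumulates the results with the
#' orientation weights. Stick spectra are pooled transition-by-transition
#' (the correct order for moment analysis: transitions are pooled first,
#' moments are taken of the pool); numeric results are averaged.
#'
#' @param f Function of a single [rotor_orientation()] row returning either a
#'   `stick_spectrum` or a numeric vector.
#' @param orientations An orientation set (e.g. [zcw_orientations()]).
#' @return A pooled `stick_spectrum` or the weighted numeric average.
#' @export
powder_average <- function(f, orientations) {
  stopifnot(nrow(orientations) >= 1)
  first <- f(orientations[1, ])
  if (inherits(first, "stick_spectrum")) {
    acc_f <- vector("list", nrow(orientations))
    acc_i <- vector("list", nrow(orientations))
    meta <- list(wr = attr(first, "wr_hz"), constr = attr(first, "construction"))
    tot <- 0
    for (k in seq_len(nrow(orientations))) {
      s <- if (k == 1) first else f(orientations[k, ])
      if (!identical(attr(s, "wr_hz"), meta$wr) ||
          !identical(attr(s, "construction"), meta$constr)) {
        abort("Inconsistent spectrum metadata across orientations.")
      }
      w <- orientations$weight[k]
      acc_f[[k]] <- s$frequency_hz
      acc_i[[k]] <- s$intensity * w
      tot <- tot + attr(s, "total_intensity") * w
    }
    out <- tibble::tibble(
      frequency_hz = unlist(acc_f), intensity = unlist(acc_i)
    )
    attr(out, "wr_hz") <- meta$wr
    attr(out, "construction") <- meta$constr
    attr(out, "total_intensity") <- tot
    attr(out, "n_orientations") <- nrow(orientations)
    class(out) <- c("stick_spectrum", class(out))
    return(out)
  }
  if (!is.numeric(first)) abort("`f` must return a stick_spectrum or a numeric vector.")
  acc <- first * orientations$weight[1]
  for (k in seq_len(nrow(orientations))[-1]) {
    acc <- acc + f(orientations[k, ]) * orientations$weight[k]
  }
  acc
}

#' Powder-averaged stick spectrum of a spin system
#'
#' Pools the transitions of the chosen effective-Hamiltonian construction
#' over a powder orientation set.
#'
#' @param system A [spin_system()].
#' @param wr_hz Spinning frequency in Hz.
#' @param construction `"order1"`, `"order2"`, `"order3"` or `"exact"`.
#' @param orientations An orientation set; default `zcw_orientations(1000)`.
#' @param n_slices Propagator time slices for `"exact"`.
#' @param floor_rel Transitions below this fraction of the per-orientation
#'   absolute intensity are dropped.
#' @return A pooled `stick_spectrum`.
#' @export
powder_spectrum <- function(system, wr_hz,
                            construction = c("order2", "order3", "order1", "exact"),
                            orientations = zcw_orientations(1000),
                            n_slices = 1000, floor_rel = 1e-12) {
  construction <- match.arg(construction)
  ctx <- .system_context(system)
  nor <- nrow(orientations)
  acc_f <- vector("list", nor)
  acc_i <- vector("list", nor)
  tot <- 0
  al <- orientations$alpha_deg * pi / 180
  be <- orientations$beta_deg * pi / 180
  ga <- orientations$gamma_deg * pi / 180
  for (k in seq_len(nor)) {
    fh <- .fourier_hamiltonian_fast(ctx, al[k], be[k], ga[k])
    H <- .construct_matrix(fh, wr_hz, construction, n_slices)
    st <- .sticks_from_matrix(H, ctx$ops$Fx, ctx$ops$Fminus, floor_rel)
    w <- orientations$weight[k]
    acc_f[[k]] <- st$frequency_hz
    acc_i[[k]] <- st$intensity * w
    tot <- tot + Re(st$total) * w
  }
  out <- tibble::tibble(frequency_hz = unlist(acc_f), intensity = unlist(acc_i))
  attr(out, "wr_hz") <- wr_hz
  attr(out, "construction") <- construction
  attr(out, "total_intensity") <- tot
  attr(out, "n_orientations") <- nor
  class(out) <- c("stick_spectrum", class(out))
  out
}

# Effective-Hamiltonian matrix for one construction (internal fast path).
.construct_matrix <- function(fh, wr_hz, construction, n_slices = 1000) {
  if (construction == "exact") {
    U <- cpp_propagator(unname(fh$h), wr_hz, as.integer(n_slices))
    cpp_unitary_log(U, wr_hz)$matrix
  } else {
    floquet_effective(fh, wr_hz, as.integer(sub("order", "", construction)))$matrix
  }
}
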