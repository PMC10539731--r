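#' Spectral region: one or more disjoint frequency intervals
#'
#' Intervals are half-open `(lower, upper]`, matching the convention for the
#' center band of an exact effective Hamiltonian whose eigenvalues lie in
#' `(-wr/2, +wr/2]`.
#'
#' @param lower_hz,upper_hz Numeric vectors of interval bounds (Hz).
#' @param line Optional labels (one per interval).
#' @return Tibble of class `spectral_region`.
#' @export
spectral_region <- function(lower_hz, upper_hz, line = NULL) {
  if (any(!is.finite(lower_hz)) || any(!is.finite(upper_hz))) {
    abort("Region bounds must be finite.")
  }
  if (any(upper_hz <= lower_hz)) abort("Each interval needs `lower_hz < upper_hz`.")
  o <- order(lower_hz)
  if (any(lower_hz[o][-1] < upper_hz[o][-length(o)])) {
    abort("Region intervals overlap; they must be disjoint.")
  }
  out <- tibble::tibble(
    line = line %||% as.character(seq_along(lower_hz)),
    lower_hz = lower_hz, upper_hz = upper_hz
  )
  class(out) <- c("spectral_region", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Index of the interval containing each frequency (NA if outside all).
.region_index <- function(region, freq_hz) {
  idx <- rep(NA_integer_, length(freq_hz))
  for (k in seq_len(nrow(region))) {
    hit <- freq_hz > region$lower_hz[k] & freq_hz <= region$upper_hz[k]
    idx[hit] <- k
  }
  idx
}

#' Center-band region around a reference frequency
#'
#' The interval `(reference - wr/2, reference + wr/2]`: the spectral region
#' free of spinning sidebands for an effective-Hamiltonian spectrum.
#'
#' @param s A `stick_spectrum` (its spinning frequency is read from the
#'   metadata), or `NULL` if `wr_hz` is given directly.
#' @param reference_hz Center of the band (Hz).
#' @param wr_hz Spinning frequency in Hz (overrides the metadata).
#' @return A [spectral_region()] with a single interval labelled "center".
#' @export
center_band <- function(s = NULL, reference_hz = 0, wr_hz = NULL) {
  wr <- wr_hz %||% attr(s, "wr_hz")
  if (is.null(wr)) abort("Spinning frequency unknown: supply `wr_hz` or a stick spectrum with metadata.")
  spectral_region(reference_hz - wr / 2, reference_hz + wr / 2, line = "center")
}

# Fast matrix-level stick computation shared by user API and powder loops.
# Returns transition frequencies (Hz), intensities, index pairs, and the
# total complex intensity.
.sticks_from_matrix <- function(H, sigma0, detect, floor_rel = 1e-12) {
  e <- cpp_eig_herm(H)
  V <- e$vectors
  sig <- Conj(t(V)) %*% sigma0 %*% V
  det <- Conj(t(V)) %*% detect %*% V
  # FID amplitude of transition (i,j) in Tr(sigma(t) d): sigma_ij * d_ji,
  # invariant under the arbitrary eigenvector phases (gauge) of V
  amp <- sig * t(det)
  total <- sum(amp)
  inten <- Re(amp)
  freq <- outer(e$values, e$values, "-") / (2 * pi)
  keep <- abs(inten) > floor_rel * sum(abs(inten))
  ij <- which(keep, arr.ind = TRUE)
  list(frequency_hz = freq[keep], intensity = inten[keep],
       i = ij[, 1], j = ij[, 2], total = total)
}

# Merge transitions closer than `tol` Hz (degenerate eigenvalue differences).
.merge_sticks <- function(freq, inten, i, j, tol = 1e-9) {
  o <- order(freq)
  freq <- freq[o]; inten <- inten[o]; i <- i[o]; j <- j[o]
  grp <- cumsum(c(1, diff(freq) > tol))
  if (max(grp) == length(freq)) {
    return(list(frequency_hz = freq, intensity = inten, i = i, j = j))
  }
  keep_first <- !duplicated(grp)
  list(
    frequency_hz = as.numeric(tapply(freq, grp, mean)),
    intensity = as.numeric(tapply(inten, grp, sum)),
    i = i[keep_first], j = j[keep_first]
  )
}

#' Stick spectrum of an effective Hamiltonian
#'
#' Diagonalizes the effective Hamiltonian and forms one transition per
#' eigenstate pair: frequency \eqn{\omega_{ij} = E_i - E_j} (signed, Hz) and
#' intensity \eqn{I_{ij} = \mathrm{Re}[(\sigma_0)_{ij} d_{ji}]} -- the
#' amplitude of that transition in the detected signal
#' \eqn{\mathrm{Tr}[\sigma(t) d]} -- with the initial density operator and
#' detection operator transformed into the eigenbasis. Equivalently
#' \eqn{(\sigma_0)_{ij} [(d^\dagger)_{ij}]^*}, which is independent of the
#' arbitrary eigenvector phases. The total intensity is set by the operators alone and is
#' identical for every Hermitian Hamiltonian of the same dimension.
#' Transitions within 1e-9 Hz are merged.
#'
#' @param heff An `effective_hamiltonian` (or a plain Hermitian matrix in
#'   rad s^-1 together with `wr_hz`).
#' @param initial Initial density operator; default total `Fx`.
#' @param detect Detection operator; default `Fminus = Fx - i Fy`.
#' @param wr_hz Spinning frequency metadata when `heff` is a plain matrix.
#' @return Tibble of class `stick_spectrum` with columns `frequency_hz`,
#'   `intensity`, `i`, `j`; attributes `wr_hz`, `construction`,
#'   `total_intensity`.
#' @export
stick_spectrum <- function(heff, initial = NULL, detect = NULL, wr_hz = NULL) {
  if (inherits(heff, "effective_hamiltonian")) {
    H <- heff$matrix
    wr <- heff$wr_hz
    constr <- heff$construction
  } else {
    H <- heff
    wr <- wr_hz
    constr <- "matrix"
  }
  if (.frobenius(H - Conj(t(H))) > 1e-10 * (1 + .frobenius(H))) {
    abort("The effective Hamiltonian must be Hermitian.")
  }
  n <- as.integer(round(log2(nrow(H))))
  ops <- spin_operators(n)
  sigma0 <- initial %||% ops$Fx
  det <- detect %||% ops$Fminus
  st <- .sticks_from_matrix(H, sigma0, det)
  if (abs(Im(st$total)) > 1e-8 * max(abs(Re(st$total)), 1e-300)) {
    warn("Imaginary residual of the total intensity exceeds 1e-8; check operator phases.")
  }
  st <- .merge_sticks(st$frequency_hz, st$intensity, st$i, st$j)
  out <- tibble::tibble(
    frequency_hz = st$frequency_hz, intensity = st$intensity,
    i = st$i, j = st$j
  )
  attr(out, "wr_hz") <- wr
  attr(out, "construction") <- constr
  attr(out, "total_intensity") <- Re(sum(out$intensity))
  class(out) <- c("stick_spectrum", class(out))
  out
}

#' Spectral moments and Gaussian-equivalent line width
#'
#' Intensity-weighted raw moments \eqn{M_n = \sum \omega^n I / \sum I} over
#' the transitions inside a region, the central second moment
#' \eqn{M_2 - M_1^2}, and the full width at half maximum of a Gaussian line
#' with the same central second moment,
#' \eqn{\mathrm{FWHM} = 2\sqrt{2\ln 2}\sqrt{M_2 - M_1^2}}.
#'
#' @param s A `stick_spectrum` (possibly powder-pooled).
#' @param region A [spectral_region()]; `NULL` uses all transitions.
#' @param n Highest raw moment to report (>= 2).
#' @return One-row tibble of class `moment_report`: `n_transitions`,
#'   `total_intensity`, `m1_hz`, `m2_raw_hz2`, `m2_central_hz2`,
#'   `gaussian_fwhm_hz`, plus `m<k>_raw` columns up to `n`.
#' @export
moments <- function(s, region = NULL, n = 2) {
  if (n < 2) abort("`n` must be at least 2.")
  f <- s$frequency_hz
  w <- s$intensity
  if (!is.null(region)) {
    keep <- !is.na(.region_index(region, f))
    f <- f[keep]; w <- w[keep]
  }
  if (length(f) == 0) abort("No transitions fall inside the region.")
  tot <- sum(w)
  if (tot == 0) abort("Transitions in the region carry zero total intensity.")
  raw <- vapply(seq_len(n), function(k) sum(w * f^k) / tot, numeric(1))
  central2 <- raw[2] - raw[1]^2
  out <- tibble::tibble(
    n_transitions = length(f),
    total_intensity = tot,
    m1_hz = raw[1],
    m2_raw_hz2 = raw[2],
    m2_central_hz2 = central2,
    gaussian_fwhm_hz = 2 * sqrt(2 * log(2)) * sqrt(max(central2, 0))
  )
  if (n > 2) {
    for (k in 3:n) out[[paste0("m", k, "_raw")]] <- raw[k]
  }
  class(out) <- c("moment_report", class(out))
  out
}

#' Bin a stick spectrum onto a regular frequency grid
#'
#' Intensity-conserving histogram over a window centered at `center_hz`,
#' optionally convolved with a Lorentzian of the given full width at half
#' maximum (the frequency-domain equivalent of exponential line broadening
#' of the time signal).
#'
#' @param s A `stick_spectrum`.
#' @param window_hz Full spectral window in Hz.
#' @param npoints Number of grid points (>= 2); digital resolution is
#'   `window_hz / npoints`.
#' @param broadening_hz Lorentzian FWHM in Hz (>= 0; 0 = plain histogram).
#' @param center_hz Window center (Hz).
#' @return Tibble of class `binned_spectrum` with `frequency_hz` (bin
#'   centers) and `intensity`; attribute `resolution_hz`.
#' @export
bin_spectrum <- function(s, window_hz, npoints, broadening_hz = 0,
                         center_hz = 0) {
  if (npoints < 2) abort("`npoints` must be at least 2.")
  if (broadening_hz < 0) abort("`broadening_hz` must be non-negative.")
  res <- window_hz / npoints
  lo <- center_hz - window_hz / 2
  idx <- floor((s$frequency_hz - lo) / res) + 1
  keep <- idx >= 1 & idx <= npoints
  v <- numeric(npoints)
  if (any(keep)) {
    agg <- rowsum(s$intensity[keep], idx[keep])
    v[as.integer(rownames(agg))] <- agg[, 1]
  }
  if (broadening_hz > 0) v <- .lorentz_convolve(v, res, broadening_hz)
  out <- tibble::tibble(
    frequency_hz = lo + (seq_len(npoints) - 0.5) * res,
    intensity = v
  )
  attr(out, "resolution_hz") <- res
  attr(out, "wr_hz") <- attr(s, "wr_hz")
  class(out) <- c("binned_spectrum", class(out))
  out
}

#' Assign spectral regions to the individual lines of a spectrum
#'
#' Partitions the center band into one region per distinct isotropic shift.
#' The default rule places boundaries at the midpoints between consecutive
#' shifts; `method = "gap"` instead clusters the observed transition
#' frequencies by gaps and assigns each cluster to the nearest shift, leaving
#' distant clusters in a `"combination"` remainder region.
#'
#' @param s A `stick_spectrum` with spinning-frequency metadata.
#' @param shifts_hz Isotropic shifts of the lines (Hz); duplicated values
#'   collapse to a single line.
#' @param method `"midpoint"` (default) or `"gap"`.
#' @param gap_hz Minimum gap separating clusters for `method = "gap"`.
#' @return A [spectral_region()] with one interval per line (and possibly
#'   `"combination"` intervals for `method = "gap"`).
#' @export
assign_line_regions <- function(s, shifts_hz, method = c("midpoint", "gap"),
                                gap_hz = NULL) {
  method <- match.arg(method)
  if (length(shifts_hz) < 1) abort("Need at least one shift.")
  shifts <- sort(unique(shifts_hz))
  cb <- center_band(s)
  if (method == "midpoint") {
    if (length(shifts) == 1) {
      return(spectral_region(cb$lower_hz, cb$upper_hz, line = "1"))
    }
    mids <- (shifts[-1] + shifts[-length(shifts)]) / 2
    lower <- pmax(c(cb$lower_hz, mids), cb$lower_hz)
    upper <- pmin(c(mids, cb$upper_hz), cb$upper_hz)
    keep <- lower < upper
    return(spectral_region(lower[keep], upper[keep],
                           line = as.character(seq_along(shifts))[keep]))
  }
  # gap-based clustering of observed transitions inside the center band
  f <- sort(s$frequency_hz[!is.na(.region_index(cb, s$frequency_hz))])
  if (length(f) == 0) abort("No transitions inside the center band.")
  gap <- gap_hz %||% max(diff(range(shifts)) / 20, 1)
  grp <- cumsum(c(1, diff(f) > gap))
  lower <- as.numeric(tapply(f, grp, min)) - gap / 2
  upper <- as.numeric(tapply(f, grp, max)) + gap / 2
  # clamp to keep clusters disjoint after padding
  if (length(lower) > 1) {
    for (k in seq_len(length(lower) - 1)) {
      if (upper[k] > lower[k + 1]) {
        mid <- (upper[k] + lower[k + 1]) / 2
        upper[k] <- mid; lower[k + 1] <- mid
      }
    }
  }
  ctr <- (lower + upper) / 2
  nearest <- vapply(ctr, function(x) which.min(abs(shifts - x)), integer(1))
  dist <- abs(shifts[nearest] - ctr)
  tol <- if (length(shifts) > 1) min(diff(shifts)) / 2 else Inf
  lab <- ifelse(dist <= tol, as.character(nearest), "combination")
  spectral_region(lower, upper, line = lab)
}
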