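# Scan drivers: powder-averaged moments, line widths, breadths and line
# shifts as a function of the spinning frequency.
#
# The Floquet constructions factor into spinning-frequency-independent
# operator blocks: Heff = H0 + A2/wr + B3/wr^2 with
#   A2 = sum_{n != 0} [H^(n), H^(-n)] / (2n)
#   B3 = sum_{n != 0} [H^(n), [H^(0), H^(-n)]] / (2n^2)
#      + sum_{k,n != 0} [H^(n), [H^(k), H^(-k-n)]] / (3nk)
# so each orientation's commutator algebra is done once per scan and reused
# across all spinning frequencies (wr in rad/s here).

.floquet_blocks <- function(fh, need_b3) {
  h <- fh$h
  hm <- function(n) h[[as.character(n)]]
  dim <- nrow(h[[1]])
  A2 <- matrix(0 + 0i, dim, dim)
  for (n in c(-2L, -1L, 1L, 2L)) {
    A2 <- A2 + .commutator(hm(n), hm(-n)) / (2 * n)
  }
  B3 <- NULL
  if (need_b3) {
    B3 <- matrix(0 + 0i, dim, dim)
    for (n in c(-2L, -1L, 1L, 2L)) {
      B3 <- B3 + .commutator(hm(n), .commutator(hm(0), hm(-n))) / (2 * n^2)
      for (k in c(-2L, -1L, 1L, 2L)) {
        if (k + n == 0 || abs(k + n) > 2) next
        B3 <- B3 + .commutator(hm(n), .commutator(hm(k), hm(-k - n))) / (3 * n * k)
      }
    }
  }
  list(A2 = A2, B3 = B3)
}

# Streaming powder moments on a (wr, construction, region line) grid.
# region_fun(wr_hz) must return a spectral_region tibble.
.scan_moments <- function(system, wr_hz, constructions, orientations,
                          region_fun, n_slices = 1000) {
  ctx <- .system_context(system)
  regions <- lapply(wr_hz, region_fun)
  nw <- length(wr_hz); nc <- length(constructions)
  nl <- vapply(regions, nrow, integer(1))
  S0 <- array(0, c(nw, nc, max(nl)))
  S1 <- S0; S2 <- S0; NT <- S0
  need_flq <- any(constructions != "exact")
  need_b3 <- "order3" %in% constructions
  al <- orientations$alpha_deg * pi / 180
  be <- orientations$beta_deg * pi / 180
  ga <- orientations$gamma_deg * pi / 180
  wts <- orientations$weight
  for (k in seq_len(nrow(orientations))) {
    fh <- .fourier_hamiltonian_fast(ctx, al[k], be[k], ga[k])
    blocks <- if (need_flq) .floquet_blocks(fh, need_b3) else NULL
    for (iw in seq_len(nw)) {
      wr <- 2 * pi * wr_hz[iw]
      for (ic in seq_len(nc)) {
        H <- switch(constructions[ic],
          order1 = fh$h[["0"]],
          order2 = fh$h[["0"]] + blocks$A2 / wr,
          order3 = fh$h[["0"]] + blocks$A2 / wr + blocks$B3 / wr^2,
          exact = cpp_unitary_log(
            cpp_propagator(unname(fh$h), wr_hz[iw], as.integer(n_slices)),
            wr_hz[iw])$matrix
        )
        st <- .sticks_from_matrix(H, ctx$ops$Fx, ctx$ops$Fminus)
        ri <- .region_index(regions[[iw]], st$frequency_hz)
        ok <- !is.na(ri)
        if (!any(ok)) next
        wI <- st$intensity[ok] * wts[k]
        f <- st$frequency_hz[ok]
        g <- ri[ok]
        S0[iw, ic, ] <- S0[iw, ic, ] + .sum_by(wI, g, max(nl))
        S1[iw, ic, ] <- S1[iw, ic, ] + .sum_by(wI * f, g, max(nl))
        S2[iw, ic, ] <- S2[iw, ic, ] + .sum_by(wI * f^2, g, max(nl))
        NT[iw, ic, ] <- NT[iw, ic, ] + .sum_by(rep(1, length(f)), g, max(nl))
      }
    }
  }
  rows <- list()
  for (iw in seq_len(nw)) {
    for (ic in seq_len(nc)) {
      for (il in seq_len(nl[iw])) {
        tot <- S0[iw, ic, il]
        m1 <- if (tot != 0) S1[iw, ic, il] / tot else NA_real_
        m2 <- if (tot != 0) S2[iw, ic, il] / tot else NA_real_
        rows[[length(rows) + 1]] <- tibble::tibble(
          wr_hz = wr_hz[iw],
          construction = constructions[ic],
          line = regions[[iw]]$line[il],
          n_transitions = NT[iw, ic, il],
          total_intensity = tot,
          m1_hz = m1,
          m2_raw_hz2 = m2,
          m2_central_hz2 = m2 - m1^2,
          gaussian_fwhm_hz = 2 * sqrt(2 * log(2)) * sqrt(pmax(m2 - m1^2, 0))
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

.sum_by <- function(x, g, nl) {
  out <- numeric(nl)
  agg <- rowsum(x, g)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# Per-line regions: midpoints between distinct isotropic shifts, intersected
# with the center band; a single distinct shift yields the full center band.
.line_region_fun <- function(system) {
  shifts <- sort(unique(system$spins$shift_hz))
  function(wr) {
    cb_lo <- -wr / 2; cb_hi <- wr / 2
    if (length(shifts) == 1) {
      return(spectral_region(cb_lo + shifts, cb_hi + shifts, line = "center"))
    }
    mids <- (shifts[-1] + shifts[-length(shifts)]) / 2
    lower <- pmax(c(cb_lo, mids), cb_lo)
    upper <- pmin(c(mids, cb_hi), cb_hi)
    keep <- lower < upper
    spectral_region(lower[keep], upper[keep],
                    line = as.character(seq_along(shifts))[keep])
  }
}

#' Line-width scan versus spinning frequency
#'
#' Powder-averaged Gaussian-equivalent line widths (FWHM from the central
#' second moment over the center band, or per line when the system carries
#' distinct shifts) for each requested effective-Hamiltonian construction
#' and spinning frequency, with linear fits of FWHM versus `1/wr`.
#'
#' @param system A [spin_system()].
#' @param wr_hz Spinning frequencies in Hz (>= 3 values).
#' @param constructions Subset of `"order1"`, `"order2"`, `"order3"`, `"exact"`.
#' @param orientations Powder orientation set.
#' @param n_slices Propagator slices for `"exact"`.
#' @return Tibble of class `linewidth_scan` (one row per `wr`, construction
#'   and line); `glance()` returns the per-construction fits of FWHM vs 1/wr.
#' @export
linewidth_scan <- function(system, wr_hz,
                           constructions = c("order2", "order3"),
                           orientations = zcw_orientations(1000),
                           n_slices = 1000) {
  if (length(wr_hz) < 3) abort("`wr_hz` needs at least 3 values.")
  out <- .scan_moments(system, sort(wr_hz), constructions, orientations,
                       .line_region_fun(system), n_slices)
  class(out) <- c("linewidth_scan", class(out))
  out
}

#' @export
glance.linewidth_scan <- function(x, ...) {
  dplyr::group_modify(
    dplyr::group_by(tibble::as_tibble(x), .data$construction, .data$line),
    function(d, key) {
      fit <- lm(gaussian_fwhm_hz ~ I(1 / wr_hz), data = d)
      # r^2 computed directly: summary.lm warns on the (expected) exact fits
      ssr <- sum(fit$residuals^2)
      sst <- sum((d$gaussian_fwhm_hz - mean(d$gaussian_fwhm_hz))^2)
      tibble::tibble(
        slope_hz2 = unname(coef(fit)[2]),
        intercept_hz = unname(coef(fit)[1]),
        r_squared = 1 - ssr / sst
      )
    }
  ) |> dplyr::ungroup()
}

# Lorentzian convolution of a regular grid by FFT (circular, zero-padded).
.lorentz_convolve <- function(v, res, broadening_hz) {
  npoints <- length(v)
  n2 <- 2L * npoints
  off <- c(seq(0, npoints), seq(-npoints + 1, -1)) * res
  kern <- (broadening_hz / 2) / (off^2 + (broadening_hz / 2)^2)
  kern <- kern / sum(kern)
  Re(fft(fft(c(v, numeric(npoints))) * fft(kern), inverse = TRUE) / n2)[seq_len(npoints)]
}

#' Breadth of a (powder) stick spectrum
#'
#' Full width of the binned spectrum at a fraction of its maximum intensity
#' (default 0.1 percent). The spectrum is binned at `resolution_hz` over the
#' observed transition range; the breadth is the span between the outermost
#' bins at or above `threshold` times the maximum bin.
#'
#' @param s A `stick_spectrum`.
#' @param threshold Intensity fraction defining the cut (default 1e-3).
#' @param resolution_hz Bin width in Hz (coarsened if the range would exceed
#'   `max_bins` bins).
#' @param broadening_hz Optional Lorentzian FWHM applied before thresholding.
#' @param max_bins Upper bound on the number of bins.
#' @return Breadth in Hz.
#' @export
spectrum_breadth <- function(s, threshold = 1e-3, resolution_hz = 0.05,
                             broadening_hz = 0, max_bins = 2^21) {
  f <- s$frequency_hz
  w <- s$intensity
  rng <- range(f)
  res <- max(resolution_hz, diff(rng) / max_bins)
  lo <- rng[1] - res
  np <- max(2L, as.integer(ceiling((rng[2] + res - lo) / res)))
  idx <- pmin(np, floor((f - lo) / res) + 1)
  v <- numeric(np)
  agg <- rowsum(w, idx)
  v[as.integer(rownames(agg))] <- agg[, 1]
  if (broadening_hz > 0) v <- .lorentz_convolve(v, res, broadening_hz)
  above <- which(v >= threshold * max(v))
  (max(above) - min(above) + 1) * res
}

#' Breadth-difference scan: exact versus third-order effective Hamiltonians
#'
#' Powder-spectrum breadths of the third-order Floquet and exact effective
#' Hamiltonians across spinning frequencies, the breadth difference
#' (third-order minus exact), and the least-squares slope of
#' `log(difference)` versus `log(wr)`. A slope near -3 is the signature of a
#' fourth-order effective-Hamiltonian contribution.
#'
#' @inheritParams linewidth_scan
#' @param threshold,resolution_hz,broadening_hz Passed to [spectrum_breadth()].
#' @return Tibble of class `breadth_scan` with per-`wr` breadths and the
#'   difference; `glance()` returns the log-log fit.
#' @export
breadth_difference_scan <- function(system, wr_hz,
                                    orientations = zcw_orientations(1000),
                                    n_slices = 1000, threshold = 1e-3,
                                    resolution_hz = 0.05, broadening_hz = 0) {
  if (length(wr_hz) < 4) abort("`wr_hz` needs at least 4 values.")
  wr_hz <- sort(wr_hz)
  ctx <- .system_context(system)
  nw <- length(wr_hz)
  nor <- nrow(orientations)
  acc <- lapply(seq_len(nw), function(i) list(
    f3 = vector("list", nor), i3 = vector("list", nor),
    fe = vector("list", nor), ie = vector("list", nor)
  ))
  al <- orientations$alpha_deg * pi / 180
  be <- orientations$beta_deg * pi / 180
  ga <- orientations$gamma_deg * pi / 180
  for (k in seq_len(nor)) {
    fh <- .fourier_hamiltonian_fast(ctx, al[k], be[k], ga[k])
    blocks <- .floquet_blocks(fh, TRUE)
    w <- orientations$weight[k]
    for (iw in seq_len(nw)) {
      wr <- 2 * pi * wr_hz[iw]
      H3 <- fh$h[["0"]] + blocks$A2 / wr + blocks$B3 / wr^2
      st3 <- .sticks_from_matrix(H3, ctx$ops$Fx, ctx$ops$Fminus)
      He <- cpp_unitary_log(
        cpp_propagator(unname(fh$h), wr_hz[iw], as.integer(n_slices)),
        wr_hz[iw])$matrix
      ste <- .sticks_from_matrix(He, ctx$ops$Fx, ctx$ops$Fminus)
      acc[[iw]]$f3[[k]] <- st3$frequency_hz
      acc[[iw]]$i3[[k]] <- st3$intensity * w
      acc[[iw]]$fe[[k]] <- ste$frequency_hz
      acc[[iw]]$ie[[k]] <- ste$intensity * w
    }
  }
  as_sticks <- function(f, i, wr) {
    out <- tibble::tibble(frequency_hz = unlist(f), intensity = unlist(i))
    attr(out, "wr_hz") <- wr
    class(out) <- c("stick_spectrum", class(out))
    out
  }
  rows <- lapply(seq_len(nw), function(iw) {
    b3 <- spectrum_breadth(as_sticks(acc[[iw]]$f3, acc[[iw]]$i3, wr_hz[iw]),
                           threshold, resolution_hz, broadening_hz)
    bex <- spectrum_breadth(as_sticks(acc[[iw]]$fe, acc[[iw]]$ie, wr_hz[iw]),
                            threshold, resolution_hz, broadening_hz)
    tibble::tibble(wr_hz = wr_hz[iw], breadth_order3_hz = b3,
                   breadth_exact_hz = bex, difference_hz = b3 - bex)
  })
  out <- dplyr::bind_rows(rows)
  if (any(out$difference_hz <= 0)) {
    warn(sprintf("%d spinning frequencies dropped from the log-log fit (non-positive breadth difference).",
                 sum(out$difference_hz <= 0)))
  }
  class(out) <- c("breadth_scan", class(out))
  out
}

#' @export
glance.breadth_scan <- function(x, ...) {
  d <- dplyr::filter(tibble::as_tibble(x), .data$difference_hz > 0)
  fit <- lm(log(difference_hz) ~ log(wr_hz), data = d)
  tibble::tibble(
    loglog_slope = unname(coef(fit)[2]),
    r_squared = summary(fit)$r.squared,
    n_points = nrow(d)
  )
}

#' Line-shift scan: first-moment deviation from the isotropic shift
#'
#' For systems with chemical shifts, the residual dipolar Hamiltonian not
#' only broadens each line but moves its center of gravity. This scan
#' reports, per line, spinning frequency and construction, the first moment
#' of the line region minus the isotropic shift.
#'
#' @inheritParams linewidth_scan
#' @return Tibble of class `shift_scan` with columns `wr_hz`,
#'   `construction`, `line`, `shift_hz`, `m1_hz`, `deviation_hz`,
#'   `gaussian_fwhm_hz`.
#' @export
shift_deviation_scan <- function(system, wr_hz,
                                 constructions = c("order2", "order3"),
                                 orientations = zcw_orientations(1000),
                                 n_slices = 1000) {
  shifts <- sort(unique(system$spins$shift_hz))
  if (length(shifts) < 2) {
    abort("The system needs at least two distinct shifts for line assignment.")
  }
  sep <- min(diff(shifts))
  if (sep < 1e-6 * max(abs(shifts))) {
    abort("Shifts too close for region assignment.")
  }
  out <- .scan_moments(system, sort(wr_hz), constructions, orientations,
                       .line_region_fun(system), n_slices)
  out$shift_hz <- shifts[as.integer(out$line)]
  out$deviation_hz <- out$m1_hz - out$shift_hz
  out <- out[, c("wr_hz", "construction", "line", "shift_hz", "m1_hz",
                 "deviation_hz", "gaussian_fwhm_hz", "total_intensity")]
  class(out) <- c("shift_scan", class(out))
  out
}

#' @export
glance.shift_scan <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(x), .data$construction, .data$line),
    shift_hz = .data$shift_hz[1],
    max_abs_deviation_hz = max(abs(.data$deviation_hz)),
    deviation_at_max_wr_hz = .data$deviation_hz[which.max(.data$wr_hz)],
    .groups = "drop"
  )
}

#' Second-moment decomposition of a multi-spin system into three-spin parts
#'
#' Compares the powder-averaged center-band second moment of the full system
#' with 3/4 times the sum over all of its three-spin sub-systems, the
#' decomposition that holds while the second-order (three-spin) effective
#' Hamiltonian dominates the residual line width.
#'
#' @inheritParams linewidth_scan
#' @param construction Effective-Hamiltonian construction (default
#'   `"order2"`, for which the decomposition is derived).
#' @return Tibble of class `decomposition_scan`: per `wr`, the full-system
#'   central second moment, 3/4 of the summed sub-system moments, and the
#'   relative deviation in percent. The per-triple moments are stored in
#'   `attr(, "triples")`.
#' @export
subsystem_decomposition <- function(system, wr_hz,
                                    orientations = zcw_orientations(1000),
                                    construction = "order2",
                                    n_slices = 1000) {
  n <- nrow(system$spins)
  if (n < 4) abort("`system` needs at least 4 spins to decompose.")
  wr_hz <- sort(wr_hz)
  cb_fun <- function(wr) spectral_region(-wr / 2, wr / 2, line = "center")
  m2_of <- function(sys) {
    sc <- .scan_moments(sys, wr_hz, construction, orientations, cb_fun, n_slices)
    sc$m2_central_hz2
  }
  full <- m2_of(system)
  triples <- utils::combn(n, 3)
  tri_rows <- list()
  sub_sum <- numeric(length(wr_hz))
  for (t in seq_len(ncol(triples))) {
    sel <- triples[, t]
    sub <- spin_system(
      data.frame(
        x = system$spins$x[sel], y = system$spins$y[sel],
        z = system$spins$z[sel], shift_ppm = system$spins$shift_ppm[sel]
      ),
      larmor_hz = system$larmor_hz, gamma = system$gamma
    )
    m2 <- m2_of(sub)
    sub_sum <- sub_sum + m2
    tri_rows[[t]] <- tibble::tibble(
      wr_hz = wr_hz, triple = paste(sel, collapse = ""), m2_central_hz2 = m2
    )
  }
  out <- tibble::tibble(
    wr_hz = wr_hz,
    m2_full_hz2 = full,
    m2_weighted_sum_hz2 = 0.75 * sub_sum,
    deviation_pct = 100 * abs(full - 0.75 * sub_sum) / full
  )
  attr(out, "triples") <- dplyr::bind_rows(tri_rows)
  class(out) <- c("decomposition_scan", class(out))
  out
}

#' @export
glance.decomposition_scan <- function(x, ...) {
  tibble::tibble(
    max_deviation_pct = max(x$deviation_pct),
    n_wr = nrow(x)
  )
}
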