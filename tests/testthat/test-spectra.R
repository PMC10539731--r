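# Stick spectra, moments, binning and region logic.

test_that("a single spin gives one transition at its shift with all intensity", {
  Iz <- diag(c(0.5, -0.5)) + 0i
  s <- stick_spectrum(2 * pi * 100 * Iz, wr_hz = 1e5)
  live <- s[abs(s$intensity) > 1e-9, ]
  expect_equal(nrow(live), 1)
  expect_equal(live$frequency_hz, 100, tolerance = 1e-10)
  expect_equal(live$intensity, 0.5)
})

test_that("total intensity is conserved for any Hamiltonian including zero", {
  sys <- random_system(3, seed = 21, shifted = TRUE)
  fh <- fourier_hamiltonian(sys, rotor_orientation(50, 60, 70))
  totals <- vapply(
    list(matrix(0 + 0i, 8, 8),
         floquet_effective(fh, 1e5, 2)$matrix,
         floquet_effective(fh, 1e5, 3)$matrix,
         exact_effective(propagator(fh, 1e5), 1e5)$matrix),
    function(H) attr(stick_spectrum(H, wr_hz = 1e5), "total_intensity"),
    numeric(1)
  )
  expect_equal(totals, rep(3 * 2^1, 4), tolerance = 1e-10)
  # the zero Hamiltonian puts everything in a single stick at 0
  s0 <- stick_spectrum(matrix(0 + 0i, 8, 8), wr_hz = 1e5)
  expect_equal(nrow(s0), 1)
  expect_equal(s0$frequency_hz, 0)
})

test_that("an isolated pair is fully refocused over the rotor period", {
  two <- spin_system(data.frame(x = c(0, 0), y = c(0, 0), z = c(0, 1.75)))
  fh <- fourier_hamiltonian(two, rotor_orientation(40, 70, 15))
  s <- stick_spectrum(exact_effective(propagator(fh, 1e5), 1e5))
  expect_lt(max(abs(s$frequency_hz[abs(s$intensity) > 1e-9])), 1e-6)
})

test_that("non-hermitian input is rejected", {
  expect_error(stick_spectrum(matrix(c(0, 1, 0, 0), 2) + 0i, wr_hz = 1e5),
               "Hermitian")
})

test_that("moments reproduce closed-form cases", {
  one <- structure(tibble::tibble(frequency_hz = 123.4, intensity = 2),
                   class = c("stick_spectrum", class(tibble::tibble())))
  m <- moments(one)
  expect_equal(m$m1_hz, 123.4)
  expect_equal(m$m2_central_hz2, 0)
  expect_equal(m$gaussian_fwhm_hz, 0)
  two <- structure(tibble::tibble(frequency_hz = c(-40, 40), intensity = c(1, 1)),
                   class = c("stick_spectrum", class(tibble::tibble())))
  m <- moments(two)
  expect_equal(m$m1_hz, 0)
  expect_equal(m$m2_raw_hz2, 1600)
  expect_equal(m$gaussian_fwhm_hz, 2 * sqrt(2 * log(2)) * 40)
})

test_that("gaussian stick ensembles recover the 2 sqrt(2 ln 2) sigma width", {
  set.seed(42)
  s <- structure(tibble::tibble(frequency_hz = rnorm(1e5, sd = 50),
                                intensity = rep(1, 1e5)),
                 class = c("stick_spectrum", class(tibble::tibble())))
  m <- moments(s)
  expect_equal(m$gaussian_fwhm_hz, 2 * sqrt(2 * log(2)) * 50, tolerance = 0.02)
  expect_equal(m$gaussian_fwhm_hz, 117.7, tolerance = 0.02)
})

test_that("moment errors distinguish empty regions from zero intensity", {
  s <- structure(tibble::tibble(frequency_hz = c(10, 20), intensity = c(1, -1)),
                 class = c("stick_spectrum", class(tibble::tibble())))
  expect_error(moments(s, spectral_region(100, 200)), "No transitions")
  expect_error(moments(s, spectral_region(5, 25)), "zero total intensity")
})

test_that("binned spectra conserve intensity and converge to stick moments", {
  sys <- three_spin_system()
  s <- powder_spectrum(sys, 5e4, "order2", zcw_orientations(100))
  spec <- bin_spectrum(s, window_hz = 2000, npoints = 20000)
  expect_equal(attr(spec, "resolution_hz"), 0.1)
  expect_equal(sum(spec$intensity), attr(s, "total_intensity"), tolerance = 1e-6)
  # Lorentzian tails carry ~w/(pi * window) of the intensity past any finite
  # window; a wide window bounds the leakage
  specb <- bin_spectrum(s, window_hz = 4e4, npoints = 20000, broadening_hz = 1)
  expect_equal(sum(specb$intensity), attr(s, "total_intensity"), tolerance = 1e-4)
  # binned second moment approaches the stick value as the grid refines
  mstick <- moments(s)$m2_raw_hz2
  mbin <- function(np) {
    b <- bin_spectrum(s, 2200, np)
    sum(b$intensity * b$frequency_hz^2) / sum(b$intensity)
  }
  err <- abs(c(mbin(500), mbin(50000)) - mstick)
  expect_lt(err[2], err[1] / 10)
  expect_error(bin_spectrum(s, 2000, 1), "npoints")
  expect_error(bin_spectrum(s, 2000, 100, broadening_hz = -1), "non-negative")
})

test_that("center band is the half-open wr window around the reference", {
  s <- structure(tibble::tibble(frequency_hz = c(-5e4, 5e4, 7.5e4), intensity = rep(1, 3)),
                 class = c("stick_spectrum", class(tibble::tibble())))
  attr(s, "wr_hz") <- 1e5
  cb <- center_band(s)
  expect_equal(cb$lower_hz, -5e4)
  expect_equal(cb$upper_hz, 5e4)
  m <- moments(s, cb)   # +5e4 included, -5e4 and 0.75 wr excluded
  expect_equal(m$n_transitions, 1L)
  expect_equal(m$m1_hz, 5e4)
  expect_error(center_band(NULL), "unknown")
})

test_that("midpoint line regions split the center band at shift midpoints", {
  s <- structure(tibble::tibble(frequency_hz = 0, intensity = 1),
                 class = c("stick_spectrum", class(tibble::tibble())))
  attr(s, "wr_hz") <- 1e5
  reg <- assign_line_regions(s, c(0, 700))
  expect_equal(reg$lower_hz, c(-5e4, 350))
  expect_equal(reg$upper_hz, c(350, 5e4))
  single <- assign_line_regions(s, 42)
  expect_equal(nrow(single), 1)
  expect_equal(c(single$lower_hz, single$upper_hz), c(-5e4, 5e4))
  expect_error(spectral_region(c(0, 50), c(100, 150)), "overlap")
})

test_that("gap clustering labels remote clusters as combination lines", {
  s <- structure(
    tibble::tibble(frequency_hz = c(-3, 0, 4, 698, 702, 1399, 1401),
                   intensity = c(1, 1, 1, 1, 1, 0.01, 0.01)),
    class = c("stick_spectrum", class(tibble::tibble()))
  )
  attr(s, "wr_hz") <- 1e4
  reg <- assign_line_regions(s, c(0, 700), method = "gap", gap_hz = 100)
  expect_setequal(unique(reg$line), c("1", "2", "combination"))
})

test_that("single-quantum lines dominate combination lines in a shifted powder spectrum", {
  sys <- three_spin_system(shifts_ppm = c(0, 0, 0.7))
  s <- powder_spectrum(sys, 1e5, "order2", zcw_orientations(200))
  sq <- spectral_region(c(-150, 550), c(150, 850))
  idx <- !is.na(masmoments:::.region_index(sq, s$frequency_hz))
  cb <- !is.na(masmoments:::.region_index(center_band(s), s$frequency_hz))
  i_sq <- sum(s$intensity[idx])
  i_rest <- sum(s$intensity[cb & !idx])
  expect_gt(i_sq, 20 * abs(i_rest))
})
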