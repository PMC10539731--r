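# Hamiltonian Fourier components, Floquet constructions, propagator and
# exact effective Hamiltonians.

test_that("fourier hamiltonian has shift-only H0 and reconstructs H(t)", {
  sys <- three_spin_system(shifts_ppm = c(-0.1, 0.2, 0.7))
  ori <- rotor_orientation(37, 63, 21)
  fh <- fourier_hamiltonian(sys, ori)
  # H^(0) is diagonal with the shift frequencies on the Zeeman populations
  expect_true(all(abs(fh$h[["0"]][lower.tri(fh$h[["0"]])]) == 0))
  ops <- spin_operators(3)
  h0 <- Reduce(`+`, Map(function(w, iz) 2 * pi * w * iz,
                        as.list(sys$spins$shift_hz), ops$Iz))
  expect_equal(fh$h[["0"]], h0, tolerance = 1e-12)
  # zero shifts give the zero matrix
  fh0 <- fourier_hamiltonian(three_spin_system(), ori)
  expect_equal(max(Mod(fh0$h[["0"]])), 0)
  # reconstruction at t = 0 equals the directly assembled secular Hamiltonian
  wr <- 1e5
  direct <- h0
  pairs <- tidy(sys)
  dops <- list(
    2 * ops$Iz[[1]] %*% ops$Iz[[2]] - ops$Ix[[1]] %*% ops$Ix[[2]] - ops$Iy[[1]] %*% ops$Iy[[2]],
    2 * ops$Iz[[1]] %*% ops$Iz[[3]] - ops$Ix[[1]] %*% ops$Ix[[3]] - ops$Iy[[1]] %*% ops$Iy[[3]],
    2 * ops$Iz[[2]] %*% ops$Iz[[3]] - ops$Ix[[2]] %*% ops$Ix[[3]] - ops$Iy[[2]] %*% ops$Iy[[3]]
  )
  for (k in 1:3) {
    tr <- oracle_coupling_trace(sys, pairs$p[k], pairs$q[k], 37, 63, 21)
    direct <- direct + tr$omega[1] * dops[[k]]   # t = 0 sample
  }
  expect_equal(hamiltonian_at(fh, wr, 0), direct, tolerance = 1e-9)
})

test_that("a single pair produces proportional Fourier components", {
  two <- spin_system(data.frame(x = c(0, 1), y = c(0, 1.2), z = c(0, 0.8)))
  fh <- fourier_hamiltonian(two, rotor_orientation(80, 30, 10))
  base <- fh$h[["1"]]
  for (n in c("-2", "-1", "2")) {
    h <- fh$h[[n]]
    ratio <- h[abs(base) > 1e-6] / base[abs(base) > 1e-6]
    expect_lt(max(Mod(ratio - ratio[1])), 1e-10)
  }
})

test_that("an isolated pair without shifts has vanishing order-2 and order-3 terms", {
  two <- spin_system(data.frame(x = c(0, 0), y = c(0, 0), z = c(0, 1.75)))
  fh <- fourier_hamiltonian(two, rotor_orientation(40, 70, 15))
  expect_equal(max(Mod(floquet_effective(fh, 1e5, 2)$matrix)), 0)
  expect_equal(max(Mod(floquet_effective(fh, 1e5, 3)$matrix)), 0)
})

test_that("order-1 equals H0 and order contributions scale as wr^-(k-1)", {
  sys <- random_system(3, seed = 5, shifted = TRUE)
  fh <- fourier_hamiltonian(sys, rotor_orientation(112, 55, 30))
  expect_equal(floquet_effective(fh, 3e5, 1)$matrix, fh$h[["0"]], tolerance = 1e-12)
  h2 <- function(w) floquet_effective(fh, w, 2)$matrix - fh$h[["0"]]
  h3 <- function(w) floquet_effective(fh, w, 3)$matrix -
    floquet_effective(fh, w, 2)$matrix
  c <- 3.7
  expect_equal(h2(3e5 * c), h2(3e5) / c, tolerance = 1e-12)
  # the order-3 increment is a difference of two constructions, so small
  # elements carry cancellation noise
  expect_equal(h3(3e5 * c), h3(3e5) / c^2, tolerance = 1e-9)
})

test_that("floquet constructions are hermitian, zero-quantum at order 2, traceless without shifts", {
  ops <- spin_operators(3)
  for (seed in c(2, 9)) {
    sys <- random_system(3, seed = seed, shifted = TRUE)
    fh <- fourier_hamiltonian(sys, rotor_orientation(80 * seed, 33 + seed, 7))
    for (ord in 1:3) {
      H <- floquet_effective(fh, 2e5, ord)$matrix
      expect_lt(frobenius(H - Conj(t(H))), 1e-12 * (1 + frobenius(H)))
    }
    H2c <- floquet_effective(fh, 2e5, 2)$matrix - fh$h[["0"]]
    expect_lt(frobenius(H2c %*% ops$Fz - ops$Fz %*% H2c), 1e-10 * frobenius(H2c))
  }
  nos <- random_system(3, seed = 4, shifted = FALSE)
  fh <- fourier_hamiltonian(nos, rotor_orientation(15, 75, 120))
  for (ord in 2:3) {
    H <- floquet_effective(fh, 1e5, ord)$matrix
    expect_lt(abs(sum(diag(H))), 1e-10 * (1 + frobenius(H)))
  }
  U <- propagator(fh, 1e5)
  Hex <- exact_effective(U, 1e5)$matrix
  expect_lt(abs(sum(diag(Hex))), 1e-8 * (1 + frobenius(Hex)))
  expect_error(floquet_effective(fh, 1e5, 4), "1, 2 or 3")
  expect_error(floquet_effective(fh, -5, 2), "positive")
})

test_that("the propagator is unitary and exact for a time-independent Hamiltonian", {
  sys <- three_spin_system(shifts_ppm = c(0.1, 0.4, 0.9))
  fh <- fourier_hamiltonian(sys, rotor_orientation(10, 40, 0))
  U <- propagator(fh, 1e5, 500)
  expect_lt(frobenius(Conj(t(U)) %*% U - diag(8)), 1e-10)
  # pair (1,2) on the rotor axis and remote spins: beta = 0 for a two-spin
  # system makes H(t) = H0 constant, so any slicing is exact
  two <- spin_system(data.frame(x = c(0, 0), y = c(0, 0), z = c(0, 1.75),
                                shift_ppm = c(0.3, 0.8)))
  fh2 <- fourier_hamiltonian(two, rotor_orientation(25, 0, 40))
  wr <- 8e4
  suppressWarnings(U2 <- propagator(fh2, wr, 5))
  expect_equal(U2, herm_expm(fh2$h[["0"]], -1i / wr), tolerance = 1e-12)
  expect_error(propagator(fh2, wr, 3), "at least 4")
  expect_warning(propagator(fh2, wr, 16), "coarse")
})

test_that("propagator slicing self-converges at second order", {
  sys <- three_spin_system()
  fh <- fourier_hamiltonian(sys, rotor_orientation(63, 49, 11))
  wr <- 4e4
  ref <- propagator(fh, wr, 6400)
  defect <- vapply(c(100, 200, 400), function(n) frobenius(propagator(fh, wr, n) - ref),
                   numeric(1))
  expect_equal(defect[1] / defect[2], 4, tolerance = 0.1)
  expect_equal(defect[2] / defect[3], 4, tolerance = 0.15)
})

test_that("exact effective Hamiltonian inverts the propagator on the principal branch", {
  expect_equal(exact_effective(diag(4) + 0i, 1e5)$matrix, matrix(0 + 0i, 4, 4))
  # single spin with a small shift: eigenfrequency splitting equals the shift
  omega <- 2 * pi * 250   # rad/s
  wr <- 1e5
  Iz <- diag(c(0.5, -0.5)) + 0i
  U1 <- herm_expm(omega * Iz, -1i / wr)
  he <- exact_effective(U1, wr)
  ev <- sort(he$eigen_rad_s) / (2 * pi)
  expect_equal(diff(ev), 250, tolerance = 1e-9)
  # round trip on a dipolar three-spin system
  sys <- three_spin_system(shifts_ppm = c(0, 0, 0.7))
  fh <- fourier_hamiltonian(sys, rotor_orientation(37, 63, 21))
  U <- propagator(fh, 5e4)
  he <- exact_effective(U, 5e4, orientation = rotor_orientation(37, 63, 21))
  expect_lt(frobenius(herm_expm(he$matrix, -1i / 5e4) - U), 1e-9)
  expect_true(all(he$eigen_rad_s / (2 * pi) > -5e4 / 2 - 1e-9))
  expect_true(all(he$eigen_rad_s / (2 * pi) <= 5e4 / 2 + 1e-9))
  expect_error(exact_effective(matrix(c(1, 1, 0, 1), 2) + 0i, 1e5), "unitary")
})

test_that("an eigenphase at the branch cut raises a warning", {
  U <- diag(c(exp(1i * pi), 1)) + 0
  expect_warning(exact_effective(U, 1e5), "branch")
})

test_that("the exact-vs-order-3 spectral residual drops eightfold when the spinning rate doubles", {
  sys <- three_spin_system()
  fh <- fourier_hamiltonian(sys, rotor_orientation(70, 40, 0))
  resid <- vapply(c(250e3, 500e3), function(wr) {
    Hex <- exact_effective(propagator(fh, wr, 2000), wr)$matrix
    eig_dist(Hex, floquet_effective(fh, wr, 3)$matrix)
  }, numeric(1))
  expect_equal(resid[1] / resid[2], 8, tolerance = 0.25 * 8)
})
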