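# masmoments

Residual dipolar line broadening in magic-angle spinning (MAS) proton
solid-state NMR, computed from effective Hamiltonians of small spin systems.

Mechanical rotation at the magic angle removes the homonuclear dipolar
coupling only to first order: because the dipolar Hamiltonian of a strongly
coupled proton network does not commute with itself at different rotor
phases, second- and higher-order effective-Hamiltonian terms survive. They
broaden the observed resonances (a residual width that shrinks roughly as
1/ν<sub>r</sub>) and also *shift* each line's center of gravity by a few
Hz. `masmoments` is for spectroscopists and method developers who want to
compute these coherent residual effects quantitatively for concrete proton
geometries, and to dissect them order by order.

## What it computes

For a spin system given by proton coordinates (Å) and isotropic shifts
(ppm), the package:

* derives all pairwise couplings δ<sub>pq</sub> = −2(μ₀/4π)γ²ħ/r³ and
  relative orientations, and the five Fourier components
  ω<sup>(m)</sup><sub>pq</sub> of each rotor-periodic coupling via rank-2
  Wigner rotations;
* builds effective Hamiltonians four ways: Floquet commutator expansions at
  orders 1–3 (H̄⁽¹⁾ = Ĥ⁽⁰⁾, H̄⁽²⁾ = ½Σ[Ĥ⁽ⁿ⁾,Ĥ⁽⁻ⁿ⁾]/nω<sub>r</sub>, …) and
  numerically exactly as H̄ = (i/τ<sub>r</sub>) ln U(τ<sub>r</sub>) from the
  time-sliced rotor-period propagator;
* converts them to stick spectra in the eigenbasis (σ₀ = F̂ₓ, detection
  F̂⁻), powder-averages over a deterministic equal-area ZCW-style
  orientation set, and reports line positions and widths through spectral
  moments: M₁ (center of gravity), central M₂, and the Gaussian-equivalent
  width FWHM = 2√(2 ln 2)·√M₂;
* provides scan drivers versus spinning frequency: line width (∝ 1/ν<sub>r</sub>
  without shifts), breadth difference between exact and third-order spectra
  (log–log slope −3, the fourth-order fingerprint), per-line shift
  deviations, and the decomposition M₂(multi-spin) ≈ ¾ Σ M₂(three-spin
  sub-systems).

See `vignettes/residual-dipolar-linewidths.Rmd` for the model, conventions
and numerical choices.

## Worked example

A CH₂-like proton pair (r = 1.75 Å) with a third proton 3 Å away:

```r
library(masmoments)

sys <- three_spin_system()
tidy(sys)
#> # A tibble: 3 × 7
#>       p     q distance delta_rad_s delta_hz theta_deg phi_deg
#>   <int> <int>    <dbl>       <dbl>    <dbl>     <dbl>   <dbl>
#> 1     1     2     1.75    -281651.  -44826.        0        0
#> 2     1     3     3        -55906.   -8898.       90        0
#> 3     2     3     3.47     -36030.   -5734.      120.       0

ori <- zcw_orientations(500)
for (constr in c("order2", "order3", "exact")) {
  s <- powder_spectrum(sys, 50e3, constr, ori)
  m <- moments(s, center_band(s))
  cat(sprintf("%-6s  total %.3f   M1 %7.1e Hz   FWHM %.1f Hz\n",
              constr, attr(s, "total_intensity"), m$m1_hz, m$gaussian_fwhm_hz))
}
#> order2  total 6.000   M1 9.9e-16 Hz   FWHM 508.0 Hz
#> order3  total 6.000   M1 6.5e-16 Hz   FWHM 509.0 Hz
#> exact   total 6.000   M1 -5.9e-16 Hz   FWHM 496.6 Hz
```

Reading: at 50 kHz MAS the three constructions conserve the total intensity
exactly (Tr F̂ₓF̂⁻ = 6 for three spins), the powder line is centered at zero,
and the second- and third-order widths agree within a few tenths of a
percent while the exact width is a little narrower — the contribution of
fourth- and higher-order terms at spinning rates comparable to the
strongest coupling. The extra breadth of the order-3 spectrum dies off as
the third power of the spinning frequency:

```r
bd <- breadth_difference_scan(sys, c(20e3, 30e3, 50e3, 75e3, 100e3, 150e3, 200e3, 250e3),
                              zcw_orientations(500))
glance(bd)
#> # A tibble: 1 × 3
#>   loglog_slope r_squared n_points
#>          <dbl>     <dbl>    <int>
#> 1        -2.99     1.000        8
```

`autoplot()` methods display spectra and every scan type; `tidy()` and
`glance()` return tibbles throughout, so results pipe straight into dplyr.

A command-line interface wrapping the same functions is installed as
`exec/masmoments` (subcommands `fixtures`, `simulate`, `scan-linewidth`,
`scan-breadth`, `scan-shift`, `decompose`; spin systems are read from small
TOML-style config files, spectra written as CSV, scans as TSV, and every
run leaves a JSON manifest of its parameters).

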