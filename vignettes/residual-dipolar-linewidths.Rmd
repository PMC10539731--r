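---
title: "Residual dipolar line broadening under magic-angle spinning: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual dipolar line broadening under magic-angle spinning: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The physical problem

Magic-angle spinning (MAS) averages the anisotropic part of the homonuclear
dipolar interaction in solids. Because the dipolar Hamiltonian of a strongly
coupled proton network does not commute with itself at different points of
the rotor trajectory, the averaging is incomplete: second- and higher-order
effective-Hamiltonian terms survive and produce a *residual* homogeneous
line broadening, plus a spinning-frequency-dependent *shift* of the line's
center of gravity. This package computes those residuals for small
(two- to five-spin) proton systems: it builds effective Hamiltonians at
several levels of approximation, turns them into powder-averaged stick
spectra, and characterizes the lines by spectral moments.

# Model

## Rotor-periodic Hamiltonian

A homonuclear system of $N$ protons with isotropic shifts $\omega_p$ and
couplings between all pairs evolves under

$$\hat H(t) = \sum_p \omega_p \hat I_{pz}
  + \sum_{p<q} \omega_{pq}(t)\,
    \bigl(2\hat I_{pz}\hat I_{qz} - \hat I_{px}\hat I_{qx} - \hat I_{py}\hat I_{qy}\bigr),$$

where the secular dipolar coupling of pair $(p,q)$ is
$\omega_{pq}(t) = \tfrac{\delta_{pq}}{2} P_2\!\bigl(\cos\Theta_{pq}(t)\bigr)$
with the point-dipole anisotropy
$\delta_{pq} = -2 \tfrac{\mu_0}{4\pi}\,\gamma^2\hbar / r_{pq}^3$
and $\Theta_{pq}(t)$ the angle between the internuclear vector and the
static field. Under MAS at frequency $\nu_r$ the angle is carried through
three ZYZ Euler rotations — pair frame to the frame of the reference pair
$(1,2)$ by $(0,\theta_{pq},\phi_{pq})$, crystallite to rotor frame by
$(\alpha,\beta,\gamma)$, rotor to laboratory by
$(-\omega_r t, -\theta_m, 0)$ — which makes $\omega_{pq}(t)$ a five-term
Fourier series $\sum_{m=-2}^{2}\omega^{(m)}_{pq} e^{im\omega_r t}$ whose
$m=0$ term vanishes identically at the magic angle
$\theta_m = \arccos(1/\sqrt3)$. The Wigner-rotation algebra is validated in
the test suite against a brute-force oracle that rotates the internuclear
vector with plain $3\times3$ matrices and Fourier-transforms
$P_2(\cos\Theta(t))$ numerically; the oracle, not any printed prefactor
convention, fixes the normalization, through the requirement that the static
limit reproduces the secular coupling of the Hamiltonian above.

## Effective Hamiltonians

Two complementary routes produce a time-independent Hamiltonian whose
single-period propagator matches the true dynamics:

1. **Floquet expansion** (orders 1–3), built from commutators of the
   Fourier components $\hat H^{(n)}$:
   $$\bar H^{(1)} = \hat H^{(0)}, \qquad
     \bar H^{(2)} = \frac{1}{2}\sum_{n\neq0}
       \frac{[\hat H^{(n)}, \hat H^{(-n)}]}{n\omega_r},$$
   $$\bar H^{(3)} = \frac{1}{2}\sum_{n\neq0}
       \frac{[\hat H^{(n)}, [\hat H^{(0)}, \hat H^{(-n)}]]}{(n\omega_r)^2}
     + \frac{1}{3}\sum_{\substack{k,n\neq0\\ k+n\neq0}}
       \frac{[\hat H^{(n)}, [\hat H^{(k)}, \hat H^{(-k-n)}]]}{nk\,\omega_r^2}.$$
   The order-$k$ term scales exactly as $\omega_r^{-(k-1)}$. Note the
   restriction $k+n\neq0$ in the double sum: the $k=-n$ terms are exactly
   the $\hat H^{(0)}$ cross terms already carried (with the correct $1/2$
   weight) by the first sum, and keeping them double-counts the
   shift–dipole cross terms. The package verifies this numerically: with
   the restriction, the residual between the exact and order-3 spectra
   falls off as $\omega_r^{-3}$ (the fourth-order signature); without it
   the residual stalls at $\omega_r^{-2}$ whenever chemical shifts are
   present. (By the Jacobi identity the restricted sum is identical to the
   variant with denominator $n(n+k)\omega_r^2$, so this is the standard
   van Vleck form.)
2. **Exact (numerical) effective Hamiltonian**: the propagator over one
   rotor period $\tau_r = 1/\nu_r$ is accumulated by midpoint time slicing
   (each Hermitian slice exponentiated through its spectral decomposition,
   so unitarity is structural), and
   $\bar H = \tfrac{i}{\tau_r}\ln U(\tau_r)$ is evaluated on the principal
   branch via the complex Schur form of the unitary. Eigenvalues are
   thereby confined to $(-\nu_r/2, +\nu_r/2]$ in frequency units; an
   eigenphase within $10^{-6}\cdot2\pi$ of the branch cut raises a warning
   because such eigenvalues are only defined modulo $\nu_r$.

### A gauge subtlety

The matrix logarithm of the propagator and the stroboscopic Floquet series
agree on *spectra* but not on *matrices*: the two are related by the
similarity transform of the periodic micromotion (kick) operator, which is
itself of order $\omega_r^{-1}$. Raw operator differences
$\|\bar H_\text{exact} - \bar H_{\le k}\|_F$ are therefore dominated by
this gauge term (at $O(\omega_r^{-1})$ with shifts, $O(\omega_r^{-2})$
without) and do not expose the convergence order of the expansion. All
convergence diagnostics in this package therefore compare the
*eigenvalue vectors* of the two constructions — a gauge-invariant
Frobenius distance — which cleanly shows the $\omega_r^{-2}$ (after order
2) and $\omega_r^{-3}$ (after order 3) scaling. Observable quantities
(transition frequencies, moments, widths) are eigenvalue-derived and
unaffected by the gauge; transition intensities acquire only an
$O(\omega_r^{-1})$ correction.

## Spectra and moments

Spectra are computed frequency-domain: the effective Hamiltonian is
diagonalized, the initial density operator ($\hat F_x$ by default) and the
detection operator ($\hat F_- = \hat F_x - i\hat F_y$) are transformed into
its eigenbasis, and each eigenstate pair contributes a stick at
$\omega_{ij} = E_i - E_j$ with intensity
$I_{ij} = \mathrm{Re}[(\sigma_0)_{ij}\, d_{ji}]$, the amplitude of that
transition in the detected signal $\mathrm{Tr}[\sigma(t)\,d]$. This form is
invariant under the arbitrary phases of numerical eigenvectors, and its
total $\mathrm{Tr}[\sigma_0 d] = N\,2^{N-2}$ is identical for every
construction — a conservation law the tests assert exactly. Signed
frequencies are kept so that the first moment measures the center of
gravity of a line.

Lines are characterized by intensity-weighted moments
$M_n = \sum \omega_{ij}^n I_{ij} / \sum I_{ij}$ over a spectral region,
and the width is reported as the FWHM of the Gaussian with the same
*central* second moment,
$\mathrm{FWHM} = 2\sqrt{2\ln2}\,\sqrt{M_2 - M_1^2}$. Subtracting $M_1^2$
keeps the spinning-frequency-dependent line *shifts* from inflating the
*width*; the raw $M_2$ is reported alongside. Working directly on stick
frequencies avoids the rounding of binned spectra; binning (with an
optional Lorentzian convolution, the frequency-domain equivalent of
exponential apodization) is provided for display and for the breadth
metric below.

Regions: the *center band* is the half-open window
$(\mathrm{ref}-\nu_r/2,\ \mathrm{ref}+\nu_r/2]$, matching the eigenvalue
support of the exact construction. For shifted systems, per-line regions
partition the center band at the midpoints between consecutive isotropic
shifts; a gap-clustering alternative assigns transition clusters to the
nearest shift and labels remote clusters as combination lines. Midpoints
are a deliberate, reproducible substitute for regions drawn by eye on a
spectrum; weak combination lines inside a line region bias its moments
negligibly at the spinning frequencies scanned here.

## Powder averaging

Crystallite orientations come from a deterministic equal-area
low-discrepancy set: $\cos\beta$ on a symmetric uniform grid and $\alpha$
advancing by the golden-ratio fraction of a turn (a ZCW-style Fibonacci
construction; no random numbers, so every run is reproducible). The set
passes second-rank quadrature tests ($\langle Y_{2m}\rangle \to 0$) and,
for the quantities studied here, $10^3$–$10^4$ points reproduce the
$10^4$–$10^5$-point results within a few percent (asserted in the tests at
the 2 % level). The third Euler angle $\gamma$ defaults to 0: eigenvalues
of the effective Hamiltonian depend on $\gamma$ only through the time
origin of the rotor cycle, so eigenvalue-derived powder observables are
$\gamma$-independent; a `gamma_steps` option exists for
intensity-sensitive studies. Moments are powder-averaged by *pooling*
transitions across orientations before taking moments — not by averaging
per-orientation moments.

# Scans and the quantities they report

* `linewidth_scan()` — Gaussian-equivalent FWHM versus $\nu_r$ per
  construction and line, with linear fits against $1/\nu_r$. Without
  shifts the order-2 width is exactly linear in $1/\nu_r$; the exact
  construction departs toward narrower lines once $\nu_r$ approaches the
  largest coupling (below ~50 kHz for a 1.75 Å proton pair).
* `breadth_difference_scan()` — the full spectral breadth is not uniquely
  defined for a powder line shape with a narrow central spike, so the
  package defines it as the width of the binned powder spectrum at 0.1 %
  of its maximum (threshold and resolution configurable). The *difference*
  between the order-3 and exact breadths isolates everything beyond third
  order; its log–log slope versus $\nu_r$ of $-3$ identifies a
  fourth-order effective-Hamiltonian contribution. The metric is validated
  by recovering that slope, not by point values.
* `shift_deviation_scan()` — per-line first moment minus the isotropic
  shift: the line shift produced by the zero-quantum structure of the
  second-order Hamiltonian, a few Hz at 100 kHz for proton geometries and
  shrinking with faster spinning.
* `subsystem_decomposition()` — center-band $M_2$ of an $N\ge4$-spin
  system versus $\tfrac{3}{4}\sum M_2(\text{three-spin subsystems})$. For
  raw full-spectrum moments under the order-2 (three-spin) Hamiltonian
  this decomposition is an operator identity — the $3/4$ is the ratio of
  the intensity normalizations $6/8$ — so the observed deviation measures
  only the center-band restriction; it stays far below the 1 % level at
  100–200 kHz.

# The built-in systems

The package ships five built-in geometries (`demo_spin_systems()`,
also emitted as config files by the CLI `fixtures` subcommand): a
CH$_2$-like pair with a remote proton (couplings $-44.8$, $-8.9$,
$-5.7$ kHz), the same geometry with two shift sets (0/0/0.7 ppm and
$-0.1$/0.2/0.7 ppm at 1 GHz), a planar four-spin extension, and a
phosphoserine-like triangle ($r_{12}=1.60$ Å, $r_{13}=r_{23}=2.35$ Å,
70° apex angles) for line-shift studies at a 20 T field. The shift values
of the phosphoserine mimic are synthetic, representative methylene/methine
values — the geometry, not the shift set, controls the behavior studied.
These fixtures are *the* study conditions for the scans; they emulate
rigid proton clusters with realistic distances but deliberately omit
everything a real crystal adds: more distant neighbours, vibrational
averaging, chemical-shift anisotropy, $J$ couplings and incoherent
relaxation. Passing tests therefore demonstrate the coherent residual
broadening mechanism, not a full prediction of experimental line widths.

# Numerical choices

* Constants: CODATA $\gamma_H = 2.6752218744\times10^8$ rad s$^{-1}$
  T$^{-1}$, $\hbar = 1.054571817\times10^{-34}$ J s, $\mu_0/4\pi =
  10^{-7}$. Published reference couplings are integer-printed; the derived
  values agree within that printing precision (about 0.5 Hz).
* Internal unit rad s$^{-1}$; all interfaces Hz and ppm. The shift sign
  convention $\omega_p = +2\pi\cdot\text{ppm}\cdot10^{-6}\cdot\nu_0$ is
  global; flipping it mirrors spectra about zero.
* Propagator slicing: 1000 midpoint slices per rotor period by default
  (slicing defect $\propto n^{-2}$, self-convergence asserted in tests);
  2000 slices are used where residuals at 1 MHz spinning are resolved.
* Degenerate transitions are merged within $10^{-9}$ Hz; transitions below
  $10^{-12}$ of the per-orientation intensity are dropped; imaginary
  residuals of the total intensity above $10^{-8}$ raise a warning.
* Scan problem sizes: the shipped tests and the acceptance script use
  2000 orientations for breadth scans, 5000 for the decomposition, and
  $\le1000$ elsewhere — sizes at which the convergence tests show the
  reported quantities are stable to a few percent or better.

# Known limitations

Hilbert-space dimension grows as $2^N$; the intended regime is $N\le5$.
No radio-frequency irradiation, off-magic-angle spinning, CSA tensors,
heteronuclei, $J$ couplings or relaxation. Breadth values depend on the
chosen threshold and resolution (their *scaling* does not). Line-region
midpoints are a convention, not a fit to observed transition clusters; for
heavily overlapping lines at slow spinning the per-line moments lose
meaning, which is the regime the scans deliberately avoid.
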