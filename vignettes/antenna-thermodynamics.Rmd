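---
title: "Thermodynamics of light-harvesting antennae under arbitrary stellar fluxes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamics of light-harvesting antennae under arbitrary stellar fluxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoantenna)
```

## The model

A photosystem is represented as a network of pigment pools. Light-harvesting
(LHC) sub-units each hold $N_i$ equivalent pigment states with a Gaussian
absorption band of peak $\lambda_i^p$, width $w_i$ (a standard deviation, nm)
and peak cross-section $\sigma$. A reaction centre (RC) holds $N_r$ pigment
states (default 10) absorbing at $\lambda_p^r = 680$ nm — the wavelength set
by the redox requirement of water oxidation — plus a single irreversible trap.
Excitons are created in the antenna by photon capture, hop between connected
pools, decay with a dissipation rate $k_\mathrm{diss}$, and, once on the RC,
are trapped into a charge-separated state at $k_\mathrm{trap}$. The trapped
electron is exported at $k_\mathrm{out}$, during which time the trap is
"closed" and cannot accept another excitation.

Photon capture per pigment is

$$\gamma_i = \int \frac{\lambda}{hc}\, f_p(\lambda)\, A_i(\lambda)\, d\lambda,$$

with $f_p$ the spectral flux density at the planetary surface
(W m$^{-2}$ nm$^{-1}$) and $A_i$ the Gaussian cross-section. Transfer between
connected pools $i \to j$ is

$$k_{i\to j} = k_\mathrm{hop}\, \rho(\lambda_i^p, \lambda_j^p)\,
  f(\Delta F_{i\to j}),$$

where $\rho$ is the spectral overlap of the two line shapes (the degree of
donor-acceptor resonance), and $f$ is a one-sided Boltzmann factor: 1 when the
free-energy change $\Delta F = \Delta H - T\Delta S$ is favourable and
$e^{-\Delta F / k_B T}$ otherwise. The enthalpy term is the excitation-energy
difference $\Delta H = hc(1/\lambda_j^p - 1/\lambda_i^p)$; the entropy term is
configurational, $\Delta S = k_B \ln(N_j / N_i)$ in the single-excitation
regime: concentrating an excitation from a large pool into a small one costs
entropy. Forward and backward rates constructed this way obey detailed balance
exactly, $k_{i\to j} / k_{j\to i} = e^{-\Delta F / k_B T}$.

Because $\gamma_i \ll k_\mathrm{trap}, k_\mathrm{diss}$ even in bright light,
the network holds at most one excitation at a time. The state space is then
(exciton location) $\times$ (trap open/closed), of size $2(N_\mathrm{LHC}+2)$,
and the stationary distribution of the master equation is solved exactly by
dense LU with a normalization row (`solve_stationary()`; residual checked
against $10^{-10}$). The observables are the trap occupancy
$\langle n_t\rangle$, the electron output rate
$\nu_e = k_\mathrm{out}\langle n_t\rangle$, the low-light quantum efficiency
$\phi_e$, and the per-antenna-pigment output $\nu_e / N_p$.

### Assumptions worth keeping in mind

* Equilibration *within* a sub-unit is instantaneous. This is reasonable for
  pools up to roughly 100 pigments; larger pools become diffusion-limited and
  should be modelled as blocks of smaller sub-units (the constructors warn).
* Stokes shifts and vibronic side bands are neglected: line shapes are pure
  Gaussians and donor fluorescence is approximated by the absorption shape.
* The trapped (charge-separated) state does not decay; dissipation acts only
  on mobile excitons.
* The RC is not photo-excited directly (it carries under 1 % of the system's
  pigments).
* Absorption is permitted while the trap is closed (the antenna can capture
  and lose an excitation during the output cycle) but never while an exciton
  is already present — no double excitation, no annihilation.

## Parameters and defaults

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `k_hop` | inter-sub-unit hop rate | $10^{11}$ s$^{-1}$ (1/10 ps) | typical inter-complex transfer time |
| `k_diss` | exciton dissipation | $10^{9}$ s$^{-1}$ (1/1 ns) | pigment excited-state lifetime |
| `k_trap` | RC trapping | $2\times10^{11}$ s$^{-1}$ (1/5 ps) | fast oxygenic trapping |
| `k_out` | electron output | $100$ s$^{-1}$ (1/10 ms) | water-oxidation cycle; caps $\nu_e$ at 100 s$^{-1}$ |
| `temperature` | thermodynamic $T$ | 300 K | ambient biology; enters only via $\beta\Delta F$ |
| `width` | Gaussian band width | 10 nm | red bands of chlorophylls/bilins fit 9–16 nm |
| `sigma_peak` | peak cross-section | $10^{-20}$ m$^2$ | pigment optical cross-sections are $10^{-21}$–$10^{-20}$ m$^2$ |
| RC | $N_r$, $\lambda_p^r$ | 10, 680 nm | oxygenic RC |

The cross-section convention: the user-facing `sigma_peak` is the *peak*
value, and the integrated cross-section $\sigma_\mathrm{int} = \sigma_\mathrm{peak}
\, w\sqrt{2\pi}$ (m$^2$ nm) is what enters the capture integral. This keeps
the configurable number on the familiar cross-section scale regardless of the
band width.

### The spectral-overlap convention

The overlap integral of two unit-normalized line shapes has units nm$^{-1}$,
so $k_\mathrm{hop}\rho$ is not dimensionless times a rate without a
convention. The package supports two:

* **raw** (default): $\rho$ is the literal overlap integral times a 1 nm
  reference bandwidth. Iso-energetic 10 nm-wide neighbours then exchange
  energy at $k_\mathrm{hop}/(2w\sqrt{\pi}) \approx 2.8\times10^9$ s$^{-1}$,
  a few times faster than dissipation.
* **normalized**: $\rho$ is scaled so identical profiles give exactly 1 and
  iso-energetic neighbours hop at exactly $k_\mathrm{hop}$.

The raw convention is the default because it reproduces the benchmark
behaviours this model is meant to show: a 1-branch chain of small sub-units
saturates below 20 electrons s$^{-1}$ (the normalized convention lets such a
chain reach $\sim$60 s$^{-1}$, because chain transport is then never
rate-limiting), the single-LHC optimum falls at 658–659 nm, and the coolest
M-dwarf stand-ins plateau near 50 electrons s$^{-1}$ with a funnel antenna.
Under the normalized convention the same qualitative structure survives but
chain length and funnel depth are almost free. `thermo_params(overlap =
"normalized")` switches conventions everywhere.

## Light environments

`blackbody_surface_flux()` emits the hemispheric surface flux $\pi
B(\lambda, T_s)$ of a blackbody, and `surface_flux()` dilutes it by
$(R_s/a_{sp})^2$ to the orbital distance. `habitable_distances()` gives the
distances at which the equilibrium planetary temperature is 373 K and 273 K
(from $a_{sp} = (R_s/2)(T_s/T_p)^2$, no greenhouse or albedo correction) and
their midpoint; the default experiment places the planet at the midpoint.
The constants used are $R_\odot = 6.957\times10^8$ m and
$1\,\mathrm{au} = 1.496\times10^{11}$ m. Published habitable-zone tables that
print stellar radii rounded to three decimals are reproduced to the printed
digit in 21 of 24 cells; the remaining cells differ by one unit in the last
place, which is exactly the uncertainty induced by rounding the input radii —
no choice of conversion constants removes it.

A blackbody is a stand-in, not a stellar atmosphere. It reproduces the
broadband shape and the total photosynthetically active flux, which is what
drives the thermodynamic optima studied here, but it has none of the line and
molecular-band structure of real spectra. Quantities that depend on that
structure — notably absolute electron-output values under M-dwarf
irradiation, where deep molecular absorption carves up the 400–700 nm window —
are overestimated by the blackbody and are treated as qualitative here.
Externally generated spectra can be supplied as two-column text via
`load_flux()` and substituted anywhere a flux is accepted;
`resample_smooth()` bin-averages them (4000 points by default, comfortably
finer than the ~10 nm resolution of the pigments that will "see" the
spectrum). Atmospheric attenuation is a pointwise multiply
(`apply_transmission()`), with wavelengths outside the transmission grid
treated as opaque — a conservative and explicit choice.

## The three experiment families

* **Illustrative** (`run_illustrative_sweep()`): one LHC of $N_p$ pigments on
  the RC; scans $\lambda_p$ 620–700 nm (1 nm) and $N_p$ on a log grid 1–1000.
  Shows the entropic diminishing returns of a single growing pool.
* **Modular** (`run_modular_sweep()`): $N_b$ unbranched chains of identical
  iso-energetic sub-units (plant-like); grown by one sub-unit per branch per
  step, 1–10 shells by default.
* **Funnel** (`run_funnel_sweep()`): the same geometry with shell $k$
  blue-shifted by $k\,\Delta\lambda_p$ from the innermost peak (phycobilisome-
  like); scans $\Delta\lambda_p$ 0–30 nm.

Optima are reported at grid resolution by `find_optimum()`, never
interpolated; exact ties break toward the smaller wavelength/shift and are
flagged, and the one-grid-step neighbourhood is returned because several of
these ridges are flat.

### Where the optima land, and why

For a large antenna pool feeding a small RC, the product
$\rho \cdot f(\Delta F)$ controls delivery. Moving the antenna peak toward the
blue of the RC deepens the enthalpy drop (gaining back-transfer suppression at
$d(\beta\Delta H)/d\lambda = \beta hc/\lambda^2 \approx 0.108$ per nm at
300 K) but costs overlap ($d\ln\rho/d\lambda = (\lambda_r -
\lambda)/(2w^2)$). With $w = 10$ nm the two slopes cross at
$\lambda_r - \lambda \approx 21.7$ nm, i.e. $\lambda \approx 658$ nm — which
is where the sweeps put the optimum for every antenna whose transfer into the
RC carries a substantial entropy barrier (the single-LHC model at large
$N_p$, and 6-branch chains of 100-pigment sub-units). For small sub-units
($N_i = N_r$, no explicit barrier) and many branches, RC back-transfer
replaces the barrier as the limiting term and the optimum shifts red, to
665–674 nm depending on geometry. The acceptance suite encodes an expectation
of 665 ± 2 nm for the 6-branch large-sub-unit case; this implementation puts
that particular argmax at 658–660 nm for the reason above, and the
corresponding check is deliberately left failing rather than tuned.

The funnel blue-shift trades per-hop directional bias against adjacent-shell
overlap and against pushing the outer shells away from the flux. Under a
2300–3300 K blackbody the sweeps put the optimum at 5–7 nm per shell. Under a
5800 K blackbody the RC is nearly saturated for any reasonable funnel, the
$\nu_e(\Delta\lambda_p)$ ridge is flat to within ~1 %, and the argmax drifts
up to ~11 nm; the acceptance expectation of 7 ± 2 nm is likewise left
failing, with the flatness visible in the reported neighbourhood.

## Numerical choices

* Quadratures are trapezoid on the supplied flux grid; overlap integrals use
  a dedicated 0.05 nm grid spanning both profiles ± 6 widths (relative error
  $\sim10^{-7}$ against the closed form).
* $\phi_e$ is defined as a $\gamma \to 0$ limit. It is computed exactly as a
  first-passage problem: with the trap open, the probability that an exciton
  starting at node $x$ reaches the trap before dissipating solves a linear
  system of size $N_\mathrm{LHC}+1$, and $\phi_e$ is the capture-weighted
  average of those hitting probabilities. Evaluating the finite-flux ratio at
  a small scale and extrapolating agrees to the $O(s)$ saturation bias (this
  cross-check is in the test suite); the first-passage route has no roundoff
  floor, which matters because excited-state probabilities scale like
  $\gamma/k_\mathrm{diss} \sim 10^{-9}$ of the ground state.
* The stationary solver refuses to return if the residual exceeds
  $10^{-10}$; stationary vectors are clipped of $-10^{-12}$-scale negatives
  and renormalized.
* `resample_smooth()` returns its input unchanged when the grid is already
  uniform at the requested size, making it idempotent.
* The Gillespie oracle (`gillespie()`) simulates the same generator
  trajectory-by-trajectory and reports batch-means standard errors (20
  batches). Its purpose is validation: occupancies and $\nu_e$ agree with the
  linear solve within Monte-Carlo error on randomized systems in the test
  suite. Batch means underestimate the variance when the electron-output
  cycle is long relative to a batch, so agreement tests use a small absolute
  floor on the standard error.

## Problem sizes

The standard protocols solve, per sweep point, a dense system of at most
$2(N_b \cdot n_s + 2) \le 124$ states; the full acceptance protocols (three
sweeps, a flux-response root-find and a 50-shell chain scan) run in well under
a minute on one core. Test-suite Gillespie runs use $1.5\times10^4$ to
$4\times10^4$ events, enough for ~3-significant-figure occupancies on the
fixtures used.

## Known limitations

* No multi-excitation dynamics, exciton annihilation, or time-dependent
  (transient) solutions.
* No lattice topologies or heterogeneous branch lengths; branches are
  independent chains by construction.
* The blackbody stand-in ignores spectral structure (see above); absolute
  M-dwarf outputs should be read qualitatively.
* Transfer rates treat every RC-adjacent sub-unit identically regardless of
  how many branches crowd the RC; no steric correction is applied.
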