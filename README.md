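# photoantenna

How large, how red, and how funnel-shaped should a photosynthetic antenna be
under a given star? `photoantenna` answers this with a minimal thermodynamic
model of the antenna–reaction-centre architecture, aimed at researchers in
photosynthesis biophysics and astrobiology who want to compare
light-harvesting strategies (plant-like modular antennae vs
phycobilisome-like enthalpy funnels) across light environments ranging from
Sun-like stars to cool M-dwarfs.

## The model

A photosystem is a network of pigment pools around a reaction centre (RC,
default N_r = 10 pigments absorbing at λ = 680 nm with a single trap).
Each light-harvesting sub-unit holds N_i equivalent pigments with a Gaussian
absorption band (peak λ_p, width w ≈ 10 nm). Three processes move
probability:

* **capture** — per-pigment rate γ = ∫ (λ/hc) f_p(λ) A(λ) dλ against the
  incident spectral flux f_p;
* **transfer** — between connected pools at
  k = k_hop · ρ(λ_i, λ_j) · f(ΔF), where ρ is the spectral overlap of the
  two bands and f(ΔF) a one-sided Boltzmann penalty on the free energy
  ΔF = ΔH − TΔS, with ΔH = hc(1/λ_j − 1/λ_i) and ΔS = k_B ln(N_j/N_i)
  (concentrating an excitation into a smaller pool costs entropy); forward
  and backward rates obey detailed balance exactly;
* **trapping and output** — the RC traps excitons at k_trap (1/5 ps); the
  trapped electron leaves at k_out (1/10 ms), during which the trap is
  closed.

In the single-excitation regime the stationary state of the master equation
is solved exactly (dense LU over 2(N+2) states), giving the electron output
rate ν_e = k_out⟨n_t⟩ (capped at 100 s⁻¹ by the output cycle), the low-light
quantum efficiency φ_e, and the per-pigment output ν_e/N_p. A Gillespie
simulator over the same network serves as an independent stochastic check.

Light environments come from two-column spectral files or from a built-in
blackbody stand-in placed at the midpoint of the star's habitable zone
(a_sp = (R_s/2)(T_s/T_p)² between the 273 K and 373 K equilibrium
distances).

## Worked example

A Sun-like star, a 6-branch funnel antenna of 100-pigment sub-units
blue-shifted 7 nm per shell:

```r
library(photoantenna)

sun <- stellar_model(5800, 0.936)          # T_s in K, radius in solar radii
habitable_distances(sun)
#> <habitable_distances> a_min = 0.526 au, a_mid = 0.754 au, a_max = 0.982 au

fl <- planet_flux(sun)                     # blackbody flux at a_mid
g  <- assign_funnel(build_branched(6, 5, 100, 665), 665, 7)
g
#> <photosystem_graph> 30 sub-unit(s), 30 edge(s), 3000 antenna pigments
#>   RC: N_r = 10, peak 680 nm

solve_photosystem(g, fl)
#> <steady_state_result> nu_e = 91.14 /s, phi_e = 0.1732, nu_e/N_p = 0.03038 /s
#>   trap closed 91.14% of the time, N_p = 3000 antenna pigments
```

Reading this: under Sun-like flux this antenna keeps the RC busy 91% of the
time — ν_e is within 10% of the 100 s⁻¹ ceiling set by the 10 ms electron
output cycle — while each captured photon has a 17% chance of becoming an
electron at low light, and the per-pigment return (0.030 s⁻¹) sits at the
approximate viability threshold for oxygenic photoautotrophs.

The sweep drivers scan whole families of structures
(`run_illustrative_sweep()`, `run_modular_sweep()`, `run_funnel_sweep()`)
and `find_optimum()` extracts grid-resolution optima with their
neighbourhoods. A thin command-line front end is installed at
`system.file("scripts", "photoantenna-cli.R", package = "photoantenna")`
with subcommands `blackbody`, `hz`, `at-planet`, `solve`, `gillespie`,
`sweep` and `graph-dump`.

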