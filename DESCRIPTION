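Package: photoantenna
Title: Thermodynamic Models of Photosynthetic Light-Harvesting Under Arbitrary Stellar Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state exciton dynamics of generalized antenna-reaction-centre
    photosystems illuminated by arbitrary stellar spectral fluxes. Builds
    single-LHC, modular branched and enthalpy-funnel antenna topologies,
    constructs energy-transfer rate constants from Gaussian pigment absorption
    profiles with a detailed-balance free-energy penalty (enthalpy from peak
    wavelengths, entropy from pigment-pool multiplicities), solves the
    single-excitation master equation for the stationary distribution, and
    derives electron output rate, quantum efficiency and per-pigment output.
    Includes blackbody surface-flux generation, habitable-zone distances,
    spectral file I/O, atmospheric transmission, a Gillespie stochastic
    validation oracle, and parameter-sweep drivers that locate optimal antenna
    configurations.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
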