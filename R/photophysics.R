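# Pigment absorption profiles, photon capture, spectral overlap, and the
# thermodynamic construction of energy-transfer rate constants.

#' Gaussian pigment absorption profile
#'
#' Photosynthetic pigments (chlorophylls, bilins, bacteriochlorophylls) have a
#' lowest-energy absorption band that is well approximated by a Gaussian in
#' wavelength. The profile is parameterized by its peak wavelength, its
#' standard deviation ("width"), and its peak optical cross-section. The
#' integrated cross-section used in capture integrals is
#' `sigma_int = sigma_peak * width * sqrt(2*pi)` (m^2 nm), so the user-facing
#' number stays on the familiar 1e-21 to 1e-20 m^2 scale of pigment optical
#' cross-sections.
#'
#' @param lambda_peak Peak wavelength, nm (> 0).
#' @param width Gaussian standard deviation, nm (> 0). Default 10 nm, typical
#'   of the red band of photosynthetic pigments.
#' @param sigma_peak Peak absorption cross-section, m^2. Default 1e-20 m^2.
#' @return Object of class `absorption_profile` with fields `lambda_peak`,
#'   `width`, `sigma_peak` and `sigma_int`.
#' @export
absorption_profile <- function(lambda_peak, width = 10, sigma_peak = 1e-20) {
  if (!is.numeric(lambda_peak) || length(lambda_peak) != 1L || lambda_peak <= 0)
    stop("lambda_peak must be a positive wavelength in nm", call. = FALSE)
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop("width must be positive", call. = FALSE)
  if (!is.numeric(sigma_peak) || length(sigma_peak) != 1L || sigma_peak <= 0)
    stop("sigma_peak must be positive", call. = FALSE)
  structure(list(lambda_peak = lambda_peak, width = width,
                 sigma_peak = sigma_peak,
                 sigma_int = sigma_peak * width * sqrt(2 * pi)),
            class = "absorption_profile")
}

#' @export
print.absorption_profile <- function(x, ...) {
  cat(sprintf("<absorption_profile> peak %g nm, width %g nm, sigma_peak %.3g m^2\n",
              x$lambda_peak, x$width, x$sigma_peak))
  invisible(x)
}

#' Absorption cross-section at a wavelength
#'
#' Evaluates `sigma_int * G(lambda; lambda_peak, width)` where `G` is the
#' unit-normalized Gaussian line shape (nm^-1), giving the wavelength-resolved
#' cross-section in m^2 (per nm of normalized line shape). The value at the
#' peak is `sigma_int / (width * sqrt(2*pi)) = sigma_peak`.
#'
#' @param profile An [absorption_profile()].
#' @param lambda Wavelength(s), nm.
#' @return Cross-section value(s), m^2.
#' @export
absorption_value <- function(profile, lambda) {
  stopifnot(inherits(profile, "absorption_profile"))
  profile$sigma_int * stats::dnorm(lambda, profile$lambda_peak, profile$width)
}

#' Photon capture rate of a single pigment
#'
#' The excitation rate gamma of one pigment under a spectral flux is the
#' overlap integral of the photon flux with the pigment cross-section:
#' `gamma = integral (lambda/hc) f_p(lambda) A(lambda) dlambda`, evaluated by
#' trapezoid quadrature on the flux grid (lambda converted to metres inside
#' `lambda/hc`), yielding photon captures per pigment per second.
#'
#' @param flux A [spectral_flux()].
#' @param profile An [absorption_profile()].
#' @return Capture rate gamma, s^-1 per pigment.
#' @export
excitation_rate <- function(flux, profile) {
  stopifnot(inherits(flux, "spectral_flux"), inherits(profile, "absorption_profile"))
  wl <- flux$wavelengths
  lo <- profile$lambda_peak - 5 * profile$width
  hi <- profile$lambda_peak + 5 * profile$width
  if (max(wl) < lo || min(wl) > hi) {
    warning("flux grid does not overlap the absorption band; gamma = 0")
    return(0)
  }
  if (min(wl) > lo || max(wl) < hi)
    warning("flux grid does not span the absorption band to +/- 5 widths")
  integrand <- (wl * 1e-9 / .hc) * flux$flux * absorption_value(profile, wl)
  trapz(wl, integrand)
}

#' Spectral overlap of two absorption profiles
#'
#' Degree of donor-acceptor resonance, computed as the overlap integral of the
#' two unit-normalized line shapes on a dedicated 0.05 nm grid spanning both
#' profiles to +/- 6 widths. The raw value has units nm^-1 and for equal
#' widths `w` equals `1/(2 w sqrt(pi)) * exp(-(dlambda)^2 / (4 w^2))`. The
#' normalized form divides by the self-overlap of two identical profiles of
#' width `sqrt(w_a w_b)`, so identical profiles give exactly 1.
#'
#' @param a,b [absorption_profile()] objects.
#' @param normalized Return the dimensionless normalized overlap (default)
#'   or the raw nm^-1 value.
#' @return Overlap value (dimensionless if `normalized`, nm^-1 otherwise).
#' @export
spectral_overlap <- function(a, b, normalized = TRUE) {
  stopifnot(inherits(a, "absorption_profile"), inherits(b, "absorption_profile"))
  lo <- min(a$lambda_peak - 6 * a$width, b$lambda_peak - 6 * b$width)
  hi <- max(a$lambda_peak + 6 * a$width, b$lambda_peak + 6 * b$width)
  grid <- seq(lo, hi, by = 0.05)
  raw <- trapz(grid, stats::dnorm(grid, a$lambda_peak, a$width) *
                     stats::dnorm(grid, b$lambda_peak, b$width))
  if (!normalized) return(raw)
  w_ref <- sqrt(a$width * b$width)
  raw / (1 / (2 * w_ref * sqrt(pi)))
}

#' Thermodynamic and kinetic parameters
#'
#' Bundle of the temperature and the four rate constants that set the
#' timescales of the model, with defaults taken from typical oxygenic
#' photosystems: inter-sub-unit hopping `k_hop` (1/10 ps), excitation
#' dissipation `k_diss` (1/1 ns), reaction-centre trapping `k_trap` (1/5 ps),
#' and electron output `k_out` (1/10 ms, the water-oxidation cycle). The
#' `overlap` field selects how the spectral-overlap factor enters transfer
#' rates: `"raw"` (default) multiplies `k_hop` by the raw overlap integral
#' times 1 nm, `"normalized"` by the dimensionless normalized overlap.
#'
#' @param temperature Thermodynamic temperature, K. Default 300.
#' @param k_hop Intrinsic hop rate, s^-1. Default 1e11.
#' @param k_diss Dissipation rate, s^-1. Default 1e9.
#' @param k_trap Trapping rate, s^-1. Default 2e11.
#' @param k_out Electron output rate, s^-1. Default 100.
#' @param overlap `"raw"` or `"normalized"`; see Details.
#' @return Object of class `thermo_params`.
#' @export
thermo_params <- function(temperature = 300, k_hop = 1e11, k_diss = 1e9,
                          k_trap = 2e11, k_out = 100,
                          overlap = c("raw", "normalized")) {
  overlap <- match.arg(overlap)
  vals <- c(temperature = temperature, k_hop = k_hop, k_trap = k_trap,
            k_out = k_out)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all thermo parameters must be strictly positive", call. = FALSE)
  # k_diss = 0 is allowed as the dissipationless limit (every captured
  # exciton is eventually trapped)
  if (!is.finite(k_diss) || k_diss < 0)
    stop("k_diss must be non-negative", call. = FALSE)
  structure(list(temperature = temperature, k_hop = k_hop, k_diss = k_diss,
                 k_trap = k_trap, k_out = k_out, overlap = overlap),
            class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf(paste0("<thermo_params> T = %g K, k_hop = %.3g/s, k_diss = %.3g/s, ",
                     "k_trap = %.3g/s, k_out = %.3g/s, overlap = %s\n"),
              x$temperature, x$k_hop, x$k_diss, x$k_trap, x$k_out, x$overlap))
  invisible(x)
}

#' Enthalpy change of an excitation transfer
#'
#' `dH = hc (1/lambda_acceptor - 1/lambda_donor)` with wavelengths in metres:
#' negative (downhill) when the acceptor absorbs further to the red.
#'
#' @param lambda_donor,lambda_acceptor Peak wavelengths, nm.
#' @return Enthalpy change, J. Vectorized.
#' @export
delta_H <- function(lambda_donor, lambda_acceptor) {
  stopifnot(all(lambda_donor > 0), all(lambda_acceptor > 0))
  .hc * (1 / (lambda_acceptor * 1e-9) - 1 / (lambda_donor * 1e-9))
}

#' Entropy change of an excitation transfer (single-excitation form)
#'
#' Moving one excitation from a pool of `N_donor` equivalent pigments to a
#' pool of `N_acceptor` changes the configurational entropy by
#' `k_B ln(N_acceptor / N_donor)`: concentrating an excitation into a smaller
#' pool costs entropy.
#'
#' @param n_donor,n_acceptor Pigment counts (>= 1).
#' @return Entropy change, J K^-1. Vectorized.
#' @export
delta_S <- function(n_donor, n_acceptor) {
  stopifnot(all(n_donor >= 1), all(n_acceptor >= 1))
  .kB * log(n_acceptor / n_donor)
}

#' Entropy change at general occupancies
#'
#' General multiplicity form: the entropy change for moving one excitation
#' from a pool holding `n_i` of `N_i` occupied pigment states to one holding
#' `n_j` of `N_j`, using binomial multiplicities
#' `W(n, N) = N! / (n! (N-n)!)`. With `n_i = 1, n_j = 0` this reduces to the
#' single-excitation form [delta_S()].
#'
#' @param n_i,n_j Current occupancies (0 <= n <= N).
#' @param N_i,N_j Pool sizes.
#' @return Entropy change, J K^-1.
#' @export
delta_S_occupancy <- function(n_i, n_j, N_i, N_j) {
  stopifnot(n_i >= 1, n_j >= 0, n_i <= N_i, n_j < N_j)
  .kB * (lchoose(N_i, n_i - 1) + lchoose(N_j, n_j + 1) -
         lchoose(N_i, n_i) - lchoose(N_j, n_j))
}

#' Boltzmann penalty on an unfavourable transfer
#'
#' Detailed balance is enforced by leaving thermodynamically favourable
#' transfers (`dF <= 0`) at full rate and penalizing unfavourable ones by
#' `exp(-dF / (k_B T))`.
#'
#' @param dF Free energy change, J. Vectorized.
#' @param thermo A [thermo_params()].
#' @return Penalty factor in (0, 1].
#' @export
boltzmann_penalty <- function(dF, thermo = thermo_params()) {
  stopifnot(inherits(thermo, "thermo_params"))
  ifelse(dF <= 0, 1, exp(-dF / (.kB * thermo$temperature)))
}

#' Free energy of an excitation transfer between sub-units
#'
#' Combines the enthalpy change (from the peak wavelengths) and the
#' single-excitation entropy change (from the pigment counts) into
#' `dF = dH - T dS`.
#'
#' @param donor,acceptor Sub-unit descriptors: lists with `n_pigments` and
#'   `profile` (an [absorption_profile()]).
#' @param thermo A [thermo_params()].
#' @return List with `dH` (J), `dS` (J/K) and `dF` (J).
#' @export
free_energy <- function(donor, acceptor, thermo = thermo_params()) {
  dH <- delta_H(donor$profile$lambda_peak, acceptor$profile$lambda_peak)
  dS <- delta_S(donor$n_pigments, acceptor$n_pigments)
  list(dH = dH, dS = dS, dF = dH - thermo$temperature * dS)
}

#' Energy-transfer rate constant between two sub-units
#'
#' The directional transfer rate in the single-excitation regime:
#' `k = k_hop * rho * f(dF)` for connected sub-units, 0 otherwise, where
#' `rho` is the spectral-overlap factor (see [thermo_params()] for the two
#' conventions) and `f` the Boltzmann penalty of the free-energy change.
#' Forward and backward rates constructed this way satisfy detailed balance:
#' their ratio is `exp(-dF / k_B T)`.
#'
#' @param donor,acceptor Sub-unit descriptors: lists with `n_pigments` and
#'   `profile`.
#' @param connected Adjacency flag; unconnected pairs transfer at rate 0.
#' @param thermo A [thermo_params()].
#' @param overlap Overlap convention override; defaults to `thermo$overlap`.
#' @return Transfer rate, s^-1.
#' @export
transfer_rate <- function(donor, acceptor, connected = TRUE,
                          thermo = thermo_params(), overlap = thermo$overlap) {
  if (!connected) return(0)
  rho <- spectral_overlap(donor$profile, acceptor$profile,
                          normalized = identical(overlap, "normalized"))
  # raw overlap carries nm^-1; one excitation hop spans a 1 nm reference
  # bandwidth so k_hop keeps units of s^-1
  fe <- free_energy(donor, acceptor, thermo)
  thermo$k_hop * rho * boltzmann_penalty(fe$dF, thermo)
}
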