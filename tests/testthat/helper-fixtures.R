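# Shared fixtures: light environments, toy graphs, and a random-photosystem
# generator for property-style tests.

sun_5800 <- stellar_model(5800, 0.936)

# blackbody flux at the mid habitable distance, cached per session
fixture_flux <- local({
  cache <- new.env(parent = emptyenv())
  function(t_star = 5800, r_star = 0.936) {
    key <- sprintf("%g|%g", t_star, r_star)
    if (is.null(cache[[key]]))
      cache[[key]] <- planet_flux(stellar_model(t_star, r_star))
    cache[[key]]
  }
})

# spectrally flat flux of given density over [lo, hi] nm
flat_flux <- function(value, lo = 400, hi = 900, n = 2001) {
  spectral_flux(seq(lo, hi, length.out = n), rep(value, n), meta = "flat")
}

# closed-form raw overlap of two Gaussian line shapes (product-of-Gaussians
# integral), the independent oracle for the quadrature implementation
raw_overlap_closed <- function(l1, w1, l2, w2) {
  s2 <- w1^2 + w2^2
  exp(-(l1 - l2)^2 / (2 * s2)) / sqrt(2 * pi * s2)
}

# random branched photosystem + thermo, reproducible under the current RNG
random_system <- function() {
  nb <- sample(1:3, 1)
  ns <- sample(1:3, 1)
  ni <- sample(c(5, 20, 80), 1)
  lam <- runif(ns, 600, 690)
  g <- build_branched(nb, ns, ni, lam,
                      rc = reaction_centre(sample(5:20, 1), 680))
  th <- thermo_params(k_out = 10^runif(1, 1.5, 2.5))
  list(graph = g, thermo = th)
}
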