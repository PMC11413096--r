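kB <- pa_constants()$k_B
eV <- 1.602176634e-19

test_that("absorption profiles integrate to the integrated cross-section", {
  p <- absorption_profile(660, width = 10, sigma_peak = 1e-20)
  grid <- seq(560, 760, by = 0.1)
  integral <- sum(diff(grid) * (head(absorption_value(p, grid), -1) +
                                tail(absorption_value(p, grid), -1)) / 2)
  expect_lt(abs(integral - p$sigma_int) / p$sigma_int, 1e-3)
  expect_equal(absorption_value(p, 660), p$sigma_int / (10 * sqrt(2 * pi)))
  expect_equal(absorption_value(p, 660), p$sigma_peak)
  expect_equal(absorption_value(p, 655), absorption_value(p, 665))
})

test_that("photon capture rate matches the flat-flux closed form and is linear", {
  p <- absorption_profile(660, width = 5)
  f0 <- 1.3
  fl <- flat_flux(f0, 660 - 40, 660 + 40)
  gamma <- excitation_rate(fl, p)
  closed <- f0 * p$sigma_int * (660e-9) / pa_constants()$hc
  expect_lt(abs(gamma - closed) / closed, 0.01)

  expect_equal(excitation_rate(flat_flux(0), p), 0)
  expect_equal(excitation_rate(flat_flux(2 * f0, 620, 700), p),
               2 * excitation_rate(flat_flux(f0, 620, 700), p))
  p2 <- absorption_profile(660, width = 5, sigma_peak = 3e-20)
  expect_equal(excitation_rate(fl, p2), 3 * gamma, tolerance = 1e-12)
  expect_warning(excitation_rate(flat_flux(1, 900, 1000), p), "overlap")
})

test_that("spectral overlap matches the product-of-Gaussians closed form", {
  a <- absorption_profile(660, 10)
  expect_equal(spectral_overlap(a, a), 1, tolerance = 1e-6)
  # equal widths w = 10, coincident peaks: 1/(2 w sqrt(pi))
  expect_equal(spectral_overlap(a, a, normalized = FALSE), 0.02821,
               tolerance = 1e-3)
  set.seed(7)
  for (i in 1:25) {
    p1 <- absorption_profile(runif(1, 400, 900), runif(1, 5, 20))
    p2 <- absorption_profile(runif(1, 400, 900), runif(1, 5, 20))
    raw <- spectral_overlap(p1, p2, normalized = FALSE)
    expect_equal(raw, raw_overlap_closed(p1$lambda_peak, p1$width,
                                         p2$lambda_peak, p2$width),
                 tolerance = 1e-3)
    expect_equal(spectral_overlap(p1, p2), spectral_overlap(p2, p1))
  }
})

test_that("enthalpy and entropy terms take their thermodynamic values", {
  expect_equal(delta_H(665, 665), 0)
  expect_equal(delta_H(665, 680) / eV, -0.041124, tolerance = 1e-4)
  expect_equal(delta_H(665, 680), -delta_H(680, 665))

  expect_equal(delta_S(50, 50), 0)
  expect_equal(delta_S(100, 10), kB * log(0.1))
  expect_equal(delta_S(100, 10), -3.18e-23, tolerance = 1e-3)
  # general multiplicity form reduces to the single-excitation form
  for (Ni in c(3, 17, 120)) for (Nj in c(2, 40)) {
    expect_equal(delta_S_occupancy(1, 0, Ni, Nj), delta_S(Ni, Nj))
  }
  # a second excitation into a half-full acceptor pool is less favourable
  expect_lt(delta_S_occupancy(1, 5, 100, 10), delta_S_occupancy(1, 0, 100, 10))
})

test_that("the Boltzmann penalty is one-sided and detailed-balance consistent", {
  th <- thermo_params()
  expect_equal(boltzmann_penalty(0, th), 1)
  expect_equal(boltzmann_penalty(-1e-20, th), 1)
  expect_equal(boltzmann_penalty(kB * 300, th), exp(-1))
  for (dF in c(-3e-20, 1e-21, 5e-20)) {
    expect_equal(boltzmann_penalty(dF, th) * boltzmann_penalty(-dF, th),
                 exp(-abs(dF) / (kB * 300)))
  }
})

test_that("transfer rates respect adjacency, iso-energetic limits and detailed balance", {
  th <- thermo_params()
  a <- list(n_pigments = 50, profile = absorption_profile(660, 10))
  expect_equal(transfer_rate(a, a, connected = FALSE, th), 0)
  # identical connected sub-units: normalized overlap 1, dF = 0
  expect_equal(transfer_rate(a, a, thermo = th, overlap = "normalized"),
               th$k_hop, tolerance = 1e-6)
  # raw convention: k_hop times the raw overlap (1 nm reference bandwidth)
  expect_equal(transfer_rate(a, a, thermo = th, overlap = "raw"),
               th$k_hop * raw_overlap_closed(660, 10, 660, 10),
               tolerance = 1e-3)

  set.seed(11)
  for (i in 1:40) {
    d <- list(n_pigments = sample(1:200, 1),
              profile = absorption_profile(runif(1, 400, 900), runif(1, 5, 20)))
    ac <- list(n_pigments = sample(1:200, 1),
               profile = absorption_profile(runif(1, 400, 900), runif(1, 5, 20)))
    fwd <- transfer_rate(d, ac, thermo = th)
    bwd <- transfer_rate(ac, d, thermo = th)
    dF <- free_energy(d, ac, th)$dF
    if (bwd == 0) {
      # spectral overlap underflows for pigments hundreds of widths apart;
      # both directions must then vanish together
      expect_equal(fwd, 0)
    } else {
      expect_equal(fwd / bwd, exp(-dF / (kB * th$temperature)), tolerance = 1e-12)
    }
    # free energy is antisymmetric under direction reversal
    expect_equal(free_energy(ac, d, th)$dF, -dF)
  }
})
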