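test_that("blackbody surface flux peaks at the Wien wavelength and grows with temperature", {
  grid <- seq(200, 2500, by = 1)
  fl <- blackbody_surface_flux(sun_5800, grid)
  expect_equal(grid[which.max(fl$flux)], 500)  # 2.898e6 / 5800 ~ 499.7 nm
  hot <- blackbody_surface_flux(stellar_model(6000, 1), grid)
  cold <- blackbody_surface_flux(stellar_model(5000, 1), grid)
  expect_true(all(hot$flux > cold$flux))
  expect_true(all(fl$flux > 0))
  expect_error(blackbody_surface_flux(sun_5800, c(-1, 500)), "positive")
  expect_error(stellar_model(-100, 1), "positive")
})

test_that("spectral flux container enforces its invariants", {
  expect_error(spectral_flux(c(500, 400), c(1, 1)), "increasing")
  expect_error(spectral_flux(c(400, 500), c(1, -1)), "non-negative")
  expect_error(spectral_flux(c(400, 500), c(1, 1, 1)), "equal length")
  expect_error(spectral_flux(400, 1), "at least 2")
})

test_that("flux files round-trip and parse errors name the offending line", {
  fl <- flat_flux(1.5, 400, 410, 11)
  path <- withr::local_tempfile(fileext = ".txt")
  write_flux(fl, path)
  back <- load_flux(path)
  expect_equal(back$wavelengths, fl$wavelengths)
  expect_equal(back$flux, fl$flux)

  writeLines(c("# comment", "400 1.0", "410 -0.5", "420 1.0"), path)
  expect_error(load_flux(path), "negative flux at line 3")

  writeLines(c("500 2.0", "400 1.0", "450 1.5"), path)
  expect_equal(load_flux(path)$wavelengths, c(400, 450, 500))

  writeLines(c("400 1.0", "400 2.0"), path)
  expect_error(load_flux(path), "duplicate wavelength")

  writeLines("400 1.0", path)
  expect_error(load_flux(path), "fewer than 2")
})

test_that("resampling conserves band power, preserves constants, and is idempotent", {
  fl <- blackbody_surface_flux(sun_5800, seq(200, 2500, by = 0.25))
  rs <- resample_smooth(fl, 4000)
  expect_length(rs$wavelengths, 4000)
  expect_lt(abs(band_power(rs) - band_power(fl)) / band_power(fl), 0.01)

  const <- flat_flux(2.5, 400, 900, 501)
  rc <- resample_smooth(const, 50)
  expect_equal(rc$flux, rep(2.5, 50))

  twice <- resample_smooth(rs, 4000)
  expect_equal(twice$flux, rs$flux, tolerance = 1e-12)
  expect_error(resample_smooth(const, 1), "between 2")
  expect_error(resample_smooth(const, 1e6), "between 2")
})

test_that("surface flux applies the inverse-square dilution and conserves spectral shape", {
  i_s <- blackbody_surface_flux(sun_5800)
  same <- surface_flux(i_s, sun_5800, sun_5800$r_star)
  expect_equal(same$flux, i_s$flux)
  quarter <- surface_flux(i_s, sun_5800, 2 * sun_5800$r_star)
  expect_equal(quarter$flux, i_s$flux / 4)
  far <- surface_flux(i_s, sun_5800, 1.3e11)
  ratio <- far$flux / i_s$flux
  expect_equal(max(ratio), min(ratio))
  expect_error(surface_flux(i_s, sun_5800, 0.5 * sun_5800$r_star), "no smaller")
})

test_that("habitable distances match the stellar-model benchmark rows", {
  hz <- habitable_distances(sun_5800)
  expect_equal(round(c(hz$a_min, hz$a_mid, hz$a_max), 3), c(0.526, 0.754, 0.982))
  hz2 <- habitable_distances(stellar_model(2300, 0.117))
  expect_equal(round(c(hz2$a_min, hz2$a_mid, hz2$a_max), 3), c(0.010, 0.015, 0.019))
  # equilibrium temperature equal to the stellar temperature puts the planet
  # at half a stellar radius
  star <- stellar_model(273, 1)
  expect_equal(habitable_distances(star)$a_max_m, star$r_star / 2)
  expect_true(hz$a_min < hz$a_mid && hz$a_mid < hz$a_max)
})

test_that("atmospheric transmission multiplies pointwise and composes", {
  fl <- fixture_flux()
  ones <- data.frame(w = c(200, 2500), t = c(1, 1))
  expect_equal(apply_transmission(fl, ones)$flux, fl$flux)
  zeros <- data.frame(w = c(200, 2500), t = c(0, 0))
  expect_equal(apply_transmission(fl, zeros)$flux, rep(0, length(fl$flux)))

  wg <- fl$wavelengths
  tx_a <- data.frame(w = wg, t = runif(length(wg)))
  tx_b <- data.frame(w = wg, t = runif(length(wg)))
  seq_ab <- apply_transmission(apply_transmission(fl, tx_a), tx_b)
  prod_ab <- apply_transmission(fl, data.frame(w = wg, t = tx_a$t * tx_b$t))
  expect_equal(seq_ab$flux, prod_ab$flux, tolerance = 1e-10)

  expect_error(apply_transmission(fl, data.frame(w = c(300, 400), t = c(0.5, 1.2))),
               "\\[0, 1\\]")
  # wavelengths outside the transmission grid are opaque
  narrow <- data.frame(w = c(500, 600), t = c(1, 1))
  att <- apply_transmission(fl, narrow)
  expect_equal(att$flux[fl$wavelengths > 700], rep(0, sum(fl$wavelengths > 700)))
})

test_that("transmission files load with validation", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# wavelength_nm transmittance", "600 0.5", "400 1.0"), path)
  tx <- load_transmission(path)
  expect_equal(tx$wavelengths, c(400, 600))
  writeLines(c("400 0.5", "600 1.5"), path)
  expect_error(load_transmission(path), "line 2")
})
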