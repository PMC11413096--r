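test_that("the single-excitation state space has 2(N+2) unique states", {
  g3 <- build_branched(3, 1, 10, 665)
  sp3 <- enumerate_states(g3)
  expect_equal(nrow(sp3), 10)
  g1 <- build_illustrative(5, 660)
  sp1 <- enumerate_states(g1)
  expect_equal(nrow(sp1), 6)
  expect_false(any(duplicated(paste(sp1$location, sp1$trap))))
  # index map is a bijection over (location, trap)
  idx <- mapply(function(l, t) photoantenna:::state_index(sp3, l, t),
                sp3$location, sp3$trap)
  expect_setequal(idx, seq_len(nrow(sp3)))
})

test_that("the generator conserves probability and carries the capture rates", {
  g <- build_illustrative(100, 659)
  th <- thermo_params()
  rates <- build_rate_set(g, fixture_flux(), th)
  sp <- enumerate_states(g)
  Q <- build_generator(sp, rates)
  expect_lt(max(abs(rowSums(Q))) / max(abs(Q)), 1e-14)
  i_empty0 <- photoantenna:::state_index(sp, "empty", 0L)
  i_s1_0 <- photoantenna:::state_index(sp, "s1", 0L)
  expect_equal(Q[i_empty0, i_s1_0], rates$gamma[["s1"]] * 100)
  # absorption is allowed while the trap is closed, from the empty antenna
  i_empty1 <- photoantenna:::state_index(sp, "empty", 1L)
  i_s1_1 <- photoantenna:::state_index(sp, "s1", 1L)
  expect_equal(Q[i_empty1, i_s1_1], rates$gamma[["s1"]] * 100)
  # but no double excitation: nothing leaves an excited state by absorption
  expect_equal(Q[i_s1_0, i_s1_1], 0)

  dark <- build_rate_set(g, NULL, th)
  Qd <- build_generator(enumerate_states(g), dark)
  expect_equal(Qd[i_empty0, i_s1_0], 0)
})

test_that("darkness collapses the stationary state onto the open ground state", {
  g <- build_illustrative(50, 660)
  rates <- build_rate_set(g, NULL, thermo_params())
  sp <- enumerate_states(g)
  p <- solve_stationary(build_generator(sp, rates))
  expect_equal(unname(p[photoantenna:::state_index(sp, "empty", 0L)]), 1)
  expect_equal(sum(p), 1)
})

test_that("two iso-energetic equal sub-units are occupied equally", {
  g <- build_branched(2, 1, 40, 660)
  th <- thermo_params()
  rates <- build_rate_set(g, NULL, th)
  rates$gamma[] <- 1e-3  # faint symmetric illumination
  sp <- enumerate_states(g)
  res <- observables(solve_stationary(build_generator(sp, rates)), sp, rates, g)
  occ <- res$occ_subunits
  expect_lt(abs(occ[1] - occ[2]) / max(occ), 1e-9)
})

test_that("stationary distributions conserve probability on randomized systems", {
  set.seed(19)
  for (i in 1:8) {
    sys <- random_system()
    scale <- 10^runif(1, -2, 2)
    res <- solve_photosystem(sys$graph, fixture_flux(), sys$thermo,
                             flux_scale = scale)
    p <- res$probabilities
    expect_equal(sum(p), 1, tolerance = 1e-10)
    expect_true(all(p >= 0 & p <= 1))
    expect_lte(res$nu_e, sys$thermo$k_out * (1 + 1e-12))
    expect_equal(res$nu_e, sys$thermo$k_out * res$occ_trap)
    expect_true(res$phi_e >= 0 && res$phi_e <= 1)
  }
})

test_that("electron output rises monotonically with flux and saturates at k_out", {
  g <- build_branched(6, 3, 100, 665)
  th <- thermo_params()
  scales <- 10^seq(-3, 3, by = 1)
  nus <- vapply(scales, function(s)
    solve_photosystem(g, fixture_flux(), th, flux_scale = s)$nu_e, 0)
  expect_true(all(diff(nus) >= -1e-9))
  expect_lt(nus[length(nus)], th$k_out + 1e-9)
  expect_gt(nus[length(nus)], 0.99 * th$k_out)
})

test_that("the quantum efficiency is 1 without dissipation and matches the low-light ratio", {
  g <- build_branched(2, 2, 50, 665)
  lossless <- thermo_params(k_diss = 0)
  rates <- build_rate_set(g, fixture_flux(), lossless)
  expect_equal(quantum_efficiency(g, rates), 1, tolerance = 1e-12)

  # independent route: solve the master equation at a small flux scale and
  # form the output/(output+dissipation) ratio directly
  th <- thermo_params()
  res <- solve_photosystem(g, fixture_flux(), th, flux_scale = 1e-3)
  ratio <- res$nu_e /
    (res$nu_e + th$k_diss * (res$occ_rc + sum(res$occ_subunits)))
  # the finite-scale ratio carries an O(flux_scale) saturation bias
  expect_equal(res$phi_e, ratio, tolerance = 5e-3)

  # the ratio converges to the first-passage value as the scale shrinks
  res2 <- solve_photosystem(g, fixture_flux(), th, flux_scale = 1e-4)
  ratio2 <- res2$nu_e /
    (res2$nu_e + th$k_diss * (res2$occ_rc + sum(res2$occ_subunits)))
  expect_lt(abs(ratio2 - res$phi_e), abs(ratio - res$phi_e) + 1e-12)
})

test_that("the Gillespie oracle reproduces the linear-solve occupancies", {
  g <- build_illustrative(100, 659)
  th <- thermo_params()
  rates <- build_rate_set(g, fixture_flux(), th)
  sp <- enumerate_states(g)
  det <- observables(solve_stationary(build_generator(sp, rates)), sp, rates, g)

  sim <- gillespie(g, rates, seed = 42, n_events = 2e4)
  sim_again <- gillespie(g, rates, seed = 42, n_events = 2e4)
  expect_identical(sim$occupancy, sim_again$occupancy)
  expect_identical(sim$nu_e, sim_again$nu_e)

  expect_lt(abs(sim$nu_e - det$nu_e), 3 * sim$nu_e_se)
  expect_lt(abs(sim$occ_trap - det$occ_trap), 3 * max(sim$occ_trap_se, 1e-4))
  # electron output events can exceed trap fillings by at most the one
  # electron in flight at the end of the run
  expect_lte(abs(sim$n_output_events - sim$n_trap_events), 1)
})

test_that("Gillespie and the linear solver agree on randomized systems", {
  set.seed(101)
  for (i in 1:5) {
    sys <- random_system()
    rates <- build_rate_set(sys$graph, fixture_flux(), sys$thermo)
    sp <- enumerate_states(sys$graph)
    det <- observables(solve_stationary(build_generator(sp, rates)),
                       sp, rates, sys$graph)
    sim <- gillespie(sys$graph, rates, seed = 1000 + i, n_events = 4e4)
    # the 4e-3 floor guards against batch-means variance underestimation
    # when trap cycles are long relative to a batch
    expect_lt(abs(sim$occ_trap - det$occ_trap), 3 * max(sim$occ_trap_se, 4e-3))
    expect_lt(abs(sim$occ_rc - det$occ_rc), 3 * max(sim$occ_rc_se, 4e-3))
    expect_lt(abs(sim$occ_antenna - sum(det$occ_subunits)),
              3 * max(sim$occ_antenna_se, 4e-3))
  }
})
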