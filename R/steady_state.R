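# Single-excitation state space, master-equation generator, stationary
# solution and derived observables.

#' Enumerate the single-excitation state space
#'
#' Because trapping and dissipation are orders of magnitude faster than photon
#' capture, the photosystem holds at most one excitation at a time. A state is
#' therefore a pair (exciton location, trap state): the location is `"empty"`
#' (no exciton), a sub-unit id, or `"RC"`, and the trap is open (0) or closed
#' (1, holding a charge-separated state). A graph with `N` sub-units yields
#' `2 (N + 2)` states; the configuration with an exciton present while the
#' trap also holds one excludes double counting of the RC excitation.
#'
#' @param graph A `photosystem_graph`.
#' @return Object of class `state_space`: a data.frame with columns
#'   `location` and `trap`, one row per state.
#' @export
enumerate_states <- function(graph) {
  stopifnot(inherits(graph, "photosystem_graph"))
  locations <- c("empty", graph$subunits$id, "RC")
  st <- data.frame(location = rep(locations, 2L),
                   trap = rep(c(0L, 1L), each = length(locations)),
                   stringsAsFactors = FALSE)
  structure(st, class = c("state_space", "data.frame"))
}

# row index of a (location, trap) pair in the state space
state_index <- function(space, location, trap) {
  n_loc <- nrow(space) / 2L
  locs <- space$location[seq_len(n_loc)]
  match(location, locs) + n_loc * trap
}

#' Assemble all rate constants for a photosystem under a flux
#'
#' Computes the per-pigment capture rate gamma of every sub-unit from the
#' incident flux and all pairwise transfer constants along the graph's edges
#' from the detailed-balance construction in [transfer_rate()]. Spectral
#' overlaps are evaluated once per unique profile pair.
#'
#' @param graph A `photosystem_graph`.
#' @param flux A [spectral_flux()], or `NULL` for darkness (all gamma 0).
#' @param thermo A [thermo_params()].
#' @return Object of class `rate_set`: `gamma` (named, s^-1 per pigment),
#'   `k` (dense node-by-node rate matrix, s^-1, nodes = sub-units then "RC"),
#'   `n_pigments` (named), and `thermo`.
#' @export
build_rate_set <- function(graph, flux, thermo = thermo_params()) {
  stopifnot(inherits(graph, "photosystem_graph"), inherits(thermo, "thermo_params"))
  su <- graph$subunits
  nodes <- c(su$id, "RC")
  # gamma per unique absorption profile
  key <- sprintf("%.6f|%.6f|%.6g", su$lambda_peak, su$width, su$sigma_peak)
  gamma_by_key <- vapply(unique(key), function(k) {
    i <- match(k, key)
    if (is.null(flux)) return(0)
    excitation_rate(flux, absorption_profile(su$lambda_peak[i], su$width[i],
                                             su$sigma_peak[i]))
  }, 0)
  gamma <- stats::setNames(gamma_by_key[key], su$id)

  desc <- c(lapply(su$id, function(id) subunit_descriptor(graph, id)),
            list(subunit_descriptor(graph, "RC")))
  names(desc) <- nodes
  k <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  beta <- 1 / (.kB * thermo$temperature)
  rho_cache <- new.env(parent = emptyenv())
  rho_of <- function(a, b) {
    ck <- paste(sort(c(sprintf("%.6f|%.6f", a$profile$lambda_peak, a$profile$width),
                       sprintf("%.6f|%.6f", b$profile$lambda_peak, b$profile$width))),
                collapse = "+")
    if (is.null(rho_cache[[ck]]))
      rho_cache[[ck]] <- spectral_overlap(a$profile, b$profile,
                                          normalized = identical(thermo$overlap,
                                                                 "normalized"))
    rho_cache[[ck]]
  }
  for (e in seq_len(nrow(graph$edges))) {
    a <- graph$edges[e, 1]; b <- graph$edges[e, 2]
    da <- desc[[a]]; db <- desc[[b]]
    rho <- rho_of(da, db)
    dF <- free_energy(da, db, thermo)$dF
    pen_f <- if (dF <= 0) 1 else exp(-beta * dF)
    pen_b <- if (-dF <= 0) 1 else exp(beta * dF)
    k[a, b] <- thermo$k_hop * rho * pen_f
    k[b, a] <- thermo$k_hop * rho * pen_b
  }
  structure(list(gamma = gamma, k = k,
                 n_pigments = stats::setNames(c(su$n_pigments, graph$rc$n_pigments),
                                              nodes),
                 thermo = thermo),
            class = "rate_set")
}

#' Build the master-equation generator
#'
#' Dense transition-rate matrix `Q` over the single-excitation state space,
#' with `Q[a, b]` the rate of the jump a -> b and diagonal entries minus the
#' row exit sums, so every row sums to zero and total probability is
#' conserved. The processes are: photon capture `(empty, t) -> (i, t)` at
#' `gamma_i N_i`; dissipation `(i, t) -> (empty, t)` and
#' `(RC, t) -> (empty, t)` at `k_diss`; transfer along edges at the
#' detailed-balance rates; trapping `(RC, 0) -> (empty, 1)` at `k_trap` (the
#' exciton becomes the trapped charge-separated state, which does not
#' dissipate); and electron output `(., 1) -> (., 0)` at `k_out`.
#'
#' @param space A `state_space`.
#' @param rates A `rate_set`.
#' @return Square rate matrix, s^-1, with state labels as dimnames.
#' @export
build_generator <- function(space, rates) {
  stopifnot(inherits(space, "state_space"), inherits(rates, "rate_set"))
  if (any(rates$gamma < 0) || any(rates$k < 0))
    stop("negative rates", call. = FALSE)
  th <- rates$thermo
  n <- nrow(space)
  n_loc <- n / 2L
  subs <- names(rates$gamma)
  Q <- matrix(0, n, n,
              dimnames = list(paste(space$location, space$trap, sep = "/"), NULL))
  colnames(Q) <- rownames(Q)
  idx <- function(loc, t) state_index(space, loc, t)
  for (t in 0:1) {
    for (i in subs) {
      Q[idx("empty", t), idx(i, t)] <- rates$gamma[i] * rates$n_pigments[i]
      Q[idx(i, t), idx("empty", t)] <- th$k_diss
    }
    Q[idx("RC", t), idx("empty", t)] <- th$k_diss
    nodes <- c(subs, "RC")
    for (a in nodes) for (b in nodes) {
      if (rates$k[a, b] > 0)
        Q[idx(a, t), idx(b, t)] <- Q[idx(a, t), idx(b, t)] + rates$k[a, b]
    }
  }
  Q[idx("RC", 0), idx("empty", 1)] <- Q[idx("RC", 0), idx("empty", 1)] + th$k_trap
  locs <- space$location[seq_len(n_loc)]
  for (loc in locs) Q[idx(loc, 1), idx(loc, 0)] <- Q[idx(loc, 1), idx(loc, 0)] + th$k_out
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Solve for the stationary distribution
#'
#' Solves `Q^T pi = 0` with the probability-normalization constraint replacing
#' one equation, by dense LU factorization. The residual of the stationary
#' condition is checked against 1e-10 (relative to the largest rate).
#'
#' @param generator Rate matrix from [build_generator()].
#' @return Numeric vector of stationary probabilities (sums to 1).
#' @export
solve_stationary <- function(generator) {
  n <- nrow(generator)
  A <- t(generator)
  scale <- max(abs(A))
  A[n, ] <- scale  # normalization row, scaled to the matrix magnitude
  b <- c(rep(0, n - 1L), scale)
  p <- tryCatch(solve(A, b), error = function(e)
    stop(sprintf("stationary solve failed (%s); condition estimate %.3g",
                 conditionMessage(e), kappa(A)), call. = FALSE))
  resid <- max(abs(t(generator) %*% p)) / scale
  if (!is.finite(resid) || resid > 1e-10)
    stop(sprintf("stationary residual %.3g exceeds tolerance; condition %.3g",
                 resid, kappa(A)), call. = FALSE)
  p[p < 0 & p > -1e-12] <- 0
  p <- p / sum(p)
  stats::setNames(p, rownames(generator))
}

#' Low-light quantum efficiency
#'
#' The absolute quantum efficiency is the fraction of captured photons that
#' yield an output electron in the limit of non-saturating light. In that
#' limit each captured exciton performs an independent first-passage walk on
#' the open-trap network, so the efficiency is the capture-weighted
#' trap-hitting probability: for each excited location the probability of
#' reaching the trap before dissipating solves a small linear system, and the
#' weights are the sub-unit capture rates `gamma_i N_i` (uniform pigment
#' weights are used in darkness, where the weighting is immaterial).
#'
#' @param graph A `photosystem_graph`.
#' @param rates A `rate_set`.
#' @return Efficiency in `[0, 1]`.
#' @export
quantum_efficiency <- function(graph, rates) {
  stopifnot(inherits(graph, "photosystem_graph"), inherits(rates, "rate_set"))
  th <- rates$thermo
  nodes <- c(graph$subunits$id, "RC")
  nn <- length(nodes)
  k <- rates$k[nodes, nodes, drop = FALSE]
  out <- rowSums(k) + th$k_diss + ifelse(nodes == "RC", th$k_trap, 0)
  # h = P(exciton at node reaches the trap before dissipating)
  A <- diag(out, nn) - k
  rhs <- ifelse(nodes == "RC", th$k_trap, 0)
  h <- solve(A, rhs)
  w <- rates$gamma * rates$n_pigments[names(rates$gamma)]
  if (sum(w) <= 0) w <- rates$n_pigments[names(rates$gamma)]
  sum(w * h[match(names(w), nodes)]) / sum(w)
}

#' Derive steady-state observables
#'
#' Marginal occupancies and performance measures from a stationary
#' distribution: the trap occupancy `occ_trap` (fraction of time the RC is
#' closed), the RC and per-sub-unit exciton occupancies, the electron output
#' rate `nu_e = k_out * occ_trap`, the low-light quantum efficiency `phi_e`,
#' and the per-antenna-pigment output `nu_e / N_p` (N_p excludes the RC).
#'
#' @param probabilities Stationary vector from [solve_stationary()].
#' @param space The `state_space` the vector is indexed by.
#' @param rates The `rate_set` used to build the generator.
#' @param graph The `photosystem_graph`.
#' @return Object of class `steady_state_result`.
#' @export
observables <- function(probabilities, space, rates, graph) {
  stopifnot(inherits(space, "state_space"))
  n_loc <- nrow(space) / 2L
  p <- probabilities
  subs <- graph$subunits$id
  occ_trap <- sum(p[space$trap == 1L])
  occ_rc <- sum(p[space$location == "RC"])
  occ_subunits <- vapply(subs, function(i) sum(p[space$location == i]), 0)
  nu_e <- rates$thermo$k_out * occ_trap
  n_p <- n_antenna_pigments(graph)
  structure(list(probabilities = p,
                 occ_trap = occ_trap, occ_rc = occ_rc,
                 occ_subunits = occ_subunits,
                 nu_e = nu_e,
                 phi_e = quantum_efficiency(graph, rates),
                 nu_e_per_pigment = nu_e / n_p,
                 n_antenna_pigments = n_p),
            class = "steady_state_result")
}

#' @export
print.steady_state_result <- function(x, ...) {
  cat(sprintf(paste0("<steady_state_result> nu_e = %.4g /s, phi_e = %.4g, ",
                     "nu_e/N_p = %.4g /s\n  trap closed %.2f%% of the time, ",
                     "N_p = %d antenna pigments\n"),
              x$nu_e, x$phi_e, x$nu_e_per_pigment, 100 * x$occ_trap,
              x$n_antenna_pigments))
  invisible(x)
}

#' Solve a photosystem under a light environment
#'
#' End-to-end pipeline: rate construction, generator assembly, stationary
#' solve and observables.
#'
#' @param graph A `photosystem_graph`.
#' @param flux A [spectral_flux()] (or `NULL` for darkness).
#' @param thermo A [thermo_params()].
#' @param flux_scale Dimensionless multiplier applied to all capture rates
#'   (useful for light-response curves without rebuilding spectra).
#' @return A `steady_state_result`.
#' @examples
#' g <- build_illustrative(100, 659)
#' fl <- planet_flux(stellar_model(5800, 0.936))
#' solve_photosystem(g, fl)
#' @export
solve_photosystem <- function(graph, flux, thermo = thermo_params(),
                              flux_scale = 1) {
  rates <- build_rate_set(graph, flux, thermo)
  if (flux_scale != 1) rates$gamma <- rates$gamma * flux_scale
  space <- enumerate_states(graph)
  Q <- build_generator(space, rates)
  p <- solve_stationary(Q)
  observables(p, space, rates, graph)
}
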