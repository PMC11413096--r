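# Parameter-sweep drivers over the three antenna families and optimum
# extraction.

as_flux_list <- function(fluxes) {
  if (inherits(fluxes, "spectral_flux")) {
    lab <- sub("^.*T_s = ([0-9.]+) K.*$", "\\1", fluxes$meta)
    if (identical(lab, fluxes$meta)) lab <- "flux"
    fluxes <- stats::setNames(list(fluxes), lab)
  }
  if (!is.list(fluxes) || !all(vapply(fluxes, inherits, TRUE, "spectral_flux")))
    stop("fluxes must be a spectral_flux or a named list of them", call. = FALSE)
  if (is.null(names(fluxes)) || any(!nzchar(names(fluxes))))
    stop("each flux needs a name (typically the stellar temperature)", call. = FALSE)
  fluxes
}

#' Logarithmic antenna-size grid
#'
#' Approximately log-spaced pigment counts between `from` and `to`, deduplicated
#' after rounding.
#'
#' @param from,to Smallest and largest count.
#' @param n Number of grid points before deduplication.
#' @return Integer vector.
#' @export
size_grid_log <- function(from = 1, to = 1000, n = 12) {
  unique(round(10^seq(log10(from), log10(to), length.out = n)))
}

sweep_skeleton <- function(rows, family, params) {
  rows$half_max <- rows$nu_e >= params$thermo$k_out / 2
  rows$per_pigment_ok <- rows$nu_e_per_pigment > 0.03
  structure(rows, class = c("sweep_result", "data.frame"),
            provenance = list(family = family,
                              package_version = as.character(utils::packageVersion("photoantenna")),
                              parameters = params$echo,
                              flux_meta = params$flux_meta))
}

#' @export
print.sweep_result <- function(x, ...) {
  pr <- attr(x, "provenance")
  cat(sprintf("<sweep_result> family '%s', %d grid points\n", pr$family, nrow(x)))
  NextMethod()
}

#' Sweep the single-LHC illustrative model
#'
#' For every combination of incident flux, antenna peak wavelength and antenna
#' size, builds the single-LHC photosystem, solves the steady state, and
#' tabulates the electron output `nu_e`, the low-light efficiency `phi_e`
#' (an intrinsic antenna property, computed once per (lambda, N_p) and
#' independent of the flux) and the per-pigment output.
#'
#' @param fluxes A [spectral_flux()] or named list of them (names label the
#'   `t_star` column).
#' @param lambda_grid Antenna peak wavelengths to scan, nm.
#' @param size_grid Antenna pigment counts to scan.
#' @param thermo A [thermo_params()].
#' @param rc A [reaction_centre()].
#' @param width Antenna profile width, nm.
#' @return A `sweep_result` data.frame in long form.
#' @export
run_illustrative_sweep <- function(fluxes, lambda_grid = 620:700,
                                   size_grid = size_grid_log(),
                                   thermo = thermo_params(),
                                   rc = reaction_centre(), width = 10) {
  fluxes <- as_flux_list(fluxes)
  stopifnot(length(lambda_grid) > 0, length(size_grid) > 0)
  rows <- vector("list", 0L)
  phi_cache <- matrix(NA_real_, length(lambda_grid), length(size_grid))
  for (fi in seq_along(fluxes)) {
    fl <- fluxes[[fi]]
    for (li in seq_along(lambda_grid)) {
      lam <- lambda_grid[li]
      for (ni in seq_along(size_grid)) {
        np <- size_grid[ni]
        g <- suppressWarnings(build_illustrative(np, lam, rc = rc, width = width))
        res <- solve_photosystem(g, fl, thermo)
        if (is.na(phi_cache[li, ni])) phi_cache[li, ni] <- res$phi_e
        rows[[length(rows) + 1L]] <- data.frame(
          family = "illustrative", t_star = names(fluxes)[fi],
          n_branches = NA_integer_, n_subunit = np, n_shells = NA_integer_,
          lambda = lam, delta_lambda = NA_real_, n_pigments = np,
          nu_e = res$nu_e, phi_e = phi_cache[li, ni],
          nu_e_per_pigment = res$nu_e_per_pigment,
          stringsAsFactors = FALSE)
      }
    }
  }
  sweep_skeleton(do.call(rbind, rows), "illustrative",
                 list(thermo = thermo,
                      echo = list(lambda_grid = lambda_grid, size_grid = size_grid,
                                  rc = unclass(rc)[c("n_pigments")],
                                  thermo = unclass(thermo)),
                      flux_meta = vapply(fluxes, `[[`, "", "meta")))
}

#' Sweep the branched modular antenna
#'
#' Grows a branched antenna of identical iso-energetic sub-units one shell per
#' branch at a time and scans the common peak wavelength; one row per
#' (flux, lambda, shell count).
#'
#' @param fluxes A [spectral_flux()] or named list of them.
#' @param lambda_grid Common sub-unit peak wavelengths, nm.
#' @param n_branches Number of branches (1, 6 or 12 in the standard
#'   geometries).
#' @param subunit_size Pigments per sub-unit (10 "small" or 100 "large").
#' @param shells Shell counts to scan (antenna grows by one sub-unit per
#'   branch per step).
#' @param thermo A [thermo_params()].
#' @param rc A [reaction_centre()].
#' @param width Sub-unit profile width, nm.
#' @return A `sweep_result` data.frame in long form.
#' @export
run_modular_sweep <- function(fluxes, lambda_grid = 620:700, n_branches = 6,
                              subunit_size = 100, shells = 1:10,
                              thermo = thermo_params(),
                              rc = reaction_centre(), width = 10) {
  fluxes <- as_flux_list(fluxes)
  rows <- vector("list", 0L)
  for (fi in seq_along(fluxes)) {
    fl <- fluxes[[fi]]
    for (lam in lambda_grid) {
      for (ns in shells) {
        g <- build_branched(n_branches, ns, subunit_size, lam, rc = rc,
                            width = width)
        res <- solve_photosystem(g, fl, thermo)
        rows[[length(rows) + 1L]] <- data.frame(
          family = "modular", t_star = names(fluxes)[fi],
          n_branches = n_branches, n_subunit = subunit_size, n_shells = ns,
          lambda = lam, delta_lambda = NA_real_,
          n_pigments = n_antenna_pigments(g),
          nu_e = res$nu_e, phi_e = res$phi_e,
          nu_e_per_pigment = res$nu_e_per_pigment,
          stringsAsFactors = FALSE)
      }
    }
  }
  sweep_skeleton(do.call(rbind, rows), "modular",
                 list(thermo = thermo,
                      echo = list(lambda_grid = lambda_grid, n_branches = n_branches,
                                  subunit_size = subunit_size, shells = shells,
                                  thermo = unclass(thermo)),
                      flux_meta = vapply(fluxes, `[[`, "", "meta")))
}

#' Sweep the funnel antenna blue-shift
#'
#' For the branched geometry with the innermost shell pinned at
#' `lambda_inner`, scans the per-shell blue-shift `delta_lambda` and the
#' number of shells; one row per (flux, delta_lambda, shell count). A
#' `delta_lambda` of 0 reduces to the modular antenna.
#'
#' @param fluxes A [spectral_flux()] or named list of them.
#' @param delta_grid Blue-shifts per shell to scan, nm.
#' @param lambda_inner Peak of the shell adjacent to the RC, nm.
#' @param n_branches,subunit_size,shells,thermo,rc,width As in
#'   [run_modular_sweep()].
#' @return A `sweep_result` data.frame in long form.
#' @export
run_funnel_sweep <- function(fluxes, delta_grid = 0:30, lambda_inner = 665,
                             n_branches = 6, subunit_size = 100, shells = 1:10,
                             thermo = thermo_params(),
                             rc = reaction_centre(), width = 10) {
  fluxes <- as_flux_list(fluxes)
  rows <- vector("list", 0L)
  for (fi in seq_along(fluxes)) {
    fl <- fluxes[[fi]]
    for (dl in delta_grid) {
      for (ns in shells) {
        g <- build_branched(n_branches, ns, subunit_size, lambda_inner,
                            rc = rc, width = width)
        g <- assign_funnel(g, lambda_inner, dl)
        res <- solve_photosystem(g, fl, thermo)
        rows[[length(rows) + 1L]] <- data.frame(
          family = "funnel", t_star = names(fluxes)[fi],
          n_branches = n_branches, n_subunit = subunit_size, n_shells = ns,
          lambda = lambda_inner, delta_lambda = dl,
          n_pigments = n_antenna_pigments(g),
          nu_e = res$nu_e, phi_e = res$phi_e,
          nu_e_per_pigment = res$nu_e_per_pigment,
          stringsAsFactors = FALSE)
      }
    }
  }
  sweep_skeleton(do.call(rbind, rows), "funnel",
                 list(thermo = thermo,
                      echo = list(delta_grid = delta_grid, lambda_inner = lambda_inner,
                                  n_branches = n_branches, subunit_size = subunit_size,
                                  shells = shells, thermo = unclass(thermo)),
                      flux_meta = vapply(fluxes, `[[`, "", "meta")))
}

#' Extract the optimum from a sweep table
#'
#' Argmax of an objective over a scanned variable, at grid resolution (never
#' interpolated). For each value of the scanned variable the objective is
#' maximized over all other dimensions first. Exact ties are broken toward
#' the smaller scanned value and flagged. The one-grid-step neighbourhood of
#' the optimum is reported so flat ridges are visible.
#'
#' @param result A `sweep_result`.
#' @param objective `"nu_e"` or `"nu_e_per_pigment"`.
#' @param over `"lambda"` or `"delta_lambda"`.
#' @return List with `argmax`, `value`, `tie` (logical), and `neighbourhood`
#'   (data.frame of scanned value vs best objective around the optimum).
#' @export
find_optimum <- function(result, objective = c("nu_e", "nu_e_per_pigment"),
                         over = c("lambda", "delta_lambda")) {
  objective <- match.arg(objective)
  over <- match.arg(over)
  if (!nrow(result)) stop("empty sweep table", call. = FALSE)
  x <- result[[over]]
  if (all(is.na(x))) stop(sprintf("sweep has no '%s' column values", over), call. = FALSE)
  vals <- sort(unique(x))
  best <- vapply(vals, function(v) max(result[[objective]][x == v]), 0)
  top <- max(best)
  hits <- vals[best == top]
  arg <- min(hits)
  i <- match(arg, vals)
  nb <- seq(max(1L, i - 1L), min(length(vals), i + 1L))
  list(argmax = arg, value = top, tie = length(hits) > 1L,
       neighbourhood = data.frame(value = vals[nb], objective = best[nb]))
}
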