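# Spectral flux containers, blackbody stand-ins, rescaling to the planetary
# surface, habitable orbital distances, and atmospheric transmission.

#' Spectral flux at a surface
#'
#' Container for a spectral flux density sampled on a wavelength grid. This is
#' the light environment seen by the photosystem: either the stellar surface
#' flux `I_s(lambda)` or the flux at the planetary surface `f_p(lambda)`.
#'
#' @param wavelengths Strictly increasing wavelength grid, nm.
#' @param flux Spectral flux density at each grid point, W m^-2 nm^-1
#'   (non-negative).
#' @param meta Free-text provenance (source, stellar temperature, distance).
#' @return Object of class `spectral_flux` with fields `wavelengths`, `flux`
#'   and `meta`.
#' @export
spectral_flux <- function(wavelengths, flux, meta = "") {
  wavelengths <- as.numeric(wavelengths)
  flux <- as.numeric(flux)
  if (length(wavelengths) != length(flux))
    stop("wavelengths and flux must have equal length", call. = FALSE)
  if (length(wavelengths) < 2L)
    stop("a spectral flux needs at least 2 grid points", call. = FALSE)
  if (anyNA(wavelengths) || anyNA(flux))
    stop("NA values in spectral flux", call. = FALSE)
  if (any(diff(wavelengths) <= 0))
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  if (any(flux < 0))
    stop("flux must be non-negative", call. = FALSE)
  structure(list(wavelengths = wavelengths, flux = flux, meta = meta),
            class = "spectral_flux")
}

#' @export
print.spectral_flux <- function(x, ...) {
  cat(sprintf("<spectral_flux> %d points, %.1f-%.1f nm", length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  cat(sprintf(", band power %.4g W m^-2", band_power(x)))
  if (nzchar(x$meta)) cat("\n  ", x$meta)
  cat("\n")
  invisible(x)
}

#' Stellar model
#'
#' Effective temperature and radius of a star. Radii may be given in metres
#' or in solar radii; values below 100 are interpreted as solar radii and
#' converted with 1 R_sun = 6.957e8 m.
#'
#' @param t_star Effective temperature, K (> 0).
#' @param r_star Stellar radius: solar radii if < 100, metres otherwise.
#' @return Object of class `stellar_model` with `t_star` (K) and `r_star` (m).
#' @export
stellar_model <- function(t_star, r_star) {
  if (!is.numeric(t_star) || length(t_star) != 1L || !is.finite(t_star) || t_star <= 0)
    stop("t_star must be a positive temperature in K", call. = FALSE)
  if (!is.numeric(r_star) || length(r_star) != 1L || !is.finite(r_star) || r_star <= 0)
    stop("r_star must be a positive radius", call. = FALSE)
  if (r_star < 100) r_star <- r_star * .R_sun
  structure(list(t_star = t_star, r_star = r_star), class = "stellar_model")
}

#' @export
print.stellar_model <- function(x, ...) {
  cat(sprintf("<stellar_model> T_s = %g K, R_s = %.4g m (%.3f R_sun)\n",
              x$t_star, x$r_star, x$r_star / .R_sun))
  invisible(x)
}

#' Default wavelength grid
#'
#' 200-2500 nm in 4000 points, covering the photosynthetically active region
#' (400-700 nm) and the near-infrared window relevant to anoxygenic
#' phototrophy under cool stars.
#'
#' @return Numeric wavelength grid, nm.
#' @export
default_grid <- function() seq(200, 2500, length.out = 4000)

#' Blackbody surface spectral flux
#'
#' Hemispheric surface flux density pi * B(lambda, T_s) of a blackbody at the
#' stellar effective temperature, in W m^-2 nm^-1. This is the package's
#' stand-in for a synthetic stellar spectrum: it reproduces the broadband
#' shape of the stellar flux while ignoring line and molecular-band structure.
#'
#' @param star A [stellar_model()].
#' @param grid Wavelength grid, nm (all > 0).
#' @return A [spectral_flux()] of the stellar surface flux.
#' @examples
#' sun <- stellar_model(5800, 0.936)
#' I_s <- blackbody_surface_flux(sun)
#' @export
blackbody_surface_flux <- function(star, grid = default_grid()) {
  stopifnot(inherits(star, "stellar_model"))
  if (any(!is.finite(grid)) || any(grid <= 0))
    stop("wavelength grid must be positive and finite", call. = FALSE)
  lam <- grid * 1e-9
  # Planck spectral radiance in W m^-3 sr^-1; pi for hemispheric emission,
  # 1e-9 converts per-metre to per-nanometre.
  B <- 2 * .h * .c^2 / lam^5 / expm1(.hc / (lam * .kB * star$t_star))
  spectral_flux(grid, pi * B * 1e-9,
                meta = sprintf("blackbody surface flux, T_s = %g K", star$t_star))
}

#' Band-integrated power of a spectral flux
#'
#' Trapezoid integral of the flux over its wavelength grid, W m^-2.
#'
#' @param flux A [spectral_flux()].
#' @return Integrated power, W m^-2.
#' @export
band_power <- function(flux) {
  stopifnot(inherits(flux, "spectral_flux"))
  trapz(flux$wavelengths, flux$flux)
}

# trapezoid quadrature on an irregular grid
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Load a spectral flux from a two-column text file
#'
#' Whitespace- or comma-delimited text with columns wavelength (nm) and
#' spectral flux density (W m^-2 nm^-1); lines starting with `#` are comments.
#' Rows are sorted by wavelength on read.
#'
#' @param path Path to the file.
#' @return A [spectral_flux()].
#' @export
load_flux <- function(path) {
  tab <- read_two_column(path, "flux")
  if (any(tab$v2 < 0)) {
    bad <- tab$line[which(tab$v2 < 0)[1]]
    stop(sprintf("negative flux at line %d of '%s'", bad, path), call. = FALSE)
  }
  o <- order(tab$v1)
  if (anyDuplicated(tab$v1)) {
    d <- tab$line[which(duplicated(tab$v1[o]))[1]]
    stop(sprintf("duplicate wavelength at line %d of '%s'", d, path), call. = FALSE)
  }
  spectral_flux(tab$v1[o], tab$v2[o], meta = sprintf("loaded from %s", path))
}

# Shared two-column text reader; returns values plus original line numbers so
# errors can name the offending row.
read_two_column <- function(path, what) {
  if (!file.exists(path)) stop(sprintf("no such file: '%s'", path), call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- which(keep)
  if (length(lines) < 2L)
    stop(sprintf("'%s' has fewer than 2 data rows", path), call. = FALSE)
  parts <- strsplit(trimws(raw[keep]), "[,[:space:]]+")
  v1 <- suppressWarnings(vapply(parts, function(p) as.numeric(p[1]), 0))
  v2 <- suppressWarnings(vapply(parts, function(p) as.numeric(p[2]), 0))
  bad <- which(is.na(v1) | is.na(v2))
  if (length(bad))
    stop(sprintf("cannot parse %s at line %d of '%s'", what, lines[bad[1]], path),
         call. = FALSE)
  list(v1 = v1, v2 = v2, line = lines)
}

#' Write a spectral flux to a two-column text file
#'
#' Emits the header line `# wavelength_nm flux_W_m2_nm` followed by two
#' whitespace-separated columns.
#'
#' @param flux A [spectral_flux()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flux <- function(flux, path) {
  stopifnot(inherits(flux, "spectral_flux"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# wavelength_nm flux_W_m2_nm", con)
  writeLines(sprintf("%.10g %.10g", flux$wavelengths, flux$flux), con)
  invisible(path)
}

#' Smooth and resample a spectral flux
#'
#' Bin-averages the flux onto `n_points` equal-width wavelength bins spanning
#' the input range (smoothing and downsampling in one pass). Band-integrated
#' power is conserved to within about 1 percent for smooth spectra. Applying
#' the operation twice at the same `n_points` is a no-op.
#'
#' @param flux A [spectral_flux()].
#' @param n_points Number of output points (2 <= n_points <= input length).
#' @return A resampled [spectral_flux()].
#' @export
resample_smooth <- function(flux, n_points = 4000) {
  stopifnot(inherits(flux, "spectral_flux"))
  n_in <- length(flux$wavelengths)
  if (!is.numeric(n_points) || length(n_points) != 1L || n_points < 2L || n_points > n_in)
    stop("n_points must be between 2 and the input length", call. = FALSE)
  n_points <- as.integer(n_points)
  # a spectrum already on a uniform grid of the requested size is returned
  # unchanged, making the operation idempotent at fixed n_points
  steps <- diff(flux$wavelengths)
  if (n_in == n_points && max(steps) - min(steps) < 1e-9 * mean(steps))
    return(flux)
  lo <- min(flux$wavelengths); hi <- max(flux$wavelengths)
  edges <- seq(lo, hi, length.out = n_points + 1L)
  centres <- (edges[-1] + edges[-(n_points + 1L)]) / 2
  # average the (linearly interpolated) flux over each bin on a fine grid so
  # that repeated application at the same n_points is stable
  idx <- findInterval(flux$wavelengths, edges, rightmost.closed = TRUE)
  mean_flux <- vapply(seq_len(n_points), function(b) {
    inside <- flux$wavelengths[idx == b]
    xs <- sort(unique(c(edges[b], inside, edges[b + 1L])))
    ys <- stats::approx(flux$wavelengths, flux$flux, xout = xs, rule = 2)$y
    trapz(xs, ys) / (edges[b + 1L] - edges[b])
  }, 0)
  spectral_flux(centres, mean_flux,
                meta = paste0(flux$meta, sprintf(" [resampled to %d points]", n_points)))
}

#' Scale a stellar surface flux to the planetary surface
#'
#' Applies the radiative-equilibrium dilution factor `(R_s / a_sp)^2` that
#' relates the stellar surface spectral flux density to the flux density
#' arriving at an orbiting planet.
#'
#' @param i_s Stellar surface flux, a [spectral_flux()].
#' @param star A [stellar_model()].
#' @param a_sp Orbital distance in metres (>= the stellar radius).
#' @return A [spectral_flux()] of the flux at the planet.
#' @export
surface_flux <- function(i_s, star, a_sp) {
  stopifnot(inherits(i_s, "spectral_flux"), inherits(star, "stellar_model"))
  if (!is.numeric(a_sp) || length(a_sp) != 1L || !is.finite(a_sp) || a_sp < star$r_star)
    stop("a_sp must be a distance in metres no smaller than the stellar radius",
         call. = FALSE)
  scale <- (star$r_star / a_sp)^2
  spectral_flux(i_s$wavelengths, i_s$flux * scale,
                meta = sprintf("%s, at a_sp = %.4g m (%.3f au)", i_s$meta,
                               a_sp, a_sp / .au))
}

#' Habitable orbital distances
#'
#' Orbital distances at which the equilibrium planetary surface temperature
#' equals 373 K (`a_min`, "steam line") and 273 K (`a_max`, "ice line"), from
#' `a_sp = R_s/2 (T_s/T_p)^2`, plus their midpoint `a_mid`. No greenhouse or
#' albedo correction is applied, so Earth sits slightly outside the band this
#' yields for a Sun-like star.
#'
#' @param star A [stellar_model()].
#' @return Object of class `habitable_distances` with `a_min`, `a_mid`,
#'   `a_max` in astronomical units and the same values in metres under
#'   `a_min_m`, `a_mid_m`, `a_max_m`.
#' @examples
#' habitable_distances(stellar_model(5800, 0.936))  # 0.526 / 0.754 / 0.982 au
#' @export
habitable_distances <- function(star) {
  stopifnot(inherits(star, "stellar_model"))
  a_at <- function(t_p) star$r_star / 2 * (star$t_star / t_p)^2
  a_min_m <- a_at(373); a_max_m <- a_at(273)
  structure(list(a_min = a_min_m / .au, a_mid = (a_min_m + a_max_m) / 2 / .au,
                 a_max = a_max_m / .au,
                 a_min_m = a_min_m, a_mid_m = (a_min_m + a_max_m) / 2,
                 a_max_m = a_max_m),
            class = "habitable_distances")
}

#' @export
print.habitable_distances <- function(x, ...) {
  cat(sprintf("<habitable_distances> a_min = %.3f au, a_mid = %.3f au, a_max = %.3f au\n",
              x$a_min, x$a_mid, x$a_max))
  invisible(x)
}

#' Blackbody flux at the mid habitable distance
#'
#' Convenience wrapper: blackbody surface flux diluted to the midpoint of the
#' habitable zone of `star`. This is the package's default light environment
#' for antenna experiments.
#'
#' @param star A [stellar_model()].
#' @param grid Wavelength grid, nm.
#' @return A [spectral_flux()].
#' @export
planet_flux <- function(star, grid = default_grid()) {
  hz <- habitable_distances(star)
  surface_flux(blackbody_surface_flux(star, grid), star, hz$a_mid_m)
}

#' Load an atmospheric transmission spectrum
#'
#' Two-column text (wavelength nm, transmittance in `[0, 1]`), `#` comments.
#'
#' @param path Path to the file.
#' @return A data.frame with columns `wavelengths` and `transmission`, sorted
#'   by wavelength, of class `transmission_spectrum`.
#' @export
load_transmission <- function(path) {
  tab <- read_two_column(path, "transmission")
  if (any(tab$v2 < 0 | tab$v2 > 1)) {
    bad <- tab$line[which(tab$v2 < 0 | tab$v2 > 1)[1]]
    stop(sprintf("transmission outside [0,1] at line %d of '%s'", bad, path),
         call. = FALSE)
  }
  o <- order(tab$v1)
  structure(data.frame(wavelengths = tab$v1[o], transmission = tab$v2[o]),
            class = c("transmission_spectrum", "data.frame"))
}

#' Attenuate a flux by an atmospheric transmission spectrum
#'
#' Multiplies the flux pointwise by a transmission function. The transmission
#' is interpolated linearly onto the flux grid; wavelengths outside the
#' transmission grid are treated as opaque (transmission 0).
#'
#' @param f_p A [spectral_flux()].
#' @param tx A `transmission_spectrum`, or any data.frame/matrix whose first
#'   two columns are wavelength (nm) and transmittance in `[0, 1]`.
#' @return The attenuated [spectral_flux()].
#' @export
apply_transmission <- function(f_p, tx) {
  stopifnot(inherits(f_p, "spectral_flux"))
  tx <- as.data.frame(tx)
  wl <- as.numeric(tx[[1]]); tr <- as.numeric(tx[[2]])
  if (any(!is.finite(tr)) || any(tr < 0 | tr > 1))
    stop("transmission values must lie in [0, 1]", call. = FALSE)
  t_on_grid <- stats::approx(wl, tr, xout = f_p$wavelengths, rule = 1)$y
  t_on_grid[is.na(t_on_grid)] <- 0
  spectral_flux(f_p$wavelengths, f_p$flux * t_on_grid,
                meta = paste0(f_p$meta, " [atmosphere-attenuated]"))
}
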