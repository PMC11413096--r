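# Configuration schema, rate parsing, and result serialization. One config
# file drives spectra, photosystem construction, solving and sweeps; every
# default is resolved at load time so the echoed config fully reproduces a
# run.

config_defaults <- function() {
  list(
    star = list(t_star = 5800, r_star = 0.936, distance = "mid"),
    flux = list(source = "blackbody", path = ""),
    thermo = list(temperature = 300, k_hop = "10 ps", k_diss = "1 ns",
                  k_trap = "5 ps", k_out = "10 ms", overlap = "raw"),
    rc = list(n_pigments = 10, lambda_peak = 680, width = 10,
              sigma_peak = 1e-20),
    topology = list(kind = "illustrative", n_pigments = 100,
                    lambda_peak = 665, n_branches = 6, n_shells = 5,
                    n_pigments_per_subunit = 100, lambda_inner = 665,
                    delta_lambda = 0, width = 10, sigma_peak = 1e-20),
    sweep = NULL,
    seed = NULL
  )
}

sweep_defaults <- function() {
  list(family = "illustrative", lambda_min = 620, lambda_max = 700,
       lambda_step = 1, delta_min = 0, delta_max = 30, delta_step = 1,
       size_min = 1, size_max = 1000, size_points = 12, shells_max = 10)
}

#' Parse a rate given as a frequency or a timescale
#'
#' Accepts a plain number (s^-1) or a string timescale with suffix `ps`,
#' `ns`, `us`, `ms` or `s` (e.g. `"10 ps"` means the rate `1 / 10 ps`).
#'
#' @param x Number or string.
#' @return Rate, s^-1.
#' @export
parse_rate <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  m <- regmatches(x, regexec("^\\s*([0-9.eE+-]+)\\s*(ps|ns|us|ms|s)\\s*$", x))[[1]]
  if (length(m) != 3L)
    stop(sprintf("cannot parse rate '%s' (number in s^-1 or timescale like '10 ps')", x),
         call. = FALSE)
  mult <- c(ps = 1e-12, ns = 1e-9, us = 1e-6, ms = 1e-3, s = 1)[[m[3]]]
  1 / (as.numeric(m[2]) * mult)
}

merge_section <- function(user, defaults, section) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key(s) in '%s': %s", section,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  utils::modifyList(defaults, user)
}

#' Load and validate a run configuration
#'
#' Reads a YAML (or JSON) configuration, rejects unknown keys section by
#' section, resolves every default, and parses timescale-style rates into
#' s^-1. The returned object is fully explicit: writing it back out with
#' [write_config()] and re-loading gives an identical configuration.
#'
#' @param path Path to a YAML/JSON config file.
#' @return Object of class `run_config` (a fully resolved named list).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: '%s'", path), call. = FALSE)
  user <- yaml::read_yaml(path)
  resolve_config(user)
}

#' Resolve a configuration list against the schema
#'
#' @param user A (possibly partial) named list of config sections.
#' @return A `run_config`.
#' @export
resolve_config <- function(user) {
  if (is.null(user)) user <- list()
  def <- config_defaults()
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  cfg <- list()
  for (s in c("star", "flux", "thermo", "rc", "topology"))
    cfg[[s]] <- merge_section(user[[s]], def[[s]], s)
  cfg$sweep <- if (is.null(user$sweep)) NULL else
    merge_section(user$sweep, sweep_defaults(), "sweep")
  cfg$seed <- user$seed
  for (r in c("k_hop", "k_diss", "k_trap", "k_out"))
    cfg$thermo[[r]] <- parse_rate(cfg$thermo[[r]])
  if (!cfg$thermo$overlap %in% c("raw", "normalized"))
    stop("thermo$overlap must be 'raw' or 'normalized'", call. = FALSE)
  if (!cfg$topology$kind %in% c("illustrative", "branched"))
    stop("topology$kind must be 'illustrative' or 'branched'", call. = FALSE)
  structure(cfg, class = "run_config")
}

#' Write a resolved configuration
#'
#' @param cfg A `run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Build model objects from a configuration
#'
#' Helpers that turn config sections into the package's native objects.
#'
#' @param cfg A `run_config`.
#' @return `config_star()` a [stellar_model()]; `config_thermo()` a
#'   [thermo_params()]; `config_rc()` a [reaction_centre()];
#'   `config_graph()` a `photosystem_graph`; `config_flux()` a
#'   [spectral_flux()] at the configured orbital distance.
#' @name config_build
NULL

#' @rdname config_build
#' @export
config_star <- function(cfg) stellar_model(cfg$star$t_star, cfg$star$r_star)

#' @rdname config_build
#' @export
config_thermo <- function(cfg) {
  th <- cfg$thermo
  thermo_params(th$temperature, th$k_hop, th$k_diss, th$k_trap, th$k_out,
                overlap = th$overlap)
}

#' @rdname config_build
#' @export
config_rc <- function(cfg) {
  rc <- cfg$rc
  reaction_centre(rc$n_pigments, rc$lambda_peak, rc$width, rc$sigma_peak)
}

#' @rdname config_build
#' @export
config_graph <- function(cfg) {
  tp <- cfg$topology
  rc <- config_rc(cfg)
  if (identical(tp$kind, "illustrative")) {
    suppressWarnings(build_illustrative(tp$n_pigments, tp$lambda_peak, rc = rc,
                                        width = tp$width,
                                        sigma_peak = tp$sigma_peak))
  } else {
    g <- build_branched(tp$n_branches, tp$n_shells, tp$n_pigments_per_subunit,
                        tp$lambda_inner, rc = rc, width = tp$width,
                        sigma_peak = tp$sigma_peak)
    assign_funnel(g, tp$lambda_inner, tp$delta_lambda)
  }
}

#' @rdname config_build
#' @export
config_flux <- function(cfg) {
  star <- config_star(cfg)
  if (identical(cfg$flux$source, "file")) {
    if (!nzchar(cfg$flux$path)) stop("flux source 'file' needs flux$path", call. = FALSE)
    fl <- load_flux(cfg$flux$path)
  } else {
    fl <- blackbody_surface_flux(star)
    d <- cfg$star$distance
    a_m <- if (identical(d, "mid")) habitable_distances(star)$a_mid_m
           else as.numeric(d) * .au
    fl <- surface_flux(fl, star, a_m)
  }
  fl
}

#' Serialize a result to JSON or CSV
#'
#' Bit-stable writer: JSON with sorted keys and full precision, or CSV with a
#' fixed, documented column order (`family, t_star, n_branches, n_subunit,
#' n_shells, lambda, delta_lambda, n_pigments, nu_e, phi_e,
#' nu_e_per_pigment, half_max, per_pigment_ok` for sweep tables). Two
#' identical runs produce byte-identical files. A provenance block (package
#' version and parameters) is embedded in JSON output and as `#` comment
#' lines in CSV output.
#'
#' @param x A `steady_state_result`, `sweep_result`, `habitable_distances`
#'   or plain list.
#' @param path Output path.
#' @param format `"json"` or `"csv"` (CSV only for tabular input).
#' @return `path`, invisibly.
#' @export
write_result <- function(x, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!is.data.frame(x)) stop("csv output needs a tabular result", call. = FALSE)
    con <- file(path, "w")
    on.exit(close(con))
    pr <- attr(x, "provenance")
    if (!is.null(pr)) {
      writeLines(sprintf("# photoantenna %s sweep family=%s",
                         pr$package_version, pr$family), con)
      writeLines(paste0("# flux: ", paste(pr$flux_meta, collapse = "; ")), con)
    }
    cols <- intersect(c("family", "t_star", "n_branches", "n_subunit",
                        "n_shells", "lambda", "delta_lambda", "n_pigments",
                        "nu_e", "phi_e", "nu_e_per_pigment", "half_max",
                        "per_pigment_ok"), names(x))
    utils::write.table(format(as.data.frame(x)[, cols], digits = 15, trim = TRUE,
                              scientific = NA),
                       con, sep = ",", row.names = FALSE, quote = FALSE)
  } else {
    obj <- if (is.data.frame(x)) as.data.frame(x) else
      x[order(names(x))][!vapply(x[order(names(x))], is.function, TRUE)]
    payload <- list(result = obj,
                    provenance = list(
                      package = "photoantenna",
                      version = as.character(utils::packageVersion("photoantenna"))))
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
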