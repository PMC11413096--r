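# Photosystem network construction: reaction centre, light-harvesting
# sub-units, adjacency, and the three topology families.

#' Reaction centre definition
#'
#' The reaction centre (RC) is a pool of `n_pigments` equivalent pigment
#' states feeding a single irreversible trap. The default peak wavelength of
#' 680 nm is set by the redox requirement of water oxidation in oxygenic
#' photosystems.
#'
#' @param n_pigments Pigment count N_r (default 10).
#' @param lambda_peak RC absorption peak, nm (default 680).
#' @param width Gaussian width, nm (default 10).
#' @param sigma_peak Peak cross-section, m^2 (default 1e-20).
#' @return Object of class `reaction_centre`.
#' @export
reaction_centre <- function(n_pigments = 10, lambda_peak = 680, width = 10,
                            sigma_peak = 1e-20) {
  if (n_pigments < 1) stop("the RC needs at least one pigment", call. = FALSE)
  structure(list(n_pigments = as.integer(n_pigments),
                 profile = absorption_profile(lambda_peak, width, sigma_peak)),
            class = "reaction_centre")
}

# internal constructor + validation shared by the builders
new_photosystem_graph <- function(rc, subunits, edges) {
  stopifnot(inherits(rc, "reaction_centre"), is.data.frame(subunits))
  need <- c("id", "n_pigments", "lambda_peak", "width", "sigma_peak",
            "shell", "branch")
  if (!all(need %in% names(subunits)))
    stop("subunit table missing columns: ",
         paste(setdiff(need, names(subunits)), collapse = ", "), call. = FALSE)
  if (anyDuplicated(subunits$id)) stop("duplicate sub-unit ids", call. = FALSE)
  if (any(subunits$n_pigments < 1)) stop("sub-units need >= 1 pigment", call. = FALSE)
  if (any(subunits$lambda_peak <= 0))
    stop("sub-unit peak wavelengths must be positive", call. = FALSE)
  if (any(subunits$n_pigments > 100))
    warning("sub-units with more than ~100 pigments equilibrate diffusively; ",
            "consider a block of smaller sub-units")
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("edges must be a 2-column matrix", call. = FALSE)
  nodes <- c(subunits$id, "RC")
  if (!all(edges %in% nodes)) stop("edge endpoints must be sub-unit ids or 'RC'",
                                   call. = FALSE)
  if (any(edges[, 1] == edges[, 2])) stop("self-edges are not allowed", call. = FALSE)
  # connectivity from the RC over the undirected edge set
  adj <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  seen <- "RC"; frontier <- "RC"
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt); frontier <- nxt
  }
  if (!setequal(seen, nodes)) stop("graph is not connected", call. = FALSE)
  structure(list(rc = rc, subunits = subunits, edges = edges),
            class = "photosystem_graph")
}

#' @export
print.photosystem_graph <- function(x, ...) {
  cat(sprintf("<photosystem_graph> %d sub-unit(s), %d edge(s), %d antenna pigments\n",
              nrow(x$subunits), nrow(x$edges), n_antenna_pigments(x)))
  cat(sprintf("  RC: N_r = %d, peak %g nm\n", x$rc$n_pigments,
              x$rc$profile$lambda_peak))
  invisible(x)
}

#' Total number of antenna pigments
#'
#' Sum of pigment counts over the light-harvesting sub-units. The RC is not
#' part of the antenna and is excluded.
#'
#' @param graph A `photosystem_graph`.
#' @return Integer pigment count.
#' @export
n_antenna_pigments <- function(graph) {
  stopifnot(inherits(graph, "photosystem_graph"))
  sum(graph$subunits$n_pigments)
}

#' Single-LHC illustrative photosystem
#'
#' The simplest antenna: one light-harvesting sub-unit of `n_pigments`
#' equivalent pigments coupled directly to the RC. Used to illustrate the
#' diminishing returns of growing a single pigment pool; `n_pigments` may
#' exceed the ~100-pigment equilibration guideline (a warning is issued).
#'
#' @param n_pigments Antenna pigment count N_p (>= 1).
#' @param lambda_peak Antenna absorption peak, nm.
#' @param rc A [reaction_centre()].
#' @param width,sigma_peak Antenna profile parameters.
#' @return A `photosystem_graph`.
#' @export
build_illustrative <- function(n_pigments, lambda_peak, rc = reaction_centre(),
                               width = 10, sigma_peak = 1e-20) {
  if (n_pigments < 1) stop("n_pigments must be >= 1", call. = FALSE)
  subunits <- data.frame(id = "s1", n_pigments = as.integer(n_pigments),
                         lambda_peak = lambda_peak, width = width,
                         sigma_peak = sigma_peak, shell = 0L, branch = 1L,
                         stringsAsFactors = FALSE)
  new_photosystem_graph(rc, subunits, matrix(c("s1", "RC"), 1))
}

#' Branched modular photosystem
#'
#' `n_branches` identical unbranched chains of LHC sub-units radiate from the
#' RC: within a branch, shell k couples to shells k-1 and k+1, and each
#' branch's innermost sub-unit (shell 0) couples to the RC. Branches are not
#' interconnected; a lattice would let the exciton wander and dilute delivery
#' to the RC. Total antenna size is `n_branches * n_shells * n_pigments`.
#'
#' @param n_branches Number of branches N_b (1 = linear "1D", 6 = planar
#'   "2D", 12 = "3D" close packing).
#' @param n_shells Sub-units per branch.
#' @param n_pigments_per_subunit Pigments per sub-unit (10 = "small",
#'   100 = "large").
#' @param lambda_by_shell Peak wavelength per shell, nm; length `n_shells`
#'   (recycled if scalar).
#' @param rc A [reaction_centre()].
#' @param width,sigma_peak Sub-unit profile parameters.
#' @return A `photosystem_graph`.
#' @examples
#' g <- build_branched(6, 5, 100, 665)   # 30 sub-units, 3000 antenna pigments
#' @export
build_branched <- function(n_branches, n_shells, n_pigments_per_subunit,
                           lambda_by_shell, rc = reaction_centre(),
                           width = 10, sigma_peak = 1e-20) {
  if (n_branches < 1 || n_shells < 1)
    stop("n_branches and n_shells must be >= 1", call. = FALSE)
  if (length(lambda_by_shell) == 1L)
    lambda_by_shell <- rep(lambda_by_shell, n_shells)
  if (length(lambda_by_shell) != n_shells)
    stop(sprintf("lambda_by_shell has length %d but n_shells = %d",
                 length(lambda_by_shell), n_shells), call. = FALSE)
  shells <- rep(seq_len(n_shells) - 1L, times = n_branches)
  branches <- rep(seq_len(n_branches), each = n_shells)
  ids <- sprintf("b%ds%d", branches, shells + 1L)
  subunits <- data.frame(id = ids,
                         n_pigments = as.integer(n_pigments_per_subunit),
                         lambda_peak = lambda_by_shell[shells + 1L],
                         width = width, sigma_peak = sigma_peak,
                         shell = shells, branch = branches,
                         stringsAsFactors = FALSE)
  inner <- ifelse(shells == 0L, "RC", sprintf("b%ds%d", branches, shells))
  new_photosystem_graph(rc, subunits, cbind(ids, inner))
}

#' Assign an enthalpy-funnel wavelength ladder
#'
#' Overwrites the sub-unit peak wavelengths with a progressive blue-shift
#' moving outward from the RC: shell k (0-based, shell 0 adjacent to the RC)
#' receives `lambda_inner - k * delta_lambda`. Inward transfer then releases
#' enthalpy at every hop, compensating the entropy cost of concentrating the
#' excitation. All other fields are untouched; `delta_lambda = 0` leaves a
#' modular (iso-energetic) antenna.
#'
#' @param graph A `photosystem_graph`.
#' @param lambda_inner Peak wavelength of shell 0, nm.
#' @param delta_lambda Blue-shift per shell, nm (>= 0).
#' @return The re-labelled `photosystem_graph`.
#' @export
assign_funnel <- function(graph, lambda_inner, delta_lambda) {
  stopifnot(inherits(graph, "photosystem_graph"))
  if (delta_lambda < 0) stop("delta_lambda must be >= 0", call. = FALSE)
  peaks <- lambda_inner - graph$subunits$shell * delta_lambda
  if (any(peaks <= 0))
    stop("funnel assignment drives a peak wavelength non-positive", call. = FALSE)
  graph$subunits$lambda_peak <- peaks
  graph
}

#' Combined antenna absorption spectrum
#'
#' Pigment-count-weighted sum of the sub-unit Gaussian cross-sections on a
#' wavelength grid, normalized to unit peak. This is the spectrum an
#' absorbance measurement of the whole antenna (excluding the RC) would see.
#'
#' @param graph A `photosystem_graph`.
#' @param grid Wavelength grid, nm.
#' @return A data.frame with columns `wavelengths` (nm) and `absorption`
#'   (arbitrary units, peak 1).
#' @export
antenna_absorption_spectrum <- function(graph, grid = seq(400, 750, by = 0.5)) {
  stopifnot(inherits(graph, "photosystem_graph"))
  su <- graph$subunits
  total <- rowSums(vapply(seq_len(nrow(su)), function(i) {
    p <- absorption_profile(su$lambda_peak[i], su$width[i], su$sigma_peak[i])
    su$n_pigments[i] * absorption_value(p, grid)
  }, numeric(length(grid))))
  data.frame(wavelengths = grid, absorption = total / max(total))
}

# sub-unit descriptor (n_pigments + profile) for rate construction
subunit_descriptor <- function(graph, id) {
  if (identical(id, "RC"))
    return(list(n_pigments = graph$rc$n_pigments, profile = graph$rc$profile))
  i <- match(id, graph$subunits$id)
  if (is.na(i)) stop(sprintf("no sub-unit '%s'", id), call. = FALSE)
  su <- graph$subunits[i, ]
  list(n_pigments = su$n_pigments,
       profile = absorption_profile(su$lambda_peak, su$width, su$sigma_peak))
}

#' Dump a photosystem graph as a plain list
#'
#' Nodes and edges in a JSON-friendly structure, for inspection or
#' serialization.
#'
#' @param graph A `photosystem_graph`.
#' @return A list with `rc`, `subunits` and `edges` entries.
#' @export
graph_dump <- function(graph) {
  stopifnot(inherits(graph, "photosystem_graph"))
  list(rc = list(n_pigments = graph$rc$n_pigments,
                 lambda_peak = graph$rc$profile$lambda_peak,
                 width = graph$rc$profile$width),
       subunits = graph$subunits,
       edges = data.frame(from = graph$edges[, 1], to = graph$edges[, 2],
                          stringsAsFactors = FALSE))
}
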