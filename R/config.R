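#' Analysis configuration
#'
#' Bundles the numeric knobs shared by the geometric stages. Defaults follow
#' common structural-bioinformatics practice: a 1.4 Angstrom water probe for
#' accessibility, 960 points on the deterministic golden-spiral lattice, and
#' a 0.8 Angstrom grid for tunnel search.
#'
#' @param probe_radius solvent probe radius in Angstrom (> 0).
#' @param sphere_points number of lattice points per atom for the
#'   Shrake-Rupley surface calculation (>= 100).
#' @param grid_spacing tunnel-search grid spacing in Angstrom, in (0.1, 2].
#' @param probe_min minimum clearance in Angstrom for a tunnel grid node to
#'   be considered open.
#' @param excluded_ranges list of `c(chain, start, end)` triples naming
#'   residue ranges excluded from reported results (e.g. disordered loops).
#' @param max_asa which max-ASA reference set to use ("tien" or "miller").
#' @param seed integer seed recorded in reports.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(probe_radius = 1.4, sphere_points = 960,
                            grid_spacing = 0.8, probe_min = 0.8,
                            excluded_ranges = list(),
                            max_asa = c("tien", "miller"), seed = 1L) {
  max_asa <- match.arg(max_asa)
  stopifnot(is.numeric(probe_radius), length(probe_radius) == 1, probe_radius > 0)
  stopifnot(sphere_points >= 100)
  if (!(grid_spacing > 0.1 && grid_spacing <= 2.0))
    stop("grid_spacing must be in (0.1, 2.0]")
  for (rng in excluded_ranges) {
    if (length(rng) != 3) stop("excluded range must be (chain, start, end)")
    if (as.integer(rng[2]) > as.integer(rng[3]))
      stop("excluded range start must be <= end: ", paste(rng, collapse = "-"))
  }
  structure(list(probe_radius = probe_radius,
                 sphere_points = as.integer(sphere_points),
                 grid_spacing = grid_spacing,
                 probe_min = probe_min,
                 excluded_ranges = excluded_ranges,
                 max_asa = max_asa,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

## TRUE for residues falling inside one of the excluded ranges
.in_excluded_range <- function(chain, resno, config) {
  if (length(config$excluded_ranges) == 0) return(rep(FALSE, length(resno)))
  out <- rep(FALSE, length(resno))
  for (rng in config$excluded_ranges) {
    out <- out | (chain == rng[1] &
                    resno >= as.integer(rng[2]) & resno <= as.integer(rng[3]))
  }
  out
}
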