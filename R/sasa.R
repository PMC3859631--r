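## Solvent-accessible surface area (Shrake-Rupley) on a deterministic
## golden-spiral sphere lattice, relative accessibility and buriedness.

#' Deterministic quasi-uniform points on the unit sphere
#'
#' Golden-spiral (Fibonacci) lattice; fully deterministic so surface areas
#' are exactly reproducible run-to-run.
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-atom and per-residue solvent-accessible surface area
#'
#' Shrake-Rupley: each atom is expanded by the probe radius and sampled with
#' a deterministic sphere lattice; a sample point is accessible if it lies
#' outside every other atom's expanded sphere. Heavy atoms only.
#'
#' @param structure a [clc_structure()].
#' @param config an [analysis_config()]; uses `probe_radius` and
#'   `sphere_points`.
#' @return object of class `sasa_result`: list with `per_atom` (numeric,
#'   one value per atom row), `per_residue` (named by residue key),
#'   `probe_radius`, `sphere_points`.
#' @export
shrake_rupley <- function(structure, config = analysis_config()) {
  a <- structure$atoms
  n <- nrow(a)
  if (n == 0) stop("empty structure")
  probe <- config$probe_radius
  pts <- golden_spiral_points(config$sphere_points)
  xyz <- coords(structure)
  rad <- a$vdw + probe
  per_atom <- numeric(n)
  # neighbour candidates via squared-distance threshold per atom pair
  for (i in seq_len(n)) {
    ri <- rad[i]
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 < (ri + rad)^2 & seq_len(n) != i)
    if (length(nb) == 0) {
      per_atom[i] <- 4 * pi * ri^2
      next
    }
    p <- pts * ri
    p[, 1] <- p[, 1] + xyz[i, 1]
    p[, 2] <- p[, 2] + xyz[i, 2]
    p[, 3] <- p[, 3] + xyz[i, 3]
    free <- rep(TRUE, nrow(p))
    for (j in nb) {
      if (!any(free)) break
      dd <- (p[free, 1] - xyz[j, 1])^2 + (p[free, 2] - xyz[j, 2])^2 +
        (p[free, 3] - xyz[j, 3])^2
      free[free] <- dd >= rad[j]^2
    }
    per_atom[i] <- mean(free) * 4 * pi * ri^2
  }
  keys <- .atom_keys(a)
  per_residue <- tapply(per_atom, factor(keys, levels = unique(keys)), sum)
  structure(list(per_atom = per_atom,
                 per_residue = stats::setNames(as.numeric(per_residue),
                                               names(per_residue)),
                 probe_radius = probe,
                 sphere_points = config$sphere_points),
            class = "sasa_result")
}

#' Relative accessibility and buriedness per residue
#'
#' RSA is the residue surface area as a percentage of a maximal-exposure
#' reference (Gly-X-Gly theoretical values by default). A residue is flagged
#' buried when RSA is strictly below 15 percent, the conventional
#' buried/exposed cut.
#'
#' @param sasa a `sasa_result` from [shrake_rupley()].
#' @param structure the structure the areas were computed on.
#' @param max_asa reference set, "tien" (default) or "miller".
#' @param buried_below RSA threshold in percent (strict less-than).
#' @return data.frame with one row per residue: `key`, `chain`, `resno`,
#'   `resid`, `sasa`, `max_asa_ref`, `rsa` (percent; NA for residues absent
#'   from the reference table), `buried`, `standard`.
#' @export
relative_sasa <- function(sasa, structure, max_asa = c("tien", "miller"),
                          buried_below = 15) {
  max_asa <- match.arg(max_asa)
  ri <- residue_index(structure)
  props <- aa_properties(max_asa)
  ref <- props[ri$resid, "max_asa"]
  s <- unname(sasa$per_residue[ri$key])
  rsa <- 100 * s / ref
  # compare on 9 decimals so a value sitting exactly on the threshold is not
  # pushed across it by binary representation error
  out <- data.frame(key = ri$key, chain = ri$chain, resno = ri$resno,
                    resid = ri$resid, sasa = s, max_asa_ref = ref, rsa = rsa,
                    buried = !is.na(rsa) & round(rsa, 9) < buried_below,
                    standard = ri$resid %in% rownames(props),
                    stringsAsFactors = FALSE)
  out$buried[!out$standard] <- NA
  out
}

#' Surface area buried on complexation, per residue of one chain
#'
#' For each residue of `chain_id`: SASA of the isolated chain minus SASA of
#' the same residue within the full assembly. Positive values mark residues
#' occluded by the partner chain(s).
#'
#' @param dimer multi-chain [clc_structure()].
#' @param chain_id chain to evaluate.
#' @param config an [analysis_config()].
#' @return named numeric vector (residue keys of `chain_id`).
#' @export
delta_sasa_on_complexation <- function(dimer, chain_id,
                                       config = analysis_config()) {
  if (length(chain_ids(dimer)) < 2)
    stop("assembly must contain at least 2 chains")
  if (!chain_id %in% chain_ids(dimer)) stop("unknown chain: ", chain_id)
  alone <- get_chain(dimer, chain_id)
  s_alone <- shrake_rupley(alone, config)$per_residue
  s_dimer <- shrake_rupley(dimer, config)$per_residue
  keys <- names(s_alone)
  delta <- s_alone - s_dimer[keys]
  pmax(delta, 0)
}
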