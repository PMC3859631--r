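## Deterministic generators for benchmark fixtures: analytic-SASA sphere
## sets, helix-bundle dimers with a known contact interface, barrel
## structures with a cylindrical pore of known radius, contact-geometry
## micro-fixtures, and synthetic cohort tables with exact bookkeeping.

## assemble an atom data.frame with radii from the element table
.atoms_df <- function(x, y, z, elety, elesy, resid, chain, resno, o = 1) {
  radii <- element_radii()
  data.frame(eleno = seq_along(x), elety = elety, elesy = elesy,
             resid = resid, chain = chain, resno = resno, insert = "",
             x = x, y = y, z = z, o = o, vdw = unname(radii[elesy]),
             stringsAsFactors = FALSE)
}

#' Sphere-set structure with analytic surface areas
#'
#' Carbon pseudo-atoms at given positions. For one or two spheres the
#' companion table carries the closed-form solvent-accessible area
#' (isolated sphere, or two-sphere spherical-cap correction).
#'
#' @param positions n x 3 matrix of centers (1 <= n <= 100, no duplicated
#'   centers).
#' @param probe_radius probe used for the analytic values (default 1.4).
#' @return list with `structure` ([clc_structure()]) and `analytic`
#'   (data.frame atom/sasa; NA when no closed form applies).
#' @export
make_spheres <- function(positions, probe_radius = 1.4) {
  positions <- matrix(positions, ncol = 3)
  n <- nrow(positions)
  if (n < 1 || n > 100) stop("need between 1 and 100 spheres")
  if (anyDuplicated(apply(positions, 1, paste, collapse = ",")))
    stop("overlapping identical centers")
  atoms <- .atoms_df(positions[, 1], positions[, 2], positions[, 3],
                     elety = "CA", elesy = "C", resid = "GLY",
                     chain = "A", resno = seq_len(n))
  st <- clc_structure(atoms, title = "sphere fixture")
  R <- 1.7 + probe_radius
  analytic <- rep(NA_real_, n)
  if (n == 1) analytic <- 4 * pi * R^2
  if (n == 2) {
    d <- sqrt(sum((positions[1, ] - positions[2, ])^2))
    if (d >= 2 * R) analytic <- rep(4 * pi * R^2, 2)
    else {
      h <- R - d / 2                       # buried cap height, equal radii
      analytic <- rep(4 * pi * R^2 - 2 * pi * R * h, 2)
    }
  }
  list(structure = st,
       analytic = data.frame(atom = seq_len(n), sasa = analytic))
}

## idealized poly-Ala helix along z: N, CA, C, O backbone + CB pointing
## radially outward; rise 1.5 A and 100 degrees per residue
.poly_ala_helix <- function(n_res, chain, origin = c(0, 0, 0), r_ca = 2.3) {
  rows <- list()
  for (i in seq_len(n_res)) {
    th <- (i - 1) * 100 * pi / 180
    z0 <- (i - 1) * 1.5
    ca <- c(r_ca * cos(th), r_ca * sin(th), z0)
    nn <- c(r_ca * cos(th - 0.45), r_ca * sin(th - 0.45), z0 - 0.9)
    cc <- c(r_ca * cos(th + 0.45), r_ca * sin(th + 0.45), z0 + 0.9)
    oo <- cc + c(0.6 * cos(th + 0.45), 0.6 * sin(th + 0.45), 0.9)
    cb <- c((r_ca + 1.5) * cos(th), (r_ca + 1.5) * sin(th), z0)
    xyz <- rbind(nn, ca, cc, oo, cb)
    rows[[i]] <- .atoms_df(xyz[, 1] + origin[1], xyz[, 2] + origin[2],
                           xyz[, 3] + origin[3],
                           elety = c("N", "CA", "C", "O", "CB"),
                           elesy = c("N", "C", "C", "O", "C"),
                           resid = "ALA", chain = chain, resno = i)
  }
  out <- do.call(rbind, rows)
  out$eleno <- seq_len(nrow(out))
  out
}

#' Helix-bundle dimer with known contact interface
#'
#' Two idealized poly-Ala helices packed side by side with a specified gap
#' (closest surface approach between side-chain tips). Ground truth is the
#' set of residues with any heavy atom within `interface_cutoff` of the
#' other chain, determined by direct pairwise search during generation.
#'
#' @param n_res residues per helix (>= 10).
#' @param gap Angstrom between facing side-chain tips (>= 0).
#' @param interface_cutoff Angstrom for the ground-truth contact rule
#'   (default 4.5).
#' @return list with `structure` (two-chain [clc_structure()]) and
#'   `interface` (list of residue-key vectors per chain), plus the
#'   parameters used.
#' @export
make_bundle_dimer <- function(n_res = 20, gap = 4, interface_cutoff = 4.5) {
  if (n_res < 10) stop("helix length must be >= 10 residues")
  if (gap < 0) stop("gap must be >= 0")
  d_axis <- gap + 2 * (2.3 + 1.5)          # tip-to-tip separation = gap
  a <- .poly_ala_helix(n_res, "A")
  # rotate chain B by 180 degrees about z so its residue-1 tip faces A
  b <- .poly_ala_helix(n_res, "B")
  b$x <- -b$x; b$y <- -b$y
  b$x <- b$x + d_axis
  atoms <- rbind(a, b)
  atoms$eleno <- seq_len(nrow(atoms))
  st <- clc_structure(atoms, title = "bundle dimer fixture")
  # brute-force ground truth, independent double loop
  truth <- list(A = character(0), B = character(0))
  for (ch in c("A", "B")) {
    own <- atoms[atoms$chain == ch, ]
    oth <- atoms[atoms$chain != ch, ]
    for (rn in unique(own$resno)) {
      ra <- own[own$resno == rn, ]
      hit <- FALSE
      for (i in seq_len(nrow(ra))) {
        d <- sqrt((oth$x - ra$x[i])^2 + (oth$y - ra$y[i])^2 +
                    (oth$z - ra$z[i])^2)
        if (any(d <= interface_cutoff)) { hit <- TRUE; break }
      }
      if (hit) truth[[ch]] <- c(truth[[ch]], paste0(ch, ":", rn))
    }
  }
  list(structure = st, interface = truth, gap = gap,
       interface_cutoff = interface_cutoff, n_res = n_res)
}

#' Barrel structure with a cylindrical pore of known radius
#'
#' A perforated carbon slab emulating a membrane-embedded channel: at each
#' z level a 12-atom ring of radius `inner_radius` defines the pore wall
#' (one residue per ring), and a sealed lattice annulus fills the slab out
#' to `half_width` so the cylinder is the only open route between the two
#' faces. The analytic axis clearance is `inner_radius - 1.7` (carbon van
#' der Waals radius); an optional constricted ring narrows one level.
#'
#' @param inner_radius cylinder radius in Angstrom (>= 2).
#' @param n_rings number of z levels (>= 3).
#' @param ring_spacing Angstrom between levels.
#' @param atoms_per_ring atoms per wall ring.
#' @param half_width lateral half-extent of the slab in Angstrom.
#' @param constrict_ring optional ring index to narrow.
#' @param constrict_radius radius of the constricted ring (> 0).
#' @return list with `structure`, `axis` (two points), `bottleneck`
#'   (analytic), `wall_residues` (keys of pore-wall rings), `seed_start`,
#'   `seed_end`.
#' @export
make_barrel <- function(inner_radius = 3.0, n_rings = 8, ring_spacing = 1.5,
                        atoms_per_ring = 12, half_width = 8,
                        constrict_ring = NA, constrict_radius = 2.2) {
  if (inner_radius < 2) stop("inner radius must be >= 2 Angstrom")
  if (n_rings < 3) stop("need at least 3 rings")
  if (!is.na(constrict_ring) && constrict_radius <= 0)
    stop("constriction radius must be > 0")
  vdw_c <- unname(element_radii()["C"])
  zs <- (seq_len(n_rings) - (n_rings + 1) / 2) * ring_spacing
  radii_used <- rep(inner_radius, n_rings)
  if (!is.na(constrict_ring)) radii_used[constrict_ring] <- constrict_radius
  rows <- list()
  # pore-wall rings, one residue per z level
  for (k in seq_len(n_rings)) {
    th <- 2 * pi * (seq_len(atoms_per_ring) - 1) / atoms_per_ring
    rows[[k]] <- .atoms_df(radii_used[k] * cos(th), radii_used[k] * sin(th),
                           rep(zs[k], atoms_per_ring),
                           elety = paste0("C", seq_len(atoms_per_ring)),
                           elesy = "C", resid = "GLY", chain = "A",
                           resno = k)
  }
  # sealed filler annulus (2.0 A lattice) from beyond the rings to the edge
  gx <- seq(-half_width, half_width, by = 2.0)
  lat <- expand.grid(x = gx, y = gx)
  lat <- lat[sqrt(lat$x^2 + lat$y^2) >= inner_radius + 2.2, , drop = FALSE]
  for (k in seq_len(n_rings)) {
    n <- nrow(lat)
    rows[[n_rings + k]] <- .atoms_df(lat$x, lat$y, rep(zs[k], n),
                                     elety = paste0("C", seq_len(n)),
                                     elesy = "C", resid = "GLY", chain = "A",
                                     resno = n_rings + k)
  }
  atoms <- do.call(rbind, rows)
  atoms$eleno <- seq_len(nrow(atoms))
  st <- clc_structure(atoms, title = "barrel fixture")
  list(structure = st,
       axis = rbind(c(0, 0, min(zs)), c(0, 0, max(zs))),
       bottleneck = min(radii_used) - vdw_c,
       wall_residues = paste0("A:", seq_len(n_rings)),
       seed_start = c(0, 0, min(zs) - 3),
       seed_end = c(0, 0, max(zs) + 3))
}

#' Hydrogen-bond micro-fixture
#'
#' A glutamate side chain with a partner backbone nitrogen placed at an
#' exact donor-acceptor distance along the CD->OE1 direction (ideal
#' antecedent angle), mirroring a side-chain-to-main-chain hydrogen bond at
#' a helix packing interface.
#'
#' @param distance OE1-N distance in Angstrom (default 2.9).
#' @return list with `structure`, `focus` (residue key of the glutamate),
#'   `partner` (residue key carrying the nitrogen).
#' @export
make_hbond_pair <- function(distance = 2.9) {
  glu_xyz <- rbind(N  = c(-0.7, -1.2, 0), CA = c(0, 0, 0), C = c(-1.2, 0.9, 0),
                   O  = c(-1.9, 0.6, 0.9), CB = c(1.5, 0, 0),
                   CG = c(2.2, 1.3, 0), CD = c(3.7, 1.3, 0),
                   OE1 = c(4.4, 2.35, 0), OE2 = c(4.3, 0.2, 0))
  glu <- .atoms_df(glu_xyz[, 1], glu_xyz[, 2], glu_xyz[, 3],
                   elety = rownames(glu_xyz),
                   elesy = substr(rownames(glu_xyz), 1, 1),
                   resid = "GLU", chain = "A", resno = 291)
  dir1 <- glu_xyz["OE1", ] - glu_xyz["CD", ]
  dir1 <- dir1 / sqrt(sum(dir1^2))
  n_pos <- glu_xyz["OE1", ] + distance * dir1
  ser_xyz <- rbind(N = n_pos, CA = n_pos + c(1.0, 1.0, 0.3),
                   C = n_pos + c(2.4, 1.0, 0.3), O = n_pos + c(3.0, 2.0, 0.3),
                   CB = n_pos + c(1.0, 2.2, 1.0), OG = n_pos + c(1.0, 3.0, 1.8))
  ser <- .atoms_df(ser_xyz[, 1], ser_xyz[, 2], ser_xyz[, 3],
                   elety = rownames(ser_xyz),
                   elesy = substr(rownames(ser_xyz), 1, 1),
                   resid = "SER", chain = "A", resno = 541)
  atoms <- rbind(glu, ser)
  atoms$eleno <- seq_len(nrow(atoms))
  list(structure = clc_structure(atoms, title = "hbond fixture"),
       focus = "A:291", partner = "A:541", distance = distance)
}

#' Aromatic-stacking micro-fixture
#'
#' Two phenylalanine rings in parallel planes with a given centroid
#' separation.
#'
#' @param separation centroid distance in Angstrom (default 4.5).
#' @return list with `structure`, `focus`, `partner`.
#' @export
make_aromatic_pair <- function(separation = 4.5) {
  ring <- function(z) {
    th <- 2 * pi * (0:5) / 6
    cbind(1.39 * cos(th), 1.39 * sin(th), z)
  }
  phe_atoms <- function(z, resno) {
    r <- ring(z)
    xyz <- rbind(N = c(-2.8, -1.5, z - 1.2), CA = c(-2.6, -0.5, z - 0.6),
                 C = c(-3.6, 0.5, z - 0.6), O = c(-4.6, 0.4, z - 1.2),
                 CB = c(-2.6, -0.5, z + 0.9),
                 CG = r[1, ], CD1 = r[2, ], CE1 = r[3, ], CZ = r[4, ],
                 CE2 = r[5, ], CD2 = r[6, ])
    .atoms_df(xyz[, 1], xyz[, 2], xyz[, 3], elety = rownames(xyz),
              elesy = substr(rownames(xyz), 1, 1), resid = "PHE",
              chain = "A", resno = resno)
  }
  atoms <- rbind(phe_atoms(0, 428), phe_atoms(separation, 351))
  atoms$eleno <- seq_len(nrow(atoms))
  list(structure = clc_structure(atoms, title = "aromatic fixture"),
       focus = "A:428", partner = "A:351", separation = separation)
}

#' Default variant catalog for synthetic cohorts
#'
#' A small realistic mix of nonsense, frameshift, splice and missense
#' variants with novelty flags, used as the sampling universe of
#' [make_cohort()].
#'
#' @return data.frame with columns `cdna`, `protein`, `novel`, `freq`.
#' @export
default_variant_catalog <- function() {
  data.frame(
    cdna = c("c.2680C>T", "c.1437_1450del", "c.1238T>G", "c.568G>A",
             "c.1471+1G>A", "c.220C>T", "c.86A>C", "c.32delG"),
    protein = c("p.(Arg894*)", "p.(Pro480Hisfs*24)", "p.(Phe413Cys)",
                "p.(Gly190Arg)", "splicing effect", "p.(Gln74*)",
                "p.(His29Pro)", "p.(Gly11Valfs*66)"),
    novel = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    freq = c(0.40, 0.19, 0.06, 0.05, 0.05, 0.05, 0.10, 0.10),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic phased cohort with exact expected counts
#'
#' Samples patients with configurable fractions of single-variant probands,
#' homozygotes and cis double-variant alleles; mutations are drawn from a
#' catalog with a given allele-frequency vector. The returned ground truth
#' is exact bookkeeping recorded during generation, so downstream counting
#' can be checked without tolerance.
#'
#' @param n_patients number of probands (>= 1).
#' @param catalog data.frame like [default_variant_catalog()].
#' @param cis_fraction probability that the first allele of a two-allele
#'   patient carries a cis pair.
#' @param hom_fraction probability that a two-allele patient is homozygous.
#' @param single_fraction probability that a patient has a single detected
#'   variant.
#' @param seed integer seed; generation is fully deterministic given it.
#' @param path optional TSV output path.
#' @return list with `table` (cohort TSV layout), `truth` (denominator and
#'   per-type allele counts), and `path` (or NULL).
#' @export
make_cohort <- function(n_patients = 51, catalog = default_variant_catalog(),
                        cis_fraction = 0.05, hom_fraction = 0.2,
                        single_fraction = 0.1, seed = 1, path = NULL) {
  if (n_patients < 1) stop("n_patients must be >= 1")
  if (abs(sum(catalog$freq) - 1) > 1e-8)
    stop("catalog frequency vector must sum to 1")
  set.seed(seed)
  counts <- stats::setNames(rep(0L, nrow(catalog)), catalog$cdna)
  denom <- 0L
  rows <- list()
  draw <- function() sample.int(nrow(catalog), 1, prob = catalog$freq)
  for (p in seq_len(n_patients)) {
    vs <- list(); phase <- NULL
    if (stats::runif(1) < single_fraction) {
      i <- draw(); vs <- list(i); phase <- "1"
      counts[i] <- counts[i] + 1L; denom <- denom + 1L
    } else if (stats::runif(1) < hom_fraction) {
      i <- draw(); vs <- list(i, i); phase <- "1|2"
      counts[i] <- counts[i] + 2L; denom <- denom + 2L
    } else if (stats::runif(1) < cis_fraction) {
      i <- draw(); j <- draw(); k <- draw()
      vs <- list(i, j, k); phase <- "1|1|2"
      counts[i] <- counts[i] + 1L; counts[j] <- counts[j] + 1L
      counts[k] <- counts[k] + 1L; denom <- denom + 2L
    } else {
      i <- draw(); j <- draw()
      vs <- list(i, j); phase <- "1|2"
      counts[i] <- counts[i] + 1L; counts[j] <- counts[j] + 1L
      denom <- denom + 2L
    }
    row <- list(patient_id = as.character(p), phenotype = "BD")
    for (k in 1:3) {
      idx <- if (k <= length(vs)) vs[[k]] else NA
      row[[paste0("v", k, "_cdna")]] <- if (is.na(idx)) "" else catalog$cdna[idx]
      row[[paste0("v", k, "_protein")]] <- if (is.na(idx)) "" else catalog$protein[idx]
      row[[paste0("v", k, "_novel")]] <- if (is.na(idx)) "" else
        as.character(as.integer(catalog$novel[idx]))
    }
    row$phase <- phase
    rows[[p]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(table = tab,
       truth = list(n_disease_alleles = denom, counts = counts),
       path = path)
}

#' Write a fixture to disk with a JSON ground-truth sidecar
#'
#' Dispatcher over the fixture generators: writes a PDB (structures) or TSV
#' (cohorts) plus a `.truth.json` sidecar holding the generator's exact
#' ground truth, so downstream checks need no other input.
#'
#' @param kind one of "spheres", "bundle_dimer", "barrel", "hbond_pair",
#'   "aromatic_pair", "cohort".
#' @param out_dir output directory (created if needed).
#' @param seed integer seed (used by the cohort generator; geometric
#'   fixtures are deterministic by construction).
#' @param ... passed to the specific generator.
#' @return invisible list of written paths.
#' @export
simulate_fixture <- function(kind = c("spheres", "bundle_dimer", "barrel",
                                      "hbond_pair", "aromatic_pair", "cohort"),
                             out_dir = ".", seed = 1, ...) {
  kind <- match.arg(kind)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(out_dir, kind)
  if (kind == "cohort") {
    fx <- make_cohort(seed = seed, path = paste0(base, ".tsv"), ...)
    truth <- fx$truth
    data_path <- paste0(base, ".tsv")
  } else {
    fx <- switch(kind,
                 spheres = make_spheres(...),
                 bundle_dimer = make_bundle_dimer(...),
                 barrel = make_barrel(...),
                 hbond_pair = make_hbond_pair(...),
                 aromatic_pair = make_aromatic_pair(...))
    data_path <- paste0(base, ".pdb")
    write_pdb(fx$structure, data_path)
    truth <- fx[setdiff(names(fx), "structure")]
  }
  truth_path <- paste0(base, ".truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(data = data_path, truth = truth_path))
}
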