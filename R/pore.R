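## Ion-pathway detection: clearance-weighted shortest path on a cubic grid
## through one subunit, plus pore-lining residue assignment.

## clearance of arbitrary points: distance to nearest atom surface
## (negative inside an atom)
.clearance <- function(points, structure) {
  xyz <- coords(structure)
  vdw <- structure$atoms$vdw
  points <- matrix(points, ncol = 3)
  out <- rep(Inf, nrow(points))
  for (j in seq_len(nrow(xyz))) {
    d <- sqrt((points[, 1] - xyz[j, 1])^2 + (points[, 2] - xyz[j, 2])^2 +
                (points[, 3] - xyz[j, 3])^2) - vdw[j]
    out <- pmin(out, d)
  }
  out
}

#' Find a tunnel through a structure between two seed points
#'
#' Builds a cubic grid anchored at the structure centroid; each node's
#' clearance is the distance from the node to the nearest atom surface.
#' Nodes with clearance below `probe_min` are blocked. The tunnel is the
#' least-cost path between the nodes nearest each seed under an edge cost of
#' mean(1/clearance^2) of the endpoints times edge length, which pulls the
#' path onto the locally widest centerline. The path is smoothed with a
#' 3-point moving average and clearances recomputed on the smoothed samples.
#'
#' @param chain single-chain [clc_structure()].
#' @param start_seed,end_seed numeric length-3 points in Angstrom; must fall
#'   inside the structure bounding box padded by 5 Angstrom.
#' @param config an [analysis_config()]; uses `grid_spacing` and `probe_min`.
#' @return object of class `pore_path`: `found` (logical), `samples`
#'   (data.frame x/y/z/clearance, empty when no tunnel), `bottleneck`
#'   (minimum clearance, NA when no tunnel), `start_seed`, `end_seed`,
#'   `grid_spacing`.
#' @export
find_pore <- function(chain, start_seed, end_seed, config = analysis_config()) {
  xyz <- coords(chain)
  h <- config$grid_spacing
  pmin_clear <- config$probe_min
  bb_lo <- apply(xyz, 2, min) - 5
  bb_hi <- apply(xyz, 2, max) + 5
  for (s in list(start_seed, end_seed)) {
    if (length(s) != 3 || any(!is.finite(s))) stop("seed must be a finite 3-vector")
    if (any(s < bb_lo) || any(s > bb_hi))
      stop("seed outside the padded bounding box")
  }
  if (any(.clearance(rbind(start_seed, end_seed), chain) < 0))
    stop("seed lies inside an atom")
  no_tunnel <- function() structure(
    list(found = FALSE,
         samples = data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                              clearance = numeric(0)),
         bottleneck = NA_real_, start_seed = start_seed, end_seed = end_seed,
         grid_spacing = h),
    class = "pore_path")

  # grid anchored at the centroid so runs are exactly repeatable; the tight
  # 1 A pad keeps the search inside the structure's footprint so bulk
  # solvent outside cannot offer a cheap detour around the protein
  ctr <- colMeans(xyz)
  lo <- pmin(apply(xyz, 2, min), pmin(start_seed, end_seed)) - 1
  hi <- pmax(apply(xyz, 2, max), pmax(start_seed, end_seed)) + 1
  ax <- lapply(1:3, function(k) {
    kk <- floor((lo[k] - ctr[k]) / h):ceiling((hi[k] - ctr[k]) / h)
    ctr[k] + kk * h
  })
  nx <- length(ax[[1]]); ny <- length(ax[[2]]); nz <- length(ax[[3]])
  grid <- cbind(rep(ax[[1]], times = ny * nz),
                rep(rep(ax[[2]], each = nx), times = nz),
                rep(ax[[3]], each = nx * ny))
  clr <- .clearance(grid, chain)
  open <- clr > pmin_clear
  if (!any(open)) return(no_tunnel())

  # 26-neighbourhood edges among open nodes
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
               (offs[, 2] == 0 & offs[, 1] > 0))), , drop = FALSE]  # half-space
  idx <- which(open)
  ix <- (idx - 1) %% nx
  iy <- ((idx - 1) %/% nx) %% ny
  iz <- (idx - 1) %/% (nx * ny)
  open_flag <- open
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  inv2 <- ifelse(open_flag, 1 / clr^2, NA_real_)
  for (r in seq_len(nrow(offs))) {
    jx <- ix + offs[r, 1]; jy <- iy + offs[r, 2]; jz <- iz + offs[r, 3]
    ok <- jx >= 0 & jx < nx & jy >= 0 & jy < ny & jz >= 0 & jz < nz
    j <- jx[ok] + nx * (jy[ok] + ny * jz[ok]) + 1L
    i <- idx[ok]
    keep <- open_flag[j]
    i <- i[keep]; j <- j[keep]
    len <- sqrt(sum(offs[r, ]^2)) * h
    from <- c(from, i); to <- c(to, j)
    wt <- c(wt, 0.5 * (inv2[i] + inv2[j]) * len)
  }
  if (length(from) == 0) return(no_tunnel())

  # map grid indices to compact vertex ids
  vid <- integer(nx * ny * nz)
  vid[idx] <- seq_along(idx)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  g <- igraph::add_edges(g, rbind(vid[from], vid[to]))
  igraph::E(g)$weight <- wt

  nearest_open <- function(seed) {
    d2 <- (grid[idx, 1] - seed[1])^2 + (grid[idx, 2] - seed[2])^2 +
      (grid[idx, 3] - seed[3])^2
    which.min(d2)
  }
  v1 <- nearest_open(start_seed)
  v2 <- nearest_open(end_seed)
  sp <- suppressWarnings(igraph::shortest_paths(g, from = v1, to = v2,
                                                weights = igraph::E(g)$weight,
                                                output = "vpath"))
  vpath <- as.integer(sp$vpath[[1]])
  if (length(vpath) == 0 || (length(vpath) == 1 && v1 != v2))
    return(no_tunnel())
  pts <- grid[idx[vpath], , drop = FALSE]
  # 3-point moving average, endpoints fixed
  if (nrow(pts) >= 3) {
    sm <- pts
    mid <- 2:(nrow(pts) - 1)
    sm[mid, ] <- (pts[mid - 1, ] + pts[mid, ] + pts[mid + 1, ]) / 3
    pts <- sm
  }
  cl <- .clearance(pts, chain)
  structure(list(found = TRUE,
                 samples = data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                                      clearance = cl),
                 bottleneck = min(cl), start_seed = start_seed,
                 end_seed = end_seed, grid_spacing = h),
            class = "pore_path")
}

#' @export
print.pore_path <- function(x, ...) {
  if (!x$found) cat("pore_path: no tunnel\n")
  else cat("pore_path:", nrow(x$samples), "samples, bottleneck",
           round(x$bottleneck, 2), "A\n")
  invisible(x)
}

#' Residues lining a tunnel
#'
#' A residue lines the tunnel if any of its heavy atoms lies within
#' (local clearance + cutoff) of any path sample.
#'
#' @param path a [find_pore()] result.
#' @param chain the structure the path was computed on.
#' @param cutoff Angstrom beyond the local tunnel surface (default 3.0).
#' @return object of class `pore_lining`: list with `residues` (character
#'   residue keys) and `cutoff`.
#' @export
pore_lining_residues <- function(path, chain, cutoff = 3.0) {
  if (!isTRUE(path$found) || nrow(path$samples) == 0)
    return(structure(list(residues = character(0), cutoff = cutoff),
                     class = "pore_lining"))
  xyz <- coords(chain)
  keys <- .atom_keys(chain$atoms)
  s <- path$samples
  hit <- rep(FALSE, nrow(xyz))
  for (k in seq_len(nrow(s))) {
    d <- sqrt((xyz[, 1] - s$x[k])^2 + (xyz[, 2] - s$y[k])^2 +
                (xyz[, 3] - s$z[k])^2)
    hit <- hit | (d <= s$clearance[k] + cutoff)
  }
  structure(list(residues = unique(keys[hit]), cutoff = cutoff),
            class = "pore_lining")
}

#' Residues near a set of points
#'
#' Residues with any heavy atom within `cutoff` of any query point; used
#' e.g. for residues close to ion positions carried over from a template
#' structure.
#'
#' @param points numeric matrix (n x 3) or length-3 vector.
#' @param chain a [clc_structure()].
#' @param cutoff Angstrom (default 4.5, > 0).
#' @return character vector of residue keys.
#' @export
residues_near_points <- function(points, chain, cutoff = 4.5) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  points <- matrix(points, ncol = 3)
  if (nrow(points) == 0) return(character(0))
  xyz <- coords(chain)
  keys <- .atom_keys(chain$atoms)
  hit <- rep(FALSE, nrow(xyz))
  for (k in seq_len(nrow(points))) {
    d2 <- (xyz[, 1] - points[k, 1])^2 + (xyz[, 2] - points[k, 2])^2 +
      (xyz[, 3] - points[k, 3])^2
    hit <- hit | (d2 <= cutoff^2)
  }
  unique(keys[hit])
}

#' Write a tunnel as a pseudo-atom PDB for visualization
#'
#' One HETATM per path sample with the clearance in the B-factor column.
#'
#' @param path a [find_pore()] result.
#' @param file output path.
#' @export
write_pore_pdb <- function(path, file) {
  s <- path$samples
  if (nrow(s) == 0) stop("no tunnel to write")
  rec <- sprintf("HETATM%5d  O   TUN A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           O",
                 seq_len(nrow(s)), seq_len(nrow(s)), s$x, s$y, s$z, 1,
                 s$clearance)
  writeLines(c(rec, "END"), file)
  invisible(file)
}
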