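## Hierarchical structure model: a flat heavy-atom table with chain/residue
## grouping, PDB input through bio3d and fixed-width PDB output.

#' Construct a structure object from an atom table
#'
#' The atom table is the package's working representation of a protein
#' structure: one row per heavy atom with identifiers, coordinates and an
#' assigned van der Waals radius. Residues are the groups of rows sharing
#' `(chain, resno, insert)`.
#'
#' @param atoms data.frame with columns `eleno`, `elety`, `elesy`, `resid`,
#'   `chain`, `resno`, `insert`, `x`, `y`, `z`, `o`, `vdw`.
#' @param title optional title string.
#' @return object of class `clc_structure`.
#' @export
clc_structure <- function(atoms, title = "") {
  need <- c("eleno", "elety", "elesy", "resid", "chain", "resno", "insert",
            "x", "y", "z", "o", "vdw")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols))
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) == 0) stop("structure must contain at least one atom")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite atom coordinates")
  if (any(!is.finite(atoms$vdw)) || any(atoms$vdw <= 0))
    stop("all atoms must carry a positive van der Waals radius")
  atoms$insert[is.na(atoms$insert)] <- ""
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, title = title), class = "clc_structure")
}

#' @export
print.clc_structure <- function(x, ...) {
  ri <- residue_index(x)
  cat("clc_structure:", nrow(x$atoms), "atoms,", nrow(ri), "residues,",
      length(chain_ids(x)), "chain(s) [",
      paste(chain_ids(x), collapse = ","), "]\n")
  invisible(x)
}

#' Chain identifiers of a structure, in order of first appearance
#' @param structure a `clc_structure`.
#' @export
chain_ids <- function(structure) unique(structure$atoms$chain)

#' Residue-level index of a structure
#'
#' @param structure a `clc_structure`.
#' @return data.frame with one row per residue: `key` ("chain:resno" plus any
#'   insertion code), `chain`, `resno`, `insert`, `resid`.
#' @export
residue_index <- function(structure) {
  a <- structure$atoms
  key <- paste0(a$chain, ":", a$resno, a$insert)
  first <- !duplicated(key)
  data.frame(key = key[first], chain = a$chain[first], resno = a$resno[first],
             insert = a$insert[first], resid = a$resid[first],
             stringsAsFactors = FALSE)
}

## residue key for atom rows
.atom_keys <- function(atoms) paste0(atoms$chain, ":", atoms$resno, atoms$insert)

#' Extract one chain as a structure
#' @param structure a `clc_structure`.
#' @param chain chain identifier.
#' @export
get_chain <- function(structure, chain) {
  sel <- structure$atoms$chain == chain
  if (!any(sel)) stop("unknown chain: ", chain)
  clc_structure(structure$atoms[sel, , drop = FALSE], title = structure$title)
}

#' Atom coordinates as an N x 3 matrix
#' @param structure a `clc_structure`.
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

## infer an element symbol from a PDB atom name (fallback when columns 77-78
## are empty); strips digits/primes and handles two-letter elements
.infer_element <- function(elety) {
  stripped <- gsub("[0-9' ]", "", elety)
  two <- toupper(substr(stripped, 1, 2))
  one <- toupper(substr(stripped, 1, 1))
  ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG", "NA"), two, one)
}

## light fixed-width sanity scan so malformed records fail with a line number
.validate_pdb_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed PDB record (too short) at line ", i)
    nums <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(nums)))))
      stop("malformed PDB coordinate field at line ", i)
  }
  if (!any(rec == "ATOM  ")) stop("no ATOM records in ", path)
  invisible(sum(is_atom))
}

#' Read a structure from a PDB file
#'
#' Parses ATOM records (HETATM and waters are skipped), keeps the
#' highest-occupancy alternate conformer (first on ties), infers the element
#' from columns 77-78 when present and otherwise from the atom name, and
#' assigns van der Waals radii from the packaged element-radius table.
#' Hydrogens are dropped: all downstream geometry is defined on heavy atoms.
#'
#' @param path PDB file path.
#' @param model_index 1-based model to read from multi-model files.
#' @param keep_hydrogens keep H atoms (default FALSE).
#' @return a [clc_structure()].
#' @export
read_pdb <- function(path, model_index = 1L, keep_hydrogens = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  .validate_pdb_lines(path)
  multi <- model_index > 1L
  pdb <- bio3d::read.pdb(path, multi = multi, verbose = FALSE)
  a <- pdb$atom
  a <- a[a$type == "ATOM" & !(a$resid %in% c("HOH", "WAT")), , drop = FALSE]
  if (nrow(a) == 0) stop("no ATOM records in ", path)
  if (multi) {
    if (model_index > nrow(pdb$xyz)) stop("model_index beyond model count")
    xyz <- matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)  # file order
    keep <- which(pdb$atom$type == "ATOM" & !(pdb$atom$resid %in% c("HOH", "WAT")))
    a$x <- xyz[keep, 1]; a$y <- xyz[keep, 2]; a$z <- xyz[keep, 3]
  }
  a$insert[is.na(a$insert)] <- ""
  a$chain[is.na(a$chain)] <- "A"
  a$o[is.na(a$o)] <- 1
  a$alt[is.na(a$alt)] <- ""
  # altloc: keep highest occupancy, first on tie, per atom identity
  id <- paste(a$chain, a$resno, a$insert, a$elety)
  ord <- order(match(id, unique(id)), -a$o)
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety)), , drop = FALSE]
  a <- a[order(match(paste(a$chain, a$resno, a$insert),
                     unique(paste(a$chain, a$resno, a$insert)))), , drop = FALSE]
  elesy <- toupper(ifelse(is.na(a$elesy) | a$elesy == "",
                          .infer_element(a$elety), a$elesy))
  radii <- element_radii()
  unknown <- !(elesy %in% names(radii))
  if (any(unknown))
    stop("unknown element for atom(s): ",
         paste(utils::head(paste0(a$elety[unknown], " (serial ", a$eleno[unknown], ")"), 5),
               collapse = ", "))
  keep_row <- if (keep_hydrogens) rep(TRUE, nrow(a)) else elesy != "H"
  out <- data.frame(eleno = a$eleno, elety = a$elety, elesy = elesy,
                    resid = a$resid, chain = a$chain, resno = a$resno,
                    insert = a$insert, x = a$x, y = a$y, z = a$z,
                    o = a$o, vdw = unname(radii[elesy]),
                    stringsAsFactors = FALSE)[keep_row, , drop = FALSE]
  if (nrow(out) == 0) stop("no heavy atoms left after filtering in ", path)
  clc_structure(out, title = basename(path))
}

#' Write a structure to a PDB file
#'
#' Emits fixed-width ATOM records with 3-decimal coordinates, a TER record
#' between chains, and END. Reading the file back reproduces identifiers
#' exactly and coordinates to 0.001 Angstrom.
#'
#' @param structure a [clc_structure()].
#' @param path output file path.
#' @export
write_pdb <- function(structure, path) {
  a <- structure$atoms
  if (nrow(a) == 0) stop("empty structure")
  if (any(nchar(a$resid) > 3)) stop("residue name longer than 3 characters")
  name_fmt <- ifelse(nchar(a$elety) >= 4, substr(a$elety, 1, 4),
                     sprintf(" %-3s", a$elety))
  rec <- sprintf("ATOM  %5d %4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                 a$eleno %% 100000, name_fmt, a$resid, a$chain, a$resno,
                 ifelse(a$insert == "", " ", a$insert),
                 a$x, a$y, a$z, a$o, 0, a$elesy)
  # insert TER after the last atom of each chain
  last_of_chain <- cumsum(rle(a$chain)$lengths)
  out <- character(0)
  prev <- 0
  for (i in seq_along(last_of_chain)) {
    out <- c(out, rec[(prev + 1):last_of_chain[i]], "TER")
    prev <- last_of_chain[i]
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}
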