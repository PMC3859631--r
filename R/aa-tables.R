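## Packaged reference tables: amino-acid constants, element radii, atom
## templates. Loaded lazily from inst/extdata and cached per session.

.clc_cache <- new.env(parent = emptyenv())

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "clcimpact")
  if (!nzchar(path)) {
    # during development (pkgload) extdata may sit under inst/
    path <- system.file("inst", "extdata", file, package = "clcimpact")
  }
  if (!nzchar(path)) stop("packaged data file not found: ", file)
  path
}

.read_table <- function(file) {
  utils::read.delim(.extdata(file), stringsAsFactors = FALSE, fill = TRUE,
                    na.strings = c("NA", ""), quote = "")
}

#' Amino-acid property table
#'
#' Per-residue constants used by the mutation-impact rules: side-chain volume
#' (Zamyatnin residue volumes, \eqn{\\mbox{\\AA}^3}), a three-way polarity
#' class (nonpolar / polar / very_polar), a three-way charge class
#' (negative / neutral / positive, histidine counted positive), and maximal
#' accessible surface areas for the relative-accessibility denominator.
#'
#' @param max_asa which reference max-ASA set to expose in the `max_asa`
#'   column: `"tien"` (theoretical Gly-X-Gly values, default) or `"miller"`.
#' @return data.frame with one row per standard amino acid, rownames set to
#'   the three-letter code.
#' @export
aa_properties <- function(max_asa = c("tien", "miller")) {
  max_asa <- match.arg(max_asa)
  key <- paste0("aa_properties_", max_asa)
  if (is.null(.clc_cache[[key]])) {
    tab <- .read_table("aa_properties.tsv")
    rownames(tab) <- tab$res
    tab$max_asa <- if (max_asa == "tien") tab$max_asa_tien else tab$max_asa_miller
    .clc_cache[[key]] <- tab
  }
  .clc_cache[[key]]
}

#' Element van der Waals radius table
#'
#' @return named numeric vector of radii in Angstrom, names are upper-case
#'   element symbols.
#' @export
element_radii <- function() {
  if (is.null(.clc_cache$element_radii)) {
    tab <- .read_table("element_radii.tsv")
    .clc_cache$element_radii <- stats::setNames(tab$radius, toupper(tab$element))
  }
  .clc_cache$element_radii
}

#' Heavy-atom templates for the 20 standard amino acids
#'
#' One row per heavy atom: residue, atom name, element, whether it belongs to
#' the side chain, whether it is a polar (N/O) hydrogen-bond-capable atom,
#' its covalently bonded antecedent heavy atom (for the donor-angle check),
#' and whether it is part of an aromatic ring. Backbone atoms are stored
#' under the pseudo-residue `ALL`.
#'
#' @return data.frame.
#' @export
aa_atom_templates <- function() {
  if (is.null(.clc_cache$aa_atoms)) {
    tab <- .read_table("aa_atoms.tsv")
    tab$antecedent[is.na(tab$antecedent)] <- ""
    .clc_cache$aa_atoms <- tab
  }
  .clc_cache$aa_atoms
}

.standard_aas <- function() aa_properties()$res

## side-chain heavy-atom names for one residue type (backbone excluded)
.sidechain_atoms <- function(res_name) {
  tmpl <- aa_atom_templates()
  tmpl$atom[tmpl$res == res_name & tmpl$sidechain == 1]
}

.aa3_check <- function(code, what = "amino-acid code") {
  if (!code %in% .standard_aas())
    stop("unknown ", what, ": ", code)
  invisible(code)
}

## one- to three-letter amino-acid conversion
aa_one_to_three <- function(x) {
  tab <- aa_properties()
  stats::setNames(tab$res, tab$code1)[x]
}
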