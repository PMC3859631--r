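## Geometric side-chain contact detection: hydrogen bonds between N/O heavy
## atoms and aromatic ring interactions, plus the contact-loss rule used in
## mutation-impact reports.

.title_aa <- function(res) paste0(toupper(substr(res, 1, 1)),
                                  tolower(substr(res, 2, 3)))

.empty_contacts <- function() {
  data.frame(kind = character(0), focus_key = character(0),
             focus_resid = character(0), focus_atom = character(0),
             partner_key = character(0), partner_resid = character(0),
             partner_atom = character(0), distance = numeric(0),
             detail = character(0), stringsAsFactors = FALSE)
}

## rows of the atom table belonging to one residue key
.residue_atoms <- function(structure, residue_key) {
  sel <- .atom_keys(structure$atoms) == residue_key
  if (!any(sel)) stop("unknown residue: ", residue_key)
  structure$atoms[sel, , drop = FALSE]
}

#' Detect hydrogen bonds of one residue's side chain
#'
#' Heavy-atom criterion suited to models without hydrogens: a side-chain N/O
#' atom of the focus residue paired with any N/O atom of another residue at
#' donor-acceptor distance <= `dist_cutoff`, and, when the focus atom's
#' bonded antecedent is present, an antecedent-donor-acceptor angle >= 90
#' degrees. Details are formatted in the conventional
#' "Res(Atom)-ResNNN(Atom)" style.
#'
#' @param structure a [clc_structure()].
#' @param focus_residue residue key "chain:resno".
#' @param dist_cutoff Angstrom (default 3.5).
#' @return data.frame of contacts (possibly 0 rows): kind, focus/partner
#'   identifiers, distance, detail.
#' @export
detect_hbonds <- function(structure, focus_residue, dist_cutoff = 3.5) {
  fa <- .residue_atoms(structure, focus_residue)
  resname <- fa$resid[1]
  tmpl <- aa_atom_templates()
  sc_polar <- tmpl[tmpl$res == resname & tmpl$sidechain == 1 & tmpl$polar == 1, ]
  if (resname == "GLY" || nrow(sc_polar) == 0) {
    if (resname == "GLY") warning("glycine has no side chain beyond CA")
    return(.empty_contacts())
  }
  a <- structure$atoms
  keys <- .atom_keys(a)
  partner_polar <- (a$elesy %in% c("N", "O")) & keys != focus_residue
  pa <- a[partner_polar, , drop = FALSE]
  pkeys <- keys[partner_polar]
  out <- .empty_contacts()
  for (i in seq_len(nrow(sc_polar))) {
    frow <- fa[fa$elety == sc_polar$atom[i], , drop = FALSE]
    if (nrow(frow) == 0) next
    fpos <- as.numeric(frow[1, c("x", "y", "z")])
    d <- sqrt((pa$x - fpos[1])^2 + (pa$y - fpos[2])^2 + (pa$z - fpos[3])^2)
    cand <- which(d <= dist_cutoff)
    if (length(cand) == 0) next
    ante_name <- sc_polar$antecedent[i]
    ante <- fa[fa$elety == ante_name, , drop = FALSE]
    for (j in cand) {
      if (nzchar(ante_name) && nrow(ante) > 0) {
        v1 <- as.numeric(ante[1, c("x", "y", "z")]) - fpos
        v2 <- as.numeric(pa[j, c("x", "y", "z")]) - fpos
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        if (cosang > 0) next  # angle < 90 degrees
      }
      out <- rbind(out, data.frame(
        kind = "hbond", focus_key = focus_residue, focus_resid = resname,
        focus_atom = sc_polar$atom[i], partner_key = pkeys[j],
        partner_resid = pa$resid[j], partner_atom = pa$elety[j],
        distance = d[j],
        detail = sprintf("%s(%s)-%s%d(%s)", .title_aa(resname),
                         sc_polar$atom[i], .title_aa(pa$resid[j]),
                         pa$resno[j], pa$elety[j]),
        stringsAsFactors = FALSE))
    }
  }
  out
}

## ring centroid and unit normal (plane fit); NULL when the ring is incomplete
.ring_geometry <- function(structure, residue_key) {
  ra <- .residue_atoms(structure, residue_key)
  tmpl <- aa_atom_templates()
  ring_atoms <- tmpl$atom[tmpl$res == ra$resid[1] & tmpl$ring == 1]
  if (length(ring_atoms) == 0) return(NULL)
  got <- ra[ra$elety %in% ring_atoms, , drop = FALSE]
  if (nrow(got) < length(ring_atoms)) return(NULL)
  xyz <- as.matrix(got[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  n <- svd(sweep(xyz, 2, ctr))$v[, 3]
  list(centroid = ctr, normal = n / sqrt(sum(n^2)), resid = ra$resid[1],
       resno = ra$resno[1])
}

#' Detect aromatic ring interactions of one residue
#'
#' Contact between the focus ring (Phe/Tyr/Trp/His; His counted aromatic)
#' and another aromatic residue when the ring centroids are within
#' `dist_cutoff` and the ring planes are roughly parallel or strongly
#' tilted (normal-normal angle <= 60 or >= 120 degrees, covering stacked
#' and tilted-T geometries).
#'
#' @param structure a [clc_structure()].
#' @param focus_residue residue key.
#' @param dist_cutoff centroid separation cutoff in Angstrom (default 7.0).
#' @return data.frame of contacts.
#' @export
detect_aromatic <- function(structure, focus_residue, dist_cutoff = 7.0) {
  aromatic <- c("PHE", "TYR", "TRP", "HIS")
  fa <- .residue_atoms(structure, focus_residue)
  if (!fa$resid[1] %in% aromatic)
    stop("focus residue ", focus_residue, " (", fa$resid[1], ") is not aromatic")
  fg <- .ring_geometry(structure, focus_residue)
  if (is.null(fg)) {
    warning("incomplete ring in focus residue ", focus_residue)
    return(.empty_contacts())
  }
  ri <- residue_index(structure)
  others <- ri$key[ri$resid %in% aromatic & ri$key != focus_residue]
  out <- .empty_contacts()
  for (key in others) {
    og <- .ring_geometry(structure, key)
    if (is.null(og)) { warning("incomplete ring in ", key, "; skipped"); next }
    d <- sqrt(sum((fg$centroid - og$centroid)^2))
    if (d > dist_cutoff) next
    ang <- acos(pmin(1, pmax(-1, sum(fg$normal * og$normal)))) * 180 / pi
    if (ang <= 60 || ang >= 120) {
      out <- rbind(out, data.frame(
        kind = "aromatic", focus_key = focus_residue, focus_resid = fg$resid,
        focus_atom = "ring", partner_key = key, partner_resid = og$resid,
        partner_atom = "ring", distance = d,
        detail = sprintf("%s%d-%s%d", .title_aa(fg$resid), fg$resno,
                         .title_aa(og$resid), og$resno),
        stringsAsFactors = FALSE))
    }
  }
  out
}

## substitutions conservative enough that an equivalent contact may survive
.similar_pairs <- matrix(c("GLU", "ASP", "ASP", "GLU",
                           "GLN", "ASN", "ASN", "GLN",
                           "SER", "THR", "THR", "SER"),
                         ncol = 2, byrow = TRUE)

#' Wild-type contacts lost upon mutation
#'
#' A hydrogen bond is lost when the mutant side chain lacks an atom of the
#' wild-type contact's name (atom identity and chemistry change; e.g. a
#' Glu OE2 contact is lost on Glu->Gln because the mutant carries NE2).
#' An aromatic contact is lost when the mutant is not aromatic. Losses from
#' chemically similar substitutions (Glu/Asp, Gln/Asn, Ser/Thr) are flagged
#' `possibly_preserved`, since the shorter/longer analogue can partially
#' compensate.
#'
#' @param wild_contacts data.frame from [detect_hbonds()] /
#'   [detect_aromatic()].
#' @param mutant_aa 3-letter code of the substituting amino acid.
#' @return the lost contacts with a `possibly_preserved` column.
#' @export
contacts_lost <- function(wild_contacts, mutant_aa) {
  .aa3_check(mutant_aa, "mutant amino-acid code")
  if (nrow(wild_contacts) == 0) {
    out <- wild_contacts
    out$possibly_preserved <- logical(0)
    return(out)
  }
  mut_atoms <- .sidechain_atoms(mutant_aa)
  aromatic <- c("PHE", "TYR", "TRP", "HIS")
  lost <- ifelse(wild_contacts$kind == "aromatic",
                 !(mutant_aa %in% aromatic),
                 !(wild_contacts$focus_atom %in% mut_atoms))
  out <- wild_contacts[lost, , drop = FALSE]
  similar <- apply(.similar_pairs, 1, paste, collapse = "->")
  out$possibly_preserved <- if (nrow(out) == 0) logical(0) else
    paste0(out$focus_resid, "->", mutant_aa) %in% similar
  rownames(out) <- NULL
  out
}
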