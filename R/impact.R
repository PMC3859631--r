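## Mutation-impact classification: side-chain volume change, charge-class
## and polarity-class change, buriedness, localization, lost contacts.

#' Round half away from zero
#'
#' Commercial rounding as used for printed signed volume changes and
#' percentages (+30.2 -> +30, 27.5 -> 28, -28.5 -> -29). Inputs are
#' pre-rounded to 9 decimals so decimal ties such as 60.1 - 88.6 = -28.5
#' are not mis-rounded through binary representation error.
#'
#' @param x numeric vector.
#' @return numeric vector of integers.
#' @export
round_half_away <- function(x) {
  x <- round(x, 9)
  sign(x) * floor(abs(x) + 0.5)
}

#' Describe a missense mutation
#'
#' @param position residue position in protein numbering (>= 1).
#' @param wt,mut wild-type and mutant 3-letter amino-acid codes (distinct).
#' @param label optional HGVS protein string; generated when missing.
#' @return object of class `clc_mutation`.
#' @export
mutation <- function(position, wt, mut, label = NULL) {
  .aa3_check(wt, "wild-type code"); .aa3_check(mut, "mutant code")
  if (wt == mut) stop("wild-type and mutant amino acids must differ")
  position <- as.integer(position)
  if (is.na(position) || position < 1) stop("position must be a positive integer")
  if (is.null(label))
    label <- sprintf("p.(%s%d%s)", .title_aa(wt), position, .title_aa(mut))
  structure(list(position = position, wt = wt, mut = mut, label = label),
            class = "clc_mutation")
}

#' Parse a protein-level HGVS missense string
#'
#' Accepts "p.(Glu291Lys)" and "p.Glu291Lys".
#'
#' @param label HGVS protein substitution string.
#' @return a [mutation()].
#' @export
parse_mutation <- function(label) {
  m <- regmatches(label,
                  regexec("^p\\.\\(?([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2})\\)?$",
                          label))[[1]]
  if (length(m) == 0) stop("cannot parse mutation label: ", label)
  mutation(as.integer(m[3]), toupper(m[2]), toupper(m[4]), label = label)
}

#' Side-chain volume change upon substitution
#'
#' volume(mutant) - volume(wild type) from the packaged residue-volume set,
#' full precision (use [round_half_away()] for tabular display).
#'
#' @param wt,mut 3-letter codes.
#' @param table an [aa_properties()] table.
#' @return numeric, cubic Angstrom.
#' @export
delta_volume <- function(wt, mut, table = aa_properties()) {
  for (code in c(wt, mut)) if (!code %in% rownames(table))
    stop("unknown amino-acid code: ", code)
  table[mut, "volume"] - table[wt, "volume"]
}

#' Is a volume change destabilizing?
#'
#' TRUE when the absolute change is at least 30 cubic Angstrom (boundary
#' inclusive).
#'
#' @param delta volume change in cubic Angstrom.
#' @export
volume_destabilizing <- function(delta) abs(delta) >= 30

#' Charge-class change upon substitution
#'
#' Three charge classes (negative: Asp/Glu; positive: Arg/Lys/His; neutral
#' otherwise); TRUE when the classes differ.
#'
#' @inheritParams delta_volume
#' @export
charge_change <- function(wt, mut, table = aa_properties()) {
  for (code in c(wt, mut)) if (!code %in% rownames(table))
    stop("unknown amino-acid code: ", code)
  table[wt, "charge_class"] != table[mut, "charge_class"]
}

#' Polarity-class change upon substitution
#'
#' Three-way polarity partition (nonpolar / polar / very polar); TRUE when
#' the classes differ.
#'
#' @inheritParams delta_volume
#' @export
polarity_change <- function(wt, mut, table = aa_properties()) {
  for (code in c(wt, mut)) if (!code %in% rownames(table))
    stop("unknown amino-acid code: ", code)
  table[wt, "polarity_class"] != table[mut, "polarity_class"]
}

#' The compact impact triple, e.g. "+30/Yes/No"
#'
#' @param dv volume change (full precision; printed rounded, signed).
#' @param charge,polarity logical flags.
#' @export
impact_triple <- function(dv, charge, polarity) {
  sprintf("%+d/%s/%s", as.integer(round_half_away(dv)),
          ifelse(charge, "Yes", "No"), ifelse(polarity, "Yes", "No"))
}

#' Localize a mutation within the dimer
#'
#' Precedence: outside the modelled range; dimer interface; ion pathway;
#' near the interface; buried elsewhere; surface.
#'
#' @param mut a [mutation()].
#' @param interface an `interface_set` (or NULL).
#' @param lining a `pore_lining` (or NULL).
#' @param rsa_records data.frame from [relative_sasa()].
#' @param model_range integer length-2, first and last modelled position.
#' @param dimer optional two-chain structure enabling the near-interface
#'   test.
#' @param chain chain the mutation position refers to (default "A").
#' @param near_cutoff Angstrom for [near_interface()] (default 6).
#' @return one of "outside_model", "interface", "pore", "near_interface",
#'   "buried_other", "surface".
#' @export
classify_localization <- function(mut, interface, lining, rsa_records,
                                  model_range, dimer = NULL, chain = "A",
                                  near_cutoff = 6) {
  if (mut$position < model_range[1] || mut$position > model_range[2])
    return("outside_model")
  key <- paste0(chain, ":", mut$position)
  if (!is.null(interface) && key %in% unlist(interface$residues))
    return("interface")
  if (!is.null(lining) && key %in% lining$residues)
    return("pore")
  if (!is.null(interface) && !is.null(dimer) &&
      near_interface(key, dimer, cutoff = near_cutoff, interface = interface))
    return("near_interface")
  row <- rsa_records[rsa_records$key == key, , drop = FALSE]
  if (nrow(row) == 1 && isTRUE(row$buried)) return("buried_other")
  "surface"
}

#' Full per-mutation impact report
#'
#' Composes the property rules (volume / charge / polarity), buriedness,
#' localization and lost contacts into one record. Property flags are
#' computed for every mutation; for exposed positions they are additionally
#' marked as not subject to the buried-residue destabilization heuristic.
#'
#' @param mut a [mutation()] (or HGVS label string).
#' @param dimer two-chain [clc_structure()] (a single chain is accepted:
#'   interface/near-interface localization is then unavailable).
#' @param interface optional precomputed `interface_set`.
#' @param lining optional precomputed `pore_lining`.
#' @param config an [analysis_config()].
#' @param rsa_records optional precomputed [relative_sasa()] table for the
#'   assembly.
#' @param model_range first/last modelled position; defaults to the residue
#'   range present in `chain`.
#' @param chain chain holding the mutated position (default "A").
#' @return object of class `impact_report`.
#' @export
annotate_mutation <- function(mut, dimer, interface = NULL, lining = NULL,
                              config = analysis_config(), rsa_records = NULL,
                              model_range = NULL, chain = "A") {
  if (is.character(mut)) mut <- parse_mutation(mut)
  ri <- residue_index(dimer)
  in_chain <- ri[ri$chain == chain, , drop = FALSE]
  if (is.null(model_range)) model_range <- range(in_chain$resno)
  tab <- aa_properties(config$max_asa)
  dv <- delta_volume(mut$wt, mut$mut, tab)
  chg <- charge_change(mut$wt, mut$mut, tab)
  pol <- polarity_change(mut$wt, mut$mut, tab)
  key <- paste0(chain, ":", mut$position)
  outside <- mut$position < model_range[1] || mut$position > model_range[2]
  rsa <- NA_real_; buried <- NA; contacts <- .empty_contacts()
  lost <- contacts_lost(contacts, mut$mut)
  if (!outside) {
    row <- in_chain[in_chain$resno == mut$position, , drop = FALSE]
    if (nrow(row) == 0)
      stop("position ", mut$position, " absent from chain ", chain)
    if (row$resid[1] != mut$wt)
      stop("wild-type mismatch at position ", mut$position, ": expected ",
           mut$wt, ", structure has ", row$resid[1])
    if (is.null(rsa_records))
      rsa_records <- relative_sasa(shrake_rupley(dimer, config), dimer,
                                   max_asa = config$max_asa)
    rrow <- rsa_records[rsa_records$key == key, , drop = FALSE]
    rsa <- rrow$rsa[1]; buried <- rrow$buried[1]
    contacts <- detect_hbonds(dimer, key)
    if (mut$wt %in% c("PHE", "TYR", "TRP", "HIS"))
      contacts <- rbind(contacts, detect_aromatic(dimer, key))
    lost <- contacts_lost(contacts, mut$mut)
  } else {
    rsa_records <- rsa_records %||% NULL
  }
  loc <- classify_localization(mut, interface, lining,
                               rsa_records %||% data.frame(key = character(0),
                                                           buried = logical(0)),
                               model_range, dimer = dimer, chain = chain)
  structure(list(mutation = mut,
                 delta_volume = dv,
                 volume_destabilizing = volume_destabilizing(dv),
                 charge_change = chg,
                 polarity_change = pol,
                 triple = impact_triple(dv, chg, pol),
                 rsa = rsa, buried = buried,
                 surface_note = if (!outside && isFALSE(buried))
                   "surface - structural-change rules not applied" else NA_character_,
                 localization = loc,
                 contacts = contacts, contacts_lost = lost),
            class = "impact_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.impact_report <- function(x, ...) {
  cat(x$mutation$label, " ", x$triple,
      "  RSA=", ifelse(is.na(x$rsa), "outside model", sprintf("%.0f%%", x$rsa)),
      "  localization=", x$localization,
      "  contacts lost=", nrow(x$contacts_lost), "\n", sep = "")
  invisible(x)
}

#' Cross-tabulate localization against functional effect
#'
#' Counts functional-effect classes (pronounced / weak / absent
#' dominant-negative effect) within each localization class.
#'
#' @param reports list of `impact_report` objects, or a data.frame with
#'   columns `label` and `localization`.
#' @param functional_annotations named character vector mapping mutation
#'   labels to "pronounced_DN", "weak_DN" or "no_DN".
#' @return integer matrix localization x effect.
#' @export
tabulate_effect_correlation <- function(reports, functional_annotations) {
  if (is.data.frame(reports)) {
    labels <- reports$label
    locs <- reports$localization
  } else {
    labels <- vapply(reports, function(r) r$mutation$label, character(1))
    locs <- vapply(reports, function(r) r$localization, character(1))
  }
  missing <- setdiff(labels, names(functional_annotations))
  if (length(missing))
    stop("missing functional annotation for: ", paste(missing, collapse = ", "))
  eff <- factor(unname(functional_annotations[labels]),
                levels = c("pronounced_DN", "weak_DN", "no_DN"))
  loc_levels <- unique(c(locs))
  tab <- table(factor(locs, levels = loc_levels), eff)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
              dimnames = list(rownames(tab), colnames(tab)))
  m
}

#' Packaged reference table of functionally characterised channel mutations
#'
#' Transcription of published structural/functional annotations for CLCN1
#' missense mutations at the dimer interface and along the chloride pathway
#' (including six novel mutations): printed volume/charge/polarity triples,
#' printed RSA, contact strings, functional effect on the wild-type/mutant
#' heterodimer, and documented divergences between the printed volume or
#' charge values and the packaged constant set.
#'
#' @return data.frame.
#' @export
clcn1_functional_table <- function() {
  .read_table("clcn1_functional_mutations.tsv")
}
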