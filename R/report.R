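## End-to-end drivers tying the stages together and rendering plain-text
## reports (TSV + JSON) with the configuration echoed in a header block.

.pkg_version <- function() as.character(utils::packageVersion("clcimpact"))

## cheap stable hash of the configuration for the report header
.config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE)
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% .Machine$integer.max)
}

.report_header <- function(config, extra = character(0)) {
  c(sprintf("# clcimpact %s", .pkg_version()),
    sprintf("# config_hash=%s", .config_hash(config)),
    sprintf("# probe_radius=%g", config$probe_radius),
    sprintf("# sphere_points=%d", config$sphere_points),
    sprintf("# grid_spacing=%g", config$grid_spacing),
    sprintf("# probe_min=%g", config$probe_min),
    sprintf("# max_asa=%s", config$max_asa),
    sprintf("# seed=%d", config$seed),
    extra)
}

.write_tsv_report <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full structural annotation pipeline on a mutation list
#'
#' Reads a structure and a mutation table (TSV columns `label`, `position`,
#' `wt`, `mut`; three-letter codes), computes accessibility, interface
#' membership, optionally the ion pathway (when seeds are given), contacts
#' and the impact classification per mutation, and writes a TSV and a JSON
#' report. Every threshold used is echoed in the report header.
#'
#' @param structure_path PDB file of the (ideally dimeric) structure.
#' @param mutations_path TSV of mutations.
#' @param out_dir output directory.
#' @param config an [analysis_config()].
#' @param pore_seeds optional 2 x 3 matrix (start and end seed) enabling
#'   tunnel detection on the first chain.
#' @param chain chain mutations refer to.
#' @param model_range optional first/last modelled position.
#' @return invisible list with `reports` (list of `impact_report`) and the
#'   written `tsv`/`json` paths.
#' @export
run_annotate <- function(structure_path, mutations_path, out_dir = ".",
                         config = analysis_config(), pore_seeds = NULL,
                         chain = "A", model_range = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- read_pdb(structure_path)
  muts <- utils::read.delim(mutations_path, stringsAsFactors = FALSE,
                            quote = "", colClasses = "character")
  if (!all(c("label", "position", "wt", "mut") %in% names(muts)))
    stop("mutation table needs columns label, position, wt, mut")
  sasa <- shrake_rupley(st, config)
  rsa <- relative_sasa(sasa, st, max_asa = config$max_asa)
  iface <- if (length(chain_ids(st)) >= 2)
    find_interface_residues(st, config) else NULL
  lining <- NULL
  if (!is.null(pore_seeds)) {
    path <- find_pore(get_chain(st, chain), pore_seeds[1, ], pore_seeds[2, ],
                      config)
    if (path$found) lining <- pore_lining_residues(path, get_chain(st, chain))
  }
  reports <- vector("list", nrow(muts))
  for (i in seq_len(nrow(muts))) {
    m <- mutation(as.integer(muts$position[i]), toupper(muts$wt[i]),
                  toupper(muts$mut[i]), label = muts$label[i])
    reports[[i]] <- annotate_mutation(m, st, interface = iface,
                                      lining = lining, config = config,
                                      rsa_records = rsa,
                                      model_range = model_range, chain = chain)
  }
  df <- do.call(rbind, lapply(reports, function(r) data.frame(
    label = r$mutation$label, position = r$mutation$position,
    wt = r$mutation$wt, mut = r$mutation$mut,
    delta_volume = round_half_away(r$delta_volume),
    volume_destabilizing = r$volume_destabilizing,
    charge_change = r$charge_change, polarity_change = r$polarity_change,
    triple = r$triple,
    rsa = ifelse(is.na(r$rsa), "outside model", sprintf("%.1f", r$rsa)),
    buried = r$buried, localization = r$localization,
    contacts = paste(r$contacts$detail, collapse = "; "),
    contacts_lost = paste(r$contacts_lost$detail, collapse = "; "),
    note = ifelse(is.na(r$surface_note), "", r$surface_note),
    stringsAsFactors = FALSE)))
  if (is.null(df))
    df <- data.frame(label = character(0), position = integer(0),
                     wt = character(0), mut = character(0))
  tsv <- file.path(out_dir, "mutation_impact.tsv")
  json <- file.path(out_dir, "mutation_impact.json")
  .write_tsv_report(df, tsv, .report_header(config))
  jsonlite::write_json(list(tool = "clcimpact", version = .pkg_version(),
                            config = unclass(config),
                            config_hash = .config_hash(config),
                            mutations = df),
                       json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(reports = reports, tsv = tsv, json = json))
}

#' Run the cohort frequency analysis
#'
#' Loads a phased cohort table (or the packaged myotonia congenita cohort
#' transcription with `table1 = TRUE`), computes disease-allele counts,
#' frequencies and novelty summaries, and writes TSV + JSON reports.
#'
#' @param cohort_path TSV path (ignored when `table1 = TRUE`).
#' @param out_dir output directory.
#' @param table1 use the packaged cohort transcription.
#' @param config an [analysis_config()] (for the report header only).
#' @return invisible `cohort_summary` (with `novel` counts attached as an
#'   attribute), plus written paths in attributes `tsv`/`json`.
#' @export
run_cohort <- function(cohort_path = NULL, out_dir = ".", table1 = FALSE,
                       config = analysis_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- if (table1) clcn1_cohort_path() else cohort_path
  if (is.null(path)) stop("provide cohort_path or table1 = TRUE")
  cohort <- load_cohort(path)
  s <- allele_frequencies(cohort)
  nov <- summarize_novel(cohort)
  tsv <- file.path(out_dir, "cohort_frequencies.tsv")
  json <- file.path(out_dir, "cohort_summary.json")
  extra <- c(sprintf("# n_patients=%d", s$n_patients),
             sprintf("# n_disease_alleles=%d", s$n_disease_alleles),
             sprintf("# distinct_mutation_types=%d", s$n_distinct_types),
             sprintf("# novel_types=%d (truncating/splice %d, missense %d)",
                     nov$total_novel_types, nov$novel_truncating_or_splice,
                     nov$novel_missense))
  .write_tsv_report(s$frequencies, tsv, .report_header(config, extra))
  jsonlite::write_json(list(tool = "clcimpact", version = .pkg_version(),
                            config_hash = .config_hash(config),
                            n_patients = s$n_patients,
                            n_disease_alleles = s$n_disease_alleles,
                            n_distinct_types = s$n_distinct_types,
                            novel = nov, frequencies = s$frequencies),
                       json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(s, "novel") <- nov
  attr(s, "tsv") <- tsv
  attr(s, "json") <- json
  invisible(s)
}
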