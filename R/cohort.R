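## Cohort-level variant handling: HGVS-style parsing, phased allele
## grouping, disease-allele counting, novelty summaries.

#' Parse a cDNA/protein variant pair into a classified record
#'
#' Supported cDNA grammar: substitutions `c.N[+/-M]X>Y`, deletions
#' `c.N_Mdel[XX]`, `c.NdelX`, and `c.N_MdelinsXX`. A `-` between two exonic
#' coordinates (`c.1044-1156del`) is read as a range separator when the
#' second number exceeds the first by more than 100, otherwise as an
#' intronic offset. Classification: a protein `fs` is a frameshift; a
#' protein stop (`*`) without `fs` is nonsense; an intronic cDNA offset is a
#' splice variant; a protein Xxx->Yyy is missense; deletions spanning more
#' than 100 bases are large deletions, shorter in-frame ones inframe
#' deletions.
#'
#' @param cdna HGVS-like cDNA string.
#' @param protein HGVS-like protein string, "splicing effect", or "".
#' @param novel logical novelty flag.
#' @return object of class `clc_variant`: `cdna` (verbatim), `type_key`
#'   (normalised identity used for counting), `protein`, `variant_class`,
#'   `novel`.
#' @export
parse_variant <- function(cdna, protein = "", novel = FALSE) {
  if (is.na(cdna) || !nzchar(cdna)) stop("empty cDNA string")
  protein <- if (is.na(protein)) "" else protein
  cdna <- trimws(cdna); protein <- trimws(protein)
  offset <- NA_integer_; span <- NA_integer_; kind <- NULL
  type_key <- cdna
  m <- regmatches(cdna, regexec("^c\\.([0-9]+)([+-][0-9]+)?([ACGT])>([ACGT])$", cdna))[[1]]
  if (length(m)) {
    kind <- "sub"
    if (nzchar(m[3])) offset <- as.integer(m[3])
  }
  if (is.null(kind)) {
    # "-" between two coordinates: range separator iff the gap is large
    # (> 100, favouring a multi-exon span), else an intronic offset
    m <- regmatches(cdna, regexec("^c\\.([0-9]+)-([0-9]+)del([ACGT]*)$", cdna))[[1]]
    if (length(m)) {
      a <- as.integer(m[2]); b <- as.integer(m[3])
      kind <- "del"
      if (b > a + 100) {
        span <- b - a + 1L
        type_key <- sprintf("c.%d_%ddel%s", a, b, m[4])
      } else {
        offset <- -b; span <- 1L
      }
    }
  }
  if (is.null(kind)) {
    m <- regmatches(cdna, regexec("^c\\.([0-9]+)(\\+[0-9]+)?(?:_([0-9]+)(\\+[0-9]+)?)?del([ACGT]*)(?:ins([ACGT]+))?$", cdna))[[1]]
    if (length(m)) {
      kind <- if (nzchar(m[7])) "delins" else "del"
      start <- as.integer(m[2])
      if (nzchar(m[3])) offset <- as.integer(m[3])
      if (nzchar(m[4])) span <- as.integer(m[4]) - start + 1L
      else if (nzchar(m[6])) span <- nchar(m[6]) else span <- 1L
    }
  }
  if (is.null(kind)) stop("unparseable cDNA variant: ", cdna)
  variant_class <-
    if (grepl("fs", protein, fixed = TRUE)) {
      if (!is.na(span) && span > 100) "large_del" else "frameshift"
    } else if (grepl("*", protein, fixed = TRUE)) "nonsense"
    else if (!is.na(offset)) "splice"
    else if (grepl("^p\\.\\(?[A-Z][a-z]{2}[0-9]+[A-Z][a-z]{2}\\)?$", protein)) "missense"
    else if (kind %in% c("del", "delins") && !is.na(span) && span > 100) "large_del"
    else if (kind == "del" && !is.na(span) && span %% 3 == 0) "inframe_del"
    else "other"
  structure(list(cdna = cdna, type_key = type_key,
                 protein = protein, variant_class = variant_class,
                 novel = isTRUE(novel) || (is.numeric(novel) && novel == 1)),
            class = "clc_variant")
}

#' Format a parsed variant back to its cDNA string
#' @param variant a `clc_variant`.
#' @export
format_variant <- function(variant) variant$cdna

## display label for a variant type: protein form when informative
.variant_label <- function(v) {
  if (nzchar(v$protein) && grepl("^p\\.", v$protein)) v$protein else v$cdna
}

#' Load a phased cohort table
#'
#' Reads a TSV with columns `patient_id`, `phenotype`, `v1_cdna`,
#' `v1_protein`, `v1_novel`, ... (up to 3 variants) and `phase`. The phase
#' string assigns each variant to an allele group, e.g. "1|1|2" places
#' variants 1 and 2 in cis on allele 1. Patients with three variants and no
#' recorded phase get the default grouping (the two most-5' variants in cis)
#' with a warning.
#'
#' @param path TSV file path.
#' @return object of class `clc_cohort`: list of patient records, each with
#'   `patient_id`, `phenotype`, `alleles` (list of allele groups, each a
#'   list of `clc_variant`).
#' @export
load_cohort <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, fill = TRUE,
                           na.strings = c("NA"), quote = "",
                           colClasses = "character")
  if (nrow(tab) == 0) stop("empty cohort table: ", path)
  need <- c("patient_id", "phenotype", "v1_cdna", "phase")
  if (!all(need %in% names(tab)))
    stop("cohort table lacks columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  patients <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    variants <- list()
    for (k in 1:3) {
      cd <- row[[paste0("v", k, "_cdna")]]
      if (is.null(cd) || is.na(cd) || !nzchar(cd)) next
      pr <- row[[paste0("v", k, "_protein")]] %||% ""
      nv <- row[[paste0("v", k, "_novel")]] %||% "0"
      variants[[length(variants) + 1]] <-
        parse_variant(cd, pr, novel = !is.na(nv) && nv == "1")
    }
    nv <- length(variants)
    if (nv == 0) stop("patient ", row$patient_id, " has no variants")
    if (nv > 3) stop("patient ", row$patient_id, " has more than 3 variants")
    phase <- row$phase
    if (is.na(phase) || !nzchar(phase)) {
      phase <- switch(nv, "1", "1|2", "1|1|2")
      if (nv == 3)
        warning("patient ", row$patient_id,
                ": no phase recorded for 3 variants; defaulting to the two ",
                "most-5' variants in cis (1|1|2)")
    }
    groups <- as.integer(strsplit(phase, "|", fixed = TRUE)[[1]])
    if (length(groups) != nv || any(is.na(groups)))
      stop("patient ", row$patient_id, ": phase '", row$phase,
           "' inconsistent with ", nv, " variant(s)")
    ng <- length(unique(groups))
    if (!ng %in% 1:2 || (nv == 3 && ng != 2))
      stop("patient ", row$patient_id, ": contradictory phase '", phase, "'")
    if (nv == 1 && ng != 1)
      stop("patient ", row$patient_id, ": single variant cannot span 2 alleles")
    alleles <- lapply(sort(unique(groups)),
                      function(gr) variants[groups == gr])
    patients[[i]] <- list(patient_id = row$patient_id,
                          phenotype = row$phenotype, alleles = alleles)
  }
  structure(patients, class = "clc_cohort")
}

#' Path to the packaged myotonia congenita cohort transcription
#'
#' TSV transcription of a published cohort of 51 Czech myotonia congenita
#' probands with phased CLCN1 variants and novelty flags.
#' @export
clcn1_cohort_path <- function() .extdata("clcn1_czech_cohort.tsv")

#' Disease-allele counts and frequencies
#'
#' The denominator is the number of disease alleles: two per proband, one
#' for probands with a single detected variant; variants in cis on one
#' allele form a single disease allele. A mutation's count is the number of
#' allele groups containing it (homozygotes contribute two); each member of
#' a cis pair credits its own mutation. Percentages are reported to one
#' decimal, rounding half away from zero.
#'
#' @param cohort a `clc_cohort` from [load_cohort()].
#' @return object of class `cohort_summary`: `n_patients`,
#'   `n_disease_alleles`, `frequencies` (data.frame: type_key, label,
#'   variant_class, novel, n_alleles, pct), `n_distinct_types`.
#' @export
allele_frequencies <- function(cohort) {
  if (length(cohort) == 0) stop("empty cohort")
  denom <- sum(vapply(cohort, function(p) length(p$alleles), integer(1)))
  counts <- new.env(parent = emptyenv())
  meta <- list()
  for (p in cohort) {
    for (grp in p$alleles) {
      for (v in grp) {
        k <- v$type_key
        counts[[k]] <- (counts[[k]] %||% 0L) + 1L
        if (is.null(meta[[k]])) meta[[k]] <- v
        meta[[k]]$novel <- meta[[k]]$novel || v$novel
      }
    }
  }
  keys <- sort(names(meta))
  freq <- data.frame(
    type_key = keys,
    label = vapply(meta[keys], .variant_label, character(1)),
    variant_class = vapply(meta[keys], function(v) v$variant_class, character(1)),
    novel = vapply(meta[keys], function(v) v$novel, logical(1)),
    n_alleles = vapply(keys, function(k) counts[[k]], integer(1)),
    stringsAsFactors = FALSE)
  freq$pct <- round_half_away(1000 * freq$n_alleles / denom) / 10
  freq <- freq[order(-freq$n_alleles, freq$type_key), ]
  rownames(freq) <- NULL
  structure(list(n_patients = length(cohort),
                 n_disease_alleles = denom,
                 frequencies = freq,
                 n_distinct_types = nrow(freq)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("cohort_summary:", x$n_patients, "patients,", x$n_disease_alleles,
      "disease alleles,", x$n_distinct_types, "distinct mutation types\n")
  print(utils::head(x$frequencies, 5))
  invisible(x)
}

#' Count novel mutation types
#'
#' Distinct mutation types (by normalised cDNA) flagged novel, split into
#' truncating/splice (frameshift, splice, nonsense, large deletion) versus
#' missense.
#'
#' @param cohort a `clc_cohort`.
#' @return list with `total_novel_types`, `novel_truncating_or_splice`,
#'   `novel_missense`.
#' @export
summarize_novel <- function(cohort) {
  s <- allele_frequencies(cohort)$frequencies
  nov <- s[s$novel, , drop = FALSE]
  trunc_classes <- c("frameshift", "splice", "nonsense", "large_del")
  list(total_novel_types = nrow(nov),
       novel_truncating_or_splice = sum(nov$variant_class %in% trunc_classes),
       novel_missense = sum(nov$variant_class == "missense"))
}
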