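test_that("variant parsing classifies the supported HGVS forms", {
  v <- parse_variant("c.2680C>T", "p.(Arg894*)")
  expect_equal(v$variant_class, "nonsense")
  expect_equal(format_variant(v), "c.2680C>T")
  expect_equal(parse_variant("c.1437_1450del", "p.(Pro480Hisfs*24)")$variant_class,
               "frameshift")
  expect_equal(parse_variant("c.1238T>G", "p.(Phe413Cys)")$variant_class,
               "missense")
  expect_equal(parse_variant("c.1471+1G>A", "splicing effect")$variant_class,
               "splice")
  expect_equal(parse_variant("c.180+3A>T")$variant_class, "splice")
  expect_equal(parse_variant("c.1167-10T>C")$variant_class, "splice")
  expect_equal(parse_variant("c.323delA", "p.(Gln108Argfs*37)")$variant_class,
               "frameshift")
  expect_equal(parse_variant("c.946_948del", "p.(Phe316del)")$variant_class,
               "inframe_del")
  expect_error(parse_variant("g.12345A>T"), "unparseable")
  expect_error(parse_variant(""), "empty")
})

test_that("a dash between distant exonic coordinates is read as a range", {
  # large multi-exon deletion written with '-' as the range separator
  v <- parse_variant("c.1044-1156del", "p.(Glu349Lysfs*14)")
  expect_equal(v$variant_class, "large_del")
  expect_equal(v$type_key, "c.1044_1156del")
  expect_equal(v$cdna, "c.1044-1156del")
  # small gap: '-' is an intronic offset, hence a splice variant
  v2 <- parse_variant("c.1044-12del")
  expect_equal(v2$variant_class, "splice")
})

test_that("toy cohort counting: denominator and per-type credit rules", {
  tab <- data.frame(
    patient_id = c("P1", "P2", "P3"),
    phenotype = "MC",
    v1_cdna = c("c.2680C>T", "c.2680C>T", "c.1238T>G"),
    v1_protein = c("p.(Arg894*)", "p.(Arg894*)", "p.(Phe413Cys)"),
    v1_novel = "0",
    v2_cdna = c("c.2680C>T", "", "c.1471+1G>A"),
    v2_protein = c("p.(Arg894*)", "", "splicing effect"),
    v2_novel = "0",
    v3_cdna = c("", "", "c.86A>C"),
    v3_protein = c("", "", "p.(His29Pro)"),
    v3_novel = c("", "", "1"),
    phase = c("1|2", "1", "1|1|2"),
    stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  cohort <- load_cohort(f)
  s <- allele_frequencies(cohort)
  # P1 homozygous (2 alleles), P2 single variant (1), P3 two alleles with a
  # cis pair on the first: denominator 5
  expect_equal(s$n_disease_alleles, 5)
  fr <- s$frequencies
  expect_equal(fr$n_alleles[fr$type_key == "c.2680C>T"], 3L)  # 2 hom + 1
  # each member of the cis pair credits its own mutation
  expect_equal(fr$n_alleles[fr$type_key == "c.1238T>G"], 1L)
  expect_equal(fr$n_alleles[fr$type_key == "c.1471+1G>A"], 1L)
  expect_equal(fr$pct[fr$type_key == "c.2680C>T"], 60)
  nov <- summarize_novel(cohort)
  expect_equal(nov$total_novel_types, 1)
  expect_equal(nov$novel_missense, 1)
})

test_that("cohort loading validates phase strings", {
  base <- data.frame(patient_id = "P1", phenotype = "MC",
                     v1_cdna = "c.2680C>T", v1_protein = "p.(Arg894*)",
                     v1_novel = "0", v2_cdna = "c.1238T>G",
                     v2_protein = "p.(Phe413Cys)", v2_novel = "0",
                     v3_cdna = "", v3_protein = "", v3_novel = "",
                     phase = "1|2|3", stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(base, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_cohort(f), "inconsistent|contradictory")
  base$phase <- "1"
  utils::write.table(base, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_cohort(f), "inconsistent")
  # three variants without phase: default grouping with a warning
  base$v3_cdna <- "c.86A>C"; base$v3_protein <- "p.(His29Pro)"
  base$v3_novel <- "1"; base$phase <- ""
  utils::write.table(base, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_warning(cohort <- load_cohort(f), "defaulting")
  expect_length(cohort[[1]]$alleles, 2)
  expect_length(cohort[[1]]$alleles[[1]], 2)  # two most-5' variants in cis
  # empty file
  writeLines("patient_id\tphenotype\tv1_cdna\tphase", f)
  expect_error(load_cohort(f), "empty cohort")
})

test_that("allele frequencies are invariant to patient order", {
  path <- clcn1_cohort_path()
  tab <- utils::read.delim(path, colClasses = "character", quote = "")
  set.seed(3)
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tab[sample(nrow(tab)), ], f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  s1 <- suppressWarnings(allele_frequencies(load_cohort(path)))
  s2 <- suppressWarnings(allele_frequencies(load_cohort(f)))
  expect_equal(s1$n_disease_alleles, s2$n_disease_alleles)
  o1 <- s1$frequencies[order(s1$frequencies$type_key), ]
  o2 <- s2$frequencies[order(s2$frequencies$type_key), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("the packaged cohort reproduces the published summary statistics", {
  cohort <- suppressWarnings(load_cohort(clcn1_cohort_path()))
  expect_length(cohort, 51)
  s <- allele_frequencies(cohort)
  expect_equal(s$n_patients, 51)
  expect_equal(s$n_disease_alleles, 96)
  fr <- s$frequencies
  r894 <- fr[fr$label == "p.(Arg894*)", ]
  expect_equal(r894$n_alleles, 38L)
  expect_equal(r894$pct, 39.6)
  del <- fr[fr$type_key == "c.1437_1450del", ]
  expect_equal(del$n_alleles, 18L)
  expect_equal(del$pct, 18.8)
  f413 <- fr[fr$label == "p.(Phe413Cys)", ]
  expect_equal(f413$n_alleles, 6L)
  expect_equal(round_half_away(f413$pct), 6)
  # the two most frequent types are the two above
  expect_equal(fr$label[1:2], c("p.(Arg894*)", "p.(Pro480Hisfs*24)"))
  nov <- summarize_novel(cohort)
  expect_equal(nov$total_novel_types, 14)
  expect_equal(nov$novel_truncating_or_splice, 8)
  expect_equal(nov$novel_missense, 6)
  expect_output(print(s), "96 disease alleles")
})
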