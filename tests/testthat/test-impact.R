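test_that("mutation construction and HGVS parsing validate their input", {
  m <- mutation(291, "GLU", "LYS")
  expect_equal(m$label, "p.(Glu291Lys)")
  expect_equal(parse_mutation("p.(Glu291Lys)")$position, 291)
  expect_equal(parse_mutation("p.Phe413Cys")$mut, "CYS")
  expect_error(mutation(291, "GLU", "GLU"), "must differ")
  expect_error(mutation(-5, "GLU", "LYS"), "positive")
  expect_error(mutation(10, "XXX", "LYS"), "unknown")
  expect_error(parse_mutation("c.2680C>T"), "cannot parse")
})

test_that("volume, charge and polarity rules reproduce hand-checked examples", {
  # Glu(138.4) -> Lys(168.6): +30.2, prints +30, destabilizing (inclusive cut)
  dv <- delta_volume("GLU", "LYS")
  expect_equal(dv, 30.2, tolerance = 1e-9)
  expect_true(volume_destabilizing(dv))
  expect_equal(impact_triple(dv, charge_change("GLU", "LYS"),
                             polarity_change("GLU", "LYS")), "+30/Yes/No")
  # Glu -> Asp: -27, not destabilizing, same charge class
  expect_equal(impact_triple(delta_volume("GLU", "ASP"),
                             charge_change("GLU", "ASP"),
                             polarity_change("GLU", "ASP")), "-27/No/No")
  # Phe -> Cys: large shrink, both nonpolar, no charge change
  expect_equal(impact_triple(delta_volume("PHE", "CYS"),
                             charge_change("PHE", "CYS"),
                             polarity_change("PHE", "CYS")), "-81/No/No")

  # boundary: |delta| exactly 30 counts as destabilizing
  expect_true(volume_destabilizing(30))
  expect_true(volume_destabilizing(-30))
  expect_false(volume_destabilizing(29.9))
})

test_that("substitution rules are antisymmetric/symmetric as appropriate", {
  pairs <- list(c("GLY", "TRP"), c("ARG", "HIS"), c("SER", "PHE"),
                c("ASP", "LYS"))
  for (p in pairs) {
    expect_equal(delta_volume(p[1], p[2]), -delta_volume(p[2], p[1]))
    expect_equal(charge_change(p[1], p[2]), charge_change(p[2], p[1]))
    expect_equal(polarity_change(p[1], p[2]), polarity_change(p[2], p[1]))
  }
})

test_that("half-away-from-zero rounding handles ties on both sides", {
  expect_equal(round_half_away(c(0.5, 1.5, 2.4, -0.5, -1.5, -2.6)),
               c(1, 2, 2, -1, -2, -3))
})

test_that("localization follows the documented precedence order", {
  bd <- make_bundle_dimer()
  st <- bd$structure
  iface <- find_interface_residues(st, method = "distance")
  rsa <- relative_sasa(shrake_rupley(st), st)
  lining <- structure(list(residues = c("A:1", "A:5"), cutoff = 3),
                      class = "pore_lining")
  loc <- function(pos, ...) {
    classify_localization(mutation(pos, "ALA", "VAL"), dimer = st, ...)
  }
  # outside the modelled range wins over everything
  expect_equal(loc(1, iface, lining, rsa, model_range = c(2, 20)),
               "outside_model")
  expect_equal(loc(30, iface, lining, rsa, model_range = c(1, 20)),
               "outside_model")
  # interface beats pore for a residue in both sets
  expect_equal(loc(1, iface, lining, rsa, model_range = c(1, 20)), "interface")
  # pore lining next
  expect_equal(loc(5, iface, lining, rsa, model_range = c(1, 20)), "pore")
  # otherwise surface (all bundle residues are exposed)
  expect_equal(loc(10, iface, lining, rsa, model_range = c(1, 20)), "surface")
  # a mocked buried residue lands in buried_other
  rsa2 <- rsa
  rsa2$buried[rsa2$key == "A:10"] <- TRUE
  expect_equal(loc(10, iface, lining, rsa2, model_range = c(1, 20)),
               "buried_other")
})

test_that("annotation errors on wild-type mismatch and absent positions", {
  bd <- make_bundle_dimer()
  expect_error(annotate_mutation(mutation(5, "GLU", "LYS"), bd$structure),
               "expected GLU, structure has ALA")
  expect_error(annotate_mutation(mutation(19, "ALA", "VAL"), bd$structure,
                                 model_range = c(1, 25), chain = "Q"),
               "unknown chain|absent")
  expect_error(annotate_mutation(mutation(25, "ALA", "VAL"), bd$structure,
                                 model_range = c(1, 30)),
               "absent from chain")
})

test_that("a full annotation composes properties, accessibility and contacts", {
  bd <- make_bundle_dimer()
  iface <- find_interface_residues(bd$structure, method = "distance")
  rep1 <- annotate_mutation("p.(Ala1Gly)", bd$structure, interface = iface)
  expect_s3_class(rep1, "impact_report")
  expect_equal(rep1$localization, "interface")
  expect_equal(rep1$triple, "-29/No/No")
  expect_false(rep1$volume_destabilizing)
  expect_false(is.na(rep1$rsa))
  # outside the model: no accessibility, no contacts, explicit localization
  rep2 <- annotate_mutation(mutation(900, "ARG", "TRP"), bd$structure,
                            model_range = c(1, 20))
  expect_equal(rep2$localization, "outside_model")
  expect_true(is.na(rep2$rsa))
  expect_equal(nrow(rep2$contacts), 0)
  # exposed positions carry the surface caveat note
  rep3 <- annotate_mutation(mutation(10, "ALA", "VAL"), bd$structure,
                            interface = iface)
  expect_equal(rep3$localization, "surface")
  expect_match(rep3$surface_note, "structural-change rules not applied")
  expect_output(print(rep3), "localization=surface")
})

test_that("effect cross-tabulation counts labels per localization class", {
  df <- data.frame(
    label = c("m1", "m2", "m3", "m4"),
    localization = c("interface", "interface", "pore", "surface"),
    stringsAsFactors = FALSE)
  ann <- c(m1 = "pronounced_DN", m2 = "weak_DN", m3 = "pronounced_DN",
           m4 = "no_DN")
  tab <- tabulate_effect_correlation(df, ann)
  expect_equal(tab["interface", "pronounced_DN"], 1)
  expect_equal(tab["interface", "weak_DN"], 1)
  expect_equal(tab["pore", "pronounced_DN"], 1)
  expect_equal(tab["surface", "no_DN"], 1)
  expect_equal(sum(tab), 4)
  expect_error(tabulate_effect_correlation(df, ann[1:2]),
               "missing functional annotation")
})

test_that("computed triples reproduce the packaged functional table", {
  tab <- clcn1_functional_table()
  expect_equal(nrow(tab), 29)
  has_triple <- !is.na(tab$dv_printed)
  expect_equal(sum(has_triple), 21)
  rows <- tab[has_triple, ]
  computed_dv <- round_half_away(mapply(delta_volume, rows$wt, rows$mut))
  computed_chg <- ifelse(mapply(charge_change, rows$wt, rows$mut), "Yes", "No")
  computed_pol <- ifelse(mapply(polarity_change, rows$wt, rows$mut), "Yes", "No")
  match_row <- computed_dv == rows$dv_printed &
    computed_chg == rows$charge_printed & computed_pol == rows$polarity_printed
  # all rows match except the three transcribed divergences
  divergent <- rows$label[!match_row]
  expect_setequal(divergent,
                  c("p.(Tyr302His)", "p.(Met485Val)", "p.(Ile556Asn)"))
  expect_equal(sum(match_row), 18)
  # the divergent rows are flagged as such in the packaged table
  expect_setequal(rows$label[!is.na(rows$divergence)], divergent)
  # volume divergences disagree in the printed delta, charge one in the flag
  expect_equal(unname(computed_dv[rows$label == "p.(Tyr302His)"]), -40)
  expect_equal(rows$dv_printed[rows$label == "p.(Tyr302His)"], -35)
  expect_equal(unname(computed_dv[rows$label == "p.(Met485Val)"]), -23)
  expect_equal(rows$dv_printed[rows$label == "p.(Met485Val)"], 23)
  expect_equal(unname(computed_chg[rows$label == "p.(Ile556Asn)"]), "No")
  expect_equal(rows$charge_printed[rows$label == "p.(Ile556Asn)"], "Yes")
})

test_that("functional-effect tallies match the packaged annotations", {
  tab <- clcn1_functional_table()
  iface <- tab[tab$section == "interface", ]
  expect_equal(as.integer(table(factor(iface$effect,
                                       c("pronounced_DN", "weak_DN", "no_DN")))),
               c(14L, 2L, 1L))
  pore <- tab[tab$section == "pore", ]
  expect_equal(as.integer(table(factor(pore$effect,
                                       c("pronounced_DN", "weak_DN", "no_DN")))),
               c(1L, 2L, 3L))
})
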