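test_that("golden-spiral lattice is deterministic, unit-norm and well spread", {
  p1 <- golden_spiral_points(960)
  p2 <- golden_spiral_points(960)
  expect_identical(p1, p2)
  expect_equal(rowSums(p1^2), rep(1, 960), tolerance = 1e-12)
  # quasi-uniform: centroid near the origin
  expect_lt(max(abs(colMeans(p1))), 0.01)
})

test_that("single-sphere surface area matches the closed form within 1%", {
  fx <- make_spheres(rbind(c(0, 0, 0)))
  s <- shrake_rupley(fx$structure)
  analytic <- fx$analytic$sasa[1]
  expect_equal(analytic, 4 * pi * (1.7 + 1.4)^2)
  expect_lt(abs(s$per_atom[1] - analytic) / analytic, 0.01)
})

test_that("two overlapping spheres match the spherical-cap closed form within 1%", {
  for (d in c(2, 3, 4.5)) {
    fx <- make_spheres(rbind(c(0, 0, 0), c(d, 0, 0)))
    s <- shrake_rupley(fx$structure)
    expect_lt(max(abs(s$per_atom - fx$analytic$sasa) / fx$analytic$sasa), 0.01)
  }
  # beyond touching distance both spheres are fully exposed
  fx <- make_spheres(rbind(c(0, 0, 0), c(10, 0, 0)))
  expect_equal(fx$analytic$sasa, rep(4 * pi * 3.1^2, 2))
  s <- shrake_rupley(fx$structure)
  expect_equal(s$per_atom, fx$analytic$sasa, tolerance = 1e-9)
})

test_that("a fully enclosed atom has zero accessible area", {
  # central atom caged by 14 close neighbours (faces + diagonals)
  shell <- rbind(c(2, 0, 0), c(-2, 0, 0), c(0, 2, 0), c(0, -2, 0),
                 c(0, 0, 2), c(0, 0, -2),
                 2 * expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)) / sqrt(3))
  fx <- make_spheres(rbind(c(0, 0, 0), as.matrix(shell)))
  s <- shrake_rupley(fx$structure)
  expect_equal(s$per_atom[1], 0)
})

test_that("total surface area is invariant under rigid motion (0.1% at 960 points)", {
  bd <- make_bundle_dimer()
  s1 <- shrake_rupley(bd$structure)
  moved <- transform_structure(bd$structure,
                               rotation_matrix(0.7, c(1, 2, 3)), c(5, -3, 2))
  s2 <- shrake_rupley(moved)
  expect_lt(abs(sum(s1$per_atom) - sum(s2$per_atom)) / sum(s1$per_atom), 0.001)
})

test_that("surface area approaches convergence when the lattice is doubled", {
  bd <- make_bundle_dimer(n_res = 12)
  s1 <- sum(shrake_rupley(bd$structure)$per_atom)
  s2 <- sum(shrake_rupley(bd$structure,
                          analysis_config(sphere_points = 1920))$per_atom)
  expect_lt(abs(s1 - s2) / s1, 0.01)
})

test_that("total area decreases monotonically as two spheres approach", {
  tot <- vapply(c(6.5, 5.5, 4.5, 3.5, 2.5, 1.5), function(d) {
    sum(shrake_rupley(make_spheres(rbind(c(0, 0, 0), c(d, 0, 0)))$structure)$per_atom)
  }, numeric(1))
  expect_true(all(diff(tot) < 0))
})

test_that("per-atom areas agree with an independent implementation", {
  # cross-check against the biotite Shrake-Rupley on identical coordinates
  set.seed(42)
  n <- 15
  pos <- matrix(runif(n * 3, 0, 8), ncol = 3)
  fx <- make_spheres(pos)
  s <- shrake_rupley(fx$structure)
  coord_file <- withr::local_tempfile(fileext = ".csv")
  out_file <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3]),
                   coord_file, row.names = FALSE)
  script <- withr::local_tempfile(fileext = ".py")
  writeLines(c(
    "import sys",
    "import numpy as np",
    "import biotite.structure as struc",
    sprintf("xyz = np.loadtxt(%s, delimiter=',', skiprows=1)", shQuote(coord_file)),
    "n = xyz.shape[0]",
    "arr = struc.AtomArray(n)",
    "arr.coord = xyz",
    "arr.chain_id[:] = 'A'",
    "arr.res_id[:] = np.arange(1, n + 1)",
    "arr.res_name[:] = 'GLY'",
    "arr.atom_name[:] = 'CA'",
    "arr.element[:] = 'C'",
    "sasa = struc.sasa(arr, probe_radius=1.4, vdw_radii=np.full(n, 1.7), point_number=960)",
    sprintf("np.savetxt(%s, sasa)", shQuote(out_file))), script)
  status <- system2("python", script, stdout = TRUE, stderr = TRUE)
  expect_null(attr(status, "status"))
  oracle <- scan(out_file, quiet = TRUE)
  expect_lt(abs(sum(s$per_atom) - sum(oracle)) / sum(oracle), 0.02)
  expect_lt(max(abs(s$per_atom - oracle) / pmax(oracle, 1)), 0.10)
})

test_that("relative accessibility and buriedness follow the strict 15% cut", {
  bd <- make_bundle_dimer()
  s <- shrake_rupley(bd$structure)
  r <- relative_sasa(s, bd$structure)
  expect_equal(nrow(r), 40)
  expect_equal(r$rsa, 100 * r$sasa / r$max_asa_ref)
  expect_equal(r$buried, r$rsa < 15)
  # boundary is strict: exactly 15% is not buried
  mock <- s
  key <- r$key[1]
  mock$per_residue[key] <- 0.15 * r$max_asa_ref[1]
  r2 <- relative_sasa(mock, bd$structure)
  expect_false(r2$buried[r2$key == key])
  mock$per_residue[key] <- 0.1499 * r$max_asa_ref[1]
  r3 <- relative_sasa(mock, bd$structure)
  expect_true(r3$buried[r3$key == key])
})

test_that("miller reference changes RSA but not the raw areas", {
  bd <- make_bundle_dimer(n_res = 10)
  s <- shrake_rupley(bd$structure)
  rt <- relative_sasa(s, bd$structure, max_asa = "tien")
  rm_ <- relative_sasa(s, bd$structure, max_asa = "miller")
  expect_equal(rt$sasa, rm_$sasa)
  expect_false(isTRUE(all.equal(rt$rsa, rm_$rsa)))
})

test_that("buried surface on complexation is positive only at the contact zone", {
  bd <- make_bundle_dimer()
  dv <- delta_sasa_on_complexation(bd$structure, "A")
  expect_true(all(dv >= 0))
  expect_gt(dv[["A:1"]], 1)     # ground-truth contact residue
  expect_equal(dv[["A:10"]], 0) # faces away from the partner chain
  # two far-apart chains bury nothing
  far <- bd$structure
  selb <- far$atoms$chain == "B"
  far$atoms$x[selb] <- far$atoms$x[selb] + 100
  dv_far <- delta_sasa_on_complexation(far, "A")
  expect_equal(max(dv_far), 0)
  expect_error(delta_sasa_on_complexation(get_chain(bd$structure, "A"), "A"),
               "2 chains")
  expect_error(delta_sasa_on_complexation(bd$structure, "Q"), "unknown chain")
})
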