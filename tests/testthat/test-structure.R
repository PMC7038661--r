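# PDB round trips, minimum-distance geometry, proximity matrix, and the
# rule-based conformational-bias classification.

test_that("synthetic structures round-trip through PDB at format precision", {
  st <- simulate_structure(30, displacement = c(1, 2, -1), seed = 31)
  pdb <- tempfile(fileext = ".pdb")
  write_pdb(st$A, pdb)
  back <- read_structure(pdb, "oxidized")
  expect_equal(nrow(back$atoms), nrow(st$A$atoms))
  expect_equal(back$atoms$x, st$A$atoms$x, tolerance = 5e-4)
  expect_equal(back$atoms$y, st$A$atoms$y, tolerance = 5e-4)
  expect_equal(back$atoms$z, st$A$atoms$z, tolerance = 5e-4)
  expect_identical(back$atoms$resno, st$A$atoms$resno)
})

test_that("hydrogens are dropped and altlocs resolve to highest occupancy", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  H   ALA A   1       0.500   0.000   0.000  1.00  0.00           H",
    "ATOM      3  CB AALA A   1       1.000   0.000   0.000  0.30  0.00           C",
    "ATOM      4  CB BALA A   1       2.000   0.000   0.000  0.70  0.00           C",
    "ATOM      5  CA  GLY A   2       3.000   4.000   0.000  1.00  0.00           C",
    "END"), pdb)
  m <- read_structure(pdb, "reduced")
  expect_equal(nrow(m$atoms), 3L)           # H dropped, one CB kept
  cb <- m$atoms[m$atoms$atom == "CB", ]
  expect_equal(cb$x, 2)                      # the 0.70-occupancy copy
  # min-heavy uses the kept CB at (2,0,0); CA-CA is the 3-4-5 distance
  expect_equal(residue_min_distance(m, 1, 2), sqrt(17))
  expect_equal(residue_min_distance(m, 1, 2, metric = "ca"), 5)
  expect_error(read_structure(tempfile(), "x"))
})

test_that("minimum residue distance matches the exhaustive oracle and is symmetric", {
  st <- simulate_structure(30, seed = 32)
  m <- st$A
  resnos <- unique(m$atoms$resno)
  set.seed(32)
  pairs <- cbind(sample(resnos, 15, TRUE), sample(resnos, 15, TRUE))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    d <- residue_min_distance(m, a, b)
    expect_equal(d, brute_min_distance(m, a, b), tolerance = 1e-9)
    expect_equal(d, residue_min_distance(m, b, a), tolerance = 1e-12)
  }
  expect_equal(residue_min_distance(m, resnos[1], resnos[1]), 0)
  expect_error(residue_min_distance(m, 1, 999), "999")
})

test_that("adding atoms can only shrink or preserve the minimum distance", {
  st <- simulate_structure(10, seed = 33)
  m <- st$A
  d0 <- residue_min_distance(m, 1, 5)
  extra <- m$atoms[m$atoms$resno == 1, ][1, ]
  extra$atom <- "CZ"
  extra$x <- extra$x + 1    # anywhere
  m2 <- structure_model(rbind(m$atoms, extra), m$conformer)
  expect_lte(residue_min_distance(m2, 1, 5), d0 + 1e-12)
})

test_that("region membership uses inclusive 1-based bounds", {
  expect_setequal(region_membership(208), c("flexible_loop", "redox_loop"))
  expect_identical(region_membership(199), "redox_loop")
  expect_identical(region_membership(213), "flexible_loop")
  expect_length(region_membership(100), 0L)
})

test_that("proximity matrix agrees with closed-form geometry and flags missing cells", {
  # residues on a line 10 A apart; feature residues at known positions
  coords <- cbind(seq(0, 2200, by = 10), 0, 0)
  ox <- point_structure(coords[1:221, , drop = FALSE], conformer = "oxidized")
  red <- point_structure(coords[1:221, , drop = FALSE] + 5, conformer = "reduced")
  muts <- data.frame(wt = c("C", "T"), position = c(208L, 100L),
                     var = c("Y", "A"), origin = "E. coli")
  pm <- proximity_matrix(ox, red, muts)
  # mutation at a feature residue: distance zero in both conformers
  self <- pm[pm$mutation == "C208Y" & pm$feature == "Cys208", ]
  expect_equal(self$distance, c(0, 0))
  # linear geometry: |resno difference| * 10
  row <- pm[pm$mutation == "T100A" & pm$feature == "Cys199", ]
  expect_equal(row$distance, c(990, 990))
  expect_false(any(pm$missing))
  # swapping conformer inputs relabels, never changes values
  pm_sw <- proximity_matrix(red, ox, muts)
  a <- pm[pm$conformer == "oxidized", "distance"]
  b <- pm_sw[pm_sw$conformer == "reduced", "distance"]
  expect_equal(a, b)
  # unresolved position: flagged missing cells plus a warning
  short <- point_structure(coords[1:150, , drop = FALSE])
  expect_warning(pm2 <- proximity_matrix(short, short,
                                         data.frame(wt = "C", position = 208L,
                                                    var = "Y")),
                 "unresolved")
  expect_true(all(pm2$missing[pm2$mutation == "C208Y"]))
  expect_true(all(is.na(pm2$distance[pm2$missing])))
})

test_that("proximity cells equal the exhaustive oracle on random fixtures", {
  st <- simulate_structure(220, seed = 34,
                           displacement = matrix(rnorm(660), 220))
  muts <- oxyr_ale_mutations()
  pm <- proximity_matrix(st$A, st$B, muts)
  models <- list(oxidized = st$A, reduced = st$B)
  ok <- !pm$missing
  expect_true(all(ok))
  for (i in which(ok)) {
    d <- brute_min_distance(models[[pm$conformer[i]]],
                            pm$feature_resno[i], pm$position[i])
    expect_equal(pm$distance[i], d, tolerance = 1e-9)
  }
})

test_that("classification follows region-first rules with distance fallback", {
  st <- simulate_structure(220, seed = 35)
  pm <- proximity_matrix(st$A, st$B, oxyr_ale_mutations())
  # A213P: flexible loop (213 outside the redox loop, inside [205, 216])
  c213 <- classify_mutation("A213P", pm[pm$mutation == "A213P", ])
  expect_identical(c213$label, "favors_oxidized")
  expect_match(c213$evidence, "flexible loop")
  # C208G: redox loop wins over the flexible loop it also sits in
  c208 <- classify_mutation("C208G", pm[pm$mutation == "C208G", ])
  expect_identical(c208$label, "destabilizes_reduced")
  expect_match(c208$evidence, "redox loop")
  # P107L: proline arrangement
  c107 <- classify_mutation("P107L", pm[pm$mutation == "P107L", ])
  expect_identical(c107$label, "proline_interface")
  # far from everything, outside all regions: ambiguous
  far <- point_structure(rbind(c(0, 0, 0), c(1000, 0, 0)), resno = c(199, 50))
  pm_far <- proximity_matrix(far, far, data.frame(wt = "A", position = 50L,
                                                  var = "V"))
  c_far <- classify_mutation("A50V", pm_far[pm_far$mutation == "A50V", ])
  expect_identical(c_far$label, "ambiguous")
  # classification is pure in the feature order
  shuf <- pm[pm$mutation == "A213P", ]
  shuf <- shuf[sample(nrow(shuf)), ]
  expect_identical(classify_mutation("A213P", shuf)$label, c213$label)
  expect_error(classify_mutation("A213P", pm[0, ]), "empty")
})
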