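# Generators: construction consistency, determinism, noise calibration.

test_that("zero-noise expression matrices factor exactly and non-members stay zero", {
  m <- modulon_spec("OxyR", c("g0001", "g0002", "g0003"), c(1, -2, 0.5),
                    c(a = 0, b = 5))
  sim <- simulate_expression(list(m), c(a = 1L, b = 1L), n_genes = 10,
                             noise_sd = 0, seed = 1)
  expect_equal(sim$expr$values, sim$S_true %*% sim$A_true)
  non_members <- setdiff(rownames(sim$expr$values), m$member_genes)
  expect_true(all(sim$expr$values[non_members, ] == 0))
  # member rows scale with planted activity
  expect_equal(sim$expr$values["g0002", "b_r1"], -2 * 5)
})

test_that("expression generator is bitwise deterministic and replicates share activities", {
  mods <- make_study_modulons()
  s1 <- simulate_expression(mods, c(wt = 3L, evo1 = 3L), n_genes = 300,
                            noise_sd = 0.3, seed = 42)
  s2 <- simulate_expression(mods, c(wt = 3L, evo1 = 3L), n_genes = 300,
                            noise_sd = 0.3, seed = 42)
  expect_identical(s1$expr$values, s2$expr$values)
  cond <- s1$expr$samples$condition
  for (cc in unique(cond)) {
    a <- s1$A_true[, cond == cc, drop = FALSE]
    expect_true(all(a == a[, 1L]))
  }
})

test_that("residual Frobenius norm matches the noise model's chi-square expectation", {
  # ||X - S A||_F^2 ~ sigma^2 * chisq(G * N): mean n*s^2, var 2n*s^4
  sigma <- 0.25
  conds <- setNames(rep(3L, 8L), letters[1:8])
  set.seed(3)
  mods <- list(
    modulon_spec("OxyR", sprintf("g%04d", 1:25), runif(25, 0.5, 1.5),
                 setNames(rnorm(8, sd = 3), letters[1:8])),
    modulon_spec("LexA", sprintf("g%04d", 31:52), runif(22, 0.5, 1.5),
                 setNames(rnorm(8, sd = 3), letters[1:8])))
  sim <- simulate_expression(mods, conds, n_genes = 500, noise_sd = sigma,
                             seed = 3)
  n <- length(sim$expr$values)
  f2 <- sum((sim$expr$values - sim$S_true %*% sim$A_true)^2)
  expect_lt(abs(f2 - n * sigma^2), 3 * sqrt(2 * n) * sigma^2)
})

test_that("conflicting weights and empty condition lists are rejected", {
  expect_error(modulon_spec("x", c("g0001", "g0001"), c(1, 2), c(a = 1)),
               "conflicting")
  m <- modulon_spec("x", "g0001", 1, c(a = 1))
  expect_error(simulate_expression(list(m), integer(0), n_genes = 5, seed = 1),
               "non-empty")
  expect_error(modulon_spec("x", character(0), numeric(0), c(a = 1)),
               "non-empty")
})

test_that("allele generator: duplicates, planted substitutions, truth table", {
  ref <- synthetic_oxyr_reference(seed = 5)
  # all-duplicate background
  col <- simulate_alleles(ref, n_background = 5, duplicate_rate = 1, seed = 5)
  expect_true(all(col$records$dna == ref$cds))
  expect_equal(length(unique(col$records$dna)), 1L)
  # planted R201C lands at position 201
  col2 <- simulate_alleles(ref, n_background = 0,
                           planted = list(planted_variant("gA", "R", 201, "C")),
                           seed = 5)
  prot <- translate_and_dedup(col2$records)$proteins$protein
  expect_identical(substr(prot, 201, 201), "C")
  expect_identical(substr(ref$protein, 201, 201), "R")
  # wild-type mismatch is rejected with the position named
  expect_error(
    simulate_alleles(ref, planted = list(planted_variant("gB", "K", 201, "C")),
                     seed = 5),
    "position 201")
  # the seven isolate substitutions give exactly seven candidates in truth
  col3 <- simulate_alleles(ref, n_background = 50,
                           planted = make_isolate_plant(), seed = 5)
  expect_equal(sum(col3$truth$is_candidate), 7L)
  # background genomes differ from reference only synonymously
  bg <- col3$records[grepl("^bg", col3$records$genome_id), ]
  bg_prot <- translate_and_dedup(bg)$proteins$protein
  expect_true(all(bg_prot == ref$protein))
})

test_that("allele collections round-trip through FASTA with their truth table", {
  ref <- synthetic_oxyr_reference(seed = 6)
  col <- simulate_alleles(ref, n_background = 4,
                          planted = list(planted_variant("gA", "R", 201, "S")),
                          seed = 6)
  fa <- tempfile(fileext = ".fasta")
  write_alleles(col, fa)
  back <- read_alleles(fa)
  expect_identical(back$dna[match(col$records$genome_id, back$genome_id)],
                   col$records$dna)
  expect_equal(attr(back, "truth")$substitution, col$truth$substitution)
})

test_that("structure generator: identity under zero displacement, exact geometry", {
  st <- simulate_structure(10, displacement = NULL, seed = 7)
  expect_identical(st$A$atoms[, c("x", "y", "z")], st$B$atoms[, c("x", "y", "z")])
  # per-residue rigid displacement shows up verbatim in conformer B
  D <- matrix(rnorm(30), 10, 3)
  st2 <- simulate_structure(10, displacement = D, seed = 7)
  shift <- as.matrix(st2$B$atoms[, c("x", "y", "z")]) -
    as.matrix(st2$A$atoms[, c("x", "y", "z")])
  expect_equal(unname(shift), unname(D[st2$A$atoms$resno, ]), tolerance = 1e-12)
  # 3-4-5 triangle
  ps <- point_structure(rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(residue_min_distance(ps, 1, 2), 5)
  expect_error(point_structure(rbind(c(0, 0, 0), c(1, 1, 1)), resno = c(1, 1)),
               "duplicate")
})

test_that("growth generator: exact baseline before lag, no-growth doses stay flat", {
  g <- simulate_growth_curves(c("0" = 2), noise_sd = 0, n_replicates = 1,
                              baseline_od = 0.02, seed = 8)
  pre <- g$curves[g$curves$time_h < 2, ]
  expect_true(all(pre$od == 0.02))
  post <- g$curves[g$curves$time_h > 4, ]
  expect_true(all(post$od > 0.02))
  ng <- simulate_growth_curves(c("5" = NA), noise_sd = 0.003, n_replicates = 2,
                               seed = 8)
  expect_lt(max(ng$curves$od) - 0.02, 0.05)
  expect_error(simulate_growth_curves(c("0" = 1), sampling_interval = 0),
               "sampling_interval")
})

test_that("all generators are reproducible under a fixed seed", {
  expect_identical(simulate_structure(8, seed = 9), simulate_structure(8, seed = 9))
  expect_identical(simulate_growth_curves(c("0" = 1, "1" = 2), seed = 9),
                   simulate_growth_curves(c("0" = 1, "1" = 2), seed = 9))
  ref <- synthetic_oxyr_reference(seed = 9)
  expect_identical(ref, synthetic_oxyr_reference(seed = 9))
  expect_identical(simulate_alleles(ref, 10, seed = 9),
                   simulate_alleles(ref, 10, seed = 9))
})
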