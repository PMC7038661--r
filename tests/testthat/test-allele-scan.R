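# Dedup/translate, alignment statistics, substitution calling, screening
# and cross-species position mapping.

test_that("DNA and protein deduplication count code degeneracy correctly", {
  cds <- "ATGGCTCGT"              # M A R
  same <- c(g1 = cds, g2 = cds, g3 = cds, g4 = cds, g5 = cds)
  dd <- translate_and_dedup(data.frame(genome_id = names(same), dna = same))
  expect_equal(unname(dd$counts[c("n_unique_dna", "n_unique_protein")]), c(1L, 1L))
  # one synonymous change: two DNA groups, one protein group
  syn <- data.frame(genome_id = c("a", "b"), dna = c("ATGGCTCGT", "ATGGCCCGT"))
  dd2 <- translate_and_dedup(syn)
  expect_equal(unname(dd2$counts[c("n_unique_dna", "n_unique_protein")]), c(2L, 1L))
  expect_true(unname(dd2$counts["n_unique_protein"] <= dd2$counts["n_unique_dna"]))
})

test_that("pseudogenes, ambiguity codes and frame problems are flagged and excluded", {
  recs <- data.frame(
    genome_id = c("ok", "stop", "amb", "frame"),
    dna = c("ATGGCTCGTTAA",       # clean, terminal stop trimmed
            "ATGTAACGTTAA",       # internal stop
            "ATGNCTCGT",          # ambiguity code
            "ATGGCTCG"))          # length not a codon multiple
  dd <- translate_and_dedup(recs)
  expect_identical(dd$proteins$genome_id, "ok")
  expect_identical(dd$proteins$protein, "MAR")
  expect_setequal(dd$flagged$genome_id, c("stop", "amb", "frame"))
  expect_identical(dd$flagged$reason[dd$flagged$genome_id == "stop"],
                   "internal_stop_pseudogene")
})

test_that("dedup counts equal generator truth on planted collections", {
  ref <- synthetic_oxyr_reference(seed = 41)
  col <- simulate_alleles(ref, n_background = 40,
                          planted = make_isolate_plant(), seed = 41)
  dd <- translate_and_dedup(col$records)
  expect_equal(unname(dd$counts["n_genomes"]), 47L)
  expect_equal(unname(dd$counts["n_unique_dna"]),
               length(unique(col$records$dna)))
  prots <- vapply(col$records$dna, function(s) {
    p <- paste(Biostrings::getGeneticCode("11")[substring(
      s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))], collapse = "")
    sub("\\*$", "", p)
  }, "")
  expect_equal(unname(dd$counts["n_unique_protein"]), length(unique(prots)))
})

test_that("global alignment identity and similarity follow their definitions", {
  a <- "MKVLITRA"
  self <- pairwise_align(a, a)
  expect_equal(self$percent_identity, 100)
  expect_equal(self$percent_similarity, 100)
  # one terminal deletion: 3 identical pairs over alignment length 4
  d <- pairwise_align("ACDE", "ACD")
  expect_equal(d$length, 4L)
  expect_equal(d$percent_identity, 75)
  # swap symmetry
  ref <- synthetic_oxyr_reference(seed = 42)$protein
  other <- paste0(substr(ref, 1, 150), substr(ref, 161, nchar(ref)))
  ab <- pairwise_align(ref, other)
  ba <- pairwise_align(other, ref)
  expect_equal(ab$score, ba$score)
  expect_equal(ab$percent_identity, ba$percent_identity)
  expect_equal(ab$percent_similarity, ba$percent_similarity)
  expect_error(pairwise_align("ACDZ1", "ACD"), "non-amino-acid")
})

test_that("identity equals 1 - k/L for constructed gap-free mutants", {
  set.seed(43)
  ref <- synthetic_oxyr_reference(seed = 43)$protein
  L <- nchar(ref)
  for (k in c(3L, 20L, 60L)) {
    chars <- strsplit(ref, "")[[1]]
    pos <- sample(L, k)
    for (p in pos) {
      chars[p] <- setdiff(c("A", "G", "V", "L", "K"), chars[p])[1]
    }
    mut <- paste(chars, collapse = "")
    al <- pairwise_align(ref, mut)
    expect_equal(al$length, L)
    expect_equal(al$percent_identity, 100 * (1 - k / L), tolerance = 1e-12)
  }
})

test_that("substitution calls match planted truth and format as wt-pos-var", {
  ref <- synthetic_oxyr_reference(seed = 44)
  expect_equal(nrow(call_substitutions(ref$protein, ref$protein)), 0L)
  col <- simulate_alleles(ref, n_background = 0,
                          planted = list(planted_variant("gA", "R", 201, "C"),
                                         planted_variant("gB", "A", 147, "V",
                                                         synonymous_extras = 2)),
                          seed = 44)
  prots <- translate_and_dedup(col$records)$proteins
  c1 <- call_substitutions(prots$protein[prots$genome_id == "gA"], ref$protein)
  expect_identical(c1$substitution, "R201C")
  c2 <- call_substitutions(prots$protein[prots$genome_id == "gB"], ref$protein)
  expect_identical(c2$substitution, "A147V")   # synonymous extras invisible
  # multi-substitution variants come back sorted by position
  chars <- strsplit(ref$protein, "")[[1]]
  chars[c(250, 10)] <- c("W", "W")
  multi <- call_substitutions(paste(chars, collapse = ""), ref$protein)
  expect_equal(multi$position, sort(c(10L, 250L)))
  # unrelated sequence rejected
  expect_error(call_substitutions(paste(rep("W", 300), collapse = ""),
                                  ref$protein), "identity")
})

test_that("indels are reported separately and never matched as substitutions", {
  ref <- "MKVLITRAGDEF"
  gap <- "MKVLITGDEF"              # RA deleted
  calls <- call_substitutions(gap, ref)
  expect_equal(nrow(calls), 0L)
  ind <- attr(calls, "indels")
  expect_equal(nrow(ind), 1L)
  expect_identical(ind$type, "deletion")
  expect_equal(ind$length, 2L)
})

test_that("screening flags by rule and reports the shared-substitution tally", {
  ref <- synthetic_oxyr_reference(seed = 45)
  col <- simulate_alleles(ref, n_background = 50,
                          planted = make_isolate_plant(), seed = 45)
  res <- scan_alleles(col$records, ref$protein, rule = "position")
  expect_equal(unname(res$counts["n_flagged"]), 7L)
  expect_equal(unname(res$counts["n_shared_substitution"]), 2L)
  expect_setequal(res$rows$genome_id, natural_isolate_variants()$genome_id)
  expect_true(all(res$counts["n_flagged"] <= res$counts["n_genomes"]))
  expect_true(all(nzchar(res$rows$evidence)))
  # exact rule: A213T does not match the observed A213P/E variants
  res_exact <- scan_alleles(col$records, ref$protein, rule = "exact")
  expect_false("562.10507" %in% res_exact$rows$genome_id)
  expect_true("1280958.3" %in% res_exact$rows$genome_id)  # R201C, any-var ref
  # idempotence: re-screening the flagged subset re-flags the same genomes
  sub <- col$records[col$records$genome_id %in% res$rows$genome_id, ]
  res2 <- scan_alleles(sub, ref$protein, rule = "position")
  expect_setequal(res2$rows$genome_id, res$rows$genome_id)
  expect_error(screen_constitutive(list(), refset = data.frame()), "empty")
})

test_that("positions map across homologs through the alignment columns", {
  ref <- synthetic_oxyr_reference(seed = 46)$protein
  al_self <- pairwise_align(ref, ref)
  for (p in c(1L, 99L, 201L, nchar(ref))) {
    expect_equal(map_position(al_self, position_in_a = p), p)
  }
  # a 3-residue insertion in B before position 100 shifts mapping by +3
  b <- paste0(substr(ref, 1, 99), "GGG", substr(ref, 100, nchar(ref)))
  al <- pairwise_align(ref, b)
  expect_equal(map_position(al, position_in_a = 100L), 103L)
  expect_equal(map_position(al, position_in_a = 50L), 50L)
  # a deletion in B leaves the deleted positions unaligned
  d <- paste0(substr(ref, 1, 99), substr(ref, 103, nchar(ref)))
  al_d <- pairwise_align(ref, d)
  m <- map_position(al_d, position_in_a = 101L)
  expect_true(is.na(m))
  expect_true(isTRUE(attr(m, "unaligned")))
  expect_error(map_position(al, position_in_a = 5000L), "beyond")
})
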