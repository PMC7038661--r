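# Small fixture builders shared across test files. Everything is generated
# in code under fixed seeds; nothing is read from disk.

# a compact planted-modulon study: 300-gene universe, OxyR-like group
# elevated in evolved conditions, LexA-like responding in gmos, SoxS-like
# flat (null control)
make_study_modulons <- function(seed = 10) {
  set.seed(seed)
  list(
    modulon_spec("OxyR", sprintf("g%04d", 1:25), runif(25, 0.5, 1.5),
                 c(wt = 0, gmos = 0.5, evo1 = 8, evo2 = 8)),
    modulon_spec("LexA", sprintf("g%04d", 31:52), runif(22, 0.5, 1.5),
                 c(wt = 0, gmos = 5, evo1 = 0, evo2 = 0)),
    modulon_spec("SoxS", sprintf("g%04d", 61:80), runif(20, 0.5, 1.5),
                 c(wt = 0.5, gmos = 0.5, evo1 = 0.5, evo2 = 0.5))
  )
}

make_study <- function(seed = 10, noise_sd = 0.25, n_genes = 300) {
  simulate_expression(make_study_modulons(seed),
                      c(wt = 3L, gmos = 3L, evo1 = 3L, evo2 = 3L),
                      n_genes = n_genes, noise_sd = noise_sd, seed = seed)
}

# the planted-variant list mirroring the natural-isolate substitutions
make_isolate_plant <- function(synonymous_extras = 1L) {
  v <- natural_isolate_variants()
  lapply(seq_len(nrow(v)), function(i) {
    s <- v$substitution[i]
    planted_variant(v$genome_id[i],
                    wt = substr(s, 1L, 1L),
                    position = as.integer(gsub("[^0-9]", "", s)),
                    var = substr(s, nchar(s), nchar(s)),
                    synonymous_extras = synonymous_extras)
  })
}

# independent exhaustive all-atom-pair minimum distance (the oracle kept
# deliberately naive: triple loop, no vectorized shortcut shared with the
# implementation)
brute_min_distance <- function(model, resA, resB) {
  a <- model$atoms[model$atoms$resno == resA, c("x", "y", "z")]
  b <- model$atoms[model$atoms$resno == resB, c("x", "y", "z")]
  best <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum((as.numeric(a[i, ]) - as.numeric(b[j, ]))^2))
      if (d < best) best <- d
    }
  }
  best
}

# exact hypergeometric upper tail by direct summation of point masses
brute_hyper_tail <- function(overlap, regulon, members, universe) {
  ks <- overlap:min(regulon, members)
  sum(vapply(ks, function(k) {
    exp(lchoose(regulon, k) + lchoose(universe - regulon, members - k) -
          lchoose(universe, members))
  }, 0))
}
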