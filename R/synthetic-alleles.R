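# Synthetic allele collections: a reference OxyR-like coding sequence plus
# genomes carrying planted nonsynonymous substitutions, synonymous changes
# and exact duplicates, with a truth table for round-trip testing.

.cache <- new.env(parent = emptyenv())

.genetic_code <- function() {
  if (is.null(.cache$gc11)) .cache$gc11 <- Biostrings::getGeneticCode("11")
  .cache$gc11
}

.codons_for <- function(aa) {
  gc <- .genetic_code()
  names(gc)[gc == aa]
}

#' Synthetic reference OxyR protein and coding sequence
#'
#' A 305-residue random protein with the functionally important positions of
#' E. coli OxyR pinned to their wild-type identities (redox cysteines C199
#' and C208, R201, the proline arrangement P99/103/107/111, T100, L113,
#' H114, T129, A147, D172, L200, A213), so that substitution calling,
#' screening and structure mapping operate on realistic coordinates. The
#' sequence is synthetic: everything outside the pinned positions is random.
#'
#' @param length protein length (default 305, the length of E. coli OxyR).
#' @param seed integer seed.
#' @return list with `protein` (character, single string), `cds` (character,
#'   includes a terminal stop codon) and `pinned` (named integer vector of
#'   fixed positions).
#' @export
synthetic_oxyr_reference <- function(length = 305L, seed = 0L) {
  length <- .check_count(length, "length", min = 220L)
  pinned <- c(P = 99L, T = 100L, P = 103L, P = 107L, P = 111L, L = 113L,
              H = 114L, T = 129L, A = 147L, D = 172L, C = 199L, L = 200L,
              R = 201L, C = 208L, A = 213L)
  set.seed(.derive_seed(seed, "reference"))
  aas <- setdiff(unique(.genetic_code()), "*")
  prot <- sample(aas, length, replace = TRUE)
  prot[pinned] <- names(pinned)
  cds <- vapply(prot, function(a) {
    cods <- .codons_for(a)
    cods[sample.int(length(cods), 1L)]
  }, "")
  list(protein = paste(prot, collapse = ""),
       cds = paste(c(cds, "TAA"), collapse = ""),
       pinned = pinned)
}

#' Specify a variant to plant in a synthetic allele collection
#'
#' @param genome_id unique genome label.
#' @param wt,position,var the amino-acid substitution (1-based position in
#'   the reference protein).
#' @param synonymous_extras number of additional synonymous codon changes.
#' @return object of class `planted_variant`.
#' @export
planted_variant <- function(genome_id, wt, position, var,
                            synonymous_extras = 0L) {
  structure(list(genome_id = genome_id, wt = wt,
                 position = .check_count(position, "position", min = 1L),
                 var = var,
                 synonymous_extras = .check_count(synonymous_extras,
                                                  "synonymous_extras")),
            class = "planted_variant")
}

#' Substitutions reported in natural E. coli isolates
#'
#' The seven OxyR sequence changes found by screening natural-isolate
#' genomes against the constitutive-activation reference set (R201C occurs
#' twice), with their antimicrobial-resistance metadata.
#'
#' @return data.frame with columns `genome_id`, `substitution`, `amr`.
#' @export
natural_isolate_variants <- function() {
  data.frame(
    genome_id = c("1280958.3", "562.23930", "562.23771", "562.10507",
                  "562.31230", "562.22907", "562.23860"),
    substitution = c("R201C", "R201C", "R201S", "A213T", "P107T",
                     "A147V", "L200V"),
    amr = c("N.A.", "Amoxicillin resistant", "Amoxicillin susceptible",
            "N.A.", "N.A.", "Amoxicillin susceptible",
            "Amoxicillin resistant"),
    stringsAsFactors = FALSE
  )
}

.split_codons <- function(cds) {
  substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
}

.syn_change <- function(codons, at_positions, n, rng_exclude = integer()) {
  # apply n synonymous codon swaps at random eligible positions
  gc <- .genetic_code()
  eligible <- setdiff(at_positions, rng_exclude)
  eligible <- eligible[vapply(eligible, function(i) {
    length(.codons_for(gc[[codons[i]]])) > 1L
  }, TRUE)]
  if (length(eligible) == 0L || n == 0L) return(codons)
  sel <- sample(eligible, min(n, length(eligible)))
  for (i in sel) {
    alts <- setdiff(.codons_for(gc[[codons[i]]]), codons[i])
    codons[i] <- alts[sample.int(length(alts), 1L)]
  }
  codons
}

#' Simulate an allele collection with planted substitutions
#'
#' Builds DNA coding sequences for background genomes (exact duplicates of
#' the reference with probability `duplicate_rate`, otherwise carrying 1-3
#' synonymous changes) and for planted genomes (exactly the specified
#' nonsynonymous substitution plus the requested synonymous extras).
#'
#' @param reference list with `protein` and `cds` as returned by
#'   [synthetic_oxyr_reference()].
#' @param n_background number of background genomes.
#' @param planted list of [planted_variant()] objects.
#' @param duplicate_rate probability that a background genome is an exact
#'   duplicate of the reference CDS.
#' @param seed integer seed.
#' @return object of class `allele_collection`: list with `records`
#'   (data.frame: genome_id, dna), `truth` (data.frame: genome_id,
#'   substitution, n_synonymous, is_candidate) and `reference`.
#' @export
simulate_alleles <- function(reference, n_background = 50L, planted = list(),
                             duplicate_rate = 0.3, seed = 0L) {
  duplicate_rate <- .check_number(duplicate_rate, "duplicate_rate", 0, 1)
  n_background <- .check_count(n_background, "n_background")
  prot <- strsplit(reference$protein, "")[[1L]]
  ref_codons <- .split_codons(reference$cds)
  n_aa <- length(prot)
  has_stop <- length(ref_codons) == n_aa + 1L
  aa_pos <- seq_len(n_aa)
  tr <- .genetic_code()[ref_codons[aa_pos]]
  if (!identical(unname(tr), prot)) {
    stop("reference CDS does not translate to reference protein", call. = FALSE)
  }
  set.seed(.derive_seed(seed, "alleles"))
  recs <- list(); truth <- list()
  for (pv in planted) {
    if (pv$position > n_aa) {
      stop("planted position ", pv$position, " beyond reference length ",
           n_aa, call. = FALSE)
    }
    if (prot[pv$position] != pv$wt) {
      stop("planted wt '", pv$wt, "' does not match reference '",
           prot[pv$position], "' at position ", pv$position, call. = FALSE)
    }
    codons <- ref_codons
    var_codons <- .codons_for(pv$var)
    codons[pv$position] <- var_codons[sample.int(length(var_codons), 1L)]
    codons[aa_pos] <- .syn_change(codons[aa_pos], aa_pos,
                                  pv$synonymous_extras,
                                  rng_exclude = pv$position)
    recs[[pv$genome_id]] <- paste(codons, collapse = "")
    truth[[pv$genome_id]] <- data.frame(
      genome_id = pv$genome_id,
      substitution = paste0(pv$wt, pv$position, pv$var),
      n_synonymous = pv$synonymous_extras, is_candidate = TRUE,
      stringsAsFactors = FALSE)
  }
  for (b in seq_len(n_background)) {
    id <- sprintf("bg%04d", b)
    if (runif(1L) <= duplicate_rate) {
      recs[[id]] <- reference$cds
      n_syn <- 0L
    } else {
      n_syn <- sample(1:3, 1L)
      codons <- ref_codons
      codons[aa_pos] <- .syn_change(codons[aa_pos], aa_pos, n_syn)
      recs[[id]] <- paste(codons, collapse = "")
      n_syn <- sum(codons[aa_pos] != ref_codons[aa_pos])
    }
    truth[[id]] <- data.frame(genome_id = id, substitution = "",
                              n_synonymous = n_syn, is_candidate = FALSE,
                              stringsAsFactors = FALSE)
  }
  structure(list(
    records = data.frame(genome_id = names(recs),
                         dna = unlist(recs, use.names = FALSE),
                         stringsAsFactors = FALSE),
    truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
    reference = reference
  ), class = "allele_collection")
}

#' Write / read an allele collection as FASTA plus a truth-table TSV
#'
#' @param collection an `allele_collection`.
#' @param fasta_path DNA FASTA output (genome id as record id); the truth
#'   table is written next to it with suffix `.truth.tsv`.
#' @return `write_alleles` returns `fasta_path` invisibly; `read_alleles`
#'   returns a data.frame (genome_id, dna) and re-attaches the truth table
#'   as attribute `truth` when the sidecar exists.
#' @export
write_alleles <- function(collection, fasta_path) {
  stopifnot(inherits(collection, "allele_collection"))
  seqs <- Biostrings::DNAStringSet(collection$records$dna)
  names(seqs) <- collection$records$genome_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  write.table(collection$truth, paste0(fasta_path, ".truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}

#' @rdname write_alleles
#' @export
read_alleles <- function(fasta_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  out <- data.frame(genome_id = names(seqs), dna = as.character(seqs),
                    stringsAsFactors = FALSE)
  tp <- paste0(fasta_path, ".truth.tsv")
  if (file.exists(tp)) {
    attr(out, "truth") <- read.delim(tp, colClasses = c(
      genome_id = "character", substitution = "character"))
  }
  out
}
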