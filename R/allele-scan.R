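# Screening coding-sequence collections for OxyR alleles matching the
# constitutive-activation reference set: deduplication at DNA and protein
# level, substitution calling against the reference protein, position
# mapping across species, and the Table-shaped screen report.

.AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

.blosum62 <- function() {
  if (is.null(.cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .cache$blosum62 <- e$BLOSUM62
  }
  .cache$blosum62
}

#' Default constitutive-activation reference set
#'
#' Positions in the E. coli OxyR protein at which amino-acid substitutions
#' are recognized to activate OxyR constitutively: the positions hit during
#' laboratory evolution of E. coli and V. natriegens (mapped to E. coli
#' numbering) plus position 201 from promoter-activity mutant literature.
#'
#' @return data.frame with columns `position`, `var_aa` (NA = any variant)
#'   and `source`.
#' @export
constitutive_refset <- function() {
  ale <- oxyr_ale_mutations()
  src <- c("E. coli" = "ALE_Ecoli", "V. natriegens" = "ALE_Vnatriegens",
           "both" = "ALE_Ecoli")
  out <- data.frame(position = c(ale$position, 201L),
                    var_aa = c(ale$var, NA_character_),
                    source = c(unname(src[ale$origin]), "literature"),
                    stringsAsFactors = FALSE)
  out[!duplicated(out[, c("position", "var_aa")]), ]
}

.translate_cds <- function(dna) {
  codons <- .split_codons(dna)
  paste(.genetic_code()[codons], collapse = "")
}

#' Deduplicate an allele collection at DNA and protein level
#'
#' Records whose sequence contains ambiguity codes, or whose length is not a
#' multiple of three after trimming one terminal stop codon, are flagged and
#' excluded; records translating with an internal stop are flagged as
#' pseudogenes and excluded from the protein grouping.
#'
#' @param records data.frame with columns `genome_id`, `dna` (e.g. from
#'   [read_alleles()] or an [simulate_alleles()] collection's `$records`).
#' @return list with `proteins` (data.frame: genome_id, protein for callable
#'   records), `counts` (n_genomes, n_unique_dna, n_unique_protein),
#'   `dna_groups` / `protein_groups` (named membership lists) and `flagged`
#'   (data.frame: genome_id, reason).
#' @export
translate_and_dedup <- function(records) {
  stopifnot(is.data.frame(records), all(c("genome_id", "dna") %in% names(records)))
  if (anyDuplicated(records$genome_id)) {
    stop("genome ids must be unique", call. = FALSE)
  }
  flagged <- list()
  dna <- toupper(records$dna)
  ambiguous <- grepl("[^ACGT]", dna)
  for (i in which(ambiguous)) {
    flagged[[length(flagged) + 1L]] <-
      data.frame(genome_id = records$genome_id[i], reason = "ambiguity_codes")
  }
  ok <- !ambiguous
  prot <- rep(NA_character_, nrow(records))
  for (i in which(ok)) {
    s <- dna[i]
    if (nchar(s) %% 3L != 0L) {
      flagged[[length(flagged) + 1L]] <-
        data.frame(genome_id = records$genome_id[i], reason = "length_not_codon_multiple")
      ok[i] <- FALSE
      next
    }
    p <- .translate_cds(s)
    p <- sub("\\*$", "", p)             # trim one terminal stop
    if (grepl("\\*", p)) {
      flagged[[length(flagged) + 1L]] <-
        data.frame(genome_id = records$genome_id[i], reason = "internal_stop_pseudogene")
      ok[i] <- FALSE
      next
    }
    prot[i] <- p
  }
  valid <- which(!ambiguous & (ok | is.na(prot)))
  dna_valid <- which(!ambiguous)
  dna_groups <- split(records$genome_id[dna_valid], dna[dna_valid])
  prot_groups <- split(records$genome_id[ok], prot[ok])
  list(
    proteins = data.frame(genome_id = records$genome_id[ok],
                          protein = prot[ok], stringsAsFactors = FALSE),
    counts = c(n_genomes = nrow(records),
               n_unique_dna = length(dna_groups),
               n_unique_protein = length(prot_groups)),
    dna_groups = dna_groups, protein_groups = prot_groups,
    flagged = if (length(flagged)) do.call(rbind, flagged)
              else data.frame(genome_id = character(), reason = character())
  )
}

.check_protein <- function(s, what) {
  if (!is.character(s) || length(s) != 1L || nchar(s) == 0L) {
    stop(what, " must be a non-empty protein string", call. = FALSE)
  }
  bad <- setdiff(strsplit(s, "")[[1L]], .AA_LETTERS)
  if (length(bad)) {
    stop(what, " contains non-amino-acid symbol(s): ",
         paste(unique(bad), collapse = ", "), call. = FALSE)
  }
  s
}

#' Global pairwise protein alignment with identity and similarity
#'
#' Needleman-Wunsch global alignment under a BLOSUM62 substitution matrix.
#' Identity is the fraction of alignment columns with identical residues;
#' similarity the fraction with a positive substitution score (gap columns
#' count toward the length, never as identical or similar).
#'
#' @param a,b amino-acid sequences (single strings).
#' @param gap_open,gap_extend gap penalties (positive numbers; defaults 11
#'   and 1).
#' @param substitution_matrix scoring matrix (default BLOSUM62).
#' @return list with `aligned_a`, `aligned_b` (gapped strings of equal
#'   length), `score`, `length`, `percent_identity`, `percent_similarity`.
#' @export
pairwise_align <- function(a, b, gap_open = 11, gap_extend = 1,
                           substitution_matrix = NULL) {
  a <- .check_protein(a, "a"); b <- .check_protein(b, "b")
  if (is.null(substitution_matrix)) substitution_matrix <- .blosum62()
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(pa, "")[[1L]]
  cb <- strsplit(pb, "")[[1L]]
  len <- length(ca)
  no_gap <- ca != "-" & cb != "-"
  ident <- sum(no_gap & ca == cb)
  simil <- sum(vapply(which(no_gap), function(i)
    substitution_matrix[ca[i], cb[i]] > 0, TRUE))
  list(aligned_a = pa, aligned_b = pb, score = Biostrings::score(aln),
       length = len,
       percent_identity = 100 * ident / len,
       percent_similarity = 100 * simil / len)
}

#' Call amino-acid substitutions of a variant protein against a reference
#'
#' Globally aligns the variant to the reference and reports one record per
#' mismatched aligned residue pair in reference numbering (`wt`, `position`,
#' `var`, formatted like "R201C"). Gapped columns are reported separately as
#' indels and never enter substitution matching.
#'
#' @param variant_protein,reference_protein amino-acid sequences.
#' @param min_identity reject alignments below this fractional identity
#'   (default 0.5; a lower value usually means the wrong gene).
#' @param ... passed to [pairwise_align()].
#' @return data.frame with columns `wt`, `position`, `var`, `substitution`;
#'   attribute `indels` holds a data.frame of gap events (position, type,
#'   length); attribute `identity` the percent identity.
#' @export
call_substitutions <- function(variant_protein, reference_protein,
                               min_identity = 0.5, ...) {
  if (identical(variant_protein, reference_protein)) {
    out <- data.frame(wt = character(), position = integer(),
                      var = character(), substitution = character(),
                      stringsAsFactors = FALSE)
    attr(out, "indels") <- data.frame(position = integer(), type = character(),
                                      length = integer())
    attr(out, "identity") <- 100
    return(out)
  }
  aln <- pairwise_align(reference_protein, variant_protein, ...)
  if (aln$percent_identity < 100 * min_identity) {
    stop("alignment identity ", round(aln$percent_identity, 1),
         "% below threshold ", 100 * min_identity,
         "%: likely not the same gene", call. = FALSE)
  }
  cr <- strsplit(aln$aligned_a, "")[[1L]]
  cv <- strsplit(aln$aligned_b, "")[[1L]]
  ref_pos <- cumsum(cr != "-")
  subs <- which(cr != "-" & cv != "-" & cr != cv)
  out <- data.frame(wt = cr[subs], position = ref_pos[subs], var = cv[subs],
                    stringsAsFactors = FALSE)
  out <- out[order(out$position), , drop = FALSE]
  out$substitution <- paste0(out$wt, out$position, out$var)
  gap <- cr == "-" | cv == "-"
  if (any(gap)) {
    r <- rle(gap)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    gi <- which(r$values)
    indels <- data.frame(
      position = ref_pos[pmax(starts[gi] - 1L, 1L)],
      type = ifelse(cr[starts[gi]] == "-", "insertion", "deletion"),
      length = r$lengths[gi])
  } else {
    indels <- data.frame(position = integer(), type = character(),
                         length = integer())
  }
  rownames(out) <- NULL
  attr(out, "indels") <- indels
  attr(out, "identity") <- aln$percent_identity
  out
}

#' Screen substitution calls against the constitutive reference set
#'
#' Under `rule = "position"` a genome is flagged when it carries any
#' nonsynonymous change at a reference-set position; `rule = "exact"`
#' additionally requires the variant residue to match. The report also
#' tallies how many flagged genomes share an identical substitution with
#' another flagged genome.
#'
#' @param calls named list: genome id -> substitution data.frame from
#'   [call_substitutions()].
#' @param refset data.frame with columns `position`, `var_aa` (NA matches
#'   any variant) and `source` (default [constitutive_refset()]).
#' @param rule matching rule, `"position"` or `"exact"`.
#' @param metadata optional data.frame keyed by `genome_id` whose remaining
#'   columns are passed through to the report rows.
#' @param counts optional named vector from [translate_and_dedup()] to embed
#'   in the result.
#' @return object of class `screen_result`: list with `rows` (data.frame:
#'   genome_id, substitution, evidence, metadata passthrough), `counts`
#'   (incl. `n_flagged` and `n_shared_substitution`) and `rule`.
#' @export
screen_constitutive <- function(calls, refset = constitutive_refset(),
                                rule = c("position", "exact"),
                                metadata = NULL, counts = NULL) {
  rule <- match.arg(rule)
  if (is.null(refset) || nrow(refset) == 0L) {
    stop("empty constitutive reference set", call. = FALSE)
  }
  rows <- list()
  for (g in names(calls)) {
    cs <- calls[[g]]
    if (nrow(cs) == 0L) next
    if (rule == "position") {
      hit <- cs$position %in% refset$position
    } else {
      hit <- vapply(seq_len(nrow(cs)), function(i) {
        any(refset$position == cs$position[i] &
              (is.na(refset$var_aa) | refset$var_aa == cs$var[i]))
      }, TRUE)
    }
    if (any(hit)) {
      ev <- cs$substitution[hit]
      src <- vapply(cs$position[hit], function(p)
        paste(unique(refset$source[refset$position == p]), collapse = "/"), "")
      rows[[g]] <- data.frame(
        genome_id = g, substitution = paste(ev, collapse = ";"),
        evidence = paste(sprintf("%s (ref: %s)", ev, src), collapse = "; "),
        stringsAsFactors = FALSE)
    }
  }
  rows <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
          else data.frame(genome_id = character(), substitution = character(),
                          evidence = character(), stringsAsFactors = FALSE)
  if (!is.null(metadata)) {
    rows <- merge(rows, metadata, by = "genome_id", all.x = TRUE, sort = FALSE)
  }
  sub_tab <- table(unlist(strsplit(rows$substitution, ";")))
  n_shared <- sum(sub_tab[sub_tab >= 2L])
  n_genomes <- if ("n_genomes" %in% names(counts)) {
    unname(counts[["n_genomes"]])
  } else {
    length(calls)
  }
  base <- c(n_genomes = n_genomes, counts[setdiff(names(counts), "n_genomes")])
  structure(list(
    rows = rows,
    counts = c(base, n_flagged = nrow(rows),
               n_shared_substitution = as.integer(n_shared)),
    rule = rule
  ), class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("screen_result (rule:", x$rule, ")\n")
  for (nm in names(x$counts)) cat(sprintf("  %-22s %d\n", nm, x$counts[[nm]]))
  if (nrow(x$rows)) {
    cat("flagged genomes:\n")
    print(x$rows, row.names = FALSE)
  }
  invisible(x)
}

#' Full screen of a DNA allele collection against the reference set
#'
#' Convenience wrapper: deduplicates and translates the collection, calls
#' substitutions of every unique protein against the reference protein, and
#' screens the calls. Substitution calling runs once per unique protein
#' sequence, then fans out to genomes.
#'
#' @param records data.frame (`genome_id`, `dna`).
#' @param reference_protein the reference amino-acid sequence.
#' @param refset,rule,metadata see [screen_constitutive()].
#' @param min_identity see [call_substitutions()].
#' @return a `screen_result` whose `counts` include the dedup counts.
#' @export
scan_alleles <- function(records, reference_protein,
                         refset = constitutive_refset(),
                         rule = "position", metadata = NULL,
                         min_identity = 0.5) {
  dd <- translate_and_dedup(records)
  by_prot <- dd$protein_groups
  calls <- list()
  for (p in names(by_prot)) {
    cs <- call_substitutions(p, reference_protein, min_identity = min_identity)
    for (g in by_prot[[p]]) calls[[g]] <- cs
  }
  # keep genome order stable
  calls <- calls[dd$proteins$genome_id]
  screen_constitutive(calls, refset = refset, rule = rule,
                      metadata = metadata, counts = dd$counts)
}

#' Map a residue position between two aligned homologs
#'
#' @param aligned_a,aligned_b equal-length gapped sequences from
#'   [pairwise_align()] (or the list it returns).
#' @param position_in_a 1-based position in ungapped sequence A.
#' @return 1-based position in ungapped sequence B, or `NA` with attribute
#'   `unaligned = TRUE` when the position falls on a gap in B.
#' @export
map_position <- function(aligned_a, aligned_b = NULL, position_in_a) {
  if (is.list(aligned_a)) {
    aligned_b <- aligned_a$aligned_b
    aligned_a <- aligned_a$aligned_a
  }
  ca <- strsplit(aligned_a, "")[[1L]]
  cb <- strsplit(aligned_b, "")[[1L]]
  stopifnot(length(ca) == length(cb))
  position_in_a <- .check_count(position_in_a, "position_in_a", min = 1L)
  pos_a <- cumsum(ca != "-")
  if (position_in_a > max(pos_a)) {
    stop("position ", position_in_a, " beyond sequence A length ",
         max(pos_a), call. = FALSE)
  }
  col <- which(pos_a == position_in_a & ca != "-")[1L]
  if (cb[col] == "-") {
    out <- NA_integer_
    attr(out, "unaligned") <- TRUE
    return(out)
  }
  sum(cb[seq_len(col)] != "-")
}
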