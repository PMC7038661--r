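# Residue-level proximity analysis on the two OxyR redox conformers.
#
# OxyR switches between a reduced and an oxidized conformation; mutations are
# interpreted by their distance (in Angstrom) to residues and sequence
# regions known to stabilize one conformer or to gate the transition. The
# distance between two residues is the minimum over all heavy-atom pairs.

#' Construct a structure model from an atom table
#'
#' @param atoms data.frame with columns `chain`, `resno` (1-based residue
#'   number), `atom` (atom name), `x`, `y`, `z` (Angstrom).
#' @param conformer label, conventionally "oxidized" or "reduced".
#' @param source free-text provenance (e.g. a PDB id or "synthetic").
#' @return object of class `structure_model`.
#' @export
structure_model <- function(atoms, conformer, source = "unknown") {
  need <- c("chain", "resno", "atom", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stop("atoms must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  if (nrow(atoms) == 0L) stop("no atoms", call. = FALSE)
  structure(list(atoms = atoms, conformer = conformer, source = source),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model (", x$conformer, "): ",
      length(unique(x$atoms$resno)), " residues, ",
      nrow(x$atoms), " heavy atoms [", x$source, "]\n", sep = "")
  invisible(x)
}

#' Read a PDB file into a structure model
#'
#' Keeps heavy atoms of the first chain only (hydrogens dropped); alternate
#' locations are resolved to the highest-occupancy copy. Residue numbering is
#' taken verbatim from the file.
#'
#' @param path PDB file with ATOM records.
#' @param conformer label to attach ("oxidized"/"reduced").
#' @param chain chain identifier; default first chain in the file.
#' @return object of class `structure_model`.
#' @export
read_structure <- function(path, conformer, chain = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
                  error = function(e) stop("cannot parse PDB '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path, call. = FALSE)
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain %in% chain, , drop = FALSE]
  at <- at[is.na(at$elesy) | toupper(at$elesy) != "H", , drop = FALSE]
  at <- at[!grepl("^[0-9]*H", at$elety), , drop = FALSE]   # fallback on atom name
  # resolve altlocs: keep the highest-occupancy copy of each (resno, atom)
  if (any(!at$alt %in% c("", NA))) {
    key <- paste(at$resno, at$elety)
    occ <- ifelse(is.na(at$o), 1, at$o)
    keep <- unlist(lapply(split(seq_len(nrow(at)), key), function(i) {
      i[which.max(occ[i])]
    }), use.names = FALSE)
    at <- at[sort(keep), , drop = FALSE]
  }
  bad <- !is.finite(at$x) | !is.finite(at$y) | !is.finite(at$z)
  if (any(bad)) {
    stop("unreadable coordinates at atom line(s): ",
         paste(head(which(bad), 3L), collapse = ", "), call. = FALSE)
  }
  structure_model(
    data.frame(chain = at$chain, resno = at$resno, atom = at$elety,
               x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE),
    conformer = conformer, source = basename(path)
  )
}

#' Write a structure model as a minimal single-chain PDB file
#'
#' @param model a `structure_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  at <- model$atoms
  elem <- substr(gsub("[0-9]", "", at$atom), 1L, 1L)
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(at)), substr(at$atom, 1L, 4L), "GLY", at$chain, at$resno,
    at$x, at$y, at$z, 1, 0, elem)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

.res_coords <- function(model, resno) {
  at <- model$atoms[model$atoms$resno == resno, , drop = FALSE]
  if (nrow(at) == 0L) return(NULL)
  as.matrix(at[, c("x", "y", "z")])
}

#' Minimum heavy-atom distance between two residues
#'
#' @param model a `structure_model`.
#' @param resA,resB residue numbers.
#' @param metric "min-heavy" (default, minimum over all heavy-atom pairs) or
#'   "ca" (alpha-carbon to alpha-carbon).
#' @return distance in Angstrom.
#' @export
residue_min_distance <- function(model, resA, resB, metric = c("min-heavy", "ca")) {
  metric <- match.arg(metric)
  a <- .res_coords(model, resA)
  b <- .res_coords(model, resB)
  if (is.null(a)) stop("residue ", resA, " absent from structure", call. = FALSE)
  if (is.null(b)) stop("residue ", resB, " absent from structure", call. = FALSE)
  if (metric == "ca") {
    at <- model$atoms
    a <- as.matrix(at[at$resno == resA & at$atom == "CA", c("x", "y", "z")])
    b <- as.matrix(at[at$resno == resB & at$atom == "CA", c("x", "y", "z")])
    if (nrow(a) == 0L || nrow(b) == 0L) {
      stop("CA atom missing for residue ", if (nrow(a) == 0L) resA else resB,
           call. = FALSE)
    }
  }
  # all-pairs squared distances via the cross-term expansion
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(min(d2), 0))
}

#' Default OxyR structural feature annotation
#'
#' Categorized stability residues and sequence regions of E. coli OxyR used
#' to interpret mutations: the redox-active Cys-199 and partner Cys-208, the
#' Asp-172/His-114 salt bridge stabilizing the reduced dimer, the Leu-200
#' hydrophobic core of the reduced monomer, the proline arrangement
#' (99, 103, 107, 111) required for oxidized-dimer packing, the peroxide
#' binding environment, and the redox loop [199, 208] / flexible loop
#' [205, 216] regions.
#'
#' @return object of class `feature_annotation`: list with `residues`
#'   (data.frame: resno, name, category) and `regions` (named list of
#'   inclusive 1-based `[start, end]` bounds plus the proline set).
#' @export
oxyr_features <- function() {
  residues <- data.frame(
    resno = c(199L, 208L, 172L, 114L, 200L, 99L, 103L, 107L, 111L,
              129L, 147L, 100L),
    name = c("Cys199", "Cys208", "Asp172", "His114", "Leu200", "Pro99",
             "Pro103", "Pro107", "Pro111", "Thr129", "Ala147", "Thr100"),
    category = c("redox_center", "stabilizes_reduced", "stabilizes_reduced",
                 "stabilizes_reduced", "stabilizes_reduced",
                 "proline_arrangement", "proline_arrangement",
                 "proline_arrangement", "proline_arrangement",
                 "transition_state", "transition_state", "transition_state"),
    stringsAsFactors = FALSE
  )
  structure(list(
    residues = residues,
    regions = list(flexible_loop = c(205L, 216L), redox_loop = c(199L, 208L)),
    prolines = c(99L, 103L, 107L, 111L)
  ), class = "feature_annotation")
}

#' Which annotated sequence regions contain a position?
#'
#' @param position 1-based residue position.
#' @param features a `feature_annotation` (default [oxyr_features()]).
#' @return character vector of region labels (possibly empty).
#' @export
region_membership <- function(position, features = oxyr_features()) {
  position <- .check_count(position, "position", min = 1L)
  hits <- vapply(features$regions, function(b)
    position >= b[1L] && position <= b[2L], TRUE)
  names(features$regions)[hits]
}

#' Mutation records of the evolved strains
#'
#' The amino-acid substitutions observed in oxyR after laboratory evolution
#' of E. coli (iron-replete medium) and V. natriegens, in E. coli residue
#' numbering.
#'
#' @return data.frame with columns `wt`, `position`, `var`, `origin`.
#' @export
oxyr_ale_mutations <- function() {
  data.frame(
    wt = c("A", "A", "A", "T", "P", "P", "L", "L", "C", "C"),
    position = c(213L, 213L, 147L, 100L, 99L, 107L, 200L, 113L, 208L, 208L),
    var = c("P", "E", "E", "A", "T", "L", "I", "Q", "Y", "G"),
    origin = c("E. coli", "V. natriegens", "both", "E. coli", "E. coli",
               "V. natriegens", "E. coli", "V. natriegens", "both",
               "V. natriegens"),
    stringsAsFactors = FALSE
  )
}

#' Distances from mutations to structural stability features
#'
#' Computes, for every (feature residue, mutation, conformer) triple, the
#' residue-to-residue distance. Mutation positions missing from a conformer
#' (e.g. disordered loops) give a flagged missing cell, never an imputed
#' value.
#'
#' @param oxidized,reduced `structure_model` objects for the two conformers.
#' @param mutations data.frame with columns `wt`, `position`, `var` and
#'   optionally `origin` (see [oxyr_ale_mutations()]).
#' @param features a `feature_annotation`.
#' @param metric distance metric, see [residue_min_distance()].
#' @return long-format data.frame of class `distance_matrix`: columns
#'   `feature`, `category`, `feature_resno`, `mutation`, `position`,
#'   `conformer`, `distance`, `missing`.
#' @export
proximity_matrix <- function(oxidized, reduced, mutations,
                             features = oxyr_features(),
                             metric = "min-heavy") {
  stopifnot(inherits(oxidized, "structure_model"),
            inherits(reduced, "structure_model"))
  mut_lab <- paste0(mutations$wt, mutations$position, mutations$var)
  models <- list(oxidized = oxidized, reduced = reduced)
  rows <- list()
  for (m in seq_len(nrow(mutations))) {
    pos <- mutations$position[m]
    resolved_any <- FALSE
    for (cf in names(models)) {
      mod <- models[[cf]]
      pos_ok <- !is.null(.res_coords(mod, pos))
      for (f in seq_len(nrow(features$residues))) {
        fr <- features$residues$resno[f]
        fr_ok <- !is.null(.res_coords(mod, fr))
        ok <- pos_ok && fr_ok
        if (ok) resolved_any <- TRUE
        rows[[length(rows) + 1L]] <- data.frame(
          feature = features$residues$name[f],
          category = features$residues$category[f],
          feature_resno = fr,
          mutation = mut_lab[m], position = pos, conformer = cf,
          distance = if (ok) residue_min_distance(mod, fr, pos, metric) else NA_real_,
          missing = !ok, stringsAsFactors = FALSE
        )
      }
    }
    if (!resolved_any) {
      warning("mutation position ", pos,
              " unresolved in both conformers", call. = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("distance_matrix", "data.frame")
  out
}

#' Classify a mutation's predicted conformational bias
#'
#' Rule-based interpretation of one mutation from its distance row. Region
#' membership is decisive when it applies: positions in the redox loop
#' [199, 208] destabilize the reduced tetramer; positions in the flexible
#' loop [205, 216] impair the return to the reduced form and so favor the
#' oxidized conformer; positions in the proline arrangement act through the
#' oxidized-dimer interface. Otherwise the nearest annotated feature within
#' `contact_cutoff` decides via its category; beyond the cutoff the call is
#' ambiguous.
#'
#' @param mutation one-row data.frame (`wt`, `position`, `var`) or a
#'   "A213P"-style string.
#' @param matrix_row subset of a [proximity_matrix()] for this mutation.
#' @param features a `feature_annotation`.
#' @param contact_cutoff contact distance in Angstrom (default 8).
#' @return list with `label` (one of `favors_oxidized`,
#'   `destabilizes_reduced`, `redox_loop_flexibility`, `proline_interface`,
#'   `ambiguous`) and `evidence` (character vector naming the triggering
#'   region or feature and distance).
#' @export
classify_mutation <- function(mutation, matrix_row,
                              features = oxyr_features(),
                              contact_cutoff = 8) {
  if (is.character(mutation)) {
    pos <- as.integer(gsub("[^0-9]", "", mutation))
  } else {
    pos <- as.integer(mutation$position[1L])
  }
  if (nrow(matrix_row) == 0L) stop("empty distance row", call. = FALSE)
  regions <- region_membership(pos, features)
  if ("redox_loop" %in% regions) {
    return(list(label = "destabilizes_reduced",
                evidence = sprintf("position %d in redox loop [%d, %d]: reduced-tetramer interface",
                                   pos, features$regions$redox_loop[1L],
                                   features$regions$redox_loop[2L])))
  }
  if ("flexible_loop" %in% regions) {
    return(list(label = "favors_oxidized",
                evidence = sprintf("position %d in flexible loop [%d, %d]: impaired return to reduced form",
                                   pos, features$regions$flexible_loop[1L],
                                   features$regions$flexible_loop[2L])))
  }
  if (pos %in% features$prolines) {
    return(list(label = "proline_interface",
                evidence = sprintf("position %d in the proline arrangement (%s)",
                                   pos, paste(features$prolines, collapse = ", "))))
  }
  ok <- !matrix_row$missing
  if (!any(ok)) {
    return(list(label = "ambiguous", evidence = "no resolved distances"))
  }
  i <- which(ok)[which.min(matrix_row$distance[ok])]
  d <- matrix_row$distance[i]
  if (d > contact_cutoff) {
    return(list(label = "ambiguous",
                evidence = sprintf("nearest feature %s at %.1f A, beyond %.1f A cutoff",
                                   matrix_row$feature[i], d, contact_cutoff)))
  }
  label <- switch(matrix_row$category[i],
                  stabilizes_reduced = "destabilizes_reduced",
                  stabilizes_oxidized = "favors_oxidized",
                  transition_state = "favors_oxidized",
                  proline_arrangement = "proline_interface",
                  redox_center = "redox_loop_flexibility",
                  "ambiguous")
  list(label = label,
       evidence = sprintf("nearest feature %s (%s) at %.1f A (%s conformer)",
                          matrix_row$feature[i], matrix_row$category[i], d,
                          matrix_row$conformer[i]))
}
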