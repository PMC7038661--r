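# Two-conformer toy structures with controlled per-residue displacements.
# All pairwise distances follow in closed form from the construction, which
# makes the proximity stage testable against exhaustive recomputation.

#' Simulate a pair of protein conformers
#'
#' Conformer A places residues along a random walk in space with 1-5 heavy
#' atoms jittered around each residue center; conformer B is conformer A
#' with a rigid per-residue translation given by `displacement`.
#'
#' @param n_residues number of residues (>= 2).
#' @param displacement either NULL (no displacement), a single 3-vector
#'   applied to every residue, or a `n_residues` x 3 matrix of per-residue
#'   displacements in Angstrom.
#' @param atoms_per_residue integer vector recycled over residues (1-5
#'   typical); default random in 1:5.
#' @param seed integer seed.
#' @return list with elements `A` and `B`, two [structure_model()] objects
#'   labelled "oxidized" and "reduced".
#' @export
simulate_structure <- function(n_residues, displacement = NULL,
                               atoms_per_residue = NULL, seed = 0L) {
  n_residues <- .check_count(n_residues, "n_residues", min = 2L)
  set.seed(.derive_seed(seed, "structure"))
  if (is.null(atoms_per_residue)) {
    atoms_per_residue <- sample(1:5, n_residues, replace = TRUE)
  }
  atoms_per_residue <- rep_len(atoms_per_residue, n_residues)
  if (any(atoms_per_residue < 1L)) stop("each residue needs >= 1 atom", call. = FALSE)
  # residue centers: random walk with ~3.8 A steps (CA-CA like spacing)
  steps <- matrix(rnorm(3L * n_residues), ncol = 3L)
  steps <- steps / sqrt(rowSums(steps^2)) * 3.8
  centers <- apply(steps, 2L, cumsum)
  if (n_residues == 1L) centers <- matrix(centers, nrow = 1L)
  if (is.null(displacement)) {
    D <- matrix(0, n_residues, 3L)
  } else if (is.matrix(displacement)) {
    if (nrow(displacement) != n_residues || ncol(displacement) != 3L) {
      stop("displacement matrix must be n_residues x 3", call. = FALSE)
    }
    D <- displacement
  } else {
    D <- matrix(rep(as.numeric(displacement), each = n_residues), n_residues, 3L)
  }
  atom_names <- c("CA", "CB", "CG", "CD", "CE")
  rows <- lapply(seq_len(n_residues), function(r) {
    k <- atoms_per_residue[r]
    jit <- rbind(c(0, 0, 0),
                 matrix(rnorm(3L * (k - 1L), sd = 0.8), ncol = 3L))[seq_len(k), , drop = FALSE]
    data.frame(chain = "A", resno = r, atom = atom_names[seq_len(k)],
               x = centers[r, 1L] + jit[, 1L],
               y = centers[r, 2L] + jit[, 2L],
               z = centers[r, 3L] + jit[, 3L], stringsAsFactors = FALSE)
  })
  atomsA <- do.call(rbind, rows)
  if (anyDuplicated(unique(atomsA$resno)) > 0L) {
    stop("duplicate residue ids", call. = FALSE)
  }
  atomsB <- atomsA
  atomsB$x <- atomsB$x + D[atomsB$resno, 1L]
  atomsB$y <- atomsB$y + D[atomsB$resno, 2L]
  atomsB$z <- atomsB$z + D[atomsB$resno, 3L]
  list(A = structure_model(atomsA, "oxidized", source = "synthetic"),
       B = structure_model(atomsB, "reduced", source = "synthetic"))
}

#' Build a structure model from explicit single-atom residues
#'
#' Convenience constructor for exactly placed geometries (each row one
#' residue with a single CA atom), used for closed-form distance checks.
#'
#' @param coords numeric matrix, one row per residue, columns x, y, z.
#' @param resno residue numbers (default 1..n).
#' @param conformer conformer label.
#' @return a [structure_model()].
#' @export
point_structure <- function(coords, resno = seq_len(nrow(coords)),
                            conformer = "oxidized") {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 3L)
  if (anyDuplicated(resno)) stop("duplicate residue ids", call. = FALSE)
  structure_model(
    data.frame(chain = "A", resno = as.integer(resno), atom = "CA",
               x = coords[, 1L], y = coords[, 2L], z = coords[, 3L],
               stringsAsFactors = FALSE),
    conformer = conformer, source = "synthetic")
}
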