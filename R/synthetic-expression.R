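# Synthetic transcriptomes with planted independently modulated gene groups.
# Ground truth (S_true, A_true) is returned with every matrix so recovery by
# the ICA stage can be scored exactly.

#' Specify a planted i-modulon
#'
#' A ground-truth independently modulated gene group: a named set of member
#' genes with signed weights and one activity level per condition.
#'
#' @param name modulon label (e.g. the regulator it mimics, "OxyR").
#' @param member_genes character vector of member gene ids (non-empty).
#' @param weights numeric vector of non-zero signed weights, one per member.
#' @param activity named numeric vector: condition id -> activity level.
#' @return An object of class `modulon_spec`.
#' @export
modulon_spec <- function(name, member_genes, weights, activity) {
  if (length(member_genes) == 0L) stop("member_genes must be non-empty", call. = FALSE)
  if (length(weights) != length(member_genes)) {
    stop("weights must match member_genes in length", call. = FALSE)
  }
  if (any(weights == 0)) stop("member weights must be non-zero", call. = FALSE)
  if (anyDuplicated(member_genes)) {
    dup <- member_genes[duplicated(member_genes)]
    w1 <- weights[match(dup, member_genes)]
    w2 <- weights[length(weights) - match(dup, rev(member_genes)) + 1L]
    if (any(w1 != w2)) {
      stop("gene(s) ", paste(unique(dup), collapse = ", "),
           " listed with conflicting weights", call. = FALSE)
    }
    keep <- !duplicated(member_genes)
    member_genes <- member_genes[keep]
    weights <- weights[keep]
  }
  if (is.null(names(activity)) || any(!nzchar(names(activity)))) {
    stop("activity must be a named vector (condition -> level)", call. = FALSE)
  }
  structure(
    list(name = name, member_genes = as.character(member_genes),
         weights = as.numeric(weights), activity = activity),
    class = "modulon_spec"
  )
}

#' Default planted modulons mirroring the regulators tracked downstream
#'
#' Two modulons over a 1,000-gene universe: an "OxyR"-like group whose
#' activity is strongly elevated in evolved conditions and a "LexA"-like
#' group responding to peroxide exposure, plus a "SoxS"-like null group with
#' no activity difference, used as negative control.
#'
#' @param n_genes gene-universe size.
#' @param conditions character vector of condition ids; the first is the
#'   reference (wild type).
#' @param seed integer seed governing member choice and weights.
#' @return list of `modulon_spec`.
#' @export
default_modulons <- function(n_genes = 1000L,
                             conditions = c("wt", "gmos", "evo1", "evo2"),
                             seed = 0L) {
  set.seed(.derive_seed(seed, "modulons"))
  genes <- sprintf("g%04d", seq_len(n_genes))
  pick <- function(n) sample(genes, n)
  used <- character()
  pick_excl <- function(n) {
    g <- sample(setdiff(genes, used), n)
    used <<- c(used, g)
    g
  }
  act <- function(levels) setNames(levels, conditions)
  n_cond <- length(conditions)
  evo <- grepl("^evo", conditions)
  oxy_act <- ifelse(evo, 8, 0); oxy_act[conditions == "gmos"] <- 0.5
  lexa_act <- ifelse(conditions == "gmos", 5, 0)
  soxs_act <- rep(0.5, n_cond)
  list(
    modulon_spec("OxyR", pick_excl(25L), runif(25L, 0.5, 1.5) * sample(c(1, 1, 1, -1), 25L, TRUE),
                 act(oxy_act)),
    modulon_spec("LexA", pick_excl(22L), runif(22L, 0.5, 1.5) * sample(c(1, 1, 1, -1), 22L, TRUE),
                 act(lexa_act)),
    modulon_spec("SoxS", pick_excl(20L), runif(20L, 0.5, 1.5), act(soxs_act))
  )
}

#' Simulate a log-expression matrix from planted modulons
#'
#' Builds `X = S_true %*% A_true + noise` where `S_true` holds the planted
#' signed gene weights (zero outside members), `A_true` repeats each
#' condition's activity across its replicates, and the noise is i.i.d.
#' Gaussian on the log scale.
#'
#' @param modulons list of [modulon_spec()] objects.
#' @param conditions data.frame with columns `condition` and `n_replicates`,
#'   or a named integer vector (condition -> replicates).
#' @param n_genes gene-universe size; the universe must contain every member
#'   gene (ids `g0001`, `g0002`, ... are generated).
#' @param noise_sd standard deviation of the additive Gaussian noise (>= 0).
#' @param reference_condition baseline condition label (default first).
#' @param seed integer seed; identical seeds give bitwise-identical output.
#' @return list with `expr` (an [expression_matrix()]), `S_true` (genes x
#'   modulons), `A_true` (modulons x samples) and `modulons`.
#' @export
simulate_expression <- function(modulons, conditions, n_genes = 1000L,
                                noise_sd = 0.25,
                                reference_condition = NULL, seed = 0L) {
  if (!is.list(modulons) || !all(vapply(modulons, inherits, TRUE, "modulon_spec"))) {
    stop("modulons must be a list of modulon_spec objects", call. = FALSE)
  }
  noise_sd <- .check_number(noise_sd, "noise_sd", min = 0)
  if (is.data.frame(conditions)) {
    cond_ids <- as.character(conditions$condition)
    n_rep <- as.integer(conditions$n_replicates)
  } else {
    cond_ids <- names(conditions)
    n_rep <- as.integer(conditions)
  }
  if (length(cond_ids) == 0L) stop("condition list must be non-empty", call. = FALSE)
  if (any(n_rep < 1L)) stop("every condition needs >= 1 replicate", call. = FALSE)
  genes <- sprintf("g%04d", seq_len(.check_count(n_genes, "n_genes", min = 2L)))
  members <- unique(unlist(lapply(modulons, `[[`, "member_genes")))
  if (!all(members %in% genes)) {
    stop("gene universe does not contain: ",
         paste(head(setdiff(members, genes), 5L), collapse = ", "), call. = FALSE)
  }
  m <- length(modulons)
  S <- matrix(0, length(genes), m,
              dimnames = list(genes, vapply(modulons, `[[`, "", "name")))
  for (j in seq_len(m)) {
    S[modulons[[j]]$member_genes, j] <- modulons[[j]]$weights
  }
  cond_per_sample <- rep(cond_ids, n_rep)
  rep_per_sample <- unlist(lapply(n_rep, seq_len))
  sample_ids <- paste0(cond_per_sample, "_r", rep_per_sample)
  A <- matrix(0, m, length(sample_ids),
              dimnames = list(colnames(S), sample_ids))
  for (j in seq_len(m)) {
    a <- modulons[[j]]$activity
    miss <- setdiff(cond_ids, names(a))
    if (length(miss)) stop("modulon '", modulons[[j]]$name,
                           "' lacks activity for condition(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    A[j, ] <- as.numeric(a[cond_per_sample])
  }
  set.seed(.derive_seed(seed, "expression"))
  X <- S %*% A
  if (noise_sd > 0) {
    X <- X + matrix(rnorm(length(X), sd = noise_sd), nrow(X), ncol(X))
  }
  ref <- if (is.null(reference_condition)) cond_ids[1L] else reference_condition
  list(
    expr = expression_matrix(X, condition = cond_per_sample,
                             replicate = rep_per_sample,
                             reference_condition = ref),
    S_true = S, A_true = A, modulons = modulons
  )
}
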