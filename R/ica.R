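# Robust independent component analysis of expression matrices.
#
# The decomposition X_centered ~ S %*% A splits a transcriptome into
# statistically independent gene-weight vectors (columns of S); thresholding
# a column yields an i-modulon, and the corresponding row of A is its
# condition-dependent activity. Robustness is obtained by re-running FastICA
# from many random rotations and keeping only components that recur.

#' Center an expression matrix to its reference condition
#'
#' Subtracts from every gene the mean of its reference-condition samples, so
#' that activities downstream are read as changes relative to the wild-type
#' (reference) baseline and reference samples average to zero per gene.
#'
#' @param x an [expression_matrix()].
#' @return numeric matrix of the same shape as `x$values`.
#' @export
center_to_reference <- function(x) {
  stopifnot(inherits(x, "expression_matrix"))
  ref_cols <- x$samples$condition == x$reference_condition
  if (!any(ref_cols)) {
    stop("reference condition '", x$reference_condition,
         "' has no samples", call. = FALSE)
  }
  ref_mean <- rowMeans(x$values[, ref_cols, drop = FALSE])
  sweep(x$values, 1L, ref_mean)
}

# one FastICA run (symmetric decorrelation, logcosh contrast) on the whitened
# data; returns unit-variance source columns in gene space
.fastica_once <- function(Z, W0, alpha = 1, max_iter = 500L, tol = 1e-8) {
  G <- nrow(Z)
  W <- .orthonormalize(W0)
  for (iter in seq_len(max_iter)) {
    Ssrc <- Z %*% W                      # G x m sources
    gS <- tanh(alpha * Ssrc)
    gpS <- alpha * (1 - gS^2)
    W1 <- crossprod(Z, gS) / G - W %*% diag(colMeans(gpS), ncol(W))
    W1 <- .orthonormalize(W1)
    delta <- max(abs(abs(colSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) break
  }
  Z %*% W
}

.orthonormalize <- function(W) {
  s <- svd(W)
  s$u %*% t(s$v)
}

# unit L2 norm per column; sign fixed so the largest-magnitude weight is
# positive -- makes the decomposition unique up to component order
.normalize_sign <- function(S) {
  nrm <- sqrt(colSums(S^2))
  nrm[nrm == 0] <- 1
  S <- sweep(S, 2L, nrm, "/")
  flip <- vapply(seq_len(ncol(S)), function(j) {
    w <- S[, j]
    sign(w[which.max(abs(w))])
  }, 0)
  flip[flip == 0] <- 1
  sweep(S, 2L, flip, "*")
}

#' Robust ICA decomposition of a centered expression matrix
#'
#' Runs FastICA (logcosh contrast, symmetric decorrelation, eigenvalue
#' whitening in sample space) from `n_restarts` random rotations, pools all
#' recovered components, clusters them by absolute weight-vector correlation
#' (complete linkage on `1 - |r|`, cut at `cluster_height`), and keeps
#' clusters present in at least `min_recurrence` of the restarts. Cluster
#' centroids become the columns of `S` (unit norm, largest weight positive);
#' activities `A` are the least-squares projection of the centered data onto
#' `S`.
#'
#' @param Xc centered genes-by-samples matrix (see [center_to_reference()]).
#' @param n_components number of components per restart; must be smaller
#'   than `min(dim(Xc))`.
#' @param n_restarts number of random initializations (>= 1).
#' @param min_recurrence fraction of restarts in which a component cluster
#'   must recur to be retained.
#' @param cluster_height cut height on the `1 - |r|` dendrogram.
#' @param seed integer seed; the whole procedure is deterministic given it.
#' @return An object of class `ica_model`: list with `S` (genes x kept
#'   components, unit-norm columns), `A` (components x samples), `robustness`
#'   (per-component recurrence fraction), `n_requested`, and flags
#'   `degenerate` (input numerically zero) and `short` (fewer robust
#'   components than requested).
#' @export
robust_ica <- function(Xc, n_components, n_restarts = 10L,
                       min_recurrence = 0.5, cluster_height = 0.2,
                       seed = 0L) {
  stopifnot(is.matrix(Xc), is.numeric(Xc))
  n_components <- .check_count(n_components, "n_components", min = 1L)
  n_restarts <- .check_count(n_restarts, "n_restarts", min = 1L)
  min_recurrence <- .check_number(min_recurrence, "min_recurrence", 0, 1)
  if (n_components >= min(dim(Xc))) {
    stop("n_components must be < min(genes, samples)", call. = FALSE)
  }
  empty <- function(degenerate) {
    structure(list(
      S = matrix(0, nrow(Xc), 0L, dimnames = list(rownames(Xc), NULL)),
      A = matrix(0, 0L, ncol(Xc), dimnames = list(NULL, colnames(Xc))),
      robustness = numeric(0), n_requested = n_components,
      degenerate = degenerate, short = !degenerate
    ), class = "ica_model")
  }
  if (max(abs(Xc)) < 1e-12) return(empty(degenerate = TRUE))

  # whitening in sample space without removing gene-wise means: keeping the
  # mean component lets S %*% A reconstruct Xc itself (reference centering
  # already anchored the scale), so the projection attains the rank-k
  # optimum on the data as given
  C <- crossprod(Xc) / (nrow(Xc) - 1L)   # samples x samples second moment
  eg <- eigen(C, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-10
  m <- min(n_components, sum(keep))
  if (m < 1L) return(empty(degenerate = TRUE))
  K <- eg$vectors[, seq_len(m), drop = FALSE] %*%
    diag(1 / sqrt(eg$values[seq_len(m)]), m)
  Z <- Xc %*% K
  Z <- scale(Z, center = FALSE, scale = sqrt(colMeans(Z^2)))

  set.seed(.derive_seed(seed, "ica"))
  comps <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    W0 <- matrix(rnorm(m * m), m, m)
    comps[[r]] <- .normalize_sign(.fastica_once(Z, W0))
  }
  allS <- do.call(cbind, comps)
  restart_of <- rep(seq_len(n_restarts), each = m)

  if (ncol(allS) == 1L) {
    cl <- 1L
  } else {
    d <- stats::as.dist(1 - abs(stats::cor(allS)))
    cl <- stats::cutree(stats::hclust(d, method = "complete"),
                        h = cluster_height)
  }
  tab <- vapply(split(restart_of, cl),
                function(rs) length(unique(rs)) / n_restarts, 0)
  robust_ids <- names(tab)[tab >= min_recurrence]
  if (length(robust_ids) == 0L) return(empty(degenerate = FALSE))
  # rank clusters by recurrence then by explained variance of their centroid
  cent <- lapply(robust_ids, function(id) {
    cols <- allS[, cl == as.integer(id), drop = FALSE]
    sgn <- sign(as.numeric(crossprod(cols, cols[, 1L])))
    sgn[sgn == 0] <- 1
    rowMeans(sweep(cols, 2L, sgn, "*"))
  })
  S <- .normalize_sign(do.call(cbind, cent))
  expl <- rowSums(crossprod(S, Xc)^2)
  ord <- order(-tab[robust_ids], -expl)
  take <- ord[seq_len(min(n_components, length(ord)))]
  S <- S[, take, drop = FALSE]
  colnames(S) <- sprintf("IC%02d", seq_len(ncol(S)))
  A <- project_activities(Xc, S)
  structure(list(
    S = S, A = A, robustness = unname(tab[robust_ids][take]),
    n_requested = n_components, degenerate = FALSE,
    short = ncol(S) < n_components
  ), class = "ica_model")
}

#' Project samples onto a fixed set of component weights
#'
#' Least-squares activities `A = (S'S)^-1 S' Xc`, usable both inside
#' [robust_ica()] and to score new samples against a previously fitted or
#' external weight matrix.
#'
#' @param Xc centered genes-by-samples matrix.
#' @param S genes-by-components weight matrix (rows aligned with `Xc`).
#' @return components-by-samples activity matrix.
#' @export
project_activities <- function(Xc, S) {
  stopifnot(nrow(Xc) == nrow(S))
  A <- solve(crossprod(S), crossprod(S, Xc))
  dimnames(A) <- list(colnames(S), colnames(Xc))
  A
}

#' @export
print.ica_model <- function(x, ...) {
  cat("ica_model:", ncol(x$S), "robust component(s) of",
      x$n_requested, "requested\n")
  if (x$degenerate) cat("  [degenerate input: all-zero matrix]\n")
  if (x$short && !x$degenerate) cat("  [fewer robust clusters than requested]\n")
  if (length(x$robustness)) {
    cat("  recurrence:", paste(sprintf("%.2f", x$robustness), collapse = " "), "\n")
  }
  invisible(x)
}

#' Define i-modulon membership from a weight column
#'
#' Members are the genes whose absolute weight exceeds `k` robust standard
#' deviations of the weight distribution (median absolute deviation scaled
#' by 1.4826).
#'
#' @param weights named numeric weight vector (one column of `S`).
#' @param k multiple of the robust spread (default 5).
#' @return An object of class `imodulon`: list with `members`, `threshold`
#'   and `k`.
#' @export
define_membership <- function(weights, k = 5) {
  k <- .check_number(k, "k", min = 0)
  if (is.null(names(weights))) names(weights) <- seq_along(weights)
  spread <- mad(weights)                 # 1.4826 * MAD about the median
  if (spread == 0) {
    if (length(unique(weights)) == 1L) {
      stop("constant weight vector: membership undefined", call. = FALSE)
    }
    # majority of weights identical (e.g. exact zeros): fall back to the
    # spread of the distribution about zero
    spread <- mad(weights, center = 0)
    if (spread == 0) spread <- sd(weights)
  }
  thr <- k * spread
  structure(list(
    members = names(weights)[abs(weights) > thr],
    threshold = thr, k = k
  ), class = "imodulon")
}

#' @export
print.imodulon <- function(x, ...) {
  cat("imodulon:", length(x$members), "member gene(s), |weight| >",
      format(x$threshold, digits = 4), "\n")
  if (!is.null(x$regulator)) {
    cat("  regulator:", x$regulator, " (p =", format(x$p_value, digits = 3), ")\n")
  }
  invisible(x)
}

#' Match an i-modulon to known regulons by hypergeometric enrichment
#'
#' For each known regulon, computes the upper-tail hypergeometric probability
#' of drawing at least the observed overlap when `length(members)` genes are
#' sampled from a universe of `universe_size`. The best match is the smallest
#' Bonferroni-adjusted p-value.
#'
#' @param members character vector of i-modulon member genes.
#' @param known_regulons named list: regulator -> character vector of genes.
#' @param universe_size total number of genes in the universe.
#' @return list with `regulator` (best match or NA), `p_value` (Bonferroni-
#'   adjusted), `table` (per-regulator overlap and raw p), and `flagged`
#'   (TRUE when the member set is empty).
#' @export
match_regulon <- function(members, known_regulons, universe_size) {
  universe_size <- .check_count(universe_size, "universe_size", min = 1L)
  sizes <- lengths(known_regulons)
  if (any(sizes > universe_size) || length(members) > universe_size) {
    stop("universe smaller than a gene set", call. = FALSE)
  }
  if (length(members) == 0L) {
    return(list(regulator = NA_character_, p_value = NA_real_,
                table = NULL, flagged = TRUE))
  }
  p_raw <- vapply(known_regulons, function(reg) {
    o <- length(intersect(members, reg))
    phyper(o - 1L, length(reg), universe_size - length(reg),
           length(members), lower.tail = FALSE)
  }, 0)
  overlap <- vapply(known_regulons, function(reg)
    length(intersect(members, reg)), 0L)
  p_adj <- pmin(p_raw * length(known_regulons), 1)
  tab <- data.frame(regulator = names(known_regulons), overlap = overlap,
                    regulon_size = sizes, p_raw = p_raw, p_bonferroni = p_adj,
                    row.names = NULL, stringsAsFactors = FALSE)
  best <- which.min(p_adj)
  list(regulator = names(known_regulons)[best],
       p_value = unname(p_adj[best]),
       table = tab[order(tab$p_bonferroni), ], flagged = FALSE)
}

#' Summarize component activity per condition
#'
#' @param A components-by-samples activity matrix (or `ica_model`).
#' @param component component index or name.
#' @param condition character vector mapping each sample column to a
#'   condition.
#' @return data.frame with per-condition `mean`, `sd` (NA when `n < 2`) and
#'   `n`, class `activity_summary`.
#' @export
activity_summary <- function(A, component, condition) {
  if (inherits(A, "ica_model")) A <- A$A
  if (is.character(component) && !component %in% rownames(A) ||
      is.numeric(component) && (component < 1 || component > nrow(A))) {
    stop("unknown component: ", component, call. = FALSE)
  }
  a <- A[component, ]
  stopifnot(length(condition) == length(a))
  out <- do.call(rbind, lapply(split(a, condition)[unique(condition)], function(v) {
    data.frame(mean = mean(v), sd = if (length(v) >= 2L) sd(v) else NA_real_,
               n = length(v))
  }))
  out <- data.frame(condition = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("activity_summary", "data.frame")
  out
}

#' Differential activity between two condition groups
#'
#' Welch two-sample t test on a component's activities; the sign of the
#' difference is `mean(group1) - mean(group2)`.
#'
#' @param A components-by-samples activity matrix (or `ica_model`).
#' @param component component index or name.
#' @param condition per-sample condition labels.
#' @param group1,group2 sets of condition labels to compare.
#' @return list with `difference`, `p_value`, `n1`, `n2`.
#' @export
differential_activity <- function(A, component, condition, group1, group2) {
  if (inherits(A, "ica_model")) A <- A$A
  a <- A[component, ]
  stopifnot(length(condition) == length(a))
  x <- a[condition %in% group1]
  y <- a[condition %in% group2]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs >= 2 samples (descriptive difference: ",
         format(mean(x) - mean(y), digits = 4), ")", call. = FALSE)
  }
  d <- mean(x) - mean(y)
  if (var(x) == 0 && var(y) == 0) {
    p <- if (d == 0) 1 else 0
  } else {
    p <- t.test(x, y, var.equal = FALSE)$p.value
  }
  list(difference = d, p_value = p, n1 = length(x), n2 = length(y))
}
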