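# Reduced proteome-allocation ("fear-greed") model.
#
# A fixed proteome budget Phi is shared between growth-promoting and
# stress-tolerance proteins. Raising the expression of gene i from its
# reference abundance phi_i by a fold change f diverts alpha*phi_i*(f-1)/Phi
# of the budget away from growth, so the relative growth rate falls linearly:
#   mu/mu0 = 1 - k_i * (f - 1),  k_i = alpha * phi_i / Phi.
# Two scaling laws follow by construction: growth decreases linearly in the
# fold change of any single gene, and the slope is proportional to the
# gene's reference abundance.

#' Construct a proteome-cost model
#'
#' @param phi_ref named numeric vector: gene -> reference abundance
#'   (dimensionless fraction of the transcriptome/proteome; all >= 0, sum
#'   <= 1).
#' @param alpha cost coefficient per unit reallocated abundance (> 0).
#' @param Phi reallocatable proteome budget (> 0).
#' @param mu0 reference growth rate in 1/h (> 0); only used to express
#'   absolute rates, all model outputs are relative.
#' @return object of class `proteome_cost_model`.
#' @export
proteome_cost_model <- function(phi_ref, alpha = 1, Phi = 1, mu0 = 1) {
  if (is.null(names(phi_ref)) || any(!nzchar(names(phi_ref)))) {
    stop("phi_ref must be a named vector (gene -> abundance)", call. = FALSE)
  }
  if (any(phi_ref < 0)) stop("abundances must be >= 0", call. = FALSE)
  if (sum(phi_ref) > 1 + 1e-9) stop("abundances must sum to <= 1", call. = FALSE)
  structure(list(
    phi_ref = phi_ref,
    alpha = .check_number(alpha, "alpha", min = 0),
    Phi = .check_number(Phi, "Phi", min = 1e-12),
    mu0 = .check_number(mu0, "mu0", min = 1e-12)
  ), class = "proteome_cost_model")
}

#' @export
print.proteome_cost_model <- function(x, ...) {
  cat("proteome_cost_model:", length(x$phi_ref), "genes; alpha/Phi =",
      format(x$alpha / x$Phi, digits = 6), "; mu0 =", x$mu0, "1/h\n")
  invisible(x)
}

#' @export
coef.proteome_cost_model <- function(object, ...) {
  c(alpha_over_Phi = object$alpha / object$Phi)
}

.check_gene <- function(model, gene) {
  if (!gene %in% names(model$phi_ref)) {
    stop("unknown gene: ", gene, call. = FALSE)
  }
  gene
}

#' Relative growth rate at a given single-gene fold change
#'
#' `mu/mu0 = 1 - alpha * phi_ref(gene) * (f - 1) / Phi`, floored at zero.
#' Fold changes below one would predict rates above one (freed budget); by
#' default the prediction is capped at the reference rate.
#'
#' @param model a [proteome_cost_model()].
#' @param gene gene id present in the model.
#' @param fold_change expression fold change relative to the reference
#'   state (>= 0); vectorized.
#' @param allow_gain if TRUE, fold changes < 1 may return values > 1.
#' @return relative growth rate(s) mu/mu0 in `[0, 1]` (or above 1 when
#'   `allow_gain`).
#' @export
growth_at_expression <- function(model, gene, fold_change, allow_gain = FALSE) {
  stopifnot(inherits(model, "proteome_cost_model"))
  .check_gene(model, gene)
  if (any(fold_change < 0)) stop("fold_change must be >= 0", call. = FALSE)
  k <- cost_slope(model, gene)
  mu <- 1 - k * (fold_change - 1)
  mu <- pmax(mu, 0)
  if (!allow_gain) mu <- pmin(mu, 1)
  mu
}

#' Cost slope of a gene (growth-rate loss per unit fold change)
#'
#' `k_i = alpha * phi_ref(gene) / Phi`; strictly increasing in the
#' reference abundance, which is the model's second scaling law.
#'
#' @inheritParams growth_at_expression
#' @return slope(s); vectorized over `gene`.
#' @export
cost_slope <- function(model, gene) {
  stopifnot(inherits(model, "proteome_cost_model"))
  for (g in gene) .check_gene(model, g)
  unname(model$alpha * model$phi_ref[gene] / model$Phi)
}

#' Growth cost of a joint regulon expression change
#'
#' Additive composition over genes: `mu/mu0 = 1 - sum_i k_i (f_i - 1)`,
#' floored at zero, with per-gene contributions ranked by absolute effect
#' (ties broken by gene id).
#'
#' @param model a [proteome_cost_model()].
#' @param fold_changes named numeric vector: gene -> fold change (>= 0).
#' @return object of class `cost_report`: list with `per_gene` (data.frame:
#'   gene, phi_ref, fold_change, slope, contribution, mu_rel_single, rank),
#'   `mu_rel_total` and `ranking` (gene ids by decreasing |contribution|).
#' @export
regulon_cost <- function(model, fold_changes) {
  stopifnot(inherits(model, "proteome_cost_model"))
  if (is.null(names(fold_changes))) stop("fold_changes must be named", call. = FALSE)
  if (any(fold_changes < 0)) stop("fold changes must be >= 0", call. = FALSE)
  genes <- names(fold_changes)
  for (g in genes) .check_gene(model, g)
  k <- cost_slope(model, genes)
  contrib <- k * (fold_changes - 1)
  ord <- order(-abs(contrib), genes)
  per_gene <- data.frame(
    gene = genes, phi_ref = unname(model$phi_ref[genes]),
    fold_change = unname(fold_changes), slope = k,
    contribution = unname(contrib),
    mu_rel_single = pmin(pmax(1 - contrib, 0), 1),
    stringsAsFactors = FALSE)
  per_gene$rank <- match(seq_len(nrow(per_gene)), ord)
  structure(list(
    per_gene = per_gene[ord, , drop = FALSE],
    mu_rel_total = max(1 - sum(contrib), 0),
    ranking = genes[ord]
  ), class = "cost_report")
}

#' @export
print.cost_report <- function(x, ...) {
  cat("cost_report: mu/mu0 =", format(x$mu_rel_total, digits = 4), "\n")
  print(utils::head(x$per_gene, 10L), row.names = FALSE)
  invisible(x)
}

#' Fit the shared cost coefficient from simulation points
#'
#' Least-squares recovery of the single shared coefficient `alpha/Phi` from
#' `(gene, fold_change, mu_rel)` triples given known reference abundances:
#' regression of `1 - mu_rel` on `phi_ref(gene) * (f - 1)` through the
#' origin. Points at the zero-growth floor are excluded. Per-gene slopes are
#' refit individually as a diagnostic; genes whose individual slope deviates
#' from the shared prediction by more than `misfit_tol` (relative) raise the
#' misfit flag.
#'
#' @param points data.frame with columns `gene`, `fold_change`, `mu_rel`.
#' @param phi_ref named numeric abundance vector covering all genes.
#' @param misfit_tol relative tolerance for the per-gene diagnostic.
#' @return a [proteome_cost_model()] with extra fields `fit` (list:
#'   residual_sd, per_gene slopes, misfit flag, n_points).
#' @export
fit_cost_model <- function(points, phi_ref, misfit_tol = 0.05) {
  need <- c("gene", "fold_change", "mu_rel")
  stopifnot(is.data.frame(points), all(need %in% names(points)))
  genes <- unique(points$gene)
  if (length(genes) < 2L) stop("need >= 2 genes", call. = FALSE)
  nf <- vapply(split(points$fold_change, points$gene),
               function(f) length(unique(f)), 0L)
  if (any(nf < 2L)) {
    stop("need >= 2 distinct fold-change values per gene (degenerate design)",
         call. = FALSE)
  }
  miss <- setdiff(genes, names(phi_ref))
  if (length(miss)) stop("phi_ref missing gene(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  above_floor <- points$mu_rel > 0
  pts <- points[above_floor, , drop = FALSE]
  x <- phi_ref[pts$gene] * (pts$fold_change - 1)
  z <- 1 - pts$mu_rel
  if (all(x == 0)) stop("degenerate design: all fold changes equal 1", call. = FALSE)
  c_hat <- sum(x * z) / sum(x^2)
  resid <- z - c_hat * x
  slopes <- vapply(split(pts, pts$gene), function(d) {
    xf <- d$fold_change - 1
    if (all(xf == 0)) return(NA_real_)
    sum(xf * (1 - d$mu_rel)) / sum(xf^2)
  }, 0)
  pred <- c_hat * phi_ref[names(slopes)]
  relerr <- ifelse(pred == 0, abs(slopes), abs(slopes - pred) / pmax(abs(pred), 1e-300))
  misfit <- any(relerr > misfit_tol, na.rm = TRUE)
  model <- proteome_cost_model(phi_ref[genes], alpha = c_hat, Phi = 1)
  model$fit <- list(alpha_over_Phi = c_hat,
                    residual_sd = if (length(resid) > 1L) sd(resid) else 0,
                    per_gene_slopes = slopes,
                    slope_relative_error = relerr,
                    misfit = misfit, n_points = nrow(pts))
  model
}
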