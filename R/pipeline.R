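# One-command orchestration: simulate inputs, then run the analysis stages
# in dependency order, writing TSV/JSON artifacts and a hash manifest.

.default_config <- function() {
  list(
    seed = 0L,
    out_dir = "oxyradapt-run",
    stages = list(simulate = TRUE, ica = TRUE, proximity = TRUE,
                  scan = TRUE, cost = TRUE, lag = TRUE),
    ica = list(n_components = 3L, n_restarts = 10L, min_recurrence = 0.5,
               membership_k = 5),
    scan = list(rule = "position", n_background = 50L, duplicate_rate = 0.3),
    proximity = list(n_residues = 220L, contact_cutoff = 8),
    cost = list(n_genes = 8L),
    lag = list(method = "tangent", delta_min = 0.05),
    expression = list(n_genes = 1000L, noise_sd = 0.25)
  )
}

.check_config_types <- function(cfg) {
  num1 <- function(x, key) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
      stop("config key '", key, "': expected a single number, got ",
           class(x)[1L], call. = FALSE)
    }
  }
  num1(cfg$seed, "seed")
  if (cfg$seed != round(cfg$seed)) stop("config key 'seed': expected an integer",
                                        call. = FALSE)
  if (!is.character(cfg$out_dir) || length(cfg$out_dir) != 1L) {
    stop("config key 'out_dir': expected a string", call. = FALSE)
  }
  for (s in names(cfg$stages)) {
    if (!is.logical(cfg$stages[[s]]) || length(cfg$stages[[s]]) != 1L) {
      stop("config key 'stages.", s, "': expected TRUE/FALSE", call. = FALSE)
    }
  }
  num1(cfg$ica$n_components, "ica.n_components")
  num1(cfg$expression$noise_sd, "expression.noise_sd")
  num1(cfg$scan$duplicate_rate, "scan.duplicate_rate")
  if (!cfg$scan$rule %in% c("position", "exact")) {
    stop("config key 'scan.rule': expected \"position\" or \"exact\"",
         call. = FALSE)
  }
  invisible(cfg)
}

.merge_config <- function(defaults, user, path = character()) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste(paste(c(path, unknown[1L]), collapse = "."), collapse = ", "),
         call. = FALSE)
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      defaults[[k]] <- .merge_config(defaults[[k]], user[[k]], c(path, k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML configuration (an empty or missing body yields the full
#' default configuration), rejects unknown keys, checks value types and
#' fills in defaults.
#'
#' @param path YAML file path, or NULL for pure defaults.
#' @param overrides named list applied on top of the file (e.g. a seed from
#'   the command line).
#' @return normalized configuration list of class `pipeline_config`.
#' @export
validate_config <- function(path = NULL, overrides = list()) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    if (!is.list(user)) stop("config must be a YAML mapping", call. = FALSE)
  }
  cfg <- .merge_config(.default_config(), user)
  cfg <- .merge_config(cfg, overrides)
  .check_config_types(cfg)
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = c("pipeline_config", "list"))
}

.stage_log <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes the enabled stages in dependency order (simulate -> ica,
#' proximity, scan, cost, lag), writes every artifact under
#' `config$out_dir` and a `manifest.json` listing each output file with its
#' MD5 hash, the parameters and the seed.
#'
#' @param config a `pipeline_config` from [validate_config()] (or a path /
#'   NULL, forwarded to it).
#' @param verbose print one line per stage.
#' @return invisible list of class `pipeline_report`: per-stage results plus
#'   `manifest`.
#' @export
run_pipeline <- function(config = NULL, verbose = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  report <- list(config = config)
  outputs <- character()
  emit <- function(path) outputs <<- c(outputs, path)

  if (!isTRUE(config$stages$simulate)) {
    stop("pipeline requires the simulate stage (no external inputs configured)",
         call. = FALSE)
  }
  .stage_log(verbose, "simulate", "generating synthetic inputs (seed ", seed, ")")
  sim <- simulate_expression(
    default_modulons(config$expression$n_genes, seed = seed),
    conditions = c(wt = 3L, gmos = 3L, evo1 = 3L, evo2 = 3L),
    n_genes = config$expression$n_genes,
    noise_sd = config$expression$noise_sd, seed = seed)
  expr_path <- file.path(out, "expression.tsv")
  write_expression(sim$expr, expr_path)
  emit(expr_path); emit(.sidecar_path(expr_path))

  ref <- synthetic_oxyr_reference(seed = seed)
  planted <- lapply(seq_len(nrow(natural_isolate_variants())), function(i) {
    v <- natural_isolate_variants()[i, ]
    planted_variant(v$genome_id,
                    wt = substr(v$substitution, 1L, 1L),
                    position = as.integer(gsub("[^0-9]", "", v$substitution)),
                    var = substr(v$substitution, nchar(v$substitution),
                                 nchar(v$substitution)),
                    synonymous_extras = 1L)
  })
  alleles <- simulate_alleles(ref, n_background = config$scan$n_background,
                              planted = planted,
                              duplicate_rate = config$scan$duplicate_rate,
                              seed = seed)
  fasta_path <- file.path(out, "alleles.fasta")
  write_alleles(alleles, fasta_path)
  emit(fasta_path); emit(paste0(fasta_path, ".truth.tsv"))

  structs <- simulate_structure(config$proximity$n_residues,
                                displacement = c(1.5, 0, 0), seed = seed)
  pdb_ox <- file.path(out, "oxidized.pdb")
  pdb_red <- file.path(out, "reduced.pdb")
  write_pdb(structs$A, pdb_ox); write_pdb(structs$B, pdb_red)
  emit(pdb_ox); emit(pdb_red)

  growth <- simulate_growth_curves(
    lag_by_dose = c("0" = 1, "1" = 1.6, "2.5" = 2.4, "5" = NA),
    strain = "GMOS", seed = seed)
  growth_tol <- simulate_growth_curves(
    lag_by_dose = c("0" = 1, "1" = 1.05, "2.5" = 1.1, "5" = 1.15),
    strain = "evolved", seed = seed + 1L)
  growth_path <- file.path(out, "growth.tsv")
  write_growth(rbind(growth$curves, growth_tol$curves), growth_path)
  emit(growth_path)
  report$simulate <- list(expression = expr_path, alleles = fasta_path,
                          structures = c(pdb_ox, pdb_red), growth = growth_path)

  if (isTRUE(config$stages$ica)) {
    .stage_log(verbose, "ica", "robust decomposition")
    Xc <- center_to_reference(sim$expr)
    fit <- robust_ica(Xc, n_components = config$ica$n_components,
                      n_restarts = config$ica$n_restarts,
                      min_recurrence = config$ica$min_recurrence, seed = seed)
    s_path <- file.path(out, "ica_S.tsv"); a_path <- file.path(out, "ica_A.tsv")
    write.table(data.frame(gene = rownames(fit$S), fit$S, check.names = FALSE),
                s_path, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(component = rownames(fit$A), fit$A,
                           check.names = FALSE),
                a_path, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(s_path); emit(a_path)
    regulons <- lapply(sim$modulons, `[[`, "member_genes")
    names(regulons) <- vapply(sim$modulons, `[[`, "", "name")
    mods <- lapply(seq_len(ncol(fit$S)), function(j) {
      im <- define_membership(fit$S[, j], k = config$ica$membership_k)
      mr <- match_regulon(im$members, regulons, nrow(fit$S))
      list(component = colnames(fit$S)[j], regulator = mr$regulator,
           p = mr$p_value, genes = im$members)
    })
    mod_path <- file.path(out, "imodulons.json")
    jsonlite::write_json(mods, mod_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    emit(mod_path)
    report$ica <- list(model = fit, imodulons = mods)
  }

  if (isTRUE(config$stages$proximity)) {
    .stage_log(verbose, "proximity", "mutation-to-feature distances")
    ox <- read_structure(pdb_ox, "oxidized")
    red <- read_structure(pdb_red, "reduced")
    pm <- proximity_matrix(ox, red, oxyr_ale_mutations())
    pm_path <- file.path(out, "proximity.tsv")
    write.table(pm, pm_path, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(pm_path)
    cls <- lapply(unique(pm$mutation), function(m) {
      c(list(mutation = m),
        classify_mutation(m, pm[pm$mutation == m, , drop = FALSE],
                          contact_cutoff = config$proximity$contact_cutoff))
    })
    cls_path <- file.path(out, "classification.json")
    jsonlite::write_json(cls, cls_path, auto_unbox = TRUE, pretty = TRUE)
    emit(cls_path)
    report$proximity <- list(matrix = pm, classification = cls)
  }

  if (isTRUE(config$stages$scan)) {
    .stage_log(verbose, "scan", "allele screen, rule=", config$scan$rule)
    meta <- natural_isolate_variants()[, c("genome_id", "amr")]
    res <- scan_alleles(alleles$records, ref$protein,
                        rule = config$scan$rule, metadata = meta)
    scan_path <- file.path(out, "screen.tsv")
    write.table(res$rows, scan_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    counts_path <- file.path(out, "screen_counts.json")
    jsonlite::write_json(as.list(res$counts), counts_path, auto_unbox = TRUE)
    emit(scan_path); emit(counts_path)
    report$scan <- res
  }

  if (isTRUE(config$stages$cost)) {
    .stage_log(verbose, "cost", "proteome-allocation ranking")
    phi <- c(ahpC = 0.020, katG = 0.012, ahpF = 0.009, dps = 0.005,
             sufA = 0.003, grxA = 0.002, trxC = 0.001, katE = 0.0005)
    model <- proteome_cost_model(phi[seq_len(config$cost$n_genes)],
                                 alpha = 0.5, Phi = 0.1)
    rep_cost <- regulon_cost(model, setNames(rep(4, length(model$phi_ref)),
                                             names(model$phi_ref)))
    cost_path <- file.path(out, "cost_report.tsv")
    write.table(rep_cost$per_gene, cost_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    emit(cost_path)
    report$cost <- rep_cost
  }

  if (isTRUE(config$stages$lag)) {
    .stage_log(verbose, "lag", "lag estimation and dose response")
    curves <- read_growth(growth_path)
    tab <- dose_response_table(curves, method = config$lag$method,
                               delta_min = config$lag$delta_min)
    lag_path <- file.path(out, "dose_response.tsv")
    write.table(tab, lag_path, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(lag_path)
    report$lag <- tab
  }

  manifest <- list(
    seed = seed,
    parameters = unclass(config),
    outputs = lapply(outputs, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  report$manifest <- manifest
  class(report) <- "pipeline_report"
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report:", length(x$manifest$outputs), "artifacts in",
      x$config$out_dir, "(seed", x$manifest$seed, ")\n")
  invisible(x)
}
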