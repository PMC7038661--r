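#' Construct a gene-by-sample log-expression matrix object
#'
#' Container for log-scale expression values together with the sample metadata
#' (condition and replicate labels) and a designated reference condition
#' against which i-modulon activities are interpreted.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row names
#'   are gene identifiers, column names sample identifiers.
#' @param condition character vector, one condition label per sample column.
#' @param replicate vector of replicate labels per sample (defaults to a
#'   within-condition counter).
#' @param reference_condition condition whose samples define the expression
#'   baseline. Defaults to the first condition.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `samples` (data.frame: sample_id, condition, replicate) and
#'   `reference_condition`.
#' @export
expression_matrix <- function(values, condition, replicate = NULL,
                              reference_condition = condition[1L]) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(values)) stop("expression values must not contain NA", call. = FALSE)
  if (ncol(values) < 2L) stop("need at least 2 samples", call. = FALSE)
  if (length(condition) != ncol(values)) {
    stop("condition must have one entry per sample column", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("g%04d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%03d", seq_len(ncol(values)))
  }
  condition <- as.character(condition)
  if (is.null(replicate)) {
    replicate <- stats::ave(seq_along(condition), condition, FUN = seq_along)
  }
  if (!reference_condition %in% condition) {
    stop("reference condition '", reference_condition,
         "' has no samples", call. = FALSE)
  }
  structure(
    list(
      values = values,
      samples = data.frame(
        sample_id = colnames(values),
        condition = condition,
        replicate = as.character(replicate),
        stringsAsFactors = FALSE
      ),
      reference_condition = reference_condition
    ),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values), "samples\n")
  cat("  conditions:", paste(unique(x$samples$condition), collapse = ", "), "\n")
  cat("  reference :", x$reference_condition, "\n")
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Write / read an expression matrix as TSV plus a metadata sidecar
#'
#' The matrix file has genes as rows and a header of sample ids; the sidecar
#' maps each sample to its condition and replicate and records the reference
#' condition in a comment line.
#'
#' @param x an `expression_matrix`.
#' @param path path of the matrix TSV; the sidecar is written next to it with
#'   suffix `.samples.tsv`.
#' @return `write_expression` returns `path` invisibly; `read_expression`
#'   returns an `expression_matrix`.
#' @export
write_expression <- function(x, path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(gene = rownames(x$values), x$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- .sidecar_path(path)
  con <- file(side, "w")
  on.exit(close(con))
  writeLines(paste0("# reference_condition=", x$reference_condition), con)
  write.table(x$samples, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1L]]
  side <- .sidecar_path(path)
  if (!file.exists(side)) stop("sample sidecar not found: ", side, call. = FALSE)
  first <- readLines(side, n = 1L)
  ref <- sub("^# reference_condition=", "", first)
  samples <- read.delim(side, comment.char = "#",
                        colClasses = "character")
  ord <- match(colnames(values), samples$sample_id)
  if (anyNA(ord)) stop("sidecar does not cover all samples", call. = FALSE)
  expression_matrix(values,
                    condition = samples$condition[ord],
                    replicate = samples$replicate[ord],
                    reference_condition = ref)
}

.sidecar_path <- function(path) {
  sub("\\.tsv$", "", path) |> paste0(".samples.tsv")
}
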