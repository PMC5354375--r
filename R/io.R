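#' Read a gene x sample expression matrix with its condition annotation
#'
#' Expects delimited text (tab or comma, auto-detected): a header row of
#' sample ids, first column of unique gene ids, and finite numeric values
#' (assumed already log-transformed and normalized; no preprocessing is
#' performed). The annotation file maps every sample id to `"WT"` or
#' `"KO"` in two columns (`sample_id`, `condition`).
#'
#' @param path Expression matrix file.
#' @param annotation_path Two-column sample annotation file.
#' @param drop_incomplete_genes If `TRUE`, genes with missing values are
#'   dropped (and reported via a message) instead of raising an error.
#' @param transpose If `TRUE`, the file is samples x genes and is
#'   transposed after reading.
#' @return A list of class `expression_data` with `expr` (numeric matrix,
#'   genes x samples) and `condition` (named character vector).
#' @export
read_expression <- function(path, annotation_path,
                            drop_incomplete_genes = FALSE,
                            transpose = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (!file.exists(annotation_path)) {
    stop(sprintf("file not found: %s", annotation_path))
  }
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (ncol(dt) < 2L) stop("expression file needs an id column plus data columns")
  ids <- as.character(dt[[1]])
  mat <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  if (transpose) mat <- t(mat)

  dup <- unique(rownames(mat)[duplicated(rownames(mat))])
  if (length(dup) > 0) {
    stop(sprintf("duplicated gene id(s): %s", paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(colnames(mat))) stop("duplicated sample ids")

  incomplete <- rownames(mat)[!stats::complete.cases(mat) |
                                rowSums(!is.finite(mat)) > 0]
  if (length(incomplete) > 0) {
    if (!drop_incomplete_genes) {
      stop(sprintf(
        "missing/non-finite values in gene(s): %s (use drop_incomplete_genes = TRUE to drop them)",
        paste(utils::head(incomplete, 10), collapse = ", ")
      ))
    }
    message(sprintf("dropping %d gene(s) with missing values: %s",
                    length(incomplete),
                    paste(utils::head(incomplete, 10), collapse = ", ")))
    mat <- mat[setdiff(rownames(mat), incomplete), , drop = FALSE]
  }

  ann <- data.table::fread(annotation_path, header = TRUE,
                           data.table = FALSE)
  if (ncol(ann) < 2L) stop("annotation needs columns sample_id, condition")
  cond <- stats::setNames(as.character(ann[[2]]), as.character(ann[[1]]))
  bad <- setdiff(unique(cond), c("WT", "KO"))
  if (length(bad) > 0) {
    stop(sprintf("annotation conditions must be WT or KO; found: %s",
                 paste(bad, collapse = ", ")))
  }
  unannotated <- setdiff(colnames(mat), names(cond))
  if (length(unannotated) > 0) {
    stop(sprintf("samples without annotation: %s",
                 paste(unannotated, collapse = ", ")))
  }
  structure(
    list(expr = mat, condition = cond[colnames(mat)]),
    class = "expression_data"
  )
}

#' @export
print.expression_data <- function(x, ...) {
  cat(sprintf("<expression_data> %d genes x %d samples (%d WT, %d KO)\n",
              nrow(x$expr), ncol(x$expr),
              sum(x$condition == "WT"), sum(x$condition == "KO")))
  invisible(x)
}

#' Write an expression matrix as tab-separated text
#'
#' Inverse of [read_expression()]: genes in rows, a `gene_id` first
#' column, sample ids in the header. Values are written at full precision
#' so a read round-trip is exact.
#'
#' @param expr Numeric matrix with row and column names.
#' @param path Output file.
#' @param condition Optional named condition vector; when given, a
#'   matching annotation file is written next to `path` with suffix
#'   `.annotation.tsv`, and its path returned as an attribute.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, condition = NULL) {
  # %.17g guarantees an exact numeric round trip through text
  chr <- matrix(sprintf("%.17g", expr), nrow = nrow(expr),
                dimnames = dimnames(expr))
  df <- data.frame(gene_id = rownames(expr), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  if (!is.null(condition)) {
    ann_path <- paste0(sub("\\.(tsv|csv|txt)$", "", path), ".annotation.tsv")
    data.table::fwrite(
      data.frame(sample_id = names(condition), condition = unname(condition)),
      ann_path, sep = "\t"
    )
    attr(path, "annotation_path") <- ann_path
  }
  invisible(path)
}

#' Write per-gene screening results as tab-separated text
#'
#' Rows are sorted ascending by log10 Bayes factor — most-downstream genes
#' first — with ties broken by gene id and failed genes placed last.
#' Numeric columns are printed with 6 significant digits.
#'
#' @param results Data frame from [screen_genes()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  required <- c("gene_id", "log10_bf", "alpha_hat", "loglik_m1",
                "loglik_m0", "label", "status")
  if (!all(required %in% names(results))) {
    stop("results must come from screen_genes()")
  }
  failed <- is.na(results$log10_bf)
  ord <- order(failed, results$log10_bf, results$gene_id, na.last = TRUE)
  out <- results[ord, required, drop = FALSE]
  for (col in c("log10_bf", "alpha_hat", "loglik_m1", "loglik_m0")) {
    out[[col]] <- signif(out[[col]], 6)
  }
  data.table::fwrite(out, path, sep = "\t", na = "NA")
  invisible(path)
}

#' Read / write a weighted DAG specification
#'
#' The on-disk format is YAML with two blocks: `nodes`, a list of
#' `{id, intercept, residual_sd}` records, and `edges`, a list of
#' `{from, to, weight}` records (absent for an edgeless graph).
#'
#' @param path File path.
#' @return `read_dag()` returns a [weighted_dag()]; `write_dag()` returns
#'   `path` invisibly.
#' @export
read_dag <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  spec <- yaml::read_yaml(path)
  if (is.null(spec$nodes)) stop("DAG file must contain a 'nodes' block")
  nodes <- vapply(spec$nodes, function(n) as.character(n$id), character(1))
  intercepts <- stats::setNames(
    vapply(spec$nodes, function(n) as.numeric(n$intercept %||% 0), numeric(1)),
    nodes
  )
  residual_sd <- stats::setNames(
    vapply(spec$nodes, function(n) as.numeric(n$residual_sd %||% 1), numeric(1)),
    nodes
  )
  edges <- if (length(spec$edges) > 0) {
    data.frame(
      from = vapply(spec$edges, function(e) as.character(e$from), character(1)),
      to = vapply(spec$edges, function(e) as.character(e$to), character(1)),
      weight = vapply(spec$edges, function(e) as.numeric(e$weight), numeric(1)),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(from = character(0), to = character(0), weight = numeric(0))
  }
  weighted_dag(nodes, edges, intercepts, residual_sd)
}

#' @rdname read_dag
#' @param dag A [weighted_dag()].
#' @export
write_dag <- function(dag, path) {
  stopifnot(inherits(dag, "weighted_dag"))
  spec <- list(
    nodes = lapply(dag$nodes, function(v) {
      list(id = v, intercept = dag$intercepts[[v]],
           residual_sd = dag$residual_sd[[v]])
    }),
    edges = if (nrow(dag$edges) > 0) {
      lapply(seq_len(nrow(dag$edges)), function(i) {
        list(from = dag$edges$from[i], to = dag$edges$to[i],
             weight = dag$edges$weight[i])
      })
    } else list()
  )
  yaml::write_yaml(spec, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
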