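#' Expression matrix with sample metadata
#'
#' Lightweight container for a gene x sample expression table plus per-sample
#' metadata (species, condition, replicate, dataset).
#'
#' @param values numeric matrix, rows = genes (rownames required), columns =
#'   samples (colnames required), non-negative.
#' @param sample_meta data.frame with columns `sample`, `species`,
#'   `condition` (`"control"` or `"stress"`), `replicate`, `dataset`; one row
#'   per column of `values`.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, sample_meta) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  req <- c("sample", "species", "condition", "replicate", "dataset")
  if (!all(req %in% names(sample_meta)))
    stop("sample_meta must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (!setequal(sample_meta$sample, colnames(values)) ||
      nrow(sample_meta) != ncol(values))
    stop("sample_meta rows must match matrix columns one-to-one",
         call. = FALSE)
  if (!all(sample_meta$condition %in% c("control", "stress")))
    stop("condition must be 'control' or 'stress'", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("gene ids must be unique", call. = FALSE)
  if (any(values < 0)) stop("expression values must be non-negative",
                            call. = FALSE)
  sample_meta <- sample_meta[match(colnames(values), sample_meta$sample), ]
  rownames(sample_meta) <- NULL
  for (ds in unique(sample_meta$dataset)) {
    cond <- sample_meta$condition[sample_meta$dataset == ds]
    if (!all(c("control", "stress") %in% cond))
      stop("dataset ", ds, " needs at least one control and one stress sample",
           call. = FALSE)
  }
  structure(list(values = values, sample_meta = sample_meta),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples;", length(unique(x$sample_meta$dataset)), "dataset(s)\n")
  invisible(x)
}

#' Read / write an expression matrix as TSV
#'
#' The expression TSV has a header row of sample ids with the first column
#' holding gene ids; the companion metadata TSV has columns `sample`,
#' `species`, `condition`, `replicate`, `dataset`.
#'
#' @param path expression TSV path.
#' @param meta_path sample metadata TSV path.
#' @return an [expression_matrix()].
#' @export
read_expression_tsv <- function(path, meta_path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  expression_matrix(values, meta)
}

#' @rdname read_expression_tsv
#' @param x an [expression_matrix()].
#' @export
write_expression_tsv <- function(x, path, meta_path) {
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$sample_meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(path, meta_path))
}

#' Read an ortholog/best-hit map TSV
#'
#' Columns: `gene_a`, `gene_b`, `score`, `reciprocal`, optional `target_gene`
#' (homolog id in the target species).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_ortholog_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_a", "gene_b") %in% names(map)))
    stop("ortholog map needs columns gene_a, gene_b", call. = FALSE)
  if (anyDuplicated(map[, c("gene_a", "gene_b")]))
    stop("duplicate ortholog pairs in map", call. = FALSE)
  map
}

#' Read a gene annotation TSV
#'
#' Columns: `gene`, `go_terms` (semicolon-separated, possibly empty),
#' `literature` (0/1).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(go_terms = "character"))
  if (!all(c("gene", "go_terms", "literature") %in% names(ann)))
    stop("annotation table needs columns gene, go_terms, literature",
         call. = FALSE)
  ann$go_terms[is.na(ann$go_terms)] <- ""
  ann
}
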