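#' Per-dataset fold change of stress versus control expression
#'
#' For every gene, the fold change is the ratio of mean stress expression to
#' mean control expression within a dataset. When either group mean is exactly
#' zero a pseudocount is added to both means so the ratio stays finite and
#' positive; non-degenerate values are left untouched.
#'
#' @param expr an [expression_matrix()].
#' @param dataset dataset id to use; `NULL` computes every dataset.
#' @param pseudocount value added to both group means when either is zero.
#' @return data.frame `dataset`, `gene`, `fc`, `log2fc`.
#' @export
compute_fold_change <- function(expr, dataset = NULL, pseudocount = 0.5) {
  stopifnot(inherits(expr, "expression_matrix"))
  meta <- expr$sample_meta
  datasets <- if (is.null(dataset)) unique(meta$dataset) else dataset
  out <- lapply(datasets, function(ds) {
    sel <- meta$dataset == ds
    if (!any(sel)) stop("unknown dataset: ", ds, call. = FALSE)
    ctl <- meta$sample[sel & meta$condition == "control"]
    str <- meta$sample[sel & meta$condition == "stress"]
    if (length(ctl) == 0 || length(str) == 0)
      stop("dataset ", ds, " lacks a control or stress group", call. = FALSE)
    mc <- rowMeans(expr$values[, ctl, drop = FALSE])
    ms <- rowMeans(expr$values[, str, drop = FALSE])
    deg <- mc == 0 | ms == 0
    fc <- ifelse(deg, (ms + pseudocount) / (mc + pseudocount), ms / mc)
    data.frame(dataset = ds, gene = rownames(expr$values),
               fc = fc, log2fc = log2(fc),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Assign upregulation quartile ranks within each dataset
#'
#' Genes are sorted by ascending log2 fold change (ties broken by gene id,
#' stable) and the gene at ascending position `p` of `n` receives rank
#' `1 + floor(4 * (p - 1) / n)`, so the largest fold change always lands in
#' the top quartile (rank 4).
#'
#' @param fc data.frame as from [compute_fold_change()] (columns `dataset`,
#'   `gene`, `log2fc`).
#' @return data.frame `dataset`, `gene`, `rank` (integer 1-4).
#' @export
assign_quartile_ranks <- function(fc) {
  stopifnot(all(c("dataset", "gene", "log2fc") %in% names(fc)))
  out <- lapply(split(fc, fc$dataset), function(d) {
    n <- nrow(d)
    if (n < 4) stop("need at least 4 genes per dataset to rank", call. = FALSE)
    ord <- order(d$log2fc, d$gene)
    r <- integer(n)
    r[ord] <- as.integer(1 + floor(4 * (seq_len(n) - 1) / n))
    data.frame(dataset = d$dataset, gene = d$gene, rank = r,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Aggregate per-dataset quartile ranks to one species rank per gene
#'
#' The species rank is the maximum per-dataset rank: a gene counts as detected
#' in an upregulated cluster if any dataset places it there, and the maximum
#' preserves the 1-4 range.
#'
#' @param ranks data.frame as from [assign_quartile_ranks()], possibly
#'   spanning several datasets.
#' @return data.frame `gene`, `rank`.
#' @export
aggregate_species_rank <- function(ranks) {
  stopifnot(all(c("gene", "rank") %in% names(ranks)))
  if (nrow(ranks) == 0) stop("no ranks to aggregate", call. = FALSE)
  agg <- stats::aggregate(rank ~ gene, data = ranks, FUN = max)
  agg[order(agg$gene), , drop = FALSE] -> agg
  rownames(agg) <- NULL
  agg
}

#' Genes in the top upregulation quartile
#'
#' @param species_ranks data.frame as from [aggregate_species_rank()].
#' @return character vector of genes with aggregated rank 4.
#' @export
top_quartile_set <- function(species_ranks) {
  stopifnot(all(c("gene", "rank") %in% names(species_ranks)))
  sort(species_ranks$gene[species_ranks$rank == 4])
}

#' Intersect two species' top-quartile sets through an ortholog map
#'
#' @param set_a,set_b character vectors of top-quartile genes of the two
#'   species.
#' @param ortholog_map data.frame with columns `gene_a`, `gene_b` (and
#'   optionally `target_gene`).
#' @return list with `pairs` (the map rows with `gene_a` in `set_a` and
#'   `gene_b` in `set_b`, i.e. matched ortholog groups) and `venn`
#'   (named counts: `a_only` genes of `set_a` in no matched pair, `shared`
#'   matched ortholog groups, `b_only` likewise for `set_b`).
#' @export
intersect_top_sets <- function(set_a, set_b, ortholog_map) {
  hit <- ortholog_map$gene_a %in% set_a & ortholog_map$gene_b %in% set_b
  pairs <- ortholog_map[hit, , drop = FALSE]
  rownames(pairs) <- NULL
  venn <- c(a_only = length(setdiff(set_a, pairs$gene_a)),
            shared = nrow(pairs),
            b_only = length(setdiff(set_b, pairs$gene_b)))
  list(pairs = pairs, venn = venn)
}

#' Map matched ortholog pairs to target-species candidates
#'
#' One candidate per matched ortholog group, carrying the target-species
#' homolog id from the map's `target_gene` column. Pairs without a target
#' homolog are kept with a gap flag (`target_missing = TRUE`) and a warning,
#' rather than silently dropped.
#'
#' @param pairs data.frame of matched pairs (from [intersect_top_sets()]).
#' @param ortholog_map the full map; only used when `pairs` lacks a
#'   `target_gene` column.
#' @return data.frame `gene` (target id, or the model-species id when the
#'   homolog is missing), `source = "interspecies"`, `ortholog_a`,
#'   `ortholog_b`, `target_missing`.
#' @export
map_to_target <- function(pairs, ortholog_map = NULL) {
  if (nrow(pairs) == 0)
    return(data.frame(gene = character(0), source = character(0),
                      ortholog_a = character(0), ortholog_b = character(0),
                      target_missing = logical(0), stringsAsFactors = FALSE))
  if (!"target_gene" %in% names(pairs) && !is.null(ortholog_map)) {
    idx <- match(paste(pairs$gene_a, pairs$gene_b),
                 paste(ortholog_map$gene_a, ortholog_map$gene_b))
    pairs$target_gene <- ortholog_map$target_gene[idx]
  }
  tgt <- if ("target_gene" %in% names(pairs)) pairs$target_gene else
    rep(NA_character_, nrow(pairs))
  missing <- is.na(tgt) | tgt == ""
  if (any(missing))
    warning(sum(missing), " matched pair(s) lack a target-species homolog; ",
            "kept with target_missing = TRUE", call. = FALSE)
  data.frame(gene = ifelse(missing, pairs$gene_a, tgt),
             source = "interspecies",
             ortholog_a = pairs$gene_a, ortholog_b = pairs$gene_b,
             target_missing = missing,
             stringsAsFactors = FALSE, row.names = NULL)
}

# GO component of the combined score: best (maximum) matching stress term
.go_points <- c("GO:0009409" = 4L, "GO:0006979" = 3L, "GO:0050896" = 2L)

#' Combined 0-9 candidate relevance score
#'
#' Additive score of three components: a GO component worth 4 points for
#' response to cold (GO:0009409), 3 for response to oxidative stress
#' (GO:0006979) or 2 for response to stimulus (GO:0050896) -- the best
#' matching term counts, unknown terms contribute nothing; the species
#' upregulation-cluster rank (1-4, or 0 when the ortholog was not detected in
#' an upregulated cluster); and 1 point of literature evidence. The attainable
#' maximum is therefore 4 + 4 + 1 = 9.
#'
#' @param go_terms character vector of GO ids (or a single semicolon-separated
#'   string).
#' @param species_rank integer in 0..4.
#' @param literature_flag logical.
#' @return integer score in 0..9.
#' @export
combined_score <- function(go_terms, species_rank, literature_flag) {
  if (length(go_terms) == 1 && grepl(";", go_terms))
    go_terms <- strsplit(go_terms, ";", fixed = TRUE)[[1]]
  go_terms <- go_terms[!is.na(go_terms) & nzchar(go_terms)]
  if (!species_rank %in% 0:4)
    stop("species_rank must be in 0..4", call. = FALSE)
  goc <- if (any(go_terms %in% names(.go_points)))
    max(.go_points[intersect(go_terms, names(.go_points))]) else 0L
  as.integer(goc + species_rank + as.logical(literature_flag))
}

#' Assemble and score the candidate panel
#'
#' Unites interspecies-derived and literature-derived candidates, collapses
#' duplicated target gene ids into one entry keeping both source tags,
#' attaches annotations and species ranks, computes the combined score and
#' sorts by score (descending) with ties broken by gene id.
#'
#' @param interspecies data.frame with a `gene` column (as from
#'   [map_to_target()]).
#' @param literature character vector of literature-derived gene ids, or a
#'   data.frame with a `gene` column.
#' @param annotations optional data.frame (`gene`, `go_terms`, `literature`);
#'   genes absent from it get no GO component. The literature component is 1
#'   for any literature-derived candidate or annotation-flagged gene.
#' @param species_ranks optional data.frame (`gene`, `rank`) of aggregated
#'   species ranks keyed by *target* gene id; absent genes get rank 0.
#' @return data.frame `gene`, `source`, `go_terms`, `species_rank`,
#'   `literature_flag`, `score`, sorted by decreasing score.
#' @export
assemble_panel <- function(interspecies, literature,
                           annotations = NULL, species_ranks = NULL) {
  inter_genes <- if (is.data.frame(interspecies)) interspecies$gene else
    as.character(interspecies)
  lit_genes <- if (is.data.frame(literature)) literature$gene else
    as.character(literature)
  genes <- union(inter_genes, lit_genes)
  source <- vapply(genes, function(g) {
    paste(c("interspecies"[g %in% inter_genes],
            "literature"[g %in% lit_genes]), collapse = ";")
  }, character(1))
  go <- rep("", length(genes))
  lit_flag <- genes %in% lit_genes
  if (!is.null(annotations)) {
    idx <- match(genes, annotations$gene)
    go <- ifelse(is.na(idx), "", annotations$go_terms[idx])
    lit_flag <- lit_flag |
      (!is.na(idx) & as.logical(annotations$literature[idx]))
  }
  rank <- rep(0L, length(genes))
  if (!is.null(species_ranks)) {
    idx <- match(genes, species_ranks$gene)
    rank <- ifelse(is.na(idx), 0L, species_ranks$rank[idx])
  }
  score <- mapply(combined_score, go, rank, lit_flag)
  out <- data.frame(gene = genes, source = source, go_terms = go,
                    species_rank = as.integer(rank),
                    literature_flag = lit_flag,
                    score = as.integer(score),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$score, out$gene), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
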