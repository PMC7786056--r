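#' Read a STRING-export-style interaction TSV
#'
#' Expected columns: `node1`, `node2`, per-channel scores in `[0, 1]` (for
#' example `textmining`, `experiments`, `databases`) and optionally a
#' precombined `combined_score`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_interaction_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("node1", "node2") %in% names(tab)))
    stop("interaction table needs columns node1, node2", call. = FALSE)
  if (any(tab$node1 == tab$node2)) stop("self-edges are not allowed",
                                        call. = FALSE)
  key <- paste(pmin(tab$node1, tab$node2), pmax(tab$node1, tab$node2))
  if (anyDuplicated(key)) stop("each unordered pair may occur at most once",
                               call. = FALSE)
  tab
}

#' Combine per-channel interaction scores by probabilistic OR
#'
#' The combined score of the selected evidence channels is
#' `1 - prod(1 - s_i)`: the probability that at least one channel supports
#' the interaction, treating channels as independent. When `use_precombined`
#' is set and the table carries a `combined_score` column, that column is
#' passed through unchanged. An optional prior correction (the source
#' database's random-interaction prior, 0.041) first removes the prior from
#' each channel, combines, then adds it back.
#'
#' @param table data.frame of edges with channel columns.
#' @param channels character vector of channel column names to combine.
#' @param use_precombined pass through an existing `combined_score` column.
#' @param prior `NULL` (default, no correction) or a prior probability.
#' @return the table with a `combined_score` column.
#' @export
combine_channel_scores <- function(table,
                                   channels = c("textmining", "experiments",
                                                "databases"),
                                   use_precombined = FALSE,
                                   prior = NULL) {
  if (use_precombined && "combined_score" %in% names(table))
    return(table)
  channels <- intersect(channels, names(table))
  if (length(channels) == 0)
    stop("none of the requested channels are present", call. = FALSE)
  s <- as.matrix(table[, channels, drop = FALSE])
  if (any(s < 0 | s > 1, na.rm = TRUE))
    stop("channel scores must lie in [0, 1]", call. = FALSE)
  s[is.na(s)] <- 0
  if (!is.null(prior)) {
    s <- pmax((s - prior) / (1 - prior), 0)
    combined <- 1 - apply(1 - s, 1, prod)
    combined <- combined * (1 - prior) + prior
  } else {
    combined <- 1 - apply(1 - s, 1, prod)
  }
  table$combined_score <- as.numeric(combined)
  table
}

#' Filter interaction edges by combined score
#'
#' Keeps edges whose combined score is at least the threshold (inclusive,
#' matching the "minimum required score" semantics of interaction databases;
#' the study used 0.15).
#'
#' @param table data.frame with a `combined_score` column (computed via
#'   [combine_channel_scores()] if absent).
#' @param threshold minimum combined score in `[0, 1]`.
#' @param ... passed to [combine_channel_scores()] when the column is absent.
#' @return the filtered table.
#' @export
filter_edges <- function(table, threshold = 0.15, ...) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (!"combined_score" %in% names(table))
    table <- combine_channel_scores(table, ...)
  out <- table[table$combined_score >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Induce the candidate-gene network from a filtered edge table
#'
#' Nodes are the candidate genes; edges are the table rows with both
#' endpoints in the candidate set. Candidates without any surviving edge are
#' retained as isolated nodes and flagged.
#'
#' @param candidates character vector of candidate gene ids.
#' @param table filtered edge table with `node1`, `node2`, `combined_score`.
#' @return object of class `gene_network`: list with `nodes` (data.frame
#'   `gene`, `regulation`, `score`, `isolated`) and `edges` (data.frame
#'   `node1`, `node2`, `score`).
#' @export
induce_subgraph <- function(candidates, table) {
  stopifnot(length(candidates) > 0)
  candidates <- unique(candidates)
  keep <- table$node1 %in% candidates & table$node2 %in% candidates
  edges <- data.frame(node1 = table$node1[keep], node2 = table$node2[keep],
                      score = if ("combined_score" %in% names(table))
                        table$combined_score[keep] else NA_real_,
                      stringsAsFactors = FALSE, row.names = NULL)
  connected <- union(edges$node1, edges$node2)
  nodes <- data.frame(gene = sort(candidates),
                      regulation = "none",
                      score = NA_real_,
                      isolated = !sort(candidates) %in% connected,
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(nodes = nodes, edges = edges), class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat("gene_network:", nrow(x$nodes), "nodes,", nrow(x$edges), "edges (",
      sum(x$nodes$isolated), "isolated )\n")
  invisible(x)
}

#' Annotate network nodes with regulation calls and relevance scores
#'
#' @param net a `gene_network`.
#' @param regulation named character vector (gene -> `"up"`, `"down"` or
#'   `"none"`); unnamed genes keep `"none"`.
#' @param scores named numeric vector of combined relevance scores; exported
#'   as node border weight (proportional to the score).
#' @return the annotated network.
#' @export
annotate_network <- function(net, regulation = NULL, scores = NULL) {
  stopifnot(inherits(net, "gene_network"))
  if (!is.null(regulation)) {
    bad <- setdiff(unique(regulation), c("up", "down", "none"))
    if (length(bad) > 0) stop("invalid regulation value(s): ",
                              paste(bad, collapse = ", "), call. = FALSE)
    idx <- match(net$nodes$gene, names(regulation))
    net$nodes$regulation <- ifelse(is.na(idx), net$nodes$regulation,
                                   regulation[idx])
  }
  if (!is.null(scores)) {
    idx <- match(net$nodes$gene, names(scores))
    net$nodes$score <- ifelse(is.na(idx), net$nodes$score, scores[idx])
  }
  net
}

#' Summarize a gene network
#'
#' @param net a `gene_network`.
#' @return named integer vector: `nodes`, `edges`, `up`, `down`.
#' @export
summarize_network <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  c(nodes = nrow(net$nodes), edges = nrow(net$edges),
    up = sum(net$nodes$regulation == "up"),
    down = sum(net$nodes$regulation == "down"))
}

# igraph object with node/edge attributes for export
.as_igraph <- function(net) {
  nodes <- net$nodes
  names(nodes)[names(nodes) == "gene"] <- "name"
  names(nodes)[names(nodes) == "score"] <- "relevance_score"
  nodes$relevance_score[is.na(nodes$relevance_score)] <- 0
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = nodes)
}

#' Export a gene network as GraphML or edge-list TSV
#'
#' GraphML carries node attributes `regulation` and `relevance_score` (the
#' border-weight proxy proportional to the combined score) and the edge
#' attribute `score`.
#'
#' @param net a `gene_network`.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
export_graphml <- function(net, path) {
  igraph::write_graph(.as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' @rdname export_graphml
#' @export
export_edgelist <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
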