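#' The packaged tea-plant candidate panel
#'
#' The 45-gene candidate panel: 9 interspecies-derived candidates (top-quartile
#' upregulated orthologs shared by the two model species, mapped to tea-plant
#' homologs) and 36 literature-derived cold/drought-response genes. Genes whose
#' accession is not available carry their trivial name as id and are marked
#' `id_source = "synthetic"`. A sidecar file
#' (`table1_excluded_literature.tsv`) records the literature genes that were
#' screened but not part of the 45-gene expression panel.
#'
#' @param excluded return the sidecar table instead of the panel.
#' @return data.frame `source`, `gene_id`, `description`, `trivial_name`,
#'   `id_source`.
#' @export
tea_panel_fixture <- function(excluded = FALSE) {
  f <- if (excluded) "table1_excluded_literature.tsv" else
    "table1_candidates.tsv"
  path <- system.file("extdata", f, package = "teastress")
  if (path == "") stop("fixture not found; is the package installed?",
                       call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' Defaults follow the study's stated settings: interaction-score threshold
#' 0.15 over the textmining/experiments/databases channels, significance
#' level 0.05, Actin as qPCR reference, three correlation-pattern clusters.
#'
#' @param seed integer seed for the synthetic stage.
#' @param threshold interaction-score threshold.
#' @param alpha significance level.
#' @param reference_gene qPCR reference gene id.
#' @param channels interaction evidence channels.
#' @param k_clusters correlation-pattern cluster count.
#' @param sim a [sim_config()] for the synthetic stage (its seed is
#'   overridden by `seed`).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            threshold = 0.15,
                            alpha = 0.05,
                            reference_gene = "Actin",
                            channels = c("textmining", "experiments",
                                         "databases"),
                            k_clusters = 3L,
                            sim = NULL) {
  stopifnot(threshold >= 0, threshold <= 1, alpha > 0, alpha < 1)
  if (is.null(sim)) sim <- sim_config(seed = seed,
                                      reference_gene = reference_gene)
  sim$seed <- as.integer(seed)
  sim$reference_gene <- reference_gene
  structure(list(seed = as.integer(seed), threshold = threshold,
                 alpha = alpha, reference_gene = reference_gene,
                 channels = channels, k_clusters = as.integer(k_clusters),
                 sim = sim),
            class = "pipeline_config")
}

#' Run the full synthetic-data pipeline end to end
#'
#' Stages: simulate (all inputs under the config seed), prioritize
#' (fold changes, quartile ranks, top-quartile intersection, target mapping,
#' scored panel), network (channel combination, 0.15 filtering, candidate
#' subgraph), qpcr (Livak quantification, response categories), phenotype
#' (REC, tolerant genotype) and stats (profile clustering, treatment-pair
#' PCA, cross-treatment correlations with pattern clusters). Every
#' intermediate table is written to `out_dir` and a structured report of
#' per-stage record counts is returned.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @return list report: per-stage counts, the tolerant genotype, warnings.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, stages = list(), warnings = character(0))
  note <- function(w) report$warnings <<- c(report$warnings, conditionMessage(w))
  tsv <- function(x, f) utils::write.table(x, file.path(out_dir, f),
                                           sep = "\t", quote = FALSE,
                                           row.names = FALSE)

  # -- simulate ---------------------------------------------------------
  t0 <- Sys.time()
  paths <- simulate_study(config$sim, out_dir)
  two <- gen_two_species_expression(config$sim)
  ann <- gen_annotations(two$ortholog_map$target_gene, config$sim)
  cqd <- gen_cq_data(config$sim)
  recd <- gen_rec_data(config$sim)
  report$stages$simulate <- list(
    genes_per_species = config$sim$n_genes_per_species,
    ortholog_pairs = nrow(two$ortholog_map),
    panel_genes = nrow(config$sim$panel_spec),
    seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  # -- prioritize -------------------------------------------------------
  t0 <- Sys.time()
  ranks_a <- aggregate_species_rank(
    assign_quartile_ranks(compute_fold_change(two$expr_a)))
  ranks_b <- aggregate_species_rank(
    assign_quartile_ranks(compute_fold_change(two$expr_b)))
  hit <- withCallingHandlers(
    intersect_top_sets(top_quartile_set(ranks_a), top_quartile_set(ranks_b),
                       two$ortholog_map),
    warning = function(w) { note(w); invokeRestart("muffleWarning") })
  inter <- map_to_target(hit$pairs)
  # score against the species rank of the detected orthologs (max of both)
  tgt_rank <- data.frame(
    gene = inter$gene,
    rank = pmax(ranks_a$rank[match(inter$ortholog_a, ranks_a$gene)],
                ranks_b$rank[match(inter$ortholog_b, ranks_b$gene)]),
    stringsAsFactors = FALSE)
  lit_genes <- setdiff(
    ann$annotations$gene[ann$annotations$literature == 1], inter$gene)
  panel <- assemble_panel(inter, lit_genes, annotations = ann$annotations,
                          species_ranks = tgt_rank)
  tsv(panel, "panel.tsv")
  report$stages$prioritize <- list(
    venn = as.list(hit$venn),
    interspecies_candidates = nrow(inter),
    literature_candidates = length(lit_genes),
    panel_size = nrow(panel),
    seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  # -- network ----------------------------------------------------------
  t0 <- Sys.time()
  edges <- read_interaction_tsv(paths[["interactions"]])
  edges <- combine_channel_scores(edges, channels = config$channels)
  edges <- filter_edges(edges, threshold = config$threshold)
  net <- induce_subgraph(panel$gene, edges)
  net <- annotate_network(net,
                          scores = stats::setNames(panel$score, panel$gene))
  export_graphml(net, file.path(out_dir, "network.graphml"))
  export_edgelist(net, file.path(out_dir, "network_edges.tsv"))
  report$stages$network <- c(
    as.list(summarize_network(net)),
    seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  # -- qpcr -------------------------------------------------------------
  t0 <- Sys.time()
  rel <- quantify_panel(cqd$cq, reference = config$reference_gene,
                        alpha = config$alpha)
  calls <- classify_response(rel)
  tsv(rel, "relative_expression.tsv")
  tsv(calls, "response_calls.tsv")
  report$stages$qpcr <- list(
    genes = length(unique(rel$gene)),
    significant_cells = sum(rel$significant, na.rm = TRUE),
    categories = as.list(table(calls$category)),
    seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  # -- phenotype --------------------------------------------------------
  t0 <- Sys.time()
  rec <- read_conductivity_csv(paths[["conductivity"]])
  sel <- withCallingHandlers(
    select_tolerant_genotype(rec),
    warning = function(w) { note(w); invokeRestart("muffleWarning") })
  tsv(sel$summary, "rec_summary.tsv")
  report$stages$phenotype <- list(
    genotypes = length(unique(rec$genotype)),
    tolerant_genotype = sel$tolerant_genotype,
    seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  # -- stats ------------------------------------------------------------
  t0 <- Sys.time()
  prof <- profile_matrix(rel)
  wc <- ward_cluster(prof, k = min(config$k_clusters, nrow(prof)))
  tsv(data.frame(gene = rownames(prof), cluster = wc$labels), "clusters.tsv")
  pca_pairs <- list(c("Cold", "RecCold"), c("Drought", "RecDrought"),
                    c("Cold", "Drought"))
  pca_report <- list()
  for (pr in pca_pairs) {
    p <- pca_pair(prof[, pr])
    nm <- paste(pr, collapse = "_")
    tsv(data.frame(gene = rownames(prof), p$scores),
        sprintf("pca_scores_%s.tsv", nm))
    pca_report[[nm]] <- p$var_explained[1]
  }
  # replicate-level fold changes for the correlation analysis
  reps <- replicate_log2fc(cqd$cq, reference = config$reference_gene)
  corr <- treatment_correlations(reps, alpha = config$alpha)
  tsv(corr$long, "correlations.tsv")
  cl <- correlation_clusters(corr, k = config$k_clusters)
  tsv(data.frame(gene = names(cl), cluster = as.integer(cl)),
      "correlation_clusters.tsv")
  report$stages$stats <- list(
    profile_genes = nrow(prof),
    pca_pc1_fraction = pca_report,
    significant_correlations = sum(corr$long$significant),
    correlation_clusters = length(unique(cl)),
    seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  report
}

#' Replicate-level log2 fold changes versus control
#'
#' Helper connecting the Cq table to the correlation analysis: per gene,
#' treatment and replicate, `log2fc = -(dCq - mean dCq_control)` with
#' `dCq = Cq_gene - Cq_ref` matched by replicate.
#'
#' @param cq data.frame (`gene`, `treatment`, `replicate`, `cq`).
#' @param reference reference gene id.
#' @param control control treatment label.
#' @return data.frame `gene`, `treatment`, `replicate`, `log2fc`.
#' @export
replicate_log2fc <- function(cq, reference = "Actin", control = "Control") {
  ref <- cq[cq$gene == reference, ]
  ref_key <- paste(ref$treatment, ref$replicate)
  out <- cq[cq$gene != reference, ]
  dcq <- out$cq - ref$cq[match(paste(out$treatment, out$replicate), ref_key)]
  ctl_mean <- tapply(dcq[out$treatment == control],
                     out$gene[out$treatment == control], mean)
  out$log2fc <- -(dcq - ctl_mean[out$gene])
  out <- out[out$treatment != control,
             c("gene", "treatment", "replicate", "log2fc")]
  rownames(out) <- NULL
  out
}

#' Validate pipeline input files against their schemas
#'
#' Report-only check of every provided input path: required columns, value
#' ranges and cross-field constraints, with row-numbered diagnostics.
#'
#' @param paths named list/vector of file paths; recognized names are
#'   `cq`, `conductivity`, `orthologs`, `annotations`, `interactions`.
#' @param reference_gene reference gene the Cq table must contain.
#' @return data.frame `file`, `row`, `issue` (zero rows when clean).
#' @export
validate_inputs <- function(paths, reference_gene = "Actin") {
  issues <- list()
  add <- function(file, row, issue)
    issues[[length(issues) + 1L]] <<- data.frame(
      file = file, row = row, issue = issue, stringsAsFactors = FALSE)
  for (nm in names(paths)) {
    path <- paths[[nm]]
    if (!file.exists(path)) { add(nm, NA_integer_, "file not found"); next }
    tab <- tryCatch(
      if (grepl("\\.csv$", path)) utils::read.csv(path, stringsAsFactors = FALSE)
      else utils::read.delim(path, stringsAsFactors = FALSE),
      error = function(e) NULL)
    if (is.null(tab)) { add(nm, NA_integer_, "unreadable"); next }
    if (nm == "cq") {
      req <- c("gene", "treatment", "replicate", "cq")
      miss <- setdiff(req, names(tab))
      if (length(miss)) { add(nm, NA, paste("missing columns:",
                                            paste(miss, collapse = ","))); next }
      if (!reference_gene %in% tab$gene)
        add(nm, NA_integer_,
            paste0("reference gene '", reference_gene, "' absent"))
      bad <- which(!is.na(tab$cq) & tab$cq <= 0)
      for (r in bad) add(nm, r, "cq must be positive")
    } else if (nm == "conductivity") {
      req <- c("genotype", "treatment", "L1", "L2")
      miss <- setdiff(req, names(tab))
      if (length(miss)) { add(nm, NA, paste("missing columns:",
                                            paste(miss, collapse = ","))); next }
      for (r in which(tab$L2 <= 0)) add(nm, r, "L2 must be positive")
      for (r in which(tab$L1 > tab$L2)) add(nm, r, "L1 exceeds L2")
      for (r in which(tab$L1 <= 0)) add(nm, r, "L1 must be positive")
    } else if (nm == "orthologs") {
      req <- c("gene_a", "gene_b")
      miss <- setdiff(req, names(tab))
      if (length(miss)) { add(nm, NA, paste("missing columns:",
                                            paste(miss, collapse = ","))); next }
      dup <- which(duplicated(tab[, c("gene_a", "gene_b")]))
      for (r in dup) add(nm, r, "duplicate ortholog pair")
    } else if (nm == "annotations") {
      miss <- setdiff(c("gene", "go_terms", "literature"), names(tab))
      if (length(miss)) add(nm, NA, paste("missing columns:",
                                          paste(miss, collapse = ",")))
    } else if (nm == "interactions") {
      miss <- setdiff(c("node1", "node2"), names(tab))
      if (length(miss)) { add(nm, NA, paste("missing columns:",
                                            paste(miss, collapse = ","))); next }
      for (r in which(tab$node1 == tab$node2)) add(nm, r, "self-edge")
      sc <- intersect(c("textmining", "experiments", "databases",
                        "combined_score"), names(tab))
      for (col in sc)
        for (r in which(tab[[col]] < 0 | tab[[col]] > 1))
          add(nm, r, paste0(col, " outside [0,1]"))
    }
  }
  if (length(issues) == 0)
    return(data.frame(file = character(0), row = integer(0),
                      issue = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, issues)
  rownames(out) <- NULL
  out
}
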