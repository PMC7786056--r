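#' Default qPCR panel specification
#'
#' A panel of gene groups with per-treatment true log2 fold changes used by
#' [gen_cq_data()]. The groups mirror the magnitude classes seen in long-term
#' cold/drought induction experiments on tea plant: a small set of very
#' strongly cold-induced genes (over 30-fold), genes induced in both stresses,
#' cold-specific and drought-specific responders, a recovery-elevated group,
#' a downregulated group and an unresponsive background.
#'
#' @param n_per_group integer, genes per group.
#' @return data.frame with columns `gene`, `group`, and one log2-effect column
#'   per treatment (`Cold`, `RecCold`, `Drought`, `RecDrought`). The Control
#'   treatment is the baseline and carries no column.
#' @export
default_panel_spec <- function(n_per_group = 4L) {
  groups <- list(
    strong_cold   = c(Cold = 5,   RecCold = 2,   Drought = 0.5, RecDrought = 0),
    both_up       = c(Cold = 2,   RecCold = 1,   Drought = 2,   RecDrought = 1),
    cold_specific = c(Cold = 3,   RecCold = 1,   Drought = 0,   RecDrought = 0),
    drought_specific = c(Cold = 0, RecCold = 0,  Drought = 2,   RecDrought = 1),
    recovery      = c(Cold = 0.5, RecCold = 3,   Drought = 0.5, RecDrought = 3),
    down          = c(Cold = -2,  RecCold = -1,  Drought = -2,  RecDrought = -1),
    unresponsive  = c(Cold = 0,   RecCold = 0,   Drought = 0,   RecDrought = 0)
  )
  out <- do.call(rbind, lapply(names(groups), function(g) {
    eff <- groups[[g]]
    data.frame(
      gene = sprintf("%s_%02d", g, seq_len(n_per_group)),
      group = g,
      Cold = eff[["Cold"]], RecCold = eff[["RecCold"]],
      Drought = eff[["Drought"]], RecDrought = eff[["RecDrought"]],
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generators. Defaults reproduce
#' the study-like conditions used throughout the package tests: 100 genes per
#' species with 3 control and 3 cold replicates, 9 planted conserved ortholog
#' pairs upregulated log2 4-fold against log-scale noise sd 0.3, a qPCR panel
#' with Cq noise sd 0.2 cycles, and 10 genotypes of which one is planted as the
#' most stress-tolerant.
#'
#' @param seed integer; all generator randomness derives from it.
#' @param n_genes_per_species genes simulated per species.
#' @param n_ortholog_pairs rows of the emitted ortholog map (planted pairs
#'   plus background pairs).
#' @param n_planted_conserved ortholog pairs planted in the top upregulation
#'   quartile of both species.
#' @param log2_effect_size true log2 fold change of planted responders.
#' @param noise_sd Gaussian sd of log2 expression noise.
#' @param n_replicates biological replicates per condition.
#' @param panel_spec data.frame as from [default_panel_spec()].
#' @param n_genotypes genotypes in the conductivity screen.
#' @param tolerant_index which genotype is planted as most tolerant.
#' @param background_edge_density probability of a background interaction edge.
#' @param n_specific_responders species-specific upregulated genes per species;
#'   `NULL` fills the top quartile (`ceiling(n/4) - n_planted_conserved`).
#' @param n_datasets_a,n_datasets_b independent datasets generated per species
#'   (the multi-dataset mode emulates aggregating several expression series).
#' @param cq_noise_sd Gaussian sd of Cq replicate noise on gene wells, cycles.
#' @param ref_cq_noise_sd Gaussian sd of the reference gene's Cq, cycles.
#'   Defaults to 0: a validated reference is modeled as perfectly stable, so
#'   per-gene quantification errors are independent across genes. A positive
#'   value adds a per-replicate reference term shared by all genes of that
#'   plate (the realistic common-mode structure of a shared reference well).
#' @param rec_noise_sd Gaussian sd of REC measurement noise, percent points.
#' @param reference_gene id of the qPCR reference gene.
#' @param annotation_probs named numeric: probabilities that a non-planted gene
#'   receives the cold/oxidative/stimulus GO term, a background GO term, or a
#'   literature flag.
#' @return object of class `sim_config` (validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_genes_per_species = 100L,
                       n_ortholog_pairs = 30L,
                       n_planted_conserved = 9L,
                       log2_effect_size = 4,
                       noise_sd = 0.3,
                       n_replicates = 3L,
                       panel_spec = default_panel_spec(),
                       n_genotypes = 10L,
                       tolerant_index = 1L,
                       background_edge_density = 0.05,
                       n_specific_responders = NULL,
                       n_datasets_a = 1L,
                       n_datasets_b = 1L,
                       cq_noise_sd = 0.2,
                       ref_cq_noise_sd = 0,
                       rec_noise_sd = 2,
                       reference_gene = "Actin",
                       annotation_probs = c(cold = 0.05, oxidative = 0.05,
                                            stimulus = 0.10, background = 0.30,
                                            literature = 0.15)) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes_per_species = as.integer(n_genes_per_species),
    n_ortholog_pairs = as.integer(n_ortholog_pairs),
    n_planted_conserved = as.integer(n_planted_conserved),
    log2_effect_size = log2_effect_size,
    noise_sd = noise_sd,
    n_replicates = as.integer(n_replicates),
    panel_spec = panel_spec,
    n_genotypes = as.integer(n_genotypes),
    tolerant_index = as.integer(tolerant_index),
    background_edge_density = background_edge_density,
    n_specific_responders = n_specific_responders,
    n_datasets_a = as.integer(n_datasets_a),
    n_datasets_b = as.integer(n_datasets_b),
    cq_noise_sd = cq_noise_sd,
    ref_cq_noise_sd = ref_cq_noise_sd,
    rec_noise_sd = rec_noise_sd,
    reference_gene = reference_gene,
    annotation_probs = annotation_probs
  )
  if (cfg$n_planted_conserved > cfg$n_ortholog_pairs)
    stop("n_planted_conserved must not exceed n_ortholog_pairs", call. = FALSE)
  if (cfg$n_ortholog_pairs > cfg$n_genes_per_species)
    stop("n_ortholog_pairs must not exceed n_genes_per_species", call. = FALSE)
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (cfg$n_replicates < 2) stop("n_replicates must be >= 2", call. = FALSE)
  if (cfg$n_genotypes >= 1 &&
      (cfg$tolerant_index < 1 || cfg$tolerant_index > cfg$n_genotypes))
    stop("tolerant_index out of range", call. = FALSE)
  if (cfg$background_edge_density < 0 || cfg$background_edge_density > 1)
    stop("background_edge_density must be in [0, 1]", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

# number of species-specific responders needed to fill the top quartile
.n_specific <- function(config) {
  if (!is.null(config$n_specific_responders))
    return(as.integer(config$n_specific_responders))
  max(0L, as.integer(ceiling(config$n_genes_per_species / 4)) -
        config$n_planted_conserved)
}

#' Generate paired two-species stress expression data with planted truth
#'
#' Simulates control/cold expression matrices for two species, an ortholog map
#' and the planted ground truth. Expression is generated on the log2 scale
#' (baseline + condition effect + Gaussian noise) and exponentiated, so planted
#' genes have mean log2 fold change equal to `log2_effect_size` and all other
#' genes have expected fold change 0 on the log2 scale.
#'
#' Each species' top upregulation quartile is populated by true responders:
#' the planted conserved ortholog pairs plus species-specific responders whose
#' upregulation is, by construction, not shared by their ortholog (this is the
#' biology the cross-species screen exploits: most responders are not
#' conserved). Background ortholog-map pairs therefore always involve at least
#' one non-responsive partner.
#'
#' @param config a [sim_config()].
#' @return list with elements `expr_a`, `expr_b` ([expression_matrix()]
#'   objects), `ortholog_map` (data.frame `gene_a`, `gene_b`, `score`,
#'   `reciprocal`, `target_gene`) and `truth` (list: `conserved_pairs`
#'   data.frame, per-species responder vectors, per-gene true effects).
#' @export
gen_two_species_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes_per_species
  genes_a <- sprintf("ATS%04d", seq_len(n))
  genes_b <- sprintf("SLS%04d", seq_len(n))
  n_spec <- .n_specific(config)
  if (config$n_planted_conserved + n_spec > n)
    stop("too many responders for n_genes_per_species", call. = FALSE)

  planted_a <- sample(genes_a, config$n_planted_conserved)
  planted_b <- sample(genes_b, config$n_planted_conserved)
  specific_a <- sample(setdiff(genes_a, planted_a), n_spec)
  specific_b <- sample(setdiff(genes_b, planted_b), n_spec)

  effect_a <- stats::setNames(numeric(n), genes_a)
  effect_b <- stats::setNames(numeric(n), genes_b)
  effect_a[c(planted_a, specific_a)] <- config$log2_effect_size
  effect_b[c(planted_b, specific_b)] <- config$log2_effect_size

  make_matrix <- function(genes, effects, species, n_datasets) {
    base <- stats::rnorm(length(genes), mean = 7, sd = 1.5)
    mats <- list(); metas <- list()
    for (d in seq_len(n_datasets)) {
      ds <- sprintf("%s_ds%d", species, d)
      cols <- c(sprintf("%s_control_%d", ds, seq_len(config$n_replicates)),
                sprintf("%s_cold_%d", ds, seq_len(config$n_replicates)))
      cond <- rep(c("control", "stress"), each = config$n_replicates)
      mu <- outer(base, rep(1, length(cols))) +
        outer(effects, as.numeric(cond == "stress"))
      vals <- 2 ^ (mu + matrix(stats::rnorm(length(genes) * length(cols),
                                            sd = config$noise_sd),
                               nrow = length(genes)))
      dimnames(vals) <- list(genes, cols)
      mats[[d]] <- vals
      metas[[d]] <- data.frame(sample = cols, species = species,
                               condition = cond,
                               replicate = rep(seq_len(config$n_replicates), 2),
                               dataset = ds, stringsAsFactors = FALSE)
    }
    expression_matrix(do.call(cbind, mats), do.call(rbind, metas))
  }

  expr_a <- make_matrix(genes_a, effect_a, "A", config$n_datasets_a)
  expr_b <- make_matrix(genes_b, effect_b, "B", config$n_datasets_b)

  # ortholog map: planted conserved pairs + background pairs that never link
  # two responders (non-conserved response is what makes them background)
  n_bg <- config$n_ortholog_pairs - config$n_planted_conserved
  null_a <- setdiff(genes_a, c(planted_a, specific_a))
  null_b <- setdiff(genes_b, c(planted_b, specific_b))
  bg_a <- character(0); bg_b <- character(0)
  if (n_bg > 0) {
    # half the background pairs may involve a species-specific responder on
    # one side; the partner is always non-responsive
    pool_a <- c(null_a, specific_a)
    bg_a <- sample(pool_a, min(n_bg, length(pool_a)))
    bg_b <- vapply(bg_a, function(a) {
      if (a %in% specific_a) sample(null_b, 1) else
        sample(if (stats::runif(1) < 0.5 && length(specific_b) > 0)
          specific_b else null_b, 1)
    }, character(1))
    # responder-responder links would be conserved responses, exclude them
    bad <- bg_a %in% specific_a & bg_b %in% specific_b
    bg_b[bad] <- sample(null_b, sum(bad), replace = FALSE)
  }
  map_a <- c(planted_a, bg_a)
  map_b <- c(planted_b, bg_b)
  ortholog_map <- data.frame(
    gene_a = map_a, gene_b = map_b,
    score = round(stats::runif(length(map_a), 60, 100), 1),
    reciprocal = c(rep(TRUE, config$n_planted_conserved),
                   stats::runif(length(bg_a)) < 0.7),
    target_gene = sprintf("CSS%04d", seq_along(map_a)),
    stringsAsFactors = FALSE
  )

  truth <- list(
    conserved_pairs = data.frame(gene_a = planted_a, gene_b = planted_b,
                                 target_gene =
                                   ortholog_map$target_gene[
                                     seq_len(config$n_planted_conserved)],
                                 stringsAsFactors = FALSE),
    specific_a = specific_a, specific_b = specific_b,
    effect_a = effect_a, effect_b = effect_b
  )
  list(expr_a = expr_a, expr_b = expr_b, ortholog_map = ortholog_map,
       truth = truth)
}

#' Generate gene annotations (GO terms and literature flags)
#'
#' Every gene receives a possibly empty GO-term set drawn from the three
#' stress-related terms (response to cold GO:0009409, response to oxidative
#' stress GO:0006979, response to stimulus GO:0050896) plus uninformative
#' background terms, and a boolean literature flag. Planted assignments force
#' specific annotations and are recorded in the returned truth.
#'
#' @param gene_ids character vector of gene ids.
#' @param config a [sim_config()]; `annotation_probs` drives random assignment.
#' @param planted optional list with elements `go` (named list gene -> terms)
#'   and `literature` (character vector of gene ids).
#' @return list with `annotations` (data.frame `gene`, `go_terms`
#'   semicolon-separated, `literature` 0/1) and `truth` (the planted list).
#' @export
gen_annotations <- function(gene_ids, config, planted = list()) {
  stopifnot(length(gene_ids) > 0)
  set.seed(config$seed + 1L)
  p <- config$annotation_probs
  bg_terms <- c("GO:0008150", "GO:0009987", "GO:0065007")
  go <- lapply(gene_ids, function(g) {
    terms <- character(0)
    if (stats::runif(1) < p[["cold"]]) terms <- c(terms, "GO:0009409")
    if (stats::runif(1) < p[["oxidative"]]) terms <- c(terms, "GO:0006979")
    if (stats::runif(1) < p[["stimulus"]]) terms <- c(terms, "GO:0050896")
    if (stats::runif(1) < p[["background"]]) terms <- c(terms, sample(bg_terms, 1))
    terms
  })
  names(go) <- gene_ids
  lit <- stats::runif(length(gene_ids)) < p[["literature"]]
  names(lit) <- gene_ids
  if (!is.null(planted$go))
    for (g in names(planted$go)) go[[g]] <- unique(c(go[[g]], planted$go[[g]]))
  if (!is.null(planted$literature)) lit[planted$literature] <- TRUE
  list(
    annotations = data.frame(
      gene = gene_ids,
      go_terms = vapply(go, paste, character(1), collapse = ";"),
      literature = as.integer(lit),
      stringsAsFactors = FALSE, row.names = NULL
    ),
    truth = list(go = go, literature = gene_ids[lit])
  )
}

#' Generate a STRING-export-style interaction table with planted modules
#'
#' Within-module edges carry every evidence channel at `module_score`;
#' background edges appear with probability `background_edge_density` and carry
#' a single randomly chosen channel at `background_score`. Each undirected pair
#' occurs at most once and there are no self-edges.
#'
#' @param gene_ids character vector of node ids.
#' @param modules list of character vectors (planted interaction modules).
#' @param config a [sim_config()].
#' @param module_score,background_score channel scores for module and
#'   background edges.
#' @return data.frame `node1`, `node2`, `textmining`, `experiments`,
#'   `databases`.
#' @export
gen_interaction_table <- function(gene_ids, modules, config,
                                  module_score = 0.9,
                                  background_score = 0.08) {
  stopifnot(length(gene_ids) > 0)
  set.seed(config$seed + 2L)
  channels <- c("textmining", "experiments", "databases")
  rows <- list()
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  seen <- character(0)
  for (m in modules) {
    if (length(m) < 2) next
    cmb <- utils::combn(sort(m), 2)
    for (j in seq_len(ncol(cmb))) {
      k <- key(cmb[1, j], cmb[2, j])
      if (k %in% seen) next
      seen <- c(seen, k)
      r <- stats::setNames(as.list(rep(module_score, 3)), channels)
      rows[[length(rows) + 1L]] <-
        data.frame(node1 = cmb[1, j], node2 = cmb[2, j], r,
                   stringsAsFactors = FALSE)
    }
  }
  if (config$background_edge_density > 0 && length(gene_ids) >= 2) {
    cmb <- utils::combn(sort(gene_ids), 2)
    pick <- stats::runif(ncol(cmb)) < config$background_edge_density
    for (j in which(pick)) {
      k <- key(cmb[1, j], cmb[2, j])
      if (k %in% seen) next
      seen <- c(seen, k)
      sc <- stats::setNames(as.list(rep(0, 3)), channels)
      sc[[sample(channels, 1)]] <- background_score
      rows[[length(rows) + 1L]] <-
        data.frame(node1 = cmb[1, j], node2 = cmb[2, j], sc,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(node1 = character(0), node2 = character(0),
                      textmining = numeric(0), experiments = numeric(0),
                      databases = numeric(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a qRT-PCR Cq table with planted per-treatment effects
#'
#' For every panel gene, treatment and biological replicate a quantification
#' cycle is drawn such that the expected ddCq against the reference gene and
#' the Control treatment equals minus the planted log2 effect (one PCR cycle
#' per doubling). The reference gene is stable across treatments up to noise.
#'
#' @param config a [sim_config()]; `panel_spec` holds the planted effects and
#'   `cq_noise_sd` the replicate noise.
#' @param panel_spec optional override of `config$panel_spec`.
#' @return list with `cq` (data.frame `gene`, `treatment`, `replicate`, `cq`)
#'   and `truth` (data.frame of planted log2 effects per gene x treatment).
#' @export
gen_cq_data <- function(config, panel_spec = NULL) {
  spec <- if (is.null(panel_spec)) config$panel_spec else panel_spec
  stopifnot(nrow(spec) > 0)
  set.seed(config$seed + 3L)
  treatments <- c("Control", "Cold", "RecCold", "Drought", "RecDrought")
  stress_cols <- setdiff(treatments, "Control")
  genes <- spec$gene
  base_cq <- stats::setNames(stats::runif(length(genes), 22, 28), genes)
  ref <- config$reference_gene
  rows <- list()
  for (trt in treatments) {
    for (rep_i in seq_len(config$n_replicates)) {
      ref_cq <- 20 + if (config$ref_cq_noise_sd > 0)
        stats::rnorm(1, sd = config$ref_cq_noise_sd) else 0
      rows[[length(rows) + 1L]] <- data.frame(
        gene = ref, treatment = trt, replicate = rep_i, cq = ref_cq,
        stringsAsFactors = FALSE)
      eff <- if (trt == "Control") rep(0, length(genes)) else spec[[trt]]
      rows[[length(rows) + 1L]] <- data.frame(
        gene = genes, treatment = trt, replicate = rep_i,
        cq = base_cq - eff + stats::rnorm(length(genes),
                                          sd = config$cq_noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  truth <- spec[, c("gene", "group", stress_cols)]
  cq <- do.call(rbind, rows)
  rownames(cq) <- NULL
  list(cq = cq, truth = truth)
}

#' Generate conductivity (L1/L2) data with a planted tolerant genotype
#'
#' Emits raw paired conductivity readings per genotype, treatment and
#' replicate: L1 immediately after immersion and L2 after two hours, so that
#' `100 * L1 / L2` reproduces a planted relative-electrical-conductivity (REC)
#' profile. The planted tolerant genotype has the lowest expected REC under
#' both stresses (31% vs at least 39% for all others, the spread reported for
#' contrasting tea genotypes); controls sit near 12% and recovery near 20%.
#'
#' @param config a [sim_config()] with `n_genotypes >= 2`.
#' @return list with `conductivity` (data.frame `genotype`, `treatment`,
#'   `replicate`, `L1`, `L2`) and `truth` (list: `tolerant_genotype`,
#'   `rec_profile` matrix of planted REC percentages).
#' @export
gen_rec_data <- function(config) {
  stopifnot(config$n_genotypes >= 2)
  set.seed(config$seed + 4L)
  genotypes <- sprintf("G%02d", seq_len(config$n_genotypes))
  tolerant <- genotypes[config$tolerant_index]
  treatments <- c("Control", "Cold", "RecCold", "Drought", "RecDrought")
  prof <- matrix(NA_real_, nrow = config$n_genotypes, ncol = length(treatments),
                 dimnames = list(genotypes, treatments))
  prof[, "Control"] <- 12
  prof[, "RecCold"] <- 20
  prof[, "RecDrought"] <- 20
  others <- setdiff(genotypes, tolerant)
  prof[tolerant, c("Cold", "Drought")] <- 31
  prof[others, "Cold"] <- stats::runif(length(others), 39, 60)
  prof[others, "Drought"] <- stats::runif(length(others), 39, 54)
  rows <- list()
  for (g in genotypes) for (trt in treatments) {
    for (rep_i in seq_len(config$n_replicates)) {
      l2 <- stats::runif(1, 300, 500)
      rec <- prof[g, trt] + stats::rnorm(1, sd = config$rec_noise_sd)
      rec <- min(max(rec, 0.5), 100)
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = g, treatment = trt, replicate = rep_i,
        L1 = rec / 100 * l2, L2 = l2, stringsAsFactors = FALSE)
    }
  }
  cond <- do.call(rbind, rows)
  rownames(cond) <- NULL
  list(conductivity = cond,
       truth = list(tolerant_genotype = tolerant, rec_profile = prof))
}

#' Generate replicate-level fold-change profiles under correlation regimes
#'
#' Produces per-gene, per-treatment replicate vectors of log2 fold changes
#' whose cross-treatment Pearson correlation pattern follows one of the named
#' regimes: `"all_positive"` (a shared replicate factor drives all four
#' treatments), `"stress_paired"` (cold-side and drought-side factors with
#' opposite sign) and `"stress_crossed"` (stress vs recovery factors with
#' opposite sign). Used to validate correlation-pattern clustering.
#'
#' @param n_genes_per_regime genes per regime.
#' @param n_replicates replicates per treatment (>= 3).
#' @param noise_sd sd of independent log2 noise added on top of the factor.
#' @param seed integer seed.
#' @param factor_sd sd of the shared replicate factor.
#' @return list with `replicates` (data.frame `gene`, `treatment`, `replicate`,
#'   `log2fc`) and `truth` (data.frame `gene`, `regime`).
#' @export
gen_correlated_replicates <- function(n_genes_per_regime = 5L,
                                      n_replicates = 6L,
                                      noise_sd = 0.05,
                                      seed = 1L,
                                      factor_sd = 1) {
  set.seed(seed)
  treatments <- c("Cold", "RecCold", "Drought", "RecDrought")
  signs <- list(
    all_positive   = c(Cold = 1, RecCold = 1, Drought = 1, RecDrought = 1),
    stress_paired  = c(Cold = 1, RecCold = 1, Drought = -1, RecDrought = -1),
    stress_crossed = c(Cold = 1, RecCold = -1, Drought = 1, RecDrought = -1)
  )
  rows <- list(); truth <- list()
  for (regime in names(signs)) {
    for (i in seq_len(n_genes_per_regime)) {
      g <- sprintf("%s_%02d", regime, i)
      f <- stats::rnorm(n_replicates, sd = factor_sd)
      for (trt in treatments) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, treatment = trt, replicate = seq_len(n_replicates),
          log2fc = signs[[regime]][[trt]] * f +
            stats::rnorm(n_replicates, sd = noise_sd),
          stringsAsFactors = FALSE)
      }
      truth[[length(truth) + 1L]] <- data.frame(gene = g, regime = regime,
                                                stringsAsFactors = FALSE)
    }
  }
  reps <- do.call(rbind, rows); rownames(reps) <- NULL
  tr <- do.call(rbind, truth); rownames(tr) <- NULL
  list(replicates = reps, truth = tr)
}

#' Write every synthetic input of the pipeline to a directory
#'
#' Runs all generators under the config seed and writes the TSV/CSV dialects
#' the corresponding readers accept, plus a machine-readable truth file
#' (JSON).
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a named character vector of written file paths.
#' @export
simulate_study <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  two <- gen_two_species_expression(config)
  ann <- gen_annotations(two$ortholog_map$target_gene, config)
  modules <- list(two$truth$conserved_pairs$target_gene)
  inter <- gen_interaction_table(two$ortholog_map$target_gene, modules, config)
  cqd <- gen_cq_data(config)
  recd <- gen_rec_data(config)

  paths <- c(
    expr_a = file.path(out_dir, "expression_A.tsv"),
    meta_a = file.path(out_dir, "samples_A.tsv"),
    expr_b = file.path(out_dir, "expression_B.tsv"),
    meta_b = file.path(out_dir, "samples_B.tsv"),
    orthologs = file.path(out_dir, "orthologs.tsv"),
    annotations = file.path(out_dir, "annotations.tsv"),
    interactions = file.path(out_dir, "interactions.tsv"),
    cq = file.path(out_dir, "cq.csv"),
    conductivity = file.path(out_dir, "conductivity.csv"),
    truth = file.path(out_dir, "truth.json")
  )
  write_expression_tsv(two$expr_a, paths[["expr_a"]], paths[["meta_a"]])
  write_expression_tsv(two$expr_b, paths[["expr_b"]], paths[["meta_b"]])
  utils::write.table(two$ortholog_map, paths[["orthologs"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ann$annotations, paths[["annotations"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(inter, paths[["interactions"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.csv(cqd$cq, paths[["cq"]], row.names = FALSE, quote = FALSE)
  utils::write.csv(recd$conductivity, paths[["conductivity"]],
                   row.names = FALSE, quote = FALSE)
  truth <- list(
    conserved_pairs = two$truth$conserved_pairs,
    specific_a = two$truth$specific_a,
    specific_b = two$truth$specific_b,
    panel_effects = cqd$truth,
    tolerant_genotype = recd$truth$tolerant_genotype,
    planted_modules = modules
  )
  jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
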