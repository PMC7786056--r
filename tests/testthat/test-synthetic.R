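test_that("config validation enforces the documented invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_planted_conserved = 40, n_ortholog_pairs = 30),
               "n_planted_conserved")
  expect_error(sim_config(n_ortholog_pairs = 500), "n_ortholog_pairs")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(n_replicates = 1), "n_replicates")
  expect_error(sim_config(background_edge_density = 1.5), "background_edge")
})

test_that("two-species generator plants the advertised structure", {
  cfg <- sim_config(seed = 1, n_planted_conserved = 9, log2_effect_size = 4,
                    noise_sd = 0.3)
  out <- gen_two_species_expression(cfg)
  expect_equal(nrow(out$truth$conserved_pairs), 9)
  # every planted pair is present in the emitted ortholog map
  map_keys <- paste(out$ortholog_map$gene_a, out$ortholog_map$gene_b)
  truth_keys <- paste(out$truth$conserved_pairs$gene_a,
                      out$truth$conserved_pairs$gene_b)
  expect_true(all(truth_keys %in% map_keys))
  expect_equal(nrow(out$ortholog_map), cfg$n_ortholog_pairs)
  # matrices have the right groups and replicate counts
  meta <- out$expr_a$sample_meta
  expect_equal(sum(meta$condition == "control"), cfg$n_replicates)
  expect_equal(sum(meta$condition == "stress"), cfg$n_replicates)
  # planted genes carry the planted mean log2 fold change (low noise check)
  cfg0 <- sim_config(seed = 2, noise_sd = 1e-6)
  out0 <- gen_two_species_expression(cfg0)
  fc <- compute_fold_change(out0$expr_a)
  planted <- fc$gene %in% out0$truth$conserved_pairs$gene_a
  expect_equal(fc$log2fc[planted], rep(4, sum(planted)), tolerance = 1e-4)
  null_genes <- !(fc$gene %in% c(out0$truth$conserved_pairs$gene_a,
                                 out0$truth$specific_a))
  expect_equal(max(abs(fc$log2fc[null_genes])), 0, tolerance = 1e-4)
})

test_that("identical config and seed give identical outputs", {
  cfg <- sim_config(seed = 11)
  a <- gen_two_species_expression(cfg)
  b <- gen_two_species_expression(cfg)
  expect_identical(a, b)
  expect_identical(gen_cq_data(cfg), gen_cq_data(cfg))
  expect_identical(gen_rec_data(cfg), gen_rec_data(cfg))
  expect_identical(gen_annotations(letters, cfg), gen_annotations(letters, cfg))
})

test_that("annotation generator honors planted assignments and zero probabilities", {
  cfg <- sim_config(seed = 3,
                    annotation_probs = c(cold = 0, oxidative = 0,
                                         stimulus = 0, background = 0,
                                         literature = 0))
  ann <- gen_annotations(c("g1", "g2", "g3"), cfg)
  expect_true(all(ann$annotations$go_terms == ""))
  expect_true(all(ann$annotations$literature == 0))
  ann2 <- gen_annotations(c("g1", "g2"), cfg,
                          planted = list(go = list(g1 = "GO:0009409"),
                                         literature = "g1"))
  expect_equal(ann2$annotations$go_terms[1], "GO:0009409")
  expect_equal(ann2$annotations$literature[1], 1)
  # planted gene with cold GO term, literature flag and rank 4 scores 9
  expect_equal(combined_score(ann2$annotations$go_terms[1], 4,
                              ann2$annotations$literature[1] == 1), 9)
})

test_that("interaction generator plants modules and sub-threshold background", {
  cfg0 <- sim_config(seed = 4, background_edge_density = 0)
  mods <- list(c("m1", "m2", "m3"), c("n1", "n2"))
  tab <- gen_interaction_table(c("m1", "m2", "m3", "n1", "n2", "x1", "x2"),
                               mods, cfg0)
  expect_equal(nrow(tab), 4)  # 3 within the triangle module + 1 in the pair
  key <- paste(tab$node1, tab$node2)
  expect_setequal(key, c("m1 m2", "m1 m3", "m2 m3", "n1 n2"))
  # density 1 with all scores 0.1: nothing survives the 0.15 threshold
  cfg1 <- sim_config(seed = 5, background_edge_density = 1)
  tab1 <- gen_interaction_table(letters[1:6], list(), cfg1,
                                background_score = 0.1)
  tab1 <- combine_channel_scores(tab1)
  expect_equal(nrow(filter_edges(tab1, 0.15)), 0)
  # module score 0.9: every module edge survives
  tab2 <- gen_interaction_table(c("m1", "m2", "m3"), list(c("m1", "m2", "m3")),
                                cfg0, module_score = 0.9)
  tab2 <- combine_channel_scores(tab2)
  expect_equal(nrow(filter_edges(tab2, 0.15)), 3)
  # each unordered pair at most once, no self-edges
  cfgd <- sim_config(seed = 6, background_edge_density = 0.5)
  tab3 <- gen_interaction_table(letters[1:8], mods, cfgd)
  expect_false(any(tab3$node1 == tab3$node2))
  expect_false(anyDuplicated(paste(pmin(tab3$node1, tab3$node2),
                                   pmax(tab3$node1, tab3$node2))) > 0)
})

test_that("Cq generator encodes planted effects as ddCq and keeps the reference stable", {
  spec <- data.frame(gene = "g1", group = "x", Cold = 5, RecCold = 0,
                     Drought = 0, RecDrought = 0, stringsAsFactors = FALSE)
  cfg <- sim_config(seed = 7, cq_noise_sd = 1e-9, panel_spec = spec)
  cqd <- gen_cq_data(cfg)
  rel <- quantify_panel(cqd$cq, reference = "Actin")
  expect_equal(rel$fold_change[rel$gene == "g1" & rel$treatment == "Cold"],
               32, tolerance = 1e-6)
  expect_equal(rel$fold_change[rel$gene == "g1" & rel$treatment == "Drought"],
               1, tolerance = 1e-6)
  ref <- cqd$cq[cqd$cq$gene == "Actin", ]
  expect_lt(diff(range(ref$cq)), 1e-6)
})

test_that("REC generator plants the tolerant genotype with the lowest ratio", {
  cfg <- sim_config(seed = 8, tolerant_index = 3, rec_noise_sd = 1e-9)
  recd <- gen_rec_data(cfg)
  expect_equal(recd$truth$tolerant_genotype, "G03")
  expect_true(all(recd$conductivity$L1 <= recd$conductivity$L2))
  expect_true(all(recd$conductivity$L1 > 0))
  rec <- recd$conductivity
  rec$REC <- compute_rec(rec$L1, rec$L2)
  expect_equal(select_tolerant_genotype(rec)$tolerant_genotype, "G03")
  # the planted REC profile is reproduced by the formula at zero noise
  cold <- tapply(rec$REC[rec$treatment == "Cold"],
                 rec$genotype[rec$treatment == "Cold"], mean)
  expect_equal(unname(cold["G03"]), 31, tolerance = 1e-6)
  expect_true(all(cold[names(cold) != "G03"] >= 39 - 1e-6))
})

test_that("simulate_study writes files the readers round-trip", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 9, n_genes_per_species = 40,
                    n_ortholog_pairs = 15, n_planted_conserved = 5)
  paths <- simulate_study(cfg, dir)
  expect_true(all(file.exists(paths)))
  expr <- read_expression_tsv(paths[["expr_a"]], paths[["meta_a"]])
  expect_s3_class(expr, "expression_matrix")
  expect_equal(nrow(expr$values), 40)
  map <- read_ortholog_map(paths[["orthologs"]])
  expect_equal(nrow(map), 15)
  ann <- read_annotations(paths[["annotations"]])
  expect_equal(nrow(ann), 15)
  cq <- read_cq_csv(paths[["cq"]])
  expect_true("Actin" %in% cq$gene)
  cond <- read_conductivity_csv(paths[["conductivity"]])
  expect_true(all(c("genotype", "REC") %in% names(cond)))
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(nrow(truth$conserved_pairs), 5)
})
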