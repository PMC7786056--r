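test_that("fold change follows the stated arithmetic, including the zero-mean pseudocount", {
  em <- toy_expression(
    c("g1", "g2", "g3", "g4"),
    control_vals = rbind(c(2, 2), c(3, 3), c(0, 0), c(5, 5)),
    stress_vals  = rbind(c(8, 8), c(3, 3), c(4, 4), c(10, 10)))
  fc <- compute_fold_change(em, pseudocount = 0.5)
  expect_equal(fc$fc[fc$gene == "g1"], 4)
  expect_equal(fc$log2fc[fc$gene == "g1"], 2)
  expect_equal(fc$fc[fc$gene == "g2"], 1)
  expect_equal(fc$log2fc[fc$gene == "g2"], 0)
  # zero control mean: pseudocount added to both means -> (4 + .5)/(0 + .5)
  expect_equal(fc$fc[fc$gene == "g3"], 9)
  # non-degenerate rows are untouched by the pseudocount
  expect_equal(fc$fc[fc$gene == "g4"], 2)
  expect_true(all(fc$fc > 0))
})

test_that("the sample-metadata contract rejects datasets without both groups", {
  vals <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  meta <- data.frame(sample = c("s1", "s2"), species = "A",
                     condition = c("control", "control"),
                     replicate = 1:2, dataset = "d1")
  expect_error(expression_matrix(vals, meta), "control and one stress")
})

test_that("quartile ranks reproduce the position formula on simple cases", {
  fc8 <- data.frame(dataset = "d", gene = sprintf("g%d", 1:8),
                    log2fc = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.8))
  r8 <- assign_quartile_ranks(fc8)
  expect_equal(r8$rank[match(sprintf("g%d", 1:8), r8$gene)],
               c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  fc4 <- data.frame(dataset = "d", gene = c("a", "b", "c", "d"),
                    log2fc = c(3, 1, 4, 2))
  r4 <- assign_quartile_ranks(fc4)
  expect_equal(r4$rank[match(c("b", "d", "a", "c"), r4$gene)], 1:4)
  expect_error(assign_quartile_ranks(fc4[1:3, ]), "at least 4")
  # the largest fold change always lands in the top quartile
  expect_equal(r8$rank[r8$gene == "g8"], 4L)
})

test_that("quartile ranks match the independent sort-and-position oracle with ties", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(4:50, 1)
    fc <- data.frame(dataset = "d",
                     gene = sample(sprintf("g%03d", 1:n)),
                     log2fc = sample(round(rnorm(8), 1), n, replace = TRUE))
    got <- assign_quartile_ranks(fc)
    exp <- quartile_oracle(fc)
    expect_equal(got[order(got$gene), ]$rank, exp[order(exp$gene), ]$rank)
  }
  # quartile class sizes: n divisible by 4 gives exactly n/4 per class
  fc <- data.frame(dataset = "d", gene = sprintf("g%02d", 1:40),
                   log2fc = rnorm(40))
  expect_true(all(table(assign_quartile_ranks(fc)$rank) == 10))
})

test_that("species rank aggregates per-dataset ranks by maximum", {
  r <- data.frame(dataset = c("d1", "d2", "d3"), gene = "g1",
                  rank = c(2L, 4L, 3L))
  expect_equal(aggregate_species_rank(r)$rank, 4L)
  r1 <- data.frame(dataset = "d1", gene = "g1", rank = 1L)
  expect_equal(aggregate_species_rank(r1)$rank, 1L)
  expect_error(aggregate_species_rank(r1[0, ]), "no ranks")
  # monotonicity: dominating log2fc in every dataset implies rank >= rank
  set.seed(5)
  for (i in 1:20) {
    fc <- do.call(rbind, lapply(c("d1", "d2"), function(ds)
      data.frame(dataset = ds, gene = sprintf("g%02d", 1:12),
                 log2fc = sort(rnorm(12)))))
    agg <- aggregate_species_rank(assign_quartile_ranks(fc))
    # g12 dominates g01 in both datasets
    expect_gte(agg$rank[agg$gene == "g12"], agg$rank[agg$gene == "g01"])
  }
})

test_that("top-quartile intersection and Venn counts follow the ortholog map", {
  ranks <- data.frame(gene = sprintf("g%d", 1:8),
                      rank = c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_equal(top_quartile_set(ranks), c("g7", "g8"))
  map <- data.frame(gene_a = "a1", gene_b = "b1", stringsAsFactors = FALSE)
  out <- intersect_top_sets(c("a1", "a2", "a3"), c("b1", "b2"), map)
  expect_equal(unname(out$venn), c(2L, 1L, 1L))
  expect_equal(nrow(out$pairs), 1)
  empty <- intersect_top_sets(c("a1"), c("b1"),
                              map[0, , drop = FALSE])
  expect_equal(unname(empty$venn["shared"]), 0L)
})

test_that("target mapping keeps gap-flagged candidates instead of dropping them", {
  pairs <- data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"),
                      target_gene = c("TEA003328", NA),
                      stringsAsFactors = FALSE)
  expect_warning(cand <- map_to_target(pairs), "target-species homolog")
  expect_equal(nrow(cand), 2)
  expect_equal(cand$gene[1], "TEA003328")
  expect_true(cand$target_missing[2])
  expect_equal(nrow(map_to_target(pairs[0, ])), 0)
})

test_that("combined score follows the max-GO rule and stays within 0..9", {
  expect_equal(combined_score("GO:0009409", 4, TRUE), 9L)
  expect_equal(combined_score(character(0), 1, FALSE), 1L)
  expect_equal(combined_score(c("GO:0050896", "GO:0006979"), 2, FALSE), 5L)
  expect_equal(combined_score("GO:9999999", 0, FALSE), 0L)  # unknown ignored
  expect_equal(combined_score("GO:0050896;GO:0009409", 0, FALSE), 4L)
  expect_error(combined_score("GO:0009409", 5, FALSE), "0..4")
  # bounds and monotonicity in each component
  terms <- list(character(0), "GO:0050896", "GO:0006979", "GO:0009409")
  prev <- -1L
  for (ti in seq_along(terms)) {
    s <- combined_score(terms[[ti]], 2, FALSE)
    expect_gte(s, prev); prev <- s
  }
  for (r in 0:4)
    expect_equal(combined_score("GO:0006979", r, TRUE), 3L + r + 1L)
  all_s <- unlist(lapply(terms, function(tt)
    lapply(0:4, function(r) lapply(c(TRUE, FALSE), function(l)
      combined_score(tt, r, l)))))
  expect_true(all(all_s >= 0 & all_s <= 9))
})

test_that("panel assembly unites, deduplicates and sorts candidates", {
  inter <- data.frame(gene = sprintf("T%02d", 1:9), stringsAsFactors = FALSE)
  lit <- sprintf("L%02d", 1:36)
  panel <- assemble_panel(inter, lit)
  expect_equal(nrow(panel), 45)
  # overlapping ids collapse, keeping both source tags
  panel2 <- assemble_panel(inter, c(lit, "T01"))
  expect_equal(nrow(panel2), 45)
  expect_equal(panel2$source[panel2$gene == "T01"], "interspecies;literature")
  # empty literature list: panel is the interspecies list
  expect_equal(sort(assemble_panel(inter, character(0))$gene),
               sort(inter$gene))
  # scores sorted descending, ties by gene id
  ranks <- data.frame(gene = c("T01", "T02"), rank = c(4L, 4L))
  ann <- data.frame(gene = "T01", go_terms = "GO:0009409", literature = 0)
  p3 <- assemble_panel(inter, character(0), annotations = ann,
                       species_ranks = ranks)
  expect_equal(p3$gene[1], "T01")
  expect_equal(p3$score[1], 8L)
  expect_true(all(diff(p3$score) <= 0))
})
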