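test_that("ddCq arithmetic follows the Livak formula", {
  expect_equal(delta_delta_cq(20, 20, 20, 20),
               list(ddcq = 0, fold_change = 1))
  out <- delta_delta_cq(20, 18, 24, 18)
  expect_equal(out$ddcq, -4)
  expect_equal(out$fold_change, 16)
  expect_error(delta_delta_cq(20, NA, 24, 18), "required")
})

test_that("a gene that mirrors the reference quantifies to fold change 1 everywhere", {
  treatments <- c("Control", "Cold", "Drought")
  cq <- do.call(rbind, lapply(treatments, function(trt)
    data.frame(gene = rep(c("Actin", "mirror"), each = 3),
               treatment = trt, replicate = rep(1:3, 2),
               cq = rep(c(20.1, 19.7, 20.4), 2), stringsAsFactors = FALSE)))
  rel <- quantify_panel(cq)
  expect_equal(rel$fold_change, rep(1, 3))
  expect_false(any(rel$significant))
})

test_that("adding a constant to one replicate's Cq values changes nothing", {
  set.seed(30)
  eff <- matrix(c(2, 0), 2, 1, dimnames = list(c("g1", "g2"), "Cold"))
  cq <- null_ref_cq_table(eff, noise_sd = 0.1)
  rel1 <- quantify_panel(cq)
  shifted <- cq
  pick <- shifted$replicate == 2  # plate-wide shift of replicate 2
  shifted$cq[pick] <- shifted$cq[pick] + 3.7
  rel2 <- quantify_panel(shifted)
  expect_equal(rel1$fold_change, rel2$fold_change)
  expect_equal(rel1$p, rel2$p)
})

test_that("swapping treatment and control inverts log2 fold change and keeps p", {
  set.seed(31)
  eff <- matrix(3, 1, 1, dimnames = list("g1", "Cold"))
  cq <- null_ref_cq_table(eff, noise_sd = 0.2)
  fwd <- quantify_panel(cq, control = "Control")
  rev <- quantify_panel(cq, control = "Cold")
  f <- fwd[fwd$treatment == "Cold", ]
  r <- rev[rev$treatment == "Control", ]
  expect_equal(f$log2fc, -r$log2fc)
  expect_equal(f$p, r$p)
})

test_that("missing reference and short replicate groups are handled as contracted", {
  eff <- matrix(1, 1, 1, dimnames = list("g1", "Cold"))
  cq <- null_ref_cq_table(eff, noise_sd = 0.1)
  expect_error(quantify_panel(cq, reference = "EF1a"), "absent")
  expect_error(quantify_panel(cq[cq$gene != "Actin" | cq$treatment != "Cold", ]),
               "missing for treatment")
  # one treatment replicate: untestable, flagged but not significant
  cq1 <- cq[!(cq$gene == "g1" & cq$treatment == "Cold" & cq$replicate > 1), ]
  rel <- quantify_panel(cq1)
  cold <- rel[rel$gene == "g1" & rel$treatment == "Cold", ]
  expect_true(is.na(cold$p))
  expect_false(cold$significant)
})

test_that("significance has power at planted effects of 2 or more log2 units", {
  set.seed(32)
  n_genes <- 100
  eff <- matrix(2, n_genes, 1,
                dimnames = list(sprintf("g%03d", 1:n_genes), "Cold"))
  cq <- null_ref_cq_table(eff, noise_sd = 0.2)
  rel <- quantify_panel(cq)
  hits <- rel$significant[rel$treatment == "Cold"]
  expect_gte(mean(hits), 0.95)
})

test_that("response categories follow significance flags and precedence", {
  mk <- function(gene, trt, fc, p) data.frame(
    gene = gene, treatment = trt, fold_change = fc, log2fc = log2(fc),
    p = p, significant = !is.na(p) & p <= 0.05, stringsAsFactors = FALSE)
  rel <- rbind(
    mk("both", c("Cold", "RecCold", "Drought", "RecDrought"),
       c(4, 2, 3, 2), c(0.01, 0.2, 0.01, 0.2)),
    mk("coldsp", c("Cold", "RecCold", "Drought", "RecDrought"),
       c(4, 1, 1, 1), c(0.01, 0.9, 0.9, 0.9)),
    mk("drsp", c("Cold", "RecCold", "Drought", "RecDrought"),
       c(1, 1, 3, 1), c(0.9, 0.9, 0.01, 0.9)),
    mk("recov", c("Cold", "RecCold", "Drought", "RecDrought"),
       c(1.2, 5, 1, 1), c(0.4, 0.01, 0.9, 0.9)),
    mk("down", c("Cold", "RecCold", "Drought", "RecDrought"),
       c(0.2, 0.8, 1, 1), c(0.01, 0.4, 0.9, 0.9)),
    mk("flat", c("Cold", "RecCold", "Drought", "RecDrought"),
       c(1.1, 0.9, 1, 1), c(0.5, 0.6, 0.9, 0.9)))
  calls <- classify_response(rel)
  got <- setNames(calls$category, calls$gene)
  expect_equal(unname(got[c("both", "coldsp", "drsp", "recov", "down", "flat")]),
               c("both_up", "cold_specific", "drought_specific",
                 "recovery_elevated", "down", "unresponsive"))
  expect_error(classify_response(rel[rel$treatment != "Drought", ]),
               "not quantified")
})

test_that("REC formula, bounds and error handling", {
  expect_equal(compute_rec(30, 60), 50)
  expect_equal(compute_rec(42, 42), 100)
  expect_equal(compute_rec(0, 60), 0)
  expect_error(compute_rec(10, 0), "positive")
  expect_warning(rec <- compute_rec(70, 60), "exceeds 100")
  expect_gt(rec, 100)
  # strictly increasing in L1, decreasing in L2
  expect_true(all(diff(compute_rec(c(10, 20, 30), 60)) > 0))
  expect_true(all(diff(compute_rec(30, c(60, 80, 100))) < 0))
})

test_that("tolerant-genotype selection minimizes mean stress REC with tie rule", {
  rec <- expand.grid(genotype = c("Quimen", "Kolkhida", "Sochi"),
                     treatment = c("Cold", "Drought"),
                     stringsAsFactors = FALSE)
  rec$REC <- c(31, 55, 45, 31, 50, 41)
  sel <- select_tolerant_genotype(rec)
  expect_equal(sel$tolerant_genotype, "Quimen")
  expect_equal(sel$summary$mean_rec[sel$summary$genotype == "Quimen"], 31)
  # all equal: first genotype id wins
  rec$REC <- 40
  expect_equal(select_tolerant_genotype(rec)$tolerant_genotype, "Kolkhida")
  # missing stress treatment: excluded with a warning
  rec2 <- rec[!(rec$genotype == "Kolkhida" & rec$treatment == "Drought"), ]
  rec2$REC[rec2$genotype == "Kolkhida"] <- 1
  expect_warning(sel2 <- select_tolerant_genotype(rec2), "excluded")
  expect_false(sel2$tolerant_genotype == "Kolkhida")
})
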