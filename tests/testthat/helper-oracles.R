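# Independent oracles used across tests. These re-derive expected values by a
# different route than the implementation under test.

# Quartile-rank oracle: re-derive each gene's ascending position by direct
# counting (strictly smaller log2fc, then equal log2fc with smaller gene id)
# and apply the position formula gene by gene, without any vectorized sort.
quartile_oracle <- function(fc) {
  do.call(rbind, lapply(split(fc, fc$dataset), function(d) {
    n <- nrow(d)
    r <- integer(n)
    for (i in seq_len(n)) {
      p <- sum(d$log2fc < d$log2fc[i] |
                 (d$log2fc == d$log2fc[i] & d$gene < d$gene[i])) + 1
      r[i] <- as.integer(1 + floor(4 * (p - 1) / n))
    }
    data.frame(dataset = d$dataset, gene = d$gene, rank = r,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

# From-scratch Ward (D2) agglomeration via the Lance-Williams update on
# Euclidean distances; returns the merge heights in order.
ward_heights_oracle <- function(mat) {
  n <- nrow(mat)
  d2 <- as.matrix(stats::dist(mat)) ^ 2
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bestv <- Inf
    for (i in seq_along(active)) for (j in seq_along(active)) {
      if (j <= i) next
      a <- active[i]; b <- active[j]
      if (d2[a, b] < bestv) { bestv <- d2[a, b]; best <- c(a, b) }
    }
    a <- best[1]; b <- best[2]
    heights <- c(heights, sqrt(bestv))
    na <- sizes[a]; nb <- sizes[b]
    for (k in setdiff(active, c(a, b))) {
      nk <- sizes[k]
      d2[a, k] <- d2[k, a] <-
        ((na + nk) * d2[a, k] + (nb + nk) * d2[b, k] - nk * d2[a, b]) /
        (na + nb + nk)
    }
    sizes[a] <- na + nb
    active <- setdiff(active, b)
  }
  heights
}

# Adjusted Rand index between two label vectors.
adjusted_rand <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  exp_idx <- sum_a * sum_b / n
  (sum_ij - exp_idx) / ((sum_a + sum_b) / 2 - exp_idx)
}

# Small hand-built expression matrix: one dataset, nc control and ns stress
# replicates, values supplied per gene as c(control mean ..., stress mean ...)
toy_expression <- function(genes, control_vals, stress_vals,
                           species = "A", dataset = "A_ds1") {
  nc <- ncol(control_vals); ns <- ncol(stress_vals)
  vals <- cbind(control_vals, stress_vals)
  rownames(vals) <- genes
  colnames(vals) <- c(sprintf("c%d", seq_len(nc)), sprintf("s%d", seq_len(ns)))
  meta <- data.frame(
    sample = colnames(vals), species = species,
    condition = rep(c("control", "stress"), c(nc, ns)),
    replicate = c(seq_len(nc), seq_len(ns)), dataset = dataset,
    stringsAsFactors = FALSE)
  expression_matrix(vals, meta)
}

# Cq table for a set of genes with given per-treatment true log2 effects,
# a perfectly stable reference, and iid Gaussian Cq noise on the gene wells.
null_ref_cq_table <- function(effects, n_rep = 3, noise_sd = 0.2,
                              treatments = c("Control", "Cold"),
                              ref = "Actin", base_cq = 25, ref_cq = 20) {
  genes <- rownames(effects)
  rows <- list()
  for (trt in treatments) for (r in seq_len(n_rep)) {
    rows[[length(rows) + 1L]] <- data.frame(
      gene = ref, treatment = trt, replicate = r, cq = ref_cq,
      stringsAsFactors = FALSE)
    eff <- if (trt == "Control") rep(0, length(genes)) else effects[, trt]
    rows[[length(rows) + 1L]] <- data.frame(
      gene = genes, treatment = trt, replicate = r,
      cq = base_cq - eff + rnorm(length(genes), sd = noise_sd),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
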