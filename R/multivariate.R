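#' Gene x treatment profile matrix of log2 fold changes
#'
#' Builds the complete genes-by-treatments matrix consumed by clustering and
#' PCA. Untestable or missing cells are imputed as log2 fold change 0 (no
#' change) and flagged, keeping the matrix complete.
#'
#' @param rel data.frame from [quantify_panel()].
#' @param treatments columns of the profile, in order.
#' @return numeric matrix (genes x treatments) with attribute `imputed`
#'   (logical matrix of the same shape).
#' @export
profile_matrix <- function(rel, treatments = c("Cold", "RecCold", "Drought",
                                               "RecDrought")) {
  genes <- sort(unique(rel$gene))
  m <- matrix(NA_real_, nrow = length(genes), ncol = length(treatments),
              dimnames = list(genes, treatments))
  for (i in seq_len(nrow(rel))) {
    trt <- rel$treatment[i]
    if (trt %in% treatments) m[rel$gene[i], trt] <- rel$log2fc[i]
  }
  imputed <- is.na(m) | !is.finite(m)
  m[imputed] <- 0
  attr(m, "imputed") <- imputed
  m
}

#' Ward hierarchical clustering of expression profiles
#'
#' Agglomerative clustering with the Ward criterion on Euclidean distances
#' between rows (Ward.D2: each merge minimizes the increase in within-cluster
#' variance). Rows are not rescaled, preserving the magnitude contrasts that
#' distinguish strongly and weakly induced genes.
#'
#' @param mat numeric matrix, rows = genes (>= 2).
#' @param k optional number of flat clusters to cut.
#' @return list with `hclust` (the merge tree), `order` (leaf order) and
#'   `labels` (named integer vector when `k` is given, else `NULL`).
#' @export
ward_cluster <- function(mat, k = NULL) {
  if (nrow(mat) < 2) stop("need at least 2 rows to cluster", call. = FALSE)
  if (!is.null(k) && k > nrow(mat))
    stop("k must not exceed the number of rows", call. = FALSE)
  hc <- stats::hclust(stats::dist(mat), method = "ward.D2")
  labels <- if (!is.null(k)) stats::cutree(hc, k = k) else NULL
  list(hclust = hc, order = hc$order, labels = labels)
}

#' PCA of the gene panel restricted to a pair of treatments
#'
#' Columns are centered and unit-scaled, the 2x2 correlation matrix is
#' eigendecomposed, gene scores are the projections of the standardized data
#' on the eigenvectors and the variance-explained fractions are the
#' eigenvalues over their sum. With two standardized columns the component
#' variances are `1 + r` and `1 - r`.
#'
#' @param mat numeric matrix with exactly two columns (treatments) and at
#'   least 3 rows (genes).
#' @return list with `scores` (genes x 2), `loadings` (2 x 2 orthonormal,
#'   treatments x components) and `var_explained` (length-2, sums to 1).
#' @export
pca_pair <- function(mat) {
  if (ncol(mat) != 2) stop("pca_pair expects exactly two columns",
                           call. = FALSE)
  if (nrow(mat) < 3) stop("need at least 3 genes", call. = FALSE)
  sds <- apply(mat, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column: ", paste(colnames(mat)[sds == 0],
                                         collapse = ", "), call. = FALSE)
  z <- scale(mat)
  cm <- stats::cor(mat)
  eig <- eigen(cm, symmetric = TRUE)
  scores <- z %*% eig$vectors
  colnames(scores) <- c("PC1", "PC2")
  loadings <- eig$vectors
  dimnames(loadings) <- list(colnames(mat), c("PC1", "PC2"))
  list(scores = scores, loadings = loadings,
       var_explained = eig$values / sum(eig$values))
}

#' Cross-treatment Pearson correlations of replicate-level fold changes
#'
#' For each gene, the Pearson correlation between every pair of treatments'
#' replicate vectors (replicates paired by index), with a two-sided p-value
#' from the exact t transformation `t = r * sqrt(n - 2) / sqrt(1 - r^2)` and
#' significance at `alpha`. Zero-variance vectors leave the pair undefined
#' (`r = NA`, flagged).
#'
#' @param replicates data.frame with columns `gene`, `treatment`, `replicate`
#'   and `log2fc` (replicate-level log2 fold change).
#' @param treatments treatments to correlate.
#' @param alpha significance level.
#' @return list with `long` (data.frame `gene`, `t1`, `t2`, `r`, `p`, `n`,
#'   `significant`) and `matrices` (per-gene named list of symmetric 4x4 r
#'   matrices with unit diagonal).
#' @export
treatment_correlations <- function(replicates,
                                   treatments = c("Cold", "RecCold",
                                                  "Drought", "RecDrought"),
                                   alpha = 0.05) {
  req <- c("gene", "treatment", "replicate", "log2fc")
  stopifnot(all(req %in% names(replicates)))
  genes <- sort(unique(replicates$gene))
  pairs <- utils::combn(treatments, 2)
  long <- list(); mats <- list()
  for (g in genes) {
    sub <- replicates[replicates$gene == g, ]
    reps <- sort(unique(sub$replicate))
    n <- length(reps)
    if (n < 3) stop("gene ", g, " has fewer than 3 replicates", call. = FALSE)
    vec <- lapply(treatments, function(trt) {
      v <- sub$log2fc[sub$treatment == trt][order(sub$replicate[sub$treatment == trt])]
      if (length(v) != n) stop("gene ", g, ": unequal replicate counts",
                               call. = FALSE)
      v
    })
    names(vec) <- treatments
    m <- diag(1, length(treatments))
    dimnames(m) <- list(treatments, treatments)
    for (j in seq_len(ncol(pairs))) {
      t1 <- pairs[1, j]; t2 <- pairs[2, j]
      v1 <- vec[[t1]]; v2 <- vec[[t2]]
      if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        r <- stats::cor(v1, v2)
        if (abs(r) >= 1) {
          p <- 0
        } else {
          tstat <- r * sqrt(n - 2) / sqrt(1 - r ^ 2)
          p <- 2 * stats::pt(-abs(tstat), df = n - 2)
        }
      }
      m[t1, t2] <- m[t2, t1] <- r
      long[[length(long) + 1L]] <- data.frame(
        gene = g, t1 = t1, t2 = t2, r = r, p = p, n = n,
        significant = !is.na(p) & p <= alpha,
        stringsAsFactors = FALSE)
    }
    mats[[g]] <- m
  }
  long <- do.call(rbind, long)
  rownames(long) <- NULL
  list(long = long, matrices = mats)
}

#' Cluster genes by their cross-treatment correlation pattern
#'
#' Each gene is represented by the flattened upper triangle of its treatment
#' correlation matrix and genes are Ward-clustered on these features. The
#' default of three clusters mirrors the three broad co-response regimes seen
#' in such panels (consistently positive, mixed, and sign-reversed
#' correlations). Genes with undefined correlations are excluded with a
#' warning.
#'
#' @param corr result of [treatment_correlations()].
#' @param k number of flat clusters.
#' @return named integer vector of cluster labels (genes with complete
#'   features only).
#' @export
correlation_clusters <- function(corr, k = 3) {
  mats <- corr$matrices
  feat <- t(vapply(mats, function(m) m[upper.tri(m)],
                   numeric(sum(upper.tri(mats[[1]])))))
  rownames(feat) <- names(mats)
  complete <- stats::complete.cases(feat)
  if (any(!complete))
    warning("excluding gene(s) with undefined correlations: ",
            paste(rownames(feat)[!complete], collapse = ", "), call. = FALSE)
  feat <- feat[complete, , drop = FALSE]
  if (nrow(feat) < max(k, 2))
    stop("fewer genes with complete features than clusters", call. = FALSE)
  feat <- feat[order(rownames(feat)), , drop = FALSE]  # deterministic order
  ward_cluster(feat, k = k)$labels
}
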