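#' Read a qRT-PCR Cq table (CSV)
#'
#' Columns: `gene`, `treatment`, `replicate`, `cq`.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_cq_csv <- function(path) {
  cq <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("gene", "treatment", "replicate", "cq")
  if (!all(req %in% names(cq)))
    stop("Cq table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(cq$cq <= 0)) stop("Cq values must be positive", call. = FALSE)
  cq
}

#' ddCq and fold change for one gene/treatment contrast (Livak method)
#'
#' `ddCq = (Cq_goi - Cq_ref)_treatment - (Cq_goi - Cq_ref)_control`, fold
#' change `2^-ddCq`, assuming one doubling per PCR cycle (efficiency 2).
#'
#' @param cq_goi_trt,cq_ref_trt,cq_goi_ctl,cq_ref_ctl Cq means (cycles) of the
#'   gene of interest and the reference gene under treatment and control.
#' @return list with `ddcq` and `fold_change`.
#' @export
delta_delta_cq <- function(cq_goi_trt, cq_ref_trt, cq_goi_ctl, cq_ref_ctl) {
  vals <- c(cq_goi_trt, cq_ref_trt, cq_goi_ctl, cq_ref_ctl)
  if (any(is.na(vals)) || length(vals) != 4)
    stop("all four Cq values are required", call. = FALSE)
  ddcq <- (cq_goi_trt - cq_ref_trt) - (cq_goi_ctl - cq_ref_ctl)
  list(ddcq = ddcq, fold_change = 2 ^ (-ddcq))
}

#' Relative expression of a gene panel by 2^-ddCq with significance
#'
#' For each gene and treatment, replicate-level `dCq = Cq_gene - Cq_ref` is
#' formed by matching gene and reference measurements of the same biological
#' replicate (plates are run per replicate). `ddCq` is the difference of mean
#' `dCq` between treatment and control, the mean fold change is `2^-ddCq`, and
#' the standard error is computed on the log2 scale from the replicate-level
#' fold changes `2^-(dCq - mean dCq_control)` and reported asymmetrically
#' after back-transformation (`se_low`, `se_high`). The p-value is a
#' two-sided Student t-test (pooled variance) on the replicate `dCq` values,
#' treatment versus control. No multiple-testing correction is applied by
#' default; `adjust = "BH"` enables Benjamini-Hochberg across the panel.
#'
#' @param cq data.frame (`gene`, `treatment`, `replicate`, `cq`).
#' @param reference reference gene id (default `"Actin"`).
#' @param control control treatment label.
#' @param alpha significance level.
#' @param adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return data.frame `gene`, `treatment`, `fold_change`, `log2fc`, `se_log2`,
#'   `se_low`, `se_high`, `p`, `significant`, `n`. Control rows have fold
#'   change 1 by construction and no test. Gene/treatment cells with fewer
#'   than 2 replicates in either group are flagged untestable (`p = NA`,
#'   `significant = FALSE`).
#' @export
quantify_panel <- function(cq, reference = "Actin", control = "Control",
                           alpha = 0.05, adjust = "none") {
  stopifnot(all(c("gene", "treatment", "replicate", "cq") %in% names(cq)))
  if (!reference %in% cq$gene)
    stop("reference gene '", reference, "' absent from the Cq table",
         call. = FALSE)
  treatments <- unique(cq$treatment)
  ref_missing <- setdiff(treatments,
                         unique(cq$treatment[cq$gene == reference]))
  if (length(ref_missing) > 0)
    stop("reference gene missing for treatment(s): ",
         paste(ref_missing, collapse = ", "), call. = FALSE)
  if (!control %in% treatments)
    stop("control treatment '", control, "' absent", call. = FALSE)

  ref <- cq[cq$gene == reference, ]
  ref_key <- paste(ref$treatment, ref$replicate)
  genes <- setdiff(unique(cq$gene), reference)
  rows <- list()
  for (g in genes) {
    sub <- cq[cq$gene == g, ]
    idx <- match(paste(sub$treatment, sub$replicate), ref_key)
    dcq <- sub$cq - ref$cq[idx]
    ok <- !is.na(dcq)
    dcq_by_trt <- split(dcq[ok], sub$treatment[ok])
    ctl <- dcq_by_trt[[control]]
    for (trt in treatments) {
      d <- dcq_by_trt[[trt]]
      n_d <- length(d)
      if (trt == control) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, treatment = trt, fold_change = 1, log2fc = 0,
          se_log2 = if (n_d >= 2)
            stats::sd(-(d - mean(ctl))) / sqrt(n_d) else NA_real_,
          p = NA_real_, n = n_d, stringsAsFactors = FALSE)
        next
      }
      if (is.null(d) || n_d < 2 || length(ctl) < 2) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, treatment = trt,
          fold_change = if (n_d >= 1 && length(ctl) >= 1)
            2 ^ -(mean(d) - mean(ctl)) else NA_real_,
          log2fc = if (n_d >= 1 && length(ctl) >= 1)
            -(mean(d) - mean(ctl)) else NA_real_,
          se_log2 = NA_real_, p = NA_real_, n = n_d,
          stringsAsFactors = FALSE)
        next
      }
      ddcq <- mean(d) - mean(ctl)
      rep_log2 <- -(d - mean(ctl))       # replicate-level log2 fold changes
      se <- stats::sd(rep_log2) / sqrt(n_d)
      p <- stats::t.test(d, ctl, var.equal = TRUE)$p.value
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, treatment = trt, fold_change = 2 ^ (-ddcq),
        log2fc = -ddcq, se_log2 = se, p = p, n = n_d,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust != "none") {
    testable <- !is.na(out$p)
    out$p[testable] <- stats::p.adjust(out$p[testable], method = adjust)
  }
  out$se_low <- 2 ^ (out$log2fc - out$se_log2)
  out$se_high <- 2 ^ (out$log2fc + out$se_log2)
  out$significant <- !is.na(out$p) & out$p <= alpha
  out
}

#' Classify each gene's stress-response category
#'
#' Categories, in order of precedence: `both_up` (significantly upregulated
#' in both Cold and Drought), `cold_specific` / `drought_specific`
#' (significantly up in one stress only), `recovery_elevated` (a recovery
#' treatment's fold change strictly exceeds its stress treatment's and is
#' significantly above control), `down` (significantly below control in a
#' stress and never significantly up anywhere), else `unresponsive`.
#'
#' @param rel data.frame from [quantify_panel()].
#' @param cold,drought,rec_cold,rec_drought treatment labels.
#' @return data.frame `gene`, `category`.
#' @export
classify_response <- function(rel, cold = "Cold", drought = "Drought",
                              rec_cold = "RecCold",
                              rec_drought = "RecDrought") {
  need <- c(cold, drought, rec_cold, rec_drought)
  miss <- setdiff(need, unique(rel$treatment))
  if (length(miss) > 0)
    stop("treatments not quantified: ", paste(miss, collapse = ", "),
         call. = FALSE)
  get <- function(g, trt, col) {
    v <- rel[[col]][rel$gene == g & rel$treatment == trt]
    if (length(v) == 0) NA else v[1]
  }
  genes <- unique(rel$gene)
  cat <- vapply(genes, function(g) {
    sig_up <- function(trt) isTRUE(get(g, trt, "significant") &&
                                     get(g, trt, "fold_change") > 1)
    sig_down <- function(trt) isTRUE(get(g, trt, "significant") &&
                                       get(g, trt, "fold_change") < 1)
    up_cold <- sig_up(cold); up_dr <- sig_up(drought)
    if (up_cold && up_dr) return("both_up")
    if (up_cold) return("cold_specific")
    if (up_dr) return("drought_specific")
    rec_elev <- (sig_up(rec_cold) &&
                   isTRUE(get(g, rec_cold, "fold_change") >
                            get(g, cold, "fold_change"))) ||
      (sig_up(rec_drought) &&
         isTRUE(get(g, rec_drought, "fold_change") >
                  get(g, drought, "fold_change")))
    if (rec_elev) return("recovery_elevated")
    any_up <- sig_up(rec_cold) || sig_up(rec_drought)
    if ((sig_down(cold) || sig_down(drought)) && !any_up) return("down")
    "unresponsive"
  }, character(1))
  data.frame(gene = genes, category = unname(cat),
             stringsAsFactors = FALSE, row.names = NULL)
}
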