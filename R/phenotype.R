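#' Relative electrical conductivity (REC) from paired conductivity readings
#'
#' `REC = 100 * L1 / L2`, the electrolyte-leakage index of membrane damage:
#' conductivity immediately after immersion (L1) relative to conductivity
#' after two hours (L2), as a percentage.
#'
#' @param L1 conductivity immediately after immersion (uS/cm); vectorized.
#' @param L2 conductivity after 2 h (uS/cm); must be positive.
#' @return REC percentage(s). `L1 > L2` triggers a warning but the value is
#'   still computed.
#' @export
compute_rec <- function(L1, L2) {
  if (any(L2 <= 0)) stop("L2 must be positive", call. = FALSE)
  if (any(L1 > L2)) warning("L1 > L2 for ", sum(L1 > L2),
                            " measurement(s); REC exceeds 100%",
                            call. = FALSE)
  100 * L1 / L2
}

#' Read a conductivity CSV and derive REC
#'
#' Columns: `genotype`, `treatment`, `L1`, `L2` (optionally `replicate`).
#'
#' @param path CSV path.
#' @return data.frame with an added `REC` column.
#' @export
read_conductivity_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("genotype", "treatment", "L1", "L2")
  if (!all(req %in% names(tab)))
    stop("conductivity table needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  tab$REC <- compute_rec(tab$L1, tab$L2)
  tab
}

#' Select the most stress-tolerant genotype by electrolyte leakage
#'
#' Summarizes mean REC per genotype and stress treatment and returns the
#' genotype minimizing the mean REC across the stress treatments (lowest
#' leakage = least membrane damage = most tolerant). Ties are broken by
#' genotype id; genotypes missing a stress treatment are excluded with a
#' warning.
#'
#' @param rec data.frame with columns `genotype`, `treatment` and either
#'   `REC` or `L1`/`L2` (REC is derived if absent).
#' @param stress_treatments treatments entering the tolerance summary.
#' @return list with `tolerant_genotype` and `summary` (data.frame
#'   `genotype`, one mean-REC column per stress, `mean_rec`).
#' @export
select_tolerant_genotype <- function(rec,
                                     stress_treatments = c("Cold", "Drought")) {
  if (!"REC" %in% names(rec)) rec$REC <- compute_rec(rec$L1, rec$L2)
  rec <- rec[rec$treatment %in% stress_treatments, , drop = FALSE]
  if (nrow(rec) == 0) stop("no rows for the stress treatments", call. = FALSE)
  genotypes <- sort(unique(rec$genotype))
  if (length(genotypes) < 2)
    stop("need at least 2 genotypes to compare", call. = FALSE)
  wide <- lapply(genotypes, function(g) {
    means <- vapply(stress_treatments, function(trt) {
      v <- rec$REC[rec$genotype == g & rec$treatment == trt]
      if (length(v) == 0) NA_real_ else mean(v)
    }, numeric(1))
    c(means, mean_rec = mean(means))
  })
  summary <- data.frame(genotype = genotypes,
                        do.call(rbind, wide),
                        stringsAsFactors = FALSE, row.names = NULL)
  incomplete <- is.na(summary$mean_rec)
  if (any(incomplete)) {
    warning("genotype(s) missing a stress treatment, excluded: ",
            paste(summary$genotype[incomplete], collapse = ", "),
            call. = FALSE)
  }
  usable <- summary[!incomplete, , drop = FALSE]
  if (nrow(usable) == 0) stop("no genotype has all stress treatments",
                              call. = FALSE)
  # ties broken by genotype id: order is already sorted by genotype
  best <- usable$genotype[which.min(usable$mean_rec)]
  list(tolerant_genotype = best, summary = summary)
}
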