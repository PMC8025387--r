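#' Greedy r-squared pruning of a SNP panel
#'
#' Scans the SNPs in their input order and keeps a SNP only if its squared
#' Pearson correlation with every already-kept SNP is strictly below
#' `r2_threshold`. Input order is part of the contract: permuting it can
#' change the retained set. Monomorphic SNPs have undefined r-squared and are
#' dropped with a warning.
#'
#' @param snp_ids character vector of panel SNP ids, in scan order.
#' @param genotypes samples x SNP dosage matrix whose column names cover
#'   `snp_ids`.
#' @param r2_threshold pruning threshold (default 0.3, strict `<`).
#' @return Character vector of retained SNP ids, in input order.
#' @export
prune_snps <- function(snp_ids, genotypes, r2_threshold = 0.3) {
  missing_snps <- setdiff(snp_ids, colnames(genotypes))
  if (length(missing_snps)) {
    stop("genotypes missing for: ", paste(missing_snps, collapse = ", "))
  }
  if (anyDuplicated(snp_ids)) stop("snp_ids must be unique")
  kept <- character(0)
  for (s in snp_ids) {
    g <- genotypes[, s]
    if (stats::var(g, na.rm = TRUE) == 0 || all(is.na(g))) {
      warning("monomorphic SNP dropped: ", s)
      next
    }
    ok <- TRUE
    for (k in kept) {
      r2 <- suppressWarnings(stats::cor(g, genotypes[, k], use = "complete.obs"))^2
      if (!is.na(r2) && r2 >= r2_threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, s)
  }
  kept
}

#' Polygenic risk score by risk-allele counting
#'
#' Unweighted sum of risk-allele dosages over the retained SNPs. Dosages must
#' already be oriented to the risk allele (0/1/2 copies). Missing dosages are
#' mean-imputed per SNP and the imputation is reported.
#'
#' @param snp_ids retained SNP ids (e.g. from [prune_snps()]).
#' @param genotypes samples x SNP dosage matrix.
#' @return Numeric per-sample score vector (named by rownames of
#'   `genotypes`), with an `n_imputed` attribute.
#' @export
compute_prs <- function(snp_ids, genotypes) {
  if (!length(snp_ids)) stop("no retained SNPs: cannot compute a risk score")
  g <- genotypes[, snp_ids, drop = FALSE]
  n_imp <- 0L
  if (anyNA(g)) {
    for (j in seq_len(ncol(g))) {
      miss <- is.na(g[, j])
      if (any(miss)) {
        g[miss, j] <- mean(g[, j], na.rm = TRUE)
        n_imp <- n_imp + sum(miss)
      }
    }
    message(n_imp, " missing dosages mean-imputed")
  }
  prs <- rowSums(g)
  attr(prs, "n_imputed") <- n_imp
  prs
}

#' Read a PRS panel file
#'
#' CSV with columns `chc`, `snp_id`, `risk_allele`; row order defines the
#' pruning scan order per CHC.
#'
#' @param path file path.
#' @return data.frame with one row per (chc, snp).
#' @export
read_prs_panel <- function(path) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("chc", "snp_id", "risk_allele")
  if (!all(need %in% names(panel))) {
    stop("panel must have columns: ", paste(need, collapse = ", "))
  }
  dup <- stats::aggregate(seq_len(nrow(panel)), panel["chc"], function(i) anyDuplicated(panel$snp_id[i]))
  if (any(dup$x > 0)) stop("duplicate snp_id within a CHC panel")
  panel
}
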