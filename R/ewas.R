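#' Pairwise phi coefficients between binary treatments
#'
#' The phi coefficient is the Pearson correlation of two binary variables,
#' computed from the 2x2 table as
#' `phi = (ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))`. Its departure from zero is
#' tested with the chi-square statistic `n * phi^2` on 1 degree of freedom.
#' Treatments with a degenerate margin (all 0 or all 1) give undefined phi and
#' are returned as `NA` with a warning.
#'
#' @param treatments samples x treatments 0/1 matrix with column names.
#' @return List of class `PhiMatrix` with symmetric matrices `phi` (unit
#'   diagonal) and `p`.
#' @export
phi_matrix <- function(treatments) {
  treatments <- as.matrix(treatments)
  if (!all(treatments %in% c(0, 1))) stop("treatments must be binary 0/1")
  k <- ncol(treatments)
  n <- nrow(treatments)
  nms <- colnames(treatments)
  phi <- diag(1, k)
  p <- matrix(NA_real_, k, k)
  diag(p) <- 0
  dimnames(phi) <- dimnames(p) <- list(nms, nms)
  degen <- apply(treatments, 2, function(x) length(unique(x)) < 2)
  if (any(degen)) {
    warning(
      "degenerate margin (constant column) for: ",
      paste(nms[degen], collapse = ", "), "; phi undefined"
    )
  }
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        if (degen[i] || degen[j]) {
          phi[i, j] <- phi[j, i] <- NA_real_
          next
        }
        a <- as.numeric(sum(treatments[, i] == 1 & treatments[, j] == 1))
        b <- as.numeric(sum(treatments[, i] == 1 & treatments[, j] == 0))
        cc <- as.numeric(sum(treatments[, i] == 0 & treatments[, j] == 1))
        d <- as.numeric(sum(treatments[, i] == 0 & treatments[, j] == 0))
        ph <- (a * d - b * cc) / sqrt((a + b) * (cc + d) * (a + cc) * (b + d))
        phi[i, j] <- phi[j, i] <- ph
        p[i, j] <- p[j, i] <- stats::pchisq(n * ph^2, df = 1, lower.tail = FALSE)
      }
    }
  }
  structure(list(phi = phi, p = p, n = n), class = "PhiMatrix")
}

#' Choose the co-treatments to adjust for in a treatment-specific EWAS
#'
#' When two exposures are strongly confounded by protocol (phi above
#' `phi_cut` with p below `p_cut`), adjusting one EWAS for the other would
#' absorb the signal; such co-treatments are excluded from the adjustment set.
#' All remaining co-treatments are adjusted for.
#'
#' @param phi a `PhiMatrix` from [phi_matrix()].
#' @param treatment name of the exposure of interest.
#' @param phi_cut exclusion threshold on phi (default 0.4, strict `>`).
#' @param p_cut exclusion threshold on the phi p-value (default 0.05,
#'   strict `<`).
#' @return Character vector of co-treatments to include as covariates.
#' @export
select_adjustment_set <- function(phi, treatment, phi_cut = 0.4, p_cut = 0.05) {
  stopifnot(inherits(phi, "PhiMatrix"))
  nms <- rownames(phi$phi)
  if (!treatment %in% nms) stop("unknown treatment: ", treatment)
  others <- setdiff(nms, treatment)
  excluded <- vapply(others, function(o) {
    ph <- phi$phi[treatment, o]
    pv <- phi$p[treatment, o]
    !is.na(ph) && !is.na(pv) && ph > phi_cut && pv < p_cut
  }, logical(1))
  others[!excluded]
}

# shared per-CpG OLS engine. Y: CpG x sample M matrix (may contain NA),
# X: n x p design with intercept first and the tested variable second.
# Returns data.frame cpg_id, beta, se, t, p_raw, n_used.
.ewas_ols <- function(Y, X, test_col = 2L) {
  n <- ncol(Y)
  stopifnot(nrow(X) == n)
  cpg_ids <- rownames(Y) %||% sprintf("cpg%06d", seq_len(nrow(Y)))
  res <- data.frame(
    cpg_id = cpg_ids, beta = NA_real_, se = NA_real_,
    t = NA_real_, p_raw = NA_real_, n_used = NA_integer_,
    stringsAsFactors = FALSE
  )
  complete_x <- stats::complete.cases(X)
  no_na <- !anyNA(Y) && all(complete_x)
  fit_block <- function(rows, cols) {
    Xc <- X[cols, , drop = FALSE]
    qrx <- qr(Xc)
    p <- qrx$rank
    if (p < ncol(Xc)) {
      # drop aliased covariate columns the way lm() does; if the tested
      # variable itself is aliased the block is unestimable
      keep <- qrx$pivot[seq_len(p)]
      if (!(test_col %in% keep)) {
        return(NULL)
      }
      Xc <- Xc[, sort(keep), drop = FALSE]
      tc <- match(test_col, sort(keep))
      qrx <- qr(Xc)
    } else {
      tc <- test_col
    }
    if (length(cols) <= qrx$rank) {
      return(NULL)
    }
    Yt <- t(Y[rows, cols, drop = FALSE])
    coefs <- qr.coef(qrx, Yt)
    fitted <- Xc %*% coefs
    rss <- colSums((Yt - fitted)^2)
    df <- length(cols) - qrx$rank
    xtx_inv_jj <- chol2inv(qr.R(qrx))[tc, tc]
    se <- sqrt(rss / df * xtx_inv_jj)
    bet <- coefs[tc, ]
    tt <- bet / se
    list(
      rows = rows, beta = bet, se = se, t = tt,
      p = 2 * stats::pt(abs(tt), df, lower.tail = FALSE),
      n = length(cols)
    )
  }
  if (no_na) {
    blk <- fit_block(seq_len(nrow(Y)), seq_len(n))
    if (!is.null(blk)) {
      res$beta <- blk$beta
      res$se <- blk$se
      res$t <- blk$t
      res$p_raw <- blk$p
      res$n_used <- blk$n
    }
    return(res)
  }
  for (i in seq_len(nrow(Y))) {
    cols <- which(!is.na(Y[i, ]) & complete_x)
    if (length(cols) < ncol(X) + 1) next
    if (length(unique(X[cols, test_col])) < 2) next
    blk <- fit_block(i, cols)
    if (is.null(blk)) next
    res$beta[i] <- blk$beta
    res$se[i] <- blk$se
    res$t[i] <- blk$t
    res$p_raw[i] <- blk$p
    res$n_used[i] <- blk$n
  }
  res
}

#' Epigenome-wide association scan for one exposure
#'
#' Per CpG, ordinary least squares of the M-value on the exposure plus
#' covariates, with a two-sided t-test on the exposure coefficient. Only
#' samples with an observed M-value at that CpG (and complete covariates)
#' enter each fit. Typical covariates are sex, age, the phi-selected
#' co-treatments, leukocyte proportions with one cell type dropped (the
#' proportions sum to one), genetic PCs and methylation PCs.
#'
#' @param m `MethylationMatrix` on the M scale or plain CpG x sample M
#'   matrix (NA = missing).
#' @param exposure numeric/0-1 vector, one entry per sample.
#' @param covariates data.frame or matrix of adjustment variables (may be
#'   `NULL`).
#' @param treatment label stored in the result (default `"exposure"`).
#' @return data.frame of class `ewas_result` with columns `cpg_id`,
#'   `treatment`, `beta`, `se`, `t`, `p_raw`, `n_used`. CpGs with a
#'   rank-deficient design or a constant exposure among complete cases are
#'   `NA`.
#' @export
run_ewas <- function(m, exposure, covariates = NULL, treatment = "exposure") {
  if (inherits(m, "MethylationMatrix") && m$scale != "M") {
    stop("run_ewas expects M-scale methylation; use beta_to_m() first")
  }
  Y <- as_meth_values(m)
  n <- ncol(Y)
  if (length(exposure) != n) stop("exposure length must equal the number of samples")
  X <- cbind(`(Intercept)` = 1, exposure = as.numeric(exposure))
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    cv <- as.matrix(as.data.frame(covariates))
    if (nrow(cv) != n) stop("covariates must have one row per sample")
    X <- cbind(X, cv)
  }
  out <- .ewas_ols(Y, X, test_col = 2L)
  out <- cbind(out[1], treatment = treatment, out[-1])
  class(out) <- c("ewas_result", class(out))
  out
}

#' Genomic-control adjustment of EWAS p-values
#'
#' Converts raw p-values to 1-df chi-square statistics, estimates the
#' inflation factor `lambda` as the median chi-square divided by the null
#' median 0.45494 (`qchisq(0.5, 1)`), and — only when `lambda > 1` — rescales
#' the statistics by `lambda` and recomputes p-values. Deflated scans
#' (`lambda <= 1`) are left untouched, so the correction is idempotent and
#' never makes p-values smaller.
#'
#' @param records an `ewas_result` data.frame with `p_raw`.
#' @param min_records minimum number of finite p-values required for a stable
#'   median (default 100).
#' @return The records with a `p_gc` column and a `lambda` attribute.
#' @export
genomic_control_adjust <- function(records, min_records = 100) {
  p <- records$p_raw
  ok <- is.finite(p)
  if (!any(ok)) stop("all p-values are NA; cannot estimate lambda")
  if (sum(ok) < min_records) {
    warning("fewer than ", min_records, " finite p-values; lambda estimate is unstable")
  }
  chisq <- stats::qchisq(p[ok], df = 1, lower.tail = FALSE)
  lambda <- stats::median(chisq) / stats::qchisq(0.5, df = 1)
  records$p_gc <- p
  if (lambda > 1) {
    records$p_gc[ok] <- stats::pchisq(chisq / lambda, df = 1, lower.tail = FALSE)
  }
  attr(records, "lambda") <- lambda
  records
}

#' Call epigenome-wide significant hits
#'
#' Strict threshold on the genomic-control-adjusted p-value; the conventional
#' epigenome-wide bound 9e-8 corresponds to a 5% family-wise error rate on
#' current arrays.
#'
#' @param records `ewas_result` with `p_gc` (falls back to `p_raw`).
#' @param threshold significance threshold, strict `<` (default 9e-8).
#' @return The subset of records that are hits.
#' @export
call_significant <- function(records, threshold = 9e-8) {
  p <- records$p_gc %||% records$p_raw
  if (is.null(p)) stop("records carry no p-values")
  records[which(p < threshold), , drop = FALSE]
}

#' Ordinal dose-response trend per CpG
#'
#' Cumulative dose is coded ordinally: unexposed survivors (dose 0) are level
#' 0 and exposed survivors are split at the tertiles of the exposed doses into
#' levels 1-3 (boundary ties go to the lower bin). Each CpG's M-value is
#' regressed on the ordinal code plus covariates and the trend p-value is the
#' two-sided t-test on the ordinal coefficient.
#'
#' @param m M-scale methylation (matrix or `MethylationMatrix`).
#' @param dose nonnegative cumulative dose per sample; 0 = unexposed.
#' @param covariates optional adjustment variables.
#' @param alpha trend-significance level for the `dose_responsive` flag
#'   (default 0.05).
#' @return data.frame with `cpg_id`, `beta`, `se`, `t`, `trend_p`, `n_used`,
#'   `dose_responsive`, plus an `ordinal` attribute with the per-sample codes.
#' @export
dose_response_trend <- function(m, dose, covariates = NULL, alpha = 0.05) {
  if (any(dose < 0, na.rm = TRUE)) stop("doses must be nonnegative")
  pos <- dose[dose > 0 & !is.na(dose)]
  if (length(unique(pos)) < 3) {
    stop("fewer than 3 distinct positive doses: tertile coding impossible")
  }
  cuts <- stats::quantile(pos, c(1 / 3, 2 / 3), names = FALSE)
  ordinal <- ifelse(is.na(dose), NA_real_,
    ifelse(dose == 0, 0, ifelse(dose <= cuts[1], 1, ifelse(dose <= cuts[2], 2, 3)))
  )
  res <- run_ewas(m, ordinal, covariates, treatment = "dose_trend")
  out <- data.frame(
    cpg_id = res$cpg_id, beta = res$beta, se = res$se, t = res$t,
    trend_p = res$p_raw, n_used = res$n_used,
    dose_responsive = !is.na(res$p_raw) & res$p_raw < alpha,
    stringsAsFactors = FALSE
  )
  attr(out, "ordinal") <- ordinal
  out
}

#' Paired-exposure EWAS (both treatments vs neither)
#'
#' Restricts the cohort to samples that received both of two treatments or
#' neither, and scans methylation on the both-vs-neither indicator with the
#' two paired treatments removed from the covariates. Detects joint effects
#' invisible to either single-treatment scan.
#'
#' @param m M-scale methylation.
#' @param a,b 0/1 exposure vectors for the two treatments.
#' @param covariates optional adjustment variables (columns named after `a`
#'   or `b`'s treatments should already be removed by the caller; any columns
#'   named in `drop_covariates` are removed here).
#' @param drop_covariates character vector of covariate columns to drop.
#' @param label treatment label for the result.
#' @param min_group minimum size of each group (default 10).
#' @return `ewas_result` for the both-vs-neither contrast; `n_used` counts
#'   only concordant samples.
#' @export
paired_exposure_ewas <- function(m, a, b, covariates = NULL,
                                 drop_covariates = character(0),
                                 label = "both_vs_neither", min_group = 10) {
  if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1))) stop("treatments must be binary")
  both <- a == 1 & b == 1
  neither <- a == 0 & b == 0
  if (sum(both) < min_group || sum(neither) < min_group) {
    stop(sprintf(
      "need at least %d samples per group: both = %d, neither = %d",
      min_group, sum(both), sum(neither)
    ))
  }
  keep <- both | neither
  Y <- as_meth_values(m)[, keep, drop = FALSE]
  cv <- NULL
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)[keep, , drop = FALSE]
    cv <- cv[, setdiff(names(cv), drop_covariates), drop = FALSE]
    if (ncol(cv) == 0) cv <- NULL
  }
  run_ewas(Y, as.numeric(both[keep]), cv, treatment = label)
}

#' Annotation-category enrichment of EWAS hits
#'
#' For each level of each annotation column, forms the 2x2 table of hit vs
#' non-hit CpGs by in-category vs out-of-category over the tested background,
#' reports the sample odds ratio `(a*d)/(b*c)`, the conditional-MLE odds
#' ratio and p-value from Fisher's exact test, and BH-FDR across all tested
#' categories.
#'
#' @param hits character vector of hit CpG ids.
#' @param annotation data.frame with `cpg_id` plus one or more category
#'   columns (e.g. `island_region`, `functional_region`).
#' @param background character vector of all tested CpG ids (default: all ids
#'   in `annotation`).
#' @param columns which annotation columns to test.
#' @return data.frame with `annotation`, `category`, the four table cells,
#'   `or` (sample), `or_cmle`, `p`, `p_fdr`.
#' @export
annotation_enrichment <- function(hits, annotation, background = annotation$cpg_id,
                                  columns = setdiff(
                                    names(annotation),
                                    c("cpg_id", "chrom", "pos", "gene")
                                  )) {
  background <- unique(background)
  ann <- annotation[match(background, annotation$cpg_id), , drop = FALSE]
  if (anyNA(ann$cpg_id)) stop("background contains CpGs missing from the annotation")
  is_hit <- background %in% hits
  rows <- list()
  for (col in columns) {
    for (cat in sort(unique(ann[[col]]))) {
      inc <- ann[[col]] == cat
      a <- sum(is_hit & inc)
      b <- sum(is_hit & !inc)
      cc <- sum(!is_hit & inc)
      d <- sum(!is_hit & !inc)
      ft <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))
      rows[[length(rows) + 1]] <- data.frame(
        annotation = col, category = cat,
        hit_in = a, hit_out = b, bg_in = cc, bg_out = d,
        or = (a * d) / (b * cc), or_cmle = unname(ft$estimate), p = ft$p.value,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out
}
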