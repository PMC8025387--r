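#' Residualize methylation on non-treatment covariates
#'
#' Per CpG, the residual M-value is the M-value minus its OLS fit on the
#' stated covariates (typically sex, age, leukocyte proportions, genetic PCs
#' and methylation PCs — everything in the EWAS model except the treatments).
#' Residuals are orthogonal to every covariate used. Used downstream as the
#' exposure in CHC association and as the mediator in mediation analysis.
#'
#' @param m M-scale methylation (matrix or `MethylationMatrix`).
#' @param covariates data.frame/matrix of covariates, or `NULL` for plain
#'   centering.
#' @return CpG x sample matrix of residuals (NA where the input was masked or
#'   the design was rank-deficient), with a `covariates` attribute recording
#'   the columns used.
#' @export
compute_residuals <- function(m, covariates = NULL) {
  Y <- as_meth_values(m)
  n <- ncol(Y)
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    cv <- as.matrix(as.data.frame(covariates))
    if (nrow(cv) != n) stop("covariates must have one row per sample")
    X <- cbind(X, cv)
  }
  out <- matrix(NA_real_, nrow(Y), n, dimnames = dimnames(Y))
  complete_x <- stats::complete.cases(X)
  if (!anyNA(Y) && all(complete_x)) {
    qrx <- qr(X)
    Yt <- t(Y)
    out <- t(Yt - X[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE] %*%
      qr.coef(qr(X[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]), Yt))
  } else {
    for (i in seq_len(nrow(Y))) {
      cols <- which(!is.na(Y[i, ]) & complete_x)
      if (length(cols) <= ncol(X)) next
      fit <- stats::lm.fit(X[cols, , drop = FALSE], Y[i, cols])
      out[i, cols] <- fit$residuals
    }
  }
  attr(out, "covariates") <- colnames(X)[-1]
  out
}

#' Incident-only risk set for a chronic health condition
#'
#' Survivors whose condition predates the methylation blood draw (prevalent
#' cases) are excluded from that condition's analysis; the risk set is the
#' incident cases plus never-affected controls. Samples with a missing
#' prevalence flag are excluded with a warning.
#'
#' @param sample_sheet data.frame with `<chc>_status` and `<chc>_prevalent`
#'   0/1 columns.
#' @param chc condition name.
#' @return List with `keep` (logical risk-set indicator), `status` (0/1 for
#'   kept samples, NA elsewhere), `n_cases`, `n_controls`, `n_prevalent`.
#' @export
filter_incident <- function(sample_sheet, chc) {
  scol <- paste0(chc, "_status")
  pcol <- paste0(chc, "_prevalent")
  if (!scol %in% names(sample_sheet)) stop("sample sheet lacks column ", scol)
  status <- sample_sheet[[scol]]
  prevalent <- if (pcol %in% names(sample_sheet)) sample_sheet[[pcol]] else rep(0L, length(status))
  miss <- is.na(prevalent) | is.na(status)
  if (any(miss)) {
    warning(sum(miss), " samples with missing status/onset flag excluded for ", chc)
  }
  keep <- !miss & prevalent == 0
  st <- ifelse(keep, status, NA_integer_)
  list(
    keep = keep, status = st,
    n_cases = sum(st == 1, na.rm = TRUE),
    n_controls = sum(st == 0, na.rm = TRUE),
    n_prevalent = sum(!miss & prevalent == 1)
  )
}

#' Logistic association of residual methylation with an incident CHC
#'
#' Per CpG, maximum-likelihood logistic regression of incident case status on
#' the residual M-value, adjusted for age, sex and the CHC-specific polygenic
#' risk score; Wald test on the residual-M coefficient, reported as an odds
#' ratio per residual-M unit, with BH-FDR across CpGs.
#'
#' @param resid_m CpG x sample residual M matrix (from
#'   [compute_residuals()]).
#' @param status 0/1 incident case status (NA = not in the risk set).
#' @param covariates data.frame of per-sample adjustment variables (e.g.
#'   `age`, `sex`, `prs`).
#' @param chc label stored in the records.
#' @param min_per_arm minimum cases and controls required (default 10).
#' @return data.frame with `cpg_id`, `chc`, `or`, `log_or`, `se`, `p`,
#'   `p_fdr`, `n_cases`, `n_controls`; non-converged or separated fits are NA.
#' @export
associate_chc <- function(resid_m, status, covariates = NULL, chc = "chc",
                          min_per_arm = 10) {
  keep <- !is.na(status)
  y <- status[keep]
  if (sum(y == 1) < min_per_arm || sum(y == 0) < min_per_arm) {
    stop(sprintf(
      "need at least %d cases and controls, got %d / %d",
      min_per_arm, sum(y == 1), sum(y == 0)
    ))
  }
  R <- resid_m[, keep, drop = FALSE]
  cv <- if (!is.null(covariates)) as.matrix(as.data.frame(covariates))[keep, , drop = FALSE] else NULL
  ids <- rownames(R) %||% sprintf("cpg%06d", seq_len(nrow(R)))
  out <- data.frame(
    cpg_id = ids, chc = chc, or = NA_real_, log_or = NA_real_,
    se = NA_real_, p = NA_real_,
    n_cases = sum(y == 1), n_controls = sum(y == 0),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(R))) {
    x <- R[i, ]
    ok <- !is.na(x) & (if (is.null(cv)) TRUE else stats::complete.cases(cv))
    if (sum(y[ok] == 1) < min_per_arm || sum(y[ok] == 0) < min_per_arm) next
    X <- cbind(resid_m = x[ok])
    if (!is.null(cv)) X <- cbind(X, cv[ok, , drop = FALSE])
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(cbind(1, X), y[ok], family = stats::binomial())),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged || fit$boundary) next
    co <- fit$coefficients[2]
    # Wald SE from the unscaled covariance of the IRLS fit
    w <- fit$weights
    XtWX <- crossprod(cbind(1, X) * sqrt(w))
    vc <- tryCatch(chol2inv(chol(XtWX)), error = function(e) NULL)
    if (is.null(vc)) next
    se <- sqrt(vc[2, 2])
    if (!is.finite(se) || se > 100) next # complete/quasi-separation
    out$log_or[i] <- co
    out$or[i] <- exp(co)
    out$se[i] <- se
    out$p[i] <- 2 * stats::pnorm(abs(co / se), lower.tail = FALSE)
  }
  out$p_fdr <- bh_fdr(out$p)
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone in raw-p rank, capped at 1); `NA` entries
#' pass through without affecting the ranks of the rest. Thin wrapper over
#' [stats::p.adjust()].
#'
#' @param p vector of raw p-values in (0, 1\] (NA allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Per-CHC incidence summary
#'
#' Incident cases over the at-risk denominator (prevalent cases removed),
#' with the percentage rounded to one decimal and a 95% confidence interval.
#' The default interval is the Wald normal approximation on the proportion;
#' Wilson score intervals are available via `ci_method`.
#'
#' @param sample_sheet data.frame with per-CHC status/prevalent columns, or
#'   `NULL` when `counts` is given.
#' @param chcs conditions to summarize (default: every `<chc>_status` column).
#' @param counts optional data.frame with columns `chc`, `incident`,
#'   `at_risk`, used directly instead of a sample sheet.
#' @param ci_method `"wald"` or `"wilson"`.
#' @return data.frame with `chc`, `incident`, `at_risk`, `percent` (one
#'   decimal), `ci_lo`, `ci_hi` (percent scale).
#' @export
incidence_summary <- function(sample_sheet = NULL, chcs = NULL, counts = NULL,
                              ci_method = c("wald", "wilson")) {
  ci_method <- match.arg(ci_method)
  if (is.null(counts)) {
    if (is.null(chcs)) {
      chcs <- sub("_status$", "", grep("_status$", names(sample_sheet), value = TRUE))
    }
    counts <- do.call(rbind, lapply(chcs, function(chc) {
      fi <- filter_incident(sample_sheet, chc)
      data.frame(
        chc = chc, incident = fi$n_cases,
        at_risk = fi$n_cases + fi$n_controls
      )
    }))
  }
  if (any(counts$at_risk == 0)) stop("zero at-risk denominator")
  p <- counts$incident / counts$at_risk
  z <- stats::qnorm(0.975)
  if (ci_method == "wald") {
    half <- z * sqrt(p * (1 - p) / counts$at_risk)
    lo <- pmax(p - half, 0)
    hi <- pmin(p + half, 1)
  } else {
    n <- counts$at_risk
    centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
    lo <- centre - half
    hi <- centre + half
  }
  data.frame(
    chc = counts$chc, incident = counts$incident, at_risk = counts$at_risk,
    percent = round(100 * p, 1),
    ci_lo = round(100 * lo, 1), ci_hi = round(100 * hi, 1),
    stringsAsFactors = FALSE
  )
}
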