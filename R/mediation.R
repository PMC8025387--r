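#' Quasi-Bayesian causal mediation for a continuous mediator
#'
#' Estimates the average causal mediation effect (ACME), average direct
#' effect (ADE) and total effect of a binary treatment on an outcome through a
#' continuous mediator (a residual M-value or a combined methylation score),
#' using the quasi-Bayesian Monte-Carlo algorithm: both models are fitted by
#' maximum likelihood, `n_draws` parameter vectors are drawn from the
#' multivariate normal at (estimate, covariance) of each model, and for each
#' draw counterfactual mediator values M(0)/M(1) (model mean plus a fresh
#' Gaussian error at the residual SD) are pushed through the outcome model to
#' give per-sample potential outcomes Y(t, M(t')). Effects are averaged over
#' samples and over the two treatment arms:
#' `ACME(t) = E[Y(t, M(1)) - Y(t, M(0))]`,
#' `ADE(t) = E[Y(1, M(t)) - Y(0, M(t))]`, total = mean ACME + mean ADE, all
#' on the risk-difference (probability) scale for a binomial outcome.
#' Percentile confidence intervals and the ACME p-value come from the draw
#' distribution.
#'
#' @param treatment 0/1 exposure vector.
#' @param mediator numeric mediator vector (e.g. residual M-values).
#' @param outcome 0/1 outcome (binomial family) or numeric (gaussian family);
#'   NA entries are dropped together with their covariate rows.
#' @param covariates_mediator data.frame/matrix of mediator-model covariates
#'   (e.g. other significant treatments), or `NULL`.
#' @param covariates_outcome data.frame/matrix of outcome-model covariates
#'   (e.g. age, sex, PRS, other significant treatments), or `NULL`.
#' @param family `"binomial"` (logit link, effects on the probability scale)
#'   or `"gaussian"` (identity link, in which case the ACME converges to the
#'   product of coefficients).
#' @param n_draws number of quasi-Bayesian parameter draws (>= 100).
#' @param seed integer seed for the draws.
#' @param mediator_id label stored in the result.
#' @param chc,treatment_name labels stored in the result.
#' @return An object of class `MediationResult`: list with point estimates
#'   `acme`, `ade`, `total`, `prop_mediated`, `pct_mediated`, percentile CIs,
#'   `acme_p`, Monte-Carlo standard errors (`acme_mcse`, ...), `total_or`
#'   (treatment odds ratio from the outcome model refitted without the
#'   mediator; binomial only), `n`, `n_draws`, `seed` and a
#'   `prop_flag` warning marker when ACME and total effect have opposite
#'   signs (the unclamped ratio is then reported as-is).
#' @export
mediate_single <- function(treatment, mediator, outcome,
                           covariates_mediator = NULL,
                           covariates_outcome = NULL,
                           family = c("binomial", "gaussian"),
                           n_draws = 1000, seed = 1L,
                           mediator_id = "mediator", chc = "chc",
                           treatment_name = "treatment") {
  family <- match.arg(family)
  if (n_draws < 100) stop("n_draws must be at least 100")
  t_ <- as.numeric(treatment)
  ok <- !is.na(t_) & !is.na(mediator) & !is.na(outcome)
  cm <- if (!is.null(covariates_mediator)) as.matrix(as.data.frame(covariates_mediator)) else NULL
  co <- if (!is.null(covariates_outcome)) as.matrix(as.data.frame(covariates_outcome)) else NULL
  if (!is.null(cm)) ok <- ok & stats::complete.cases(cm)
  if (!is.null(co)) ok <- ok & stats::complete.cases(co)
  t_ <- t_[ok]
  m_ <- mediator[ok]
  y_ <- outcome[ok]
  n <- length(y_)
  if (!is.null(cm)) cm <- cm[ok, , drop = FALSE]
  if (!is.null(co)) co <- co[ok, , drop = FALSE]

  # mediator model: M ~ T (+ covariates), Gaussian
  Xm <- cbind(`(Intercept)` = 1, treat = t_)
  if (!is.null(cm)) Xm <- cbind(Xm, cm)
  mfit <- stats::lm.fit(Xm, m_)
  if (mfit$rank < ncol(Xm)) stop("mediator model is rank deficient")
  sigma_m <- sqrt(sum(mfit$residuals^2) / (n - mfit$rank))
  vcov_m <- chol2inv(qr.R(qr(Xm))) * sigma_m^2
  coef_m <- mfit$coefficients

  # outcome model: Y ~ T + M (+ covariates)
  Xy <- cbind(`(Intercept)` = 1, treat = t_, med = m_)
  if (!is.null(co)) Xy <- cbind(Xy, co)
  if (family == "binomial") {
    yfit <- suppressWarnings(stats::glm.fit(Xy, y_, family = stats::binomial()))
    if (!yfit$converged) stop("outcome model did not converge")
    W <- yfit$weights
    vcov_y <- chol2inv(chol(crossprod(Xy * sqrt(W))))
    linkinv <- stats::plogis
  } else {
    yfit <- stats::lm.fit(Xy, y_)
    if (yfit$rank < ncol(Xy)) stop("outcome model is rank deficient")
    sigma_y <- sqrt(sum(yfit$residuals^2) / (n - yfit$rank))
    vcov_y <- chol2inv(qr.R(qr(Xy))) * sigma_y^2
    linkinv <- identity
  }
  coef_y <- yfit$coefficients

  set.seed(as.integer(seed))
  draws_m <- MASS::mvrnorm(n_draws, coef_m, vcov_m)
  draws_y <- MASS::mvrnorm(n_draws, coef_y, vcov_y)

  # counterfactual designs with treatment forced to 0/1
  Xm0 <- Xm
  Xm0[, "treat"] <- 0
  Xm1 <- Xm
  Xm1[, "treat"] <- 1
  base_y <- Xy
  d0 <- d1 <- z0 <- z1 <- numeric(n_draws)
  chunk <- 200L
  for (start in seq(1, n_draws, by = chunk)) {
    idx <- start:min(start + chunk - 1, n_draws)
    nb <- length(idx)
    mu0 <- Xm0 %*% t(draws_m[idx, , drop = FALSE]) # n x nb
    mu1 <- Xm1 %*% t(draws_m[idx, , drop = FALSE])
    M0 <- mu0 + matrix(stats::rnorm(n * nb, sd = sigma_m), n, nb)
    M1 <- mu1 + matrix(stats::rnorm(n * nb, sd = sigma_m), n, nb)
    # outcome linear predictor pieces: fixed covariate part + treat + med
    b_t <- draws_y[idx, "treat"]
    b_m <- draws_y[idx, "med"]
    other <- base_y[, -c(2, 3), drop = FALSE] %*%
      t(draws_y[idx, -c(2, 3), drop = FALSE]) # n x nb
    pot <- function(tval, M) {
      eta <- other + rep(tval * b_t, each = n) + M * rep(b_m, each = n)
      linkinv(eta)
    }
    y_t0_m0 <- pot(0, M0)
    y_t0_m1 <- pot(0, M1)
    y_t1_m0 <- pot(1, M0)
    y_t1_m1 <- pot(1, M1)
    d0[idx] <- colMeans(y_t0_m1 - y_t0_m0) # ACME(0)
    d1[idx] <- colMeans(y_t1_m1 - y_t1_m0) # ACME(1)
    z0[idx] <- colMeans(y_t1_m0 - y_t0_m0) # ADE(0)
    z1[idx] <- colMeans(y_t1_m1 - y_t0_m1) # ADE(1)
  }
  acme_draws <- (d0 + d1) / 2
  ade_draws <- (z0 + z1) / 2
  total_draws <- acme_draws + ade_draws # == d1 + z0 == d0 + z1 per draw

  pctl <- function(x) unname(stats::quantile(x, c(0.025, 0.975)))
  pval <- function(x) max(2 * min(mean(x > 0), mean(x < 0)), 1 / n_draws)

  acme <- mean(acme_draws)
  ade <- mean(ade_draws)
  total <- mean(total_draws)
  prop <- acme / total
  prop_flag <- sign(acme) != sign(total)
  if (prop_flag) {
    warning("ACME and total effect have opposite signs; proportion mediated reported unclamped")
  }

  total_or <- NA_real_
  if (family == "binomial") {
    Xt <- Xy[, -3, drop = FALSE] # outcome model without the mediator
    tfit <- suppressWarnings(stats::glm.fit(Xt, y_, family = stats::binomial()))
    if (tfit$converged) total_or <- exp(tfit$coefficients[["treat"]])
  }

  structure(
    list(
      treatment = treatment_name, chc = chc, mediator_id = mediator_id,
      acme = acme, acme_ci = pctl(acme_draws), acme_p = pval(acme_draws),
      ade = ade, ade_ci = pctl(ade_draws),
      total = total, total_ci = pctl(total_draws),
      total_or = total_or,
      prop_mediated = prop, pct_mediated = 100 * prop, prop_flag = prop_flag,
      acme_mcse = stats::sd(acme_draws) / sqrt(n_draws),
      ade_mcse = stats::sd(ade_draws) / sqrt(n_draws),
      total_mcse = stats::sd(total_draws) / sqrt(n_draws),
      mediator_coef = coef_m[["treat"]],
      outcome_mediator_coef = coef_y[["med"]],
      outcome_treat_coef = coef_y[["treat"]],
      family = family, n = n, n_draws = n_draws, seed = as.integer(seed)
    ),
    class = "MediationResult"
  )
}

#' @export
print.MediationResult <- function(x, ...) {
  cat(sprintf(
    "Mediation: %s -> %s -> %s (n = %d, %d draws)\n",
    x$treatment, x$mediator_id, x$chc, x$n, x$n_draws
  ))
  cat(sprintf(
    "  ACME  %+ .4f [%+.4f, %+.4f]  p = %.3g\n",
    x$acme, x$acme_ci[1], x$acme_ci[2], x$acme_p
  ))
  cat(sprintf("  ADE   %+ .4f [%+.4f, %+.4f]\n", x$ade, x$ade_ci[1], x$ade_ci[2]))
  cat(sprintf("  Total %+ .4f [%+.4f, %+.4f]", x$total, x$total_ci[1], x$total_ci[2]))
  if (is.finite(x$total_or)) cat(sprintf("  (treatment OR = %.2f)", x$total_or))
  cat(sprintf("\n  Proportion mediated: %.3f (%.1f%%)%s\n",
    x$prop_mediated, x$pct_mediated,
    if (isTRUE(x$prop_flag)) "  [opposite-signed ACME/total]" else ""
  ))
  invisible(x)
}

#' Flatten mediation results to a table
#'
#' @param results a `MediationResult` or list of them.
#' @return data.frame with one row per result (the export layout:
#'   treatment, chc, mediator, acme with CI, ade, total, total_or,
#'   prop/pct mediated, acme_p, n_draws, seed).
#' @export
mediation_table <- function(results) {
  if (inherits(results, "MediationResult")) results <- list(results)
  do.call(rbind, lapply(results, function(r) {
    data.frame(
      treatment = r$treatment, chc = r$chc, mediator = r$mediator_id,
      acme = r$acme, acme_lo = r$acme_ci[1], acme_hi = r$acme_ci[2],
      ade = r$ade, total = r$total, total_or = r$total_or,
      prop_mediated = r$prop_mediated, pct_mediation = r$pct_mediated,
      acme_p = r$acme_p, n_draws = r$n_draws, seed = r$seed,
      stringsAsFactors = FALSE
    )
  }))
}

#' FDR selection of significant mediators
#'
#' BH-FDR across candidate CpGs for one treatment-CHC pair; keeps mediators
#' with adjusted ACME p below `q`.
#'
#' @param results list of `MediationResult`s (one per candidate CpG).
#' @param q FDR level (default 0.05).
#' @return The mediation table restricted to selected mediators, with an
#'   `acme_p_fdr` column, sorted as input.
#' @export
select_mediators <- function(results, q = 0.05) {
  if (!length(results)) stop("empty candidate list")
  tab <- mediation_table(results)
  tab$acme_p_fdr <- bh_fdr(tab$acme_p)
  tab[!is.na(tab$acme_p_fdr) & tab$acme_p_fdr < q, , drop = FALSE]
}

#' Correlation pruning of significant mediators
#'
#' Sorts candidate CpGs by estimated ACME in decreasing order (ties broken by
#' CpG id) and greedily keeps a CpG only if the squared Pearson correlation of
#' its residual M-values with every already-kept CpG is strictly below
#' `r2_threshold`.
#'
#' @param mediators data.frame with `mediator` (CpG id) and `acme` columns
#'   (e.g. from [select_mediators()]).
#' @param resid_m CpG x sample residual M matrix covering the candidates.
#' @param r2_threshold pruning threshold (default 0.05).
#' @return Character vector of retained CpG ids in ACME-descending order.
#' @export
prune_mediators <- function(mediators, resid_m, r2_threshold = 0.05) {
  if (!nrow(mediators)) stop("no mediators to prune")
  ord <- order(-abs(mediators$acme), mediators$mediator)
  ids <- mediators$mediator[ord]
  if (!all(ids %in% rownames(resid_m))) {
    stop("residual M-values missing for some candidate mediators")
  }
  kept <- character(0)
  for (id in ids) {
    ok <- TRUE
    for (k in kept) {
      r2 <- suppressWarnings(stats::cor(resid_m[id, ], resid_m[k, ],
        use = "complete.obs"
      ))^2
      if (!is.na(r2) && r2 >= r2_threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, id)
  }
  kept
}

#' Combined methylation score
#'
#' Per-sample sum of residual M-values over the pruned mediator CpGs; used as
#' a single mediator in the final mediation model. Samples missing a residual
#' at any constituent CpG get `NA` and are excluded downstream.
#'
#' @param cpg_ids constituent CpG ids (>= 1).
#' @param resid_m CpG x sample residual M matrix.
#' @return Numeric per-sample score with a `constituents` attribute.
#' @export
combined_score <- function(cpg_ids, resid_m) {
  if (!length(cpg_ids)) stop("need at least one CpG")
  if (!all(cpg_ids %in% rownames(resid_m))) stop("unknown CpG id in score")
  sub <- resid_m[cpg_ids, , drop = FALSE]
  score <- colSums(sub)
  n_na <- sum(is.na(score))
  if (n_na > 0) message(n_na, " samples lack a complete combined score and are excluded")
  attr(score, "constituents") <- cpg_ids
  score
}

#' Mediation with a combined methylation score
#'
#' Identical to [mediate_single()] with the combined score as the mediator;
#' percent mediation is `100 * prop_mediated`.
#'
#' @inheritParams mediate_single
#' @param score combined score from [combined_score()].
#' @return A `MediationResult` with `mediator_id = "combined"`.
#' @export
mediate_combined <- function(treatment, score, outcome,
                             covariates_mediator = NULL,
                             covariates_outcome = NULL,
                             family = "binomial",
                             n_draws = 1000, seed = 1L, chc = "chc",
                             treatment_name = "treatment") {
  mediate_single(treatment, score, outcome,
    covariates_mediator = covariates_mediator,
    covariates_outcome = covariates_outcome,
    family = family, n_draws = n_draws, seed = seed,
    mediator_id = "combined", chc = chc, treatment_name = treatment_name
  )
}

#' Treatments with a multivariable association with a CHC
#'
#' One-shot multivariable logistic regression of CHC status on all treatments
#' plus age and sex; returns the treatments with Wald p below `alpha`. Used to
#' pick the "other significant treatments" adjusted for in mediation models.
#'
#' @param treatments samples x treatments 0/1 matrix.
#' @param status 0/1 CHC status (NA allowed).
#' @param age,sex per-sample covariates.
#' @param alpha significance level (default 0.05).
#' @return Character vector of treatment names.
#' @export
significant_treatments <- function(treatments, status, age, sex, alpha = 0.05) {
  ok <- !is.na(status)
  X <- cbind(1, treatments[ok, , drop = FALSE], age = age[ok], sex = sex[ok])
  fit <- suppressWarnings(stats::glm.fit(X, status[ok], family = stats::binomial()))
  W <- fit$weights
  vc <- chol2inv(chol(crossprod(X * sqrt(W))))
  se <- sqrt(diag(vc))
  z <- fit$coefficients / se
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  idx <- seq_len(ncol(treatments)) + 1
  colnames(treatments)[p[idx] < alpha]
}
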