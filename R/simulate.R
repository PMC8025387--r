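#' Simulation configuration for a synthetic survivor cohort
#'
#' Bundles and validates everything the cohort generators need: cohort and
#' array size, binary treatment prevalences with target pairwise phi
#' coefficients, per-treatment causal CpGs with M-scale effect sizes,
#' cell-mixture parameters (reference profiles, Dirichlet concentration),
#' M-scale noise, outcome models for chronic health conditions (CHCs),
#' detection-failure rate, and minor allele frequencies for the genotype
#' block. All downstream generators are deterministic given `seed`.
#'
#' @param n_samples number of survivors.
#' @param n_cpgs number of CpG probes.
#' @param treatments data.frame with columns `name` and `prevalence` (each in
#'   (0,1)); one row per binary treatment exposure.
#' @param phi_targets symmetric matrix of target pairwise phi coefficients
#'   (unit diagonal); `NULL` means independent treatments.
#' @param causal_cpgs named list (by treatment) of data.frames with columns
#'   `cpg` (probe index) and `delta` (M-scale shift in exposed samples).
#' @param n_cell_types number of leukocyte subtypes in the mixture.
#' @param reference_profiles optional cell-type x CpG beta matrix; generated
#'   reproducibly from the seed when `NULL`.
#' @param dirichlet_alpha positive concentration vector for the per-sample
#'   cell proportions (length `n_cell_types`). The default mimics whole blood:
#'   neutrophil-dominated with smaller lymphoid fractions.
#' @param noise_sd M-scale standard deviation of per-entry Gaussian noise.
#' @param outcome_models named list (by CHC) of lists with fields `intercept`,
#'   `treatments` (named logit coefficients), `cpgs` (logit coefficients named
#'   by probe index, applied to the mediator's residual M-value), optional
#'   `age`, `sex`, `prs` coefficients, and `prevalent_frac` (fraction of cases
#'   whose onset predates the blood draw).
#' @param detection_fail_rate fraction of matrix entries given a failed
#'   detection p-value (> 0.01).
#' @param maf vector of minor allele frequencies in (0, 0.5], one per SNP.
#' @param ld_blocks optional list of integer vectors (SNP indices); SNPs
#'   within a block are generated with allele-level correlation `ld_r` to the
#'   block's first SNP, for pruning tests.
#' @param ld_r within-block allele copy probability (dosage correlation).
#' @param seed integer master seed; every stage derives its own substream.
#' @return A validated list of class `SimulationConfig`.
#' @export
sim_config <- function(n_samples,
                       n_cpgs,
                       treatments = data.frame(name = "tx1", prevalence = 0.5),
                       phi_targets = NULL,
                       causal_cpgs = list(),
                       n_cell_types = 6,
                       reference_profiles = NULL,
                       dirichlet_alpha = NULL,
                       noise_sd = 0.5,
                       outcome_models = list(),
                       detection_fail_rate = 0,
                       maf = numeric(0),
                       ld_blocks = list(),
                       ld_r = 0.9,
                       seed = 1L) {
  stopifnot(n_samples >= 2, n_cpgs >= 1, n_cell_types >= 1)
  if (any(treatments$prevalence <= 0 | treatments$prevalence >= 1)) {
    stop("all treatment prevalences must be strictly inside (0, 1)")
  }
  k <- nrow(treatments)
  if (is.null(phi_targets)) {
    phi_targets <- diag(1, k)
  }
  phi_targets <- as.matrix(phi_targets)
  if (!isSymmetric(unname(phi_targets)) || any(abs(phi_targets) > 1)) {
    stop("phi_targets must be symmetric with entries in [-1, 1]")
  }
  diag(phi_targets) <- 1
  dimnames(phi_targets) <- list(treatments$name, treatments$name)
  for (nm in names(causal_cpgs)) {
    if (!nm %in% treatments$name) stop("causal_cpgs refers to unknown treatment ", nm)
    if (any(causal_cpgs[[nm]]$cpg < 1 | causal_cpgs[[nm]]$cpg > n_cpgs)) {
      stop("causal CpG index out of range for treatment ", nm)
    }
    if (any(!is.finite(causal_cpgs[[nm]]$delta))) stop("effect sizes must be finite")
  }
  if (is.null(dirichlet_alpha)) {
    base <- c(12, 2, 2, 3, 1.5, 1.5) # neutrophil-dominated whole blood
    dirichlet_alpha <- if (n_cell_types <= 6) base[seq_len(n_cell_types)] else c(base, rep(1.5, n_cell_types - 6))
  }
  stopifnot(length(dirichlet_alpha) == n_cell_types, all(dirichlet_alpha > 0))
  if (!is.null(reference_profiles)) {
    reference_profiles <- as.matrix(reference_profiles)
    if (nrow(reference_profiles) != n_cell_types || ncol(reference_profiles) != n_cpgs) {
      stop(sprintf(
        "reference_profiles must be %d cell types x %d CpGs, got %d x %d",
        n_cell_types, n_cpgs, nrow(reference_profiles), ncol(reference_profiles)
      ))
    }
    if (any(reference_profiles <= 0 | reference_profiles >= 1)) {
      stop("reference profile beta values must be strictly inside (0, 1)")
    }
  }
  for (chc in names(outcome_models)) {
    om <- outcome_models[[chc]]
    if (!is.null(om$treatments) && !all(names(om$treatments) %in% treatments$name)) {
      stop("outcome model for ", chc, " references unknown treatment")
    }
    if (!is.null(om$cpgs)) {
      idx <- as.integer(names(om$cpgs))
      if (any(is.na(idx)) || any(idx < 1 | idx > n_cpgs)) {
        stop("outcome model for ", chc, " has a coefficient on an unknown CpG index")
      }
    }
  }
  if (length(maf) && any(maf <= 0 | maf > 0.5)) stop("maf entries must be in (0, 0.5]")
  stopifnot(detection_fail_rate >= 0, detection_fail_rate <= 1, noise_sd >= 0)
  structure(
    list(
      n_samples = as.integer(n_samples), n_cpgs = as.integer(n_cpgs),
      treatments = treatments, phi_targets = phi_targets,
      causal_cpgs = causal_cpgs, n_cell_types = as.integer(n_cell_types),
      reference_profiles = reference_profiles, dirichlet_alpha = dirichlet_alpha,
      noise_sd = noise_sd, outcome_models = outcome_models,
      detection_fail_rate = detection_fail_rate, maf = maf,
      ld_blocks = ld_blocks, ld_r = ld_r, seed = as.integer(seed)
    ),
    class = "SimulationConfig"
  )
}

# deterministic per-stage substream; keeps derived seeds inside 32-bit range
stage_seed <- function(seed, stage) {
  offs <- c(
    treatments = 1, cells = 2, methylation = 3, outcomes = 4,
    genotypes = 5, covariates = 6, annotation = 7, reference = 8
  )
  as.integer((abs(as.numeric(seed)) * 48271 + 7919 * offs[[stage]]) %% 2147483647)
}

# upper-orthant probability P(Z1 > h1, Z2 > h2) for a standard bivariate
# normal with correlation rho, by one-dimensional quadrature
.orthant_upper <- function(h1, h2, rho) {
  if (abs(rho) >= 1) rho <- sign(rho) * 0.999999
  f <- function(z) stats::dnorm(z) * stats::pnorm((rho * z - h2) / sqrt(1 - rho^2))
  stats::integrate(f, h1, Inf, rel.tol = 1e-10)$value
}

# latent Gaussian correlation reproducing a target phi between two binary
# variables with the given prevalences (tetrachoric-style numerical inversion)
phi_to_latent_rho <- function(phi, p1, p2, pair = c("t1", "t2")) {
  if (phi == 0) return(0)
  p11 <- phi * sqrt(p1 * (1 - p1) * p2 * (1 - p2)) + p1 * p2
  lo <- max(0, p1 + p2 - 1)
  hi <- min(p1, p2)
  if (p11 < lo - 1e-12 || p11 > hi + 1e-12) {
    stop(sprintf(
      "target phi %.3f is not attainable for pair (%s, %s) with prevalences %.3f/%.3f",
      phi, pair[1], pair[2], p1, p2
    ))
  }
  h1 <- stats::qnorm(1 - p1)
  h2 <- stats::qnorm(1 - p2)
  stats::uniroot(
    function(r) .orthant_upper(h1, h2, r) - p11,
    interval = c(-0.99999, 0.99999), tol = 1e-10
  )$root
}

#' Generate correlated binary treatment exposures
#'
#' Binary exposures are produced by thresholding a latent multivariate
#' Gaussian (a Gaussian copula): each target pairwise phi coefficient is
#' converted to a latent correlation by numerically inverting the
#' bivariate-normal orthant probability, so marginal prevalences are exact in
#' expectation and the empirical phi matches its target up to sampling error.
#'
#' @param config a [sim_config()] object.
#' @return Integer 0/1 matrix, samples x treatments, with treatment names as
#'   column names.
#' @export
generate_treatments <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  p <- config$treatments$prevalence
  k <- length(p)
  R <- diag(1, k)
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        R[i, j] <- R[j, i] <- phi_to_latent_rho(
          config$phi_targets[i, j], p[i], p[j],
          pair = config$treatments$name[c(i, j)]
        )
      }
    }
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    off <- abs(R - diag(diag(R)))
    idx <- which(off == max(off), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "latent correlation matrix implied by phi_targets is not positive semidefinite (min eigenvalue %.3g); most extreme pair: (%s, %s)",
      min(ev), config$treatments$name[idx[1]], config$treatments$name[idx[2]]
    ))
  }
  set.seed(stage_seed(config$seed, "treatments"))
  L <- chol(R + diag(1e-10, k))
  Z <- matrix(stats::rnorm(config$n_samples * k), config$n_samples, k) %*% L
  X <- matrix(0L, config$n_samples, k, dimnames = list(NULL, config$treatments$name))
  for (j in seq_len(k)) X[, j] <- as.integer(Z[, j] > stats::qnorm(1 - p[j]))
  X
}

#' Generate per-sample leukocyte proportions
#'
#' Dirichlet draws with the configured concentration vector.
#'
#' @param config a [sim_config()] object.
#' @return samples x cell-type matrix with rows summing to 1.
#' @export
generate_cell_proportions <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(stage_seed(config$seed, "cells"))
  a <- config$dirichlet_alpha
  g <- matrix(stats::rgamma(config$n_samples * length(a), shape = rep(a, each = config$n_samples)),
    config$n_samples, length(a)
  )
  props <- g / rowSums(g)
  colnames(props) <- cell_type_names(length(a))
  props
}

cell_type_names <- function(k) {
  base <- c("neutrophils", "monocytes", "CD8T", "CD4T", "NK", "B")
  if (k <= 6) base[seq_len(k)] else c(base, paste0("cell", seq(7, k)))
}

default_reference_profiles <- function(config) {
  if (!is.null(config$reference_profiles)) {
    ref <- config$reference_profiles
  } else {
    set.seed(stage_seed(config$seed, "reference"))
    # bimodal beta landscape shared across cell types, plus cell-specific
    # shifts at a subset of discriminating CpGs
    base <- stats::rbeta(config$n_cpgs, 0.4, 0.4)
    ref <- matrix(rep(base, each = config$n_cell_types),
      config$n_cell_types, config$n_cpgs
    )
    n_disc <- max(1L, round(0.2 * config$n_cpgs))
    disc <- sample.int(config$n_cpgs, n_disc)
    ref[, disc] <- matrix(stats::rbeta(config$n_cell_types * n_disc, 0.5, 0.5),
      config$n_cell_types, n_disc
    )
    ref <- pmin(pmax(ref, 0.02), 0.98)
  }
  rownames(ref) <- cell_type_names(nrow(ref))
  colnames(ref) <- sprintf("cpg%06d", seq_len(ncol(ref)))
  ref
}

#' Generate cell-mixture methylation with treatment-shifted CpGs
#'
#' The baseline beta value of each (CpG, sample) cell is the cell-proportion
#' weighted mixture of the reference profiles (mixing is linear on the beta
#' scale). Treatment effects are then injected on the M scale — `delta` M
#' units added for exposed samples at each causal CpG — together with
#' Gaussian M-scale noise, and the result is mapped back to beta values,
#' clipped to (0.001, 0.999) to keep M finite. Detection p-values are
#' Uniform(0, 0.01) except for a `detection_fail_rate` fraction of entries
#' drawn above 0.01.
#'
#' @param config a [sim_config()] object.
#' @param treatments samples x treatments 0/1 matrix from
#'   [generate_treatments()].
#' @param cell_props samples x cell-type proportion matrix.
#' @return List with `beta` (CpG x sample), `detp` (CpG x sample),
#'   `m_signal` (CpG x sample M-scale deviation from the cell-mixture
#'   baseline: injected shifts plus noise — the generator-truth residual), and
#'   `reference` (the cell-type x CpG profile matrix used).
#' @export
generate_methylation <- function(config, treatments, cell_props) {
  stopifnot(inherits(config, "SimulationConfig"))
  ref <- default_reference_profiles(config)
  if (ncol(ref) != config$n_cpgs) {
    stop(sprintf(
      "reference has %d CpGs but config$n_cpgs is %d",
      ncol(ref), config$n_cpgs
    ))
  }
  if (ncol(cell_props) != nrow(ref)) stop("cell_props / reference cell-type mismatch")
  set.seed(stage_seed(config$seed, "methylation"))
  n <- config$n_samples
  base_beta <- t(cell_props %*% ref) # CpG x sample
  base_beta <- pmin(pmax(base_beta, 0.001), 0.999)
  m_base <- log2(base_beta / (1 - base_beta))
  signal <- matrix(0, config$n_cpgs, n)
  for (nm in names(config$causal_cpgs)) {
    cc <- config$causal_cpgs[[nm]]
    exposed <- treatments[, nm] == 1L
    for (r in seq_len(nrow(cc))) {
      signal[cc$cpg[r], exposed] <- signal[cc$cpg[r], exposed] + cc$delta[r]
    }
  }
  if (config$noise_sd > 0) {
    signal <- signal + matrix(stats::rnorm(config$n_cpgs * n, sd = config$noise_sd), config$n_cpgs, n)
  }
  m <- m_base + signal
  beta <- 1 / (1 + 2^(-m))
  beta <- pmin(pmax(beta, 0.001), 0.999)
  detp <- matrix(stats::runif(config$n_cpgs * n, 0, 0.01), config$n_cpgs, n)
  if (config$detection_fail_rate > 0) {
    fail <- stats::runif(config$n_cpgs * n) < config$detection_fail_rate
    detp[fail] <- stats::runif(sum(fail), 0.011, 1)
  }
  ids <- colnames(ref)
  snames <- sprintf("s%04d", seq_len(n))
  dimnames(beta) <- dimnames(detp) <- dimnames(signal) <- list(ids, snames)
  list(beta = beta, detp = detp, m_signal = signal, reference = ref)
}

#' Generate binary CHC outcomes, partially mediated by methylation
#'
#' Each chronic health condition (CHC) is drawn from a logistic model whose
#' linear predictor combines treatment exposures, the residual M-values of
#' designated mediator CpGs (the generator's `m_signal`, i.e. the deviation of
#' methylation from its cell-mixture baseline), and optional age/sex/PRS
#' terms. A configurable fraction of cases is flagged as prevalent
#' (onset before the blood draw) to exercise incident filtering.
#'
#' @param config a [sim_config()] object.
#' @param treatments samples x treatments 0/1 matrix.
#' @param m_resid CpG x sample matrix of residual (baseline-free) M-values,
#'   e.g. `generate_methylation()$m_signal`.
#' @param covariates data.frame with columns `age`, `sex` and optionally
#'   `prs_<chc>` columns used by models with a PRS coefficient.
#' @return data.frame with, per CHC, integer columns `<chc>_status` and
#'   `<chc>_prevalent` (prevalent implies status 1).
#' @export
generate_outcomes <- function(config, treatments, m_resid, covariates) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(stage_seed(config$seed, "outcomes"))
  n <- nrow(treatments)
  out <- data.frame(row.names = seq_len(n))
  for (chc in names(config$outcome_models)) {
    om <- config$outcome_models[[chc]]
    eta <- rep(om$intercept %||% 0, n)
    for (nm in names(om$treatments)) eta <- eta + om$treatments[[nm]] * treatments[, nm]
    for (nm in names(om$cpgs)) {
      j <- as.integer(nm)
      if (j < 1 || j > nrow(m_resid)) stop("outcome coefficient on unknown CpG index ", nm)
      eta <- eta + om$cpgs[[nm]] * m_resid[j, ]
    }
    if (!is.null(om$age)) eta <- eta + om$age * (covariates$age - mean(covariates$age))
    if (!is.null(om$sex)) eta <- eta + om$sex * covariates$sex
    if (!is.null(om$prs)) {
      pcol <- paste0("prs_", chc)
      if (!pcol %in% names(covariates)) stop("covariates lack column ", pcol)
      eta <- eta + om$prs * (covariates[[pcol]] - mean(covariates[[pcol]]))
    }
    y <- stats::rbinom(n, 1, stats::plogis(eta))
    prev <- integer(n)
    pf <- om$prevalent_frac %||% 0
    if (pf > 0) {
      cases <- which(y == 1L)
      prev[cases] <- stats::rbinom(length(cases), 1, pf)
    }
    out[[paste0(chc, "_status")]] <- y
    out[[paste0(chc, "_prevalent")]] <- prev
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate SNP dosages
#'
#' Independent Hardy-Weinberg dosages, `Binomial(2, maf)` per SNP, with
#' optional LD blocks in which later SNPs copy each allele of the block's
#' first SNP with probability `ld_r` (giving allele and dosage correlation
#' about `ld_r`), for exercising r-squared pruning.
#'
#' @param config a [sim_config()] object with a nonempty `maf`.
#' @return samples x SNP integer matrix with values in \{0, 1, 2\} and
#'   column names `snp1, snp2, ...`.
#' @export
generate_genotypes <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (!length(config$maf)) stop("config$maf is empty: no SNPs to generate")
  set.seed(stage_seed(config$seed, "genotypes"))
  n <- config$n_samples
  s <- length(config$maf)
  a1 <- matrix(0L, n, s)
  a2 <- matrix(0L, n, s)
  for (j in seq_len(s)) {
    a1[, j] <- stats::rbinom(n, 1, config$maf[j])
    a2[, j] <- stats::rbinom(n, 1, config$maf[j])
  }
  for (blk in config$ld_blocks) {
    anchor <- blk[1]
    for (j in blk[-1]) {
      keep1 <- stats::runif(n) < config$ld_r
      keep2 <- stats::runif(n) < config$ld_r
      a1[keep1, j] <- a1[keep1, anchor]
      a2[keep2, j] <- a2[keep2, anchor]
    }
  }
  g <- a1 + a2
  colnames(g) <- paste0("snp", seq_len(s))
  g
}

#' Generate a CpG annotation table
#'
#' Random but reproducible probe annotations in array-manifest style:
#' chromosome, 1-based position, gene label, CpG-island category and
#' functional genomic region, with marginal category frequencies loosely
#' matching a genome-wide array.
#'
#' @param config a [sim_config()] object.
#' @return data.frame with columns `cpg_id`, `chrom`, `pos`, `gene`,
#'   `island_region`, `functional_region`.
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(stage_seed(config$seed, "annotation"))
  g <- config$n_cpgs
  data.frame(
    cpg_id = sprintf("cpg%06d", seq_len(g)),
    chrom = paste0("chr", sample(1:22, g, replace = TRUE)),
    pos = sample.int(2e8, g, replace = TRUE),
    gene = ifelse(stats::runif(g) < 0.7, paste0("GENE", sample.int(600, g, replace = TRUE)), NA),
    island_region = sample(c("island", "shore", "shelf", "open_sea"), g,
      replace = TRUE, prob = c(0.2, 0.2, 0.1, 0.5)
    ),
    functional_region = sample(
      c("TSS1500", "TSS200", "5'UTR", "1st_exon", "body", "3'UTR", "intergenic"),
      g,
      replace = TRUE, prob = c(0.1, 0.08, 0.08, 0.04, 0.35, 0.05, 0.3)
    ),
    stringsAsFactors = FALSE
  )
}

#' Simulate a full synthetic survivor cohort with ground truth
#'
#' Orchestrates all generators: covariates (age at draw, sex), correlated
#' binary treatments, cell proportions, cell-mixture methylation with
#' treatment-shifted CpGs, genotypes and true polygenic scores, and binary
#' CHC outcomes partially mediated by methylation. The returned ground truth
#' records every quantity a parameter-recovery test needs, including the
#' designed proportion mediated for each (treatment, CpG, CHC) triple
#' computed by the product-of-coefficients rule
#' `a * b / (a * b + c)` (mediator path x outcome coefficient over total).
#'
#' @param config a [sim_config()] object.
#' @return List with `sample_sheet` (covariates, treatments, per-CHC status /
#'   prevalent flags, true PRS columns), `beta`, `detp` (CpG x sample),
#'   `genotypes`, `annotation`, `cell_props`, `reference`, and `ground_truth`
#'   (causal CpG sets, mediation triples with designed proportions, true cell
#'   proportions, true residual M-values, PRS).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(stage_seed(config$seed, "covariates"))
  n <- config$n_samples
  age <- round(18 + stats::rgamma(n, shape = 3, scale = 5.5), 1)
  sex <- stats::rbinom(n, 1, 0.5)
  tx <- generate_treatments(config)
  cp <- generate_cell_proportions(config)
  meth <- generate_methylation(config, tx, cp)
  geno <- if (length(config$maf)) generate_genotypes(config) else NULL
  prs <- if (!is.null(geno)) rowSums(geno) else rep(0, n)

  covars <- data.frame(age = age, sex = sex)
  for (chc in names(config$outcome_models)) covars[[paste0("prs_", chc)]] <- prs
  outcomes <- if (length(config$outcome_models)) {
    generate_outcomes(config, tx, meth$m_signal, covars)
  } else {
    data.frame(row.names = seq_len(n))
  }

  triples <- list()
  for (chc in names(config$outcome_models)) {
    om <- config$outcome_models[[chc]]
    for (nm in names(om$cpgs)) {
      j <- as.integer(nm)
      for (txn in names(om$treatments)) {
        cc <- config$causal_cpgs[[txn]]
        a <- if (!is.null(cc) && j %in% cc$cpg) cc$delta[match(j, cc$cpg)] else 0
        b <- om$cpgs[[nm]]
        cdir <- om$treatments[[txn]]
        denom <- a * b + cdir
        pm <- if (abs(denom) > 1e-12) a * b / denom else NA_real_
        if (!is.na(pm) && (pm < -2 || pm > 2)) {
          warning(sprintf(
            "designed proportion mediated %.2f outside [-2, 2] for (%s, cpg %d, %s)",
            pm, txn, j, chc
          ))
        }
        triples[[length(triples) + 1]] <- data.frame(
          treatment = txn, cpg = j, chc = chc,
          a = a, b = b, direct = cdir, prop_mediated = pm
        )
      }
    }
  }
  triples <- if (length(triples)) do.call(rbind, triples) else NULL

  sheet <- data.frame(
    sample_id = sprintf("s%04d", seq_len(n)),
    age = age, sex = sex, tx, check.names = FALSE
  )
  for (chc in names(config$outcome_models)) sheet[[paste0("prs_", chc)]] <- prs
  sheet <- cbind(sheet, outcomes)
  if (!is.null(geno)) rownames(geno) <- sheet$sample_id
  rownames(cp) <- sheet$sample_id

  list(
    sample_sheet = sheet,
    beta = meth$beta,
    detp = meth$detp,
    genotypes = geno,
    annotation = generate_annotation(config),
    cell_props = cp,
    reference = meth$reference,
    ground_truth = list(
      causal_cpg_sets = config$causal_cpgs,
      mediation_triples = triples,
      cell_props = cp,
      m_resid = meth$m_signal,
      prs = prs,
      config_seed = config$seed
    )
  )
}

#' Configure a cohort with a designed proportion mediated
#'
#' Convenience constructor for mediation parameter-recovery studies: a single
#' binary treatment (prevalence 0.5), one mediator CpG with M-scale shift
#' `delta`, and a logistic outcome whose mediated and direct logit effects are
#' split so that the product-of-coefficients proportion mediated equals
#' `prop`: mediator outcome coefficient `b = prop * total_logit / delta`,
#' direct coefficient `c = (1 - prop) * total_logit`. The intercept centers
#' the linear predictor so baseline prevalence is near one half.
#'
#' @param prop designed proportion mediated, in (0, 1).
#' @param n_samples cohort size.
#' @param seed master seed.
#' @param delta treatment effect on the mediator, M units.
#' @param total_logit total treatment effect on the outcome logit scale.
#' @param noise_sd M-scale noise standard deviation of the mediator.
#' @param n_cpgs number of CpGs simulated (the mediator is CpG 1).
#' @return A `SimulationConfig`.
#' @export
mediation_design_config <- function(prop, n_samples = 2000, seed = 1L,
                                    delta = 0.5, total_logit = 0.8,
                                    noise_sd = 0.5, n_cpgs = 5) {
  b <- prop * total_logit / delta
  cdir <- (1 - prop) * total_logit
  sim_config(
    n_samples = n_samples, n_cpgs = n_cpgs,
    treatments = data.frame(name = "tx1", prevalence = 0.5),
    causal_cpgs = list(tx1 = data.frame(cpg = 1L, delta = delta)),
    n_cell_types = 1, dirichlet_alpha = 1,
    noise_sd = noise_sd,
    outcome_models = list(chc1 = list(
      intercept = -(cdir + b * delta) / 2,
      treatments = c(tx1 = cdir),
      cpgs = stats::setNames(list(b), "1")
    )),
    seed = seed
  )
}
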