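#' Pipeline configuration
#'
#' Collects every threshold of the analysis workflow with its conventional
#' default: detection-p mask (0.01), missingness fraction (0.05),
#' epigenome-wide alpha (9e-8), phi exclusion rule (phi > 0.4 with p < 0.05),
#' SNP pruning r-squared (0.3), mediator pruning r-squared (0.05), FDR level
#' (0.05), number of mediation draws and the master seed. Unknown keys are
#' rejected so typos cannot silently change an analysis, and a config
#' round-trips losslessly through YAML.
#'
#' @param ... overrides of the defaults listed above.
#' @return A validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    detection_p = 0.01, missing_frac = 0.05, ewas_alpha = 9e-8,
    phi_cut = 0.4, phi_p = 0.05, snp_r2 = 0.3, mediator_r2 = 0.05,
    fdr_q = 0.05, n_draws = 1000, seed = 1L,
    k_meth_pcs = 4L, n_genetic_pcs = 3L, drop_cell_type = "neutrophils"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  stopifnot(
    cfg$detection_p > 0, cfg$detection_p < 1,
    cfg$missing_frac >= 0, cfg$missing_frac < 1,
    cfg$ewas_alpha > 0, cfg$ewas_alpha <= 1,
    cfg$phi_cut >= 0, cfg$phi_cut <= 1, cfg$phi_p > 0, cfg$phi_p <= 1,
    cfg$snp_r2 > 0, cfg$snp_r2 <= 1, cfg$mediator_r2 > 0, cfg$mediator_r2 <= 1,
    cfg$fdr_q > 0, cfg$fdr_q <= 1, cfg$n_draws >= 100
  )
  structure(cfg, class = "PipelineConfig")
}

#' Read / write a pipeline config as YAML
#' @param cfg a `PipelineConfig`.
#' @param path file path.
#' @return `read_pipeline_config()` returns a `PipelineConfig`.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full treatment -> methylation -> CHC workflow
#'
#' Executes the whole analysis on a synthetic cohort: simulation, QC and
#' normalization, M-value transform, leukocyte deconvolution, methylation
#' PCA, phi-based adjustment-set selection, per-treatment EWAS with genomic
#' control, significance calling, residualization, incident-filtered logistic
#' CHC association with polygenic-score adjustment, and quasi-Bayesian
#' mediation with FDR mediator selection, correlation pruning and a combined
#' methylation score. Any stage failure halts with a stage-tagged error.
#'
#' @param sim a `SimulationConfig` describing the cohort.
#' @param cfg a `PipelineConfig` (thresholds, draws, seed).
#' @return List with `ewas` (per-treatment records), `hits`, `lambda` (per
#'   treatment), `chc_assoc`, `mediation` (per-CpG results, selected and
#'   pruned mediators, combined-score result per treatment-CHC pair),
#'   `incidence`, `cohort` and a `manifest` of stage counts, seeds and the
#'   config hash.
#' @export
run_pipeline <- function(sim, cfg = pipeline_config()) {
  stopifnot(inherits(sim, "SimulationConfig"), inherits(cfg, "PipelineConfig"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  cohort <- stage("simulate", simulate_cohort(sim))
  sheet <- cohort$sample_sheet
  tx_names <- sim$treatments$name

  qc <- stage("qc", apply_qc_filters(cohort$beta, cohort$detp,
    detection_p = cfg$detection_p, missing_frac = cfg$missing_frac
  ))
  keep_samples <- match(qc$matrix$sample_ids, sheet$sample_id)
  sheet <- sheet[keep_samples, , drop = FALSE]
  mm_beta <- stage("normalize", quantile_normalize(qc$matrix))
  mm_m <- stage("transform", {
    v <- mm_beta$values
    v[!mm_beta$mask] <- pmin(pmax(v[!mm_beta$mask], 0.001), 0.999)
    beta_to_m(meth_matrix(v, scale = "beta", mask = mm_beta$mask))
  })

  cells <- stage("deconvolution", {
    cp <- estimate_cell_proportions(mm_beta, cohort$reference)
    cp[, -match(cfg$drop_cell_type, colnames(cp)), drop = FALSE]
  })
  pca <- stage("pca", methylation_pca(mm_m, k_max = 10, k_default = cfg$k_meth_pcs))
  meth_pcs <- pca$scores[, seq_len(min(cfg$k_meth_pcs, ncol(pca$scores))), drop = FALSE]
  colnames(meth_pcs) <- paste0("methPC", seq_len(ncol(meth_pcs)))

  tx <- as.matrix(sheet[, tx_names, drop = FALSE])
  phi <- stage("phi", phi_matrix(tx))
  base_cov <- data.frame(age = sheet$age, sex = sheet$sex, cells, meth_pcs,
    check.names = FALSE
  )

  ewas <- list()
  lambda <- numeric(0)
  hits <- list()
  for (txn in tx_names) {
    adj <- select_adjustment_set(phi, txn, phi_cut = cfg$phi_cut, p_cut = cfg$phi_p)
    cov_tx <- if (length(adj)) cbind(base_cov, tx[, adj, drop = FALSE]) else base_cov
    rec <- stage(
      paste0("ewas:", txn),
      run_ewas(mm_m, tx[, txn], cov_tx, treatment = txn)
    )
    rec <- stage(paste0("gc:", txn), genomic_control_adjust(rec))
    lambda[txn] <- attr(rec, "lambda")
    ewas[[txn]] <- rec
    hits[[txn]] <- call_significant(rec, threshold = cfg$ewas_alpha)
  }
  all_hits <- unique(unlist(lapply(hits, function(h) h$cpg_id)))

  resid <- stage("residuals", compute_residuals(mm_m, base_cov))

  prs <- if (!is.null(cohort$genotypes)) {
    geno <- cohort$genotypes[keep_samples, , drop = FALSE]
    retained <- stage("prs", prune_snps(colnames(geno), geno, r2_threshold = cfg$snp_r2))
    compute_prs(retained, geno)
  } else {
    rep(0, nrow(sheet))
  }

  chcs <- sub("_status$", "", grep("_status$", names(sheet), value = TRUE))
  incidence <- if (length(chcs)) stage("incidence", incidence_summary(sheet, chcs)) else NULL

  chc_assoc <- list()
  mediation <- list()
  for (chc in chcs) {
    fi <- stage(paste0("incident:", chc), filter_incident(sheet, chc))
    if (fi$n_cases < 10 || fi$n_controls < 10 || !length(all_hits)) next
    cov_chc <- data.frame(age = sheet$age, sex = sheet$sex, prs = prs)
    assoc <- stage(
      paste0("associate:", chc),
      associate_chc(resid[all_hits, , drop = FALSE], fi$status, cov_chc, chc = chc)
    )
    chc_assoc[[chc]] <- assoc
    sig_cpgs <- assoc$cpg_id[!is.na(assoc$p_fdr) & assoc$p_fdr < cfg$fdr_q]
    if (!length(sig_cpgs)) next
    sig_tx <- stage(
      paste0("sigtx:", chc),
      significant_treatments(tx, fi$status, sheet$age, sheet$sex)
    )
    for (txn in tx_names) {
      cand <- intersect(sig_cpgs, hits[[txn]]$cpg_id)
      if (!length(cand)) next
      others <- setdiff(sig_tx, txn)
      others <- intersect(others, select_adjustment_set(phi, txn,
        phi_cut = cfg$phi_cut, p_cut = cfg$phi_p
      ))
      cov_med <- if (length(others)) tx[, others, drop = FALSE] else NULL
      cov_out <- data.frame(age = sheet$age, sex = sheet$sex, prs = prs)
      if (length(others)) cov_out <- cbind(cov_out, tx[, others, drop = FALSE])
      res_list <- lapply(cand, function(cpg) {
        stage(
          paste0("mediate:", txn, ":", chc, ":", cpg),
          mediate_single(tx[, txn], resid[cpg, ], fi$status,
            covariates_mediator = cov_med, covariates_outcome = cov_out,
            n_draws = cfg$n_draws,
            seed = stage_seed(cfg$seed, "outcomes") + match(cpg, cand),
            mediator_id = cpg, chc = chc, treatment_name = txn
          )
        )
      })
      sel <- select_mediators(res_list, q = cfg$fdr_q)
      pruned <- if (nrow(sel)) prune_mediators(sel, resid, r2_threshold = cfg$mediator_r2) else character(0)
      comb <- NULL
      if (length(pruned)) {
        sc <- combined_score(pruned, resid)
        comb <- stage(
          paste0("mediate_combined:", txn, ":", chc),
          mediate_combined(tx[, txn], sc, fi$status,
            covariates_mediator = cov_med, covariates_outcome = cov_out,
            n_draws = cfg$n_draws, seed = stage_seed(cfg$seed, "outcomes"),
            chc = chc, treatment_name = txn
          )
        )
      }
      mediation[[paste(txn, chc, sep = ":")]] <- list(
        candidates = mediation_table(res_list),
        selected = sel, pruned = pruned, combined = comb
      )
    }
  }

  manifest <- list(
    config_hash = rlang::hash(list(unclass(cfg), unclass(sim))),
    seed = cfg$seed,
    n_samples = nrow(sheet),
    n_probes = nrow(mm_m$values),
    qc = qc$report[c("n_masked", "n_samples_removed", "n_probes_removed")],
    lambda = lambda,
    n_hits = vapply(hits, nrow, integer(1)),
    n_distinct_hits = length(all_hits),
    n_mediation_candidates = sum(vapply(
      mediation,
      function(m) nrow(m$candidates), integer(1)
    )),
    n_selected_mediators = sum(vapply(mediation, function(m) nrow(m$selected), integer(1))),
    n_pruned_mediators = sum(vapply(
      mediation,
      function(m) length(m$pruned), integer(1)
    ))
  )
  list(
    ewas = ewas, hits = hits, lambda = lambda, chc_assoc = chc_assoc,
    mediation = mediation, incidence = incidence, cohort = cohort,
    sample_sheet = sheet, manifest = manifest
  )
}

#' Export EWAS hits as BED
#'
#' Writes hit CpGs as a 0-based half-open BED file (the annotation table's
#' positions are 1-based, manifest convention).
#'
#' @param hits `ewas_result` rows to export.
#' @param annotation data.frame with `cpg_id`, `chrom`, `pos` (1-based).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, annotation, path) {
  idx <- match(hits$cpg_id, annotation$cpg_id)
  if (anyNA(idx)) stop("hits missing from the annotation table")
  bed <- data.frame(
    chrom = annotation$chrom[idx],
    start = annotation$pos[idx] - 1L,
    end = annotation$pos[idx],
    name = hits$cpg_id
  )
  utils::write.table(bed, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
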