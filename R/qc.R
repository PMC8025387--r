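#' Detection-p masking and missingness filters
#'
#' Standard post-array quality control for a beta matrix: any entry whose
#' detection p-value exceeds `detection_p` is set missing; then samples with
#' more than `missing_frac` missing entries are removed; then probes with more
#' than `missing_frac` missing entries (among the remaining samples) are
#' removed. Samples are filtered before probes so that a single failed sample
#' does not take otherwise good probes down with it.
#'
#' @param beta numeric CpG x sample matrix of beta values, or a
#'   `MethylationMatrix` on the beta scale.
#' @param detp numeric matrix of detection p-values, congruent with `beta`.
#' @param detection_p mask threshold; entries with detection p strictly above
#'   it are treated as missing. Default 0.01.
#' @param missing_frac maximum tolerated fraction missing per sample and per
#'   probe (strictly more is removed). Default 0.05.
#' @return A list with `matrix` (filtered `MethylationMatrix`, remaining
#'   missing entries masked) and `report` (removed sample/probe ids, counts,
#'   and the number of masked entries).
#' @export
apply_qc_filters <- function(beta, detp, detection_p = 0.01, missing_frac = 0.05) {
  vals <- as_meth_values(beta)
  if (!identical(dim(vals), dim(detp))) {
    stop("beta and detection-p matrices must have the same shape")
  }
  mm <- if (inherits(beta, "MethylationMatrix")) beta else meth_matrix(vals, scale = "beta")
  mask <- mm$mask | detp > detection_p
  n_masked <- sum(mask & !mm$mask)

  sample_missing <- colMeans(mask)
  drop_samples <- sample_missing > missing_frac
  mask2 <- mask[, !drop_samples, drop = FALSE]
  if (ncol(mask2) == 0) stop("all samples removed by the missingness filter")
  probe_missing <- rowMeans(mask2)
  drop_probes <- probe_missing > missing_frac

  vals_out <- mm$values[!drop_probes, !drop_samples, drop = FALSE]
  mask_out <- mask2[!drop_probes, , drop = FALSE]
  vals_out[mask_out] <- NA_real_
  list(
    matrix = meth_matrix(vals_out, scale = mm$scale, mask = mask_out),
    report = list(
      n_masked = n_masked,
      removed_samples = mm$sample_ids[drop_samples],
      removed_probes = mm$cpg_ids[drop_probes],
      n_samples_removed = sum(drop_samples),
      n_probes_removed = sum(drop_probes),
      detection_p = detection_p,
      missing_frac = missing_frac
    )
  )
}

#' Quantile normalization across samples
#'
#' Forces every sample (column) to share the same marginal distribution: each
#' sample's sorted values are replaced by the mean of the sorted values across
#' samples, preserving within-sample ranks. Ties receive the mean of the tied
#' quantiles, and masked entries stay masked; with unequal per-sample
#' missingness the target distribution is interpolated at each sample's own
#' quantiles. Delegates to [limma::normalizeQuantiles()].
#'
#' @param x `MethylationMatrix` or plain CpG x sample matrix; at least two
#'   samples, each with at least two unmasked values.
#' @return Same type as the input, normalized.
#' @export
quantile_normalize <- function(x) {
  vals <- as_meth_values(x)
  if (ncol(vals) < 2) stop("quantile normalization needs at least 2 samples")
  if (inherits(x, "MethylationMatrix")) vals[x$mask] <- NA_real_
  if (any(colSums(!is.na(vals)) < 2)) {
    stop("every sample needs at least 2 unmasked values")
  }
  norm <- limma::normalizeQuantiles(vals, ties = TRUE)
  dimnames(norm) <- dimnames(vals)
  if (inherits(x, "MethylationMatrix")) {
    if (x$scale == "beta") norm <- pmin(pmax(norm, 0), 1)
    meth_matrix(norm, scale = x$scale, mask = x$mask)
  } else {
    norm
  }
}
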