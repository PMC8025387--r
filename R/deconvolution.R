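#' Reference-based leukocyte deconvolution
#'
#' Estimates the proportions of leukocyte subtypes in each whole-blood sample
#' from methylation at discriminating CpGs, in the constrained-projection
#' tradition: each sample's beta profile is regressed on the reference
#' cell-type profiles under a nonnegativity constraint (via
#' [pracma::lsqnonneg()]) and the coefficients are renormalized to sum to one.
#' In the noise-free limit this is identical to the quadratic-programming
#' formulation with an equality constraint.
#'
#' @param x `MethylationMatrix` on the beta scale (or plain beta matrix,
#'   CpGs x samples).
#' @param reference cell-type x CpG matrix of reference beta profiles; column
#'   names are CpG ids and must overlap the rows of `x`. Row names are the
#'   cell-type labels (canonically neutrophils, monocytes, CD8T, CD4T, NK, B).
#' @return A sample x cell-type matrix of proportions (rows sum to 1), with a
#'   `residual_norm` attribute giving each sample's least-squares residual
#'   norm over the discriminating CpGs.
#' @export
estimate_cell_proportions <- function(x, reference) {
  vals <- as_meth_values(x)
  if (inherits(x, "MethylationMatrix") && x$scale != "beta") {
    stop("deconvolution expects beta-scale methylation")
  }
  if (!is.matrix(reference) || nrow(reference) < 2) {
    stop("reference must be a cell-type x CpG matrix with at least 2 cell types")
  }
  if (is.null(colnames(reference)) || is.null(rownames(vals))) {
    if (ncol(reference) != nrow(vals)) stop("no CpG ids and dimensions disagree")
    shared <- seq_len(nrow(vals))
    ref_use <- reference
  } else {
    shared <- intersect(colnames(reference), rownames(vals))
    if (length(shared) == 0) stop("no overlapping CpGs between matrix and reference")
    ref_use <- reference[, shared, drop = FALSE]
  }
  A <- t(ref_use) # CpG x cell-type design
  n <- ncol(vals)
  out <- matrix(NA_real_, n, nrow(reference),
    dimnames = list(colnames(vals), rownames(reference))
  )
  rnorm_ <- numeric(n)
  for (i in seq_len(n)) {
    b <- vals[shared, i]
    ok <- !is.na(b)
    fit <- pracma::lsqnonneg(A[ok, , drop = FALSE], b[ok])
    w <- fit$x
    if (sum(w) <= 0) stop("degenerate deconvolution fit for sample ", colnames(vals)[i])
    out[i, ] <- w / sum(w)
    rnorm_[i] <- sqrt(sum(fit$resid.norm))
  }
  attr(out, "residual_norm") <- rnorm_
  out
}

#' Principal components of methylation
#'
#' Centered PCA of samples over all CpGs (no scaling), used to capture latent
#' structure and batch effects. Masked entries are mean-imputed per CpG before
#' decomposition. The number of components to carry forward is chosen as the
#' point of the largest relative drop between consecutive eigenvalues within
#' the first `k_max`; when that rule is flat (all drops equal within 1e-8) the
#' fallback `k_default` is used.
#'
#' @param x `MethylationMatrix` on the M scale, or plain CpG x sample matrix.
#' @param k_max maximum number of components considered by the drop rule.
#' @param k_default fallback number of components (default 4).
#' @return List with `scores` (sample x component), `eigenvalues`
#'   (nonincreasing variances), `k` (chosen number of components) and
#'   `n_imputed` (count of mean-imputed cells).
#' @export
methylation_pca <- function(x, k_max = 10, k_default = 4) {
  vals <- as_meth_values(x)
  if (ncol(vals) < 2) stop("PCA needs at least 2 samples")
  n_imputed <- 0L
  if (anyNA(vals)) {
    for (j in which(rowSums(is.na(vals)) > 0)) {
      miss <- is.na(vals[j, ])
      vals[j, miss] <- mean(vals[j, !miss])
      n_imputed <- n_imputed + sum(miss)
    }
  }
  X <- t(vals) # samples x CpGs
  X <- sweep(X, 2, colMeans(X))
  sv <- svd(X, nu = min(dim(X)), nv = 0)
  ev <- sv$d^2 / (nrow(X) - 1)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  rownames(scores) <- colnames(vals)
  colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  k_max <- min(k_max, length(ev) - 1)
  k <- k_default
  if (k_max >= 1) {
    drops <- (ev[seq_len(k_max)] - ev[seq_len(k_max) + 1]) / ev[seq_len(k_max)]
    drops[!is.finite(drops)] <- 0
    if (diff(range(drops)) > 1e-8) k <- which.max(drops)
  }
  k <- min(max(k, 1L), ncol(scores))
  list(scores = scores, eigenvalues = ev, k = k, n_imputed = n_imputed)
}
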