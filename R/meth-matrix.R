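#' Methylation matrix container
#'
#' A light container for a CpG x sample methylation matrix together with a
#' missingness mask and a scale tag. Beta values are fractions methylated in
#' \[0, 1\]; M-values are their base-2 logits and live on the whole real line.
#' The mask is `TRUE` where a measurement is missing (e.g. failed detection p);
#' masked cells of `values` are stored as `NA`.
#'
#' @param values numeric matrix, CpGs as rows, samples as columns. Row and
#'   column names are used as CpG and sample identifiers and must be unique.
#' @param scale `"beta"` or `"M"`.
#' @param mask logical matrix of the same shape, `TRUE` = missing. Defaults to
#'   `is.na(values)`.
#' @return An object of class `MethylationMatrix`: a list with elements
#'   `values`, `mask`, `scale`, `cpg_ids`, `sample_ids`.
#' @export
meth_matrix <- function(values, scale = c("beta", "M"), mask = NULL) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (CpGs x samples)")
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("cpg%06d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("s%04d", seq_len(ncol(values)))
  }
  if (anyDuplicated(rownames(values))) stop("duplicate CpG ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (is.null(mask)) mask <- is.na(values)
  if (!identical(dim(mask), dim(values))) stop("mask shape must match values")
  mask <- mask | is.na(values)
  values[mask] <- NA_real_
  if (scale == "beta") {
    bad <- which(!mask & (values < 0 | values > 1), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop(sprintf(
        "beta values outside [0, 1], first offender at row %s, column %s",
        rownames(values)[bad[1, 1]], colnames(values)[bad[1, 2]]
      ))
    }
  }
  structure(
    list(
      values = values, mask = mask, scale = scale,
      cpg_ids = rownames(values), sample_ids = colnames(values)
    ),
    class = "MethylationMatrix"
  )
}

#' @export
print.MethylationMatrix <- function(x, ...) {
  cat(sprintf(
    "MethylationMatrix: %d CpGs x %d samples (%s scale), %d masked entries\n",
    nrow(x$values), ncol(x$values), x$scale, sum(x$mask)
  ))
  invisible(x)
}

#' @export
dim.MethylationMatrix <- function(x) dim(x$values)

as_meth_values <- function(x) {
  if (inherits(x, "MethylationMatrix")) x$values else x
}

#' Convert beta values to M-values and back
#'
#' The M-value is the base-2 logit of the beta value,
#' `M = log2(beta / (1 - beta))`; it is the usual regression scale for
#' methylation because its variance is more homoscedastic across the \[0, 1\]
#' range than beta's. `m_to_beta()` is the exact inverse.
#'
#' @param beta numeric vector/matrix of beta values strictly inside (0, 1),
#'   or a `MethylationMatrix` on the beta scale.
#' @return Same shape as the input, on the other scale. A
#'   `MethylationMatrix` input returns a `MethylationMatrix` with the scale
#'   tag flipped.
#' @export
beta_to_m <- function(beta) {
  if (inherits(beta, "MethylationMatrix")) {
    if (beta$scale != "beta") stop("input is already on the M scale")
    v <- beta$values
    v[!beta$mask] <- beta_to_m(v[!beta$mask])
    return(meth_matrix(v, scale = "M", mask = beta$mask))
  }
  x <- beta[!is.na(beta)]
  if (any(x <= 0 | x >= 1)) {
    stop("beta values must be strictly inside (0, 1); clip upstream (e.g. to [0.001, 0.999]) before transforming")
  }
  log2(beta / (1 - beta))
}

#' @param m numeric vector/matrix of M-values, or a `MethylationMatrix` on the
#'   M scale.
#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  if (inherits(m, "MethylationMatrix")) {
    if (m$scale != "M") stop("input is already on the beta scale")
    v <- m$values
    v[!m$mask] <- m_to_beta(v[!m$mask])
    return(meth_matrix(v, scale = "beta", mask = m$mask))
  }
  1 / (1 + 2^(-m))
}

#' Read / write a methylation matrix as TSV
#'
#' Plain-text interchange format: a comment line `# scale=beta|M`, then a
#' header of sample ids, then one row per CpG (id in the first column).
#' Missing entries are written as `NA` and round-trip into the mask.
#'
#' @param path file path.
#' @param x a `MethylationMatrix`.
#' @return `read_meth_matrix()` returns a `MethylationMatrix`;
#'   `write_meth_matrix()` returns `path` invisibly.
#' @export
write_meth_matrix <- function(x, path) {
  stopifnot(inherits(x, "MethylationMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# scale=%s", x$scale), con)
  df <- data.frame(cpg_id = x$cpg_ids, x$values, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_meth_matrix
#' @export
read_meth_matrix <- function(path) {
  first <- readLines(path, n = 1)
  scale <- "beta"
  skip <- 0
  if (startsWith(first, "#")) {
    skip <- 1
    m <- regmatches(first, regexec("scale=(beta|M)", first))[[1]]
    if (length(m) == 2) scale <- m[2]
  }
  df <- utils::read.table(path,
    header = TRUE, sep = "\t", skip = skip,
    check.names = FALSE
  )
  if (anyDuplicated(df[[1]])) stop("duplicate CpG ids in ", path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))) &
      !is.na(as.matrix(df[, -1, drop = FALSE])), arr.ind = TRUE)
    stop(sprintf(
      "non-numeric cell at row %d, column %d of %s",
      bad[1, 1], bad[1, 2] + 1, path
    ))
  }
  rownames(vals) <- df[[1]]
  meth_matrix(vals, scale = scale)
}
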