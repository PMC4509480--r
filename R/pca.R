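#' Standardize a genotype matrix for PCA
#'
#' Patterson-style standardization: each SNP column is centered at its mean
#' genotype and divided by `sqrt(p(1-p))` with the shrunk frequency estimate
#' `p = (1 + count_b) / (2 + 2 n_genotyped)`; missing entries are imputed to
#' the column mean (0 after centering). SNPs constant across genotyped
#' samples carry no information and are dropped with a warning.
#'
#' @param ds a post-QC `genotype_dataset`.
#' @return numeric matrix (samples x retained SNPs) with attributes
#'   `snp_means`, `snp_scales`, and `kept` (logical over input SNPs).
#' @export
standardize_genotypes <- function(ds) {
  g <- ds$genotypes
  if (length(g) == 0) stop("empty dataset")
  n <- colSums(!is.na(g))
  cb <- colSums(g, na.rm = TRUE)
  means <- cb / n
  p_hat <- (1 + cb) / (2 + 2 * n)
  scales <- sqrt(p_hat * (1 - p_hat))
  constant <- n == 0 | vapply(seq_len(ncol(g)), function(j) {
    col <- g[, j]
    col <- col[!is.na(col)]
    length(col) == 0 || all(col == col[1])
  }, logical(1))
  if (any(constant)) {
    warning(sum(constant), " constant SNP(s) dropped before PCA")
  }
  keep <- !constant
  x <- sweep(g[, keep, drop = FALSE], 2, means[keep], "-")
  x[is.na(x)] <- 0
  x <- sweep(x, 2, scales[keep], "/")
  attr(x, "snp_means") <- means[keep]
  attr(x, "snp_scales") <- scales[keep]
  attr(x, "kept") <- keep
  x
}

#' Principal component analysis of genotypes
#'
#' Eigendecomposition of the sample-by-sample covariance of the standardized
#' genotype matrix. Scores are the top-k eigenvectors (PC1 first); each PC's
#' sign is fixed so that its largest-magnitude entry is positive, making
#' results reproducible (the sign of an eigenvector is otherwise arbitrary).
#'
#' @param ds a `genotype_dataset`.
#' @param k number of components, at most `min(samples - 1, SNPs)`.
#' @return a `pca_result`: list with `scores` (samples x k, rownames = sample
#'   IDs), `eigenvalues` (all, descending), `variance_explained` (first k,
#'   as fractions of the total), `snp_means`, `snp_scales`.
#' @export
compute_pca <- function(ds, k = 10) {
  x <- standardize_genotypes(ds)
  n <- nrow(x)
  if (k > min(n - 1, ncol(x))) {
    stop("k must be <= min(samples - 1, SNPs) = ", min(n - 1, ncol(x)))
  }
  cv <- tcrossprod(x) / ncol(x)
  eig <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (vecs[which.max(abs(vecs[, j])), j] < 0) vecs[, j] <- -vecs[, j]
  }
  rownames(vecs) <- ds$samples
  colnames(vecs) <- paste0("PC", seq_len(k))
  structure(list(scores = vecs,
                 eigenvalues = vals,
                 variance_explained = vals[seq_len(k)] / sum(vals),
                 snp_means = attr(x, "snp_means"),
                 snp_scales = attr(x, "snp_scales")),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- ncol(x$scores)
  cat("pca_result:", nrow(x$scores), "samples,", k, "components\n")
  cat("  variance explained:",
      paste(sprintf("%.3f", x$variance_explained), collapse = " "), "\n")
  invisible(x)
}

#' Iterative PCA outlier detection
#'
#' Flags samples whose score exceeds `n_sigma` standard deviations on any of
#' the top `k` PCs, removing them and refitting up to `n_iter` times.
#' Disabled by default (`n_iter = 0`): outlier exclusion is an analyst
#' choice, and the default rule (6 SD, smartPCA-like) is a documented
#' stand-in.
#'
#' @param ds a `genotype_dataset`.
#' @param k number of PCs scanned.
#' @param n_sigma flagging threshold in standard deviations.
#' @param n_iter maximum refit iterations (0 disables detection).
#' @return character vector of flagged sample IDs (empty when disabled).
#' @export
detect_outliers <- function(ds, k = 10, n_sigma = 6, n_iter = 0) {
  stopifnot(n_sigma > 0)
  flagged <- character(0)
  current <- ds
  iter <- 0
  while (iter < n_iter) {
    iter <- iter + 1
    kk <- min(k, n_samples(current) - 1, n_variants(current))
    if (kk < 1) break
    pc <- compute_pca(current, kk)
    z <- scale(pc$scores)
    hit <- rownames(pc$scores)[apply(abs(z) > n_sigma, 1, any)]
    if (length(hit) == 0) break
    flagged <- c(flagged, hit)
    current <- subset_dataset(current, samples = setdiff(current$samples, hit))
  }
  flagged
}

#' Group means and standard errors of a principal component
#'
#' @param pca a `pca_result`.
#' @param metadata data frame with `sample_id` and the grouping column.
#' @param pc component index (default 1).
#' @param by grouping column name (default `"state"`).
#' @return data frame with `group`, `n`, `mean`, `se` (SE is `NA` for
#'   singleton groups).
#' @export
average_pc_by_group <- function(pca, metadata, pc = 1, by = "state") {
  idx <- match(rownames(pca$scores), metadata$sample_id)
  if (anyNA(idx)) {
    stop("metadata missing for sample(s): ",
         paste(utils::head(rownames(pca$scores)[is.na(idx)], 5), collapse = ", "))
  }
  grp <- metadata[[by]][idx]
  score <- pca$scores[, pc]
  groups <- unique(grp)
  out <- data.frame(group = groups,
                    n = vapply(groups, function(g) sum(grp == g), integer(1)),
                    mean = vapply(groups, function(g) mean(score[grp == g]),
                                  numeric(1)),
                    stringsAsFactors = FALSE)
  out$se <- ifelse(out$n > 1,
                   vapply(groups, function(g) stats::sd(score[grp == g]),
                          numeric(1)) / sqrt(out$n),
                   NA_real_)
  out
}
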