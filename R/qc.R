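#' Quality-control parameters
#'
#' Thresholds are strict in the stated direction: samples/SNPs with missing
#' fraction strictly above the cap are removed, SNPs with MAF strictly below
#' the floor or exact Hardy-Weinberg p strictly below the cut are removed,
#' and SNP pairs with genotype r-squared strictly above the ceiling are
#' pruned.
#'
#' @param max_sample_missing per-sample missing-fraction cap (default 0.10).
#' @param max_snp_missing per-SNP missing-fraction cap (default 0.10).
#' @param min_maf minor-allele-frequency floor (default 0.05).
#' @param hwe_p_min exact Hardy-Weinberg p-value cut (default 0.002).
#' @param ld_r2_max genotype r-squared ceiling for pruning (default 0.8).
#' @param ld_window,ld_step sliding-window size and step in SNPs (defaults
#'   50 and 5, the de facto convention).
#' @return a `qc_params` list.
#' @export
qc_params <- function(max_sample_missing = 0.10, max_snp_missing = 0.10,
                      min_maf = 0.05, hwe_p_min = 0.002,
                      ld_r2_max = 0.8, ld_window = 50, ld_step = 5) {
  stopifnot(max_sample_missing >= 0, max_sample_missing <= 1,
            max_snp_missing >= 0, max_snp_missing <= 1,
            min_maf >= 0, min_maf <= 0.5,
            hwe_p_min >= 0, hwe_p_min <= 1,
            ld_r2_max >= 0, ld_r2_max <= 1,
            ld_window >= ld_step, ld_step >= 1)
  structure(list(max_sample_missing = max_sample_missing,
                 max_snp_missing = max_snp_missing, min_maf = min_maf,
                 hwe_p_min = hwe_p_min, ld_r2_max = ld_r2_max,
                 ld_window = as.integer(ld_window),
                 ld_step = as.integer(ld_step)),
            class = "qc_params")
}

#' Remove samples with excess missingness
#'
#' @param ds a `genotype_dataset`.
#' @param threshold samples with missing fraction strictly greater than this
#'   are removed.
#' @return list with `dataset` and `removed` (sample IDs).
#' @export
filter_sample_missingness <- function(ds, threshold = 0.10) {
  stopifnot(threshold >= 0, threshold <= 1)
  frac <- rowMeans(is.na(ds$genotypes))
  drop <- frac > threshold
  list(dataset = subset_dataset(ds, samples = !drop),
       removed = ds$samples[drop])
}

#' Remove SNPs with excess missingness
#'
#' @inheritParams filter_sample_missingness
#' @return list with `dataset` and `removed` (snp_ids).
#' @export
filter_snp_missingness <- function(ds, threshold = 0.10) {
  stopifnot(threshold >= 0, threshold <= 1)
  frac <- colMeans(is.na(ds$genotypes))
  drop <- frac > threshold
  list(dataset = subset_dataset(ds, snps = !drop),
       removed = ds$variants$snp_id[drop])
}

#' Remove SNPs below a minor-allele-frequency floor
#'
#' MAF is `min(p, 1-p)` of the allele_b frequency over non-missing genotypes;
#' SNPs with MAF strictly below `min_maf` (including monomorphic SNPs and
#' SNPs with no genotyped samples) are removed.
#'
#' @param ds a `genotype_dataset`.
#' @param min_maf frequency floor in `[0, 0.5]`.
#' @return list with `dataset` and `removed` (snp_ids).
#' @export
filter_maf <- function(ds, min_maf = 0.05) {
  stopifnot(min_maf >= 0, min_maf <= 0.5)
  p <- allele_freqs(ds)
  maf <- pmin(p, 1 - p)
  drop <- is.nan(maf) | maf < min_maf
  list(dataset = subset_dataset(ds, snps = !drop),
       removed = ds$variants$snp_id[drop])
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test: conditioning on the allele counts, heterozygote
#' counts follow the standard conditional (hypergeometric-type) distribution;
#' the p-value sums the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed table.
#' Computed with the stable ratio recurrence over heterozygote counts; no
#' mid-p correction.
#'
#' @param n_aa,n_ab,n_bb genotype counts (major homozygote, heterozygote,
#'   minor homozygote; the test is symmetric in the homozygote labels).
#' @return the exact p-value in `[0, 1]`; defined as 1 when no individuals
#'   are genotyped.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_b <- 2 * n_bb + n_ab          # rare-or-not allele count of "b"
  rare <- min(n_b, 2 * n - n_b)
  if (rare == 0) return(1)
  # heterozygote counts share the parity of the rare allele count
  het_vals <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(het_vals))
  # start from the largest admissible het count and recurse downwards:
  # P(h-2)/P(h) = h (h-1) / (4 (hom_rare+1) (hom_common+1))
  m <- length(het_vals)
  probs[m] <- 1
  if (m >= 2) {
    for (i in m:2) {
      h <- het_vals[i]
      hom_rare <- (rare - h) / 2
      hom_common <- n - h - hom_rare
      probs[i - 1] <- probs[i] * h * (h - 1) /
        (4 * (hom_rare + 1) * (hom_common + 1))
    }
  }
  probs <- probs / sum(probs)
  if (n_ab > rare || (n_ab %% 2) != (rare %% 2)) {
    stop("heterozygote count incompatible with allele counts")
  }
  p_obs <- probs[match(n_ab, het_vals)]
  p <- sum(probs[probs <= p_obs * (1 + 1e-12)])
  min(p, 1)
}

#' Remove SNPs departing from Hardy-Weinberg equilibrium
#'
#' The exact test is computed per SNP on all samples pooled; SNPs with
#' p strictly below `p_min` are removed.
#'
#' @param ds a `genotype_dataset`.
#' @param p_min exact-test p-value cut.
#' @return list with `dataset`, `removed` (snp_ids), and `p_values`.
#' @export
filter_hwe <- function(ds, p_min = 0.002) {
  g <- ds$genotypes
  n_bb <- colSums(g == 2L, na.rm = TRUE)
  n_ab <- colSums(g == 1L, na.rm = TRUE)
  n_aa <- colSums(g == 0L, na.rm = TRUE)
  p <- vapply(seq_len(ncol(g)), function(j) hwe_exact_p(n_aa[j], n_ab[j], n_bb[j]),
              numeric(1))
  drop <- p < p_min
  list(dataset = subset_dataset(ds, snps = !drop),
       removed = ds$variants$snp_id[drop],
       p_values = stats::setNames(p, ds$variants$snp_id))
}

#' Genotype r-squared between two SNPs
#'
#' Squared Pearson correlation of genotype codes over pairwise-complete
#' samples. Undefined when fewer than two complete pairs remain or either
#' SNP is constant on the complete subset; such pairs return `NA` (treated
#' as 0 by [ld_prune()]).
#'
#' @param x,y genotype code vectors of equal length.
#' @return r-squared in `[0, 1]`, or `NA`.
#' @export
ld_r2 <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Prune SNPs in high linkage disequilibrium
#'
#' Sliding window of `ld_window` SNPs advancing by `ld_step` over variants
#' ordered by (chrom, pos). Within each window, while any surviving pair has
#' r-squared strictly above `ld_r2_max`, the pair with the largest r-squared
#' is resolved by removing its lower-MAF member (ties: the later position).
#' The procedure is deterministic.
#'
#' @param ds a `genotype_dataset` with variants ordered by (chrom, pos).
#' @param params a [qc_params()] (fields `ld_r2_max`, `ld_window`, `ld_step`).
#' @return list with `dataset` and `removed` (snp_ids).
#' @export
ld_prune <- function(ds, params = qc_params()) {
  L <- n_variants(ds)
  if (L < 2) return(list(dataset = ds, removed = character(0)))
  p <- allele_freqs(ds)
  maf <- pmin(p, 1 - p)
  keep <- rep(TRUE, L)
  win <- params$ld_window
  step <- params$ld_step
  starts <- seq(1L, max(1L, L - 1L), by = step)
  chrom <- ds$variants$chrom
  for (s in starts) {
    idx <- s:min(s + win - 1L, L)
    idx <- idx[keep[idx]]
    idx <- idx[chrom[idx] == chrom[idx[1]]]  # windows do not straddle chromosomes
    if (length(idx) < 2) next
    repeat {
      sub <- ds$genotypes[, idx, drop = FALSE]
      r2 <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs")^2)
      r2[!is.finite(r2)] <- 0
      diag(r2) <- 0
      if (max(r2) <= params$ld_r2_max) break
      hit <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
      i1 <- idx[hit[1]]; i2 <- idx[hit[2]]
      # remove the lower-MAF member; ties broken towards the later position
      victim <- if (maf[i1] < maf[i2]) i1
        else if (maf[i2] < maf[i1]) i2
        else max(i1, i2)
      keep[victim] <- FALSE
      idx <- idx[idx != victim]
      if (length(idx) < 2) break
    }
  }
  list(dataset = subset_dataset(ds, snps = keep),
       removed = ds$variants$snp_id[!keep])
}

#' Run the full QC chain
#'
#' Stages in order: sample missingness, SNP missingness, MAF, exact
#' Hardy-Weinberg, LD pruning. Each stage's removals are recorded; the chain
#' is deterministic and idempotent.
#'
#' @param ds a `genotype_dataset`.
#' @param params a [qc_params()].
#' @param ld whether to run the LD-pruning stage (it is skipped when merging
#'   of platform datasets is still pending).
#' @return list with `dataset` and `report` (a data frame with one row per
#'   stage: removals and retained dimensions, in application order).
#' @export
run_qc <- function(ds, params = qc_params(), ld = TRUE) {
  stages <- list()
  log_stage <- function(name, removed_samples, removed_snps, d) {
    stages[[length(stages) + 1]] <<- data.frame(
      stage = name, removed_samples = removed_samples,
      removed_snps = removed_snps, retained_samples = n_samples(d),
      retained_snps = n_variants(d), stringsAsFactors = FALSE)
  }
  st <- filter_sample_missingness(ds, params$max_sample_missing)
  log_stage("sample_missingness", length(st$removed), 0L, st$dataset)
  st2 <- filter_snp_missingness(st$dataset, params$max_snp_missing)
  log_stage("snp_missingness", 0L, length(st2$removed), st2$dataset)
  st3 <- filter_maf(st2$dataset, params$min_maf)
  log_stage("maf", 0L, length(st3$removed), st3$dataset)
  st4 <- filter_hwe(st3$dataset, params$hwe_p_min)
  log_stage("hwe", 0L, length(st4$removed), st4$dataset)
  out <- st4$dataset
  if (ld) {
    st5 <- ld_prune(out, params)
    log_stage("ld_prune", 0L, length(st5$removed), st5$dataset)
    out <- st5$dataset
  }
  list(dataset = out, report = do.call(rbind, stages))
}
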