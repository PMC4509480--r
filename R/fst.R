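#' Weir-Cockerham F_ST variance components for one SNP, two populations
#'
#' Decomposes allele-frequency variance into a (between populations),
#' b (between individuals within populations) and c (within individuals),
#' yielding the per-SNP estimate `theta = a / (a + b + c)`. With r = 2
#' populations of n_i genotyped individuals, allele_b frequencies
#' p_i and heterozygote frequencies h_i:
#' \deqn{\bar n = \sum n_i / r,\quad
#'       n_c = (r \bar n - \sum n_i^2 / (r\bar n)) / (r - 1)}
#' \deqn{\bar p = \sum n_i p_i / (r\bar n),\quad
#'       s^2 = \sum n_i (p_i - \bar p)^2 / ((r-1)\bar n),\quad
#'       \bar h = \sum n_i h_i / (r\bar n)}
#' \deqn{a = \frac{\bar n}{n_c}\Big[s^2 - \frac{1}{\bar n - 1}
#'       \big(\bar p(1-\bar p) - \tfrac{r-1}{r}s^2 - \tfrac{\bar h}{4}\big)\Big]}
#' \deqn{b = \frac{\bar n}{\bar n - 1}\Big[\bar p(1-\bar p)
#'       - \tfrac{r-1}{r}s^2 - \tfrac{2\bar n - 1}{4\bar n}\bar h\Big],\qquad
#'       c = \bar h / 2}
#' The estimator is unbiased near zero and may legitimately go negative;
#' values are reported unclipped. `theta` is `NA` when the denominator is
#' not positive (e.g. both populations fixed for the same allele).
#'
#' @param counts1,counts2 `allele_counts` for the two populations (see
#'   [allele_counts()], [allele_counts_from_freq()]); both need
#'   `n_genotyped >= 2`.
#' @return an `fst_components` list: `a`, `b`, `c`, `theta`, `nbar`, `nc`,
#'   `s2`, `hbar`, `pbar`.
#' @export
per_snp_fst <- function(counts1, counts2) {
  stopifnot(inherits(counts1, "allele_counts"), inherits(counts2, "allele_counts"))
  n <- c(counts1$n_genotyped, counts2$n_genotyped)
  if (any(n < 2)) stop("both populations need n_genotyped >= 2")
  p <- c(counts1$count_b, counts2$count_b) / (2 * n)
  h <- c(counts1$count_het, counts2$count_het) / n
  comp <- wc_components(n1 = n[1], n2 = n[2], p1 = p[1], p2 = p[2],
                        h1 = h[1], h2 = h[2])
  structure(lapply(comp, as.numeric), class = "fst_components")
}

# vectorized Weir-Cockerham components over SNPs (r = 2 populations)
wc_components <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                        (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  denom <- a + b + cc
  theta <- ifelse(is.finite(denom) & denom > 0, a / denom, NA_real_)
  # fully degenerate sites: both populations monomorphic for the same allele
  degenerate <- pbar * (1 - pbar) == 0 & s2 == 0 & hbar == 0
  a <- ifelse(degenerate, 0, a)
  b <- ifelse(degenerate, 0, b)
  cc <- ifelse(degenerate, 0, cc)
  list(a = a, b = b, c = cc, theta = theta, nbar = nbar, nc = nc,
       s2 = s2, hbar = hbar, pbar = pbar)
}

#' Per-SNP F_ST table between two sample groups
#'
#' Vectorized Weir-Cockerham components across all SNPs, with per-SNP sample
#' sizes recomputed from non-missing genotypes and heterozygosity taken from
#' the observed heterozygote counts.
#'
#' @param ds a `genotype_dataset`.
#' @param group1,group2 sample ID vectors (or indexes) for the two groups.
#' @return data frame with one row per SNP: `snp_id`, `chrom`, `pos`, `n1`,
#'   `n2`, `p1`, `p2`, `a`, `b`, `c`, `theta`.
#' @export
snp_fst_table <- function(ds, group1, group2) {
  g1 <- ds$genotypes[resolve_index(group1, ds$samples, "sample"), , drop = FALSE]
  g2 <- ds$genotypes[resolve_index(group2, ds$samples, "sample"), , drop = FALSE]
  n1 <- colSums(!is.na(g1)); n2 <- colSums(!is.na(g2))
  p1 <- colSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- colSums(g1 == 1L, na.rm = TRUE) / n1
  h2 <- colSums(g2 == 1L, na.rm = TRUE) / n2
  comp <- wc_components(n1, n2, p1, p2, h1, h2)
  usable <- n1 >= 2 & n2 >= 2
  out <- data.frame(snp_id = ds$variants$snp_id, chrom = ds$variants$chrom,
                    pos = ds$variants$pos, n1 = n1, n2 = n2,
                    p1 = p1, p2 = p2,
                    a = comp$a, b = comp$b, c = comp$c, theta = comp$theta,
                    stringsAsFactors = FALSE)
  out$a[!usable] <- NA_real_
  out$b[!usable] <- NA_real_
  out$c[!usable] <- NA_real_
  out$theta[!usable] <- NA_real_
  out
}

#' Genome-wide F_ST between two groups (ratio of sums)
#'
#' The genome-wide estimate combines per-SNP variance components as
#' `sum(a) / sum(a + b + c)` over SNPs with defined components — the
#' standard low-bias combination, rather than averaging per-SNP ratios.
#'
#' @inheritParams snp_fst_table
#' @param table optionally, a precomputed [snp_fst_table()].
#' @return a `genomewide_fst` object with `point`, `n_snps_used` (bootstrap
#'   fields empty; see [bootstrap_fst()]).
#' @export
genomewide_fst <- function(ds, group1, group2, table = NULL) {
  tab <- if (is.null(table)) snp_fst_table(ds, group1, group2) else table
  ok <- is.finite(tab$a) & is.finite(tab$b) & is.finite(tab$c)
  if (!any(ok)) stop("no usable SNPs for genome-wide F_ST")
  a <- tab$a[ok]
  d <- tab$a[ok] + tab$b[ok] + tab$c[ok]
  structure(list(point = sum(a) / sum(d), ci_lower = NA_real_,
                 ci_upper = NA_real_, boot_se = NA_real_, n_boot = 0L,
                 n_snps_used = sum(ok)),
            class = "genomewide_fst")
}

#' @export
print.genomewide_fst <- function(x, ...) {
  cat(sprintf("genome-wide F_ST = %.6g (%d SNPs)\n", x$point, x$n_snps_used))
  if (x$n_boot > 0) {
    cat(sprintf("  95%% bootstrap CI [%.6g, %.6g], boot SE %.3g (%d replicates)\n",
                x$ci_lower, x$ci_upper, x$boot_se, x$n_boot))
  }
  invisible(x)
}

#' Genome-wide F_ST with SNP-bootstrap confidence interval
#'
#' The resampling unit is the SNP: each replicate draws `L` SNPs with
#' replacement and recomputes the ratio of sums; the CI is the 2.5/97.5
#' percentile of the replicates and `boot_se` their standard deviation.
#' Resampling SNPs (not individuals) treats the sampled individuals as fixed
#' and quantifies genomic sampling variation; an individual-level bootstrap
#' is available via `unit = "individual"`.
#'
#' @inheritParams snp_fst_table
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed for the resampling stream.
#' @param conf confidence level (default 0.95).
#' @param unit `"snp"` (default) or `"individual"`.
#' @param return_replicates keep the replicate estimates (for diagnostics).
#' @return a `genomewide_fst` object.
#' @export
bootstrap_fst <- function(ds, group1, group2, n_boot = 1000, seed = 1,
                          conf = 0.95, unit = c("snp", "individual"),
                          return_replicates = FALSE) {
  stopifnot(n_boot >= 1)
  unit <- match.arg(unit)
  tab <- snp_fst_table(ds, group1, group2)
  base <- genomewide_fst(ds, group1, group2, table = tab)
  set.seed(seed)
  if (unit == "snp") {
    ok <- is.finite(tab$a) & is.finite(tab$b) & is.finite(tab$c)
    a <- tab$a[ok]
    d <- tab$a[ok] + tab$b[ok] + tab$c[ok]
    L <- length(a)
    reps <- numeric(n_boot)
    # chunked so index matrices stay small at genome-wide L
    chunk <- max(1L, floor(2e7 / L))
    done <- 0L
    while (done < n_boot) {
      m <- min(chunk, n_boot - done)
      idx <- matrix(sample.int(L, L * m, replace = TRUE), m, L)
      num <- matrix(a[idx], m, L)
      den <- matrix(d[idx], m, L)
      reps[done + seq_len(m)] <- rowSums(num) / rowSums(den)
      done <- done + m
    }
  } else {
    i1 <- resolve_index(group1, ds$samples, "sample")
    i2 <- resolve_index(group2, ds$samples, "sample")
    reps <- vapply(seq_len(n_boot), function(b) {
      r1 <- sample(i1, length(i1), replace = TRUE)
      r2 <- sample(i2, length(i2), replace = TRUE)
      # resampled individuals get fresh IDs so grouping stays well-defined
      sub <- genotype_dataset(ds$genotypes[c(r1, r2), , drop = FALSE],
                              sprintf("b%05d", seq_along(c(r1, r2))),
                              ds$variants)
      genomewide_fst(sub, seq_along(r1), length(r1) + seq_along(r2))$point
    }, numeric(1))
  }
  alpha <- (1 - conf) / 2
  ci <- stats::quantile(reps, c(alpha, 1 - alpha), names = FALSE)
  out <- structure(list(point = base$point, ci_lower = ci[1], ci_upper = ci[2],
                        boot_se = stats::sd(reps), n_boot = as.integer(n_boot),
                        n_snps_used = base$n_snps_used),
                   class = "genomewide_fst")
  if (return_replicates) out$replicates <- reps
  out
}

#' Pairwise genome-wide F_ST between all groups
#'
#' @param ds a `genotype_dataset`.
#' @param grouping character vector of group labels aligned with
#'   `ds$samples` (or a named vector keyed by sample ID).
#' @param n_boot bootstrap replicates per pair (0 for point estimates only).
#' @param seed integer seed.
#' @return list with `point` (symmetric matrix, `NA` diagonal) and, when
#'   `n_boot > 0`, `boot` (list of `genomewide_fst` keyed "A|B").
#' @export
pairwise_fst_matrix <- function(ds, grouping, n_boot = 0, seed = 1) {
  if (!is.null(names(grouping))) {
    grouping <- grouping[ds$samples]
  }
  stopifnot(length(grouping) == n_samples(ds))
  groups <- unique(grouping)
  if (length(groups) < 2) stop("need at least two groups")
  m <- matrix(NA_real_, length(groups), length(groups),
              dimnames = list(groups, groups))
  boot <- list()
  pair_i <- 0L
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (j <= i) next
      pair_i <- pair_i + 1L
      g1 <- ds$samples[grouping == groups[i]]
      g2 <- ds$samples[grouping == groups[j]]
      if (n_boot > 0) {
        fit <- bootstrap_fst(ds, g1, g2, n_boot = n_boot,
                             seed = derive_seed(seed, pair_i))
        boot[[paste(groups[i], groups[j], sep = "|")]] <- fit
      } else {
        fit <- genomewide_fst(ds, g1, g2)
      }
      m[i, j] <- m[j, i] <- fit$point
    }
  }
  out <- list(point = m)
  if (n_boot > 0) out$boot <- boot
  out
}

#' Most differentiated SNPs
#'
#' Two modes: `top_fraction` returns the SNPs in the top fraction of the
#' theta distribution, including every SNP tied with the boundary value;
#' `abs_threshold` returns all SNPs with theta strictly greater than the
#' threshold. Both return rows ranked by descending theta.
#'
#' @param table data frame with at least `snp_id` and `theta` (e.g. from
#'   [snp_fst_table()]).
#' @param top_fraction fraction of SNPs to keep (default 0.01); ignored when
#'   `abs_threshold` is given.
#' @param abs_threshold absolute theta cutoff (strict), or `NULL`.
#' @return the selected rows of `table`, ranked by descending theta.
#' @export
top_differentiated <- function(table, top_fraction = 0.01, abs_threshold = NULL) {
  stopifnot(nrow(table) > 0)
  tab <- table[is.finite(table$theta), , drop = FALSE]
  tab <- tab[order(-tab$theta), , drop = FALSE]
  if (!is.null(abs_threshold)) {
    return(tab[tab$theta > abs_threshold, , drop = FALSE])
  }
  n_top <- max(1L, ceiling(top_fraction * nrow(tab)))
  boundary <- tab$theta[n_top]
  tab[tab$theta >= boundary, , drop = FALSE]
}

#' SNPs whose minor allele differs between two groups
#'
#' For each SNP the within-group minor allele is `allele_b` when its
#' frequency is below 0.5, `allele_a` when above, and resolved to `allele_b`
#' at an exact 0.5 tie. SNPs lacking genotyped samples in either group are
#' skipped.
#'
#' @inheritParams snp_fst_table
#' @return list with `count` and `snp_ids`.
#' @export
minor_allele_discordance <- function(ds, group1, group2) {
  g1 <- ds$genotypes[resolve_index(group1, ds$samples, "sample"), , drop = FALSE]
  g2 <- ds$genotypes[resolve_index(group2, ds$samples, "sample"), , drop = FALSE]
  n1 <- colSums(!is.na(g1)); n2 <- colSums(!is.na(g2))
  p1 <- colSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(g2, na.rm = TRUE) / (2 * n2)
  minor1 <- ifelse(p1 <= 0.5, "b", "a")
  minor2 <- ifelse(p2 <= 0.5, "b", "a")
  ok <- n1 > 0 & n2 > 0
  disc <- ok & minor1 != minor2
  list(count = sum(disc), snp_ids = ds$variants$snp_id[disc])
}
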