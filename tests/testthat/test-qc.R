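test_that("sample-missingness filter is strict at the threshold", {
  g <- matrix(0L, 3, 100)
  g[1, 1:11] <- NA  # 11% missing -> removed at 0.10
  g[2, 1:10] <- NA  # exactly 10% -> retained
  res <- filter_sample_missingness(make_ds(g), 0.10)
  expect_equal(res$removed, "ind001")
  expect_equal(n_samples(res$dataset), 2)
})

test_that("missingness filters match a brute-force scan on random data", {
  for (seed in 1:4) {
    ds <- random_ds(20, 60, seed = seed, miss = 0.12)
    rs <- filter_sample_missingness(ds, 0.10)
    expect_setequal(rs$removed,
                    ds$samples[rowMeans(is.na(ds$genotypes)) > 0.10])
    rc <- filter_snp_missingness(ds, 0.10)
    expect_setequal(rc$removed,
                    ds$variants$snp_id[colMeans(is.na(ds$genotypes)) > 0.10])
  }
})

test_that("all-missing SNPs are removed, complete SNPs retained", {
  g <- matrix(1L, 4, 3)
  g[, 2] <- NA
  res <- filter_snp_missingness(make_ds(g), 0.5)
  expect_equal(res$removed, "s002")
})

test_that("MAF filter is strict below the floor and drops monomorphic SNPs", {
  # 10 individuals: col1 MAF 0.05 (retained), col2 MAF 0 (removed),
  # col3 MAF 0.049 scaled via 1000 individuals below
  g <- cbind(c(1L, rep(0L, 9)), rep(0L, 10), c(2L, rep(0L, 9)))
  res <- filter_maf(make_ds(g), 0.05)
  expect_equal(sort(res$removed), c("s002"))
  g2 <- matrix(0L, 1000, 1)
  g2[1:98] <- 1L  # MAF 0.049
  expect_equal(filter_maf(make_ds(g2), 0.05)$removed, "s001")
  g2[99:100] <- 1L  # MAF 0.050 exactly -> retained
  expect_length(filter_maf(make_ds(g2), 0.05)$removed, 0)
  for (seed in 1:3) {
    ds <- random_ds(30, 40, seed = seed, miss = 0.05)
    p <- allele_freqs(ds)
    expect_setequal(filter_maf(ds, 0.2)$removed,
                    ds$variants$snp_id[pmin(p, 1 - p) < 0.2])
  }
})

test_that("exact Hardy-Weinberg p matches enumeration and is symmetric", {
  expect_equal(hwe_exact_p(5, 0, 0), 1)
  expect_equal(hwe_exact_p(0, 0, 7), 1)
  expect_equal(hwe_exact_p(0, 0, 0), 1)
  # n = 10 with 10/10 alleles: full enumeration over het in {0,2,...,10}
  expect_equal(hwe_exact_p(0, 10, 0), hwe_enum_p(0, 10, 0), tolerance = 1e-12)
  # exhaustive for all genotype triples up to n = 25
  for (n in c(5, 12, 25)) {
    for (n_ab in 0:n) {
      for (n_bb in 0:(n - n_ab)) {
        n_aa <- n - n_ab - n_bb
        expect_lt(abs(hwe_exact_p(n_aa, n_ab, n_bb) -
                        hwe_enum_p(n_aa, n_ab, n_bb)), 1e-12)
        expect_equal(hwe_exact_p(n_aa, n_ab, n_bb),
                     hwe_exact_p(n_bb, n_ab, n_aa))
      }
    }
  }
  # random larger tables
  set.seed(1)
  for (i in 1:200) {
    cnt <- as.vector(rmultinom(1, sample(10:200, 1), runif(3)))
    p <- hwe_exact_p(cnt[1], cnt[2], cnt[3])
    expect_lt(abs(p - hwe_enum_p(cnt[1], cnt[2], cnt[3])), 1e-12)
    expect_gte(p, 0); expect_lte(p, 1)
  }
})

test_that("HWE filter removes extreme-heterozygote SNPs and keeps boundary ones", {
  g <- cbind(rep(1L, 30),                      # all het: strong departure
             rep(c(0L, 1L, 2L), 10))           # perfect HWE-ish
  res <- filter_hwe(make_ds(g), 0.002)
  expect_equal(res$removed, "s001")
  expect_lt(res$p_values[["s001"]], 0.002)
  # strictness: a SNP exactly at p_min survives
  p2 <- res$p_values[["s002"]]
  res2 <- filter_hwe(make_ds(g[, 2, drop = FALSE]), p_min = p2)
  expect_length(res2$removed, 0)
  # oracle re-scan on random data
  for (seed in 1:3) {
    ds <- random_ds(40, 30, seed = seed, miss = 0.05)
    res_r <- filter_hwe(ds, 0.05)
    brute <- vapply(seq_len(30), function(j) {
      col <- ds$genotypes[, j]
      hwe_enum_p(sum(col == 0, na.rm = TRUE), sum(col == 1, na.rm = TRUE),
                 sum(col == 2, na.rm = TRUE))
    }, numeric(1))
    expect_setequal(res_r$removed, ds$variants$snp_id[brute < 0.05])
  }
})

test_that("genotype r-squared matches the correlation formula", {
  expect_equal(ld_r2(c(0, 1, 2, 0), c(0, 1, 2, 0)), 1)
  expect_equal(ld_r2(c(0, 1, 2, 0), c(2, 1, 0, 2)), 1)  # perfect negative
  expect_true(is.na(ld_r2(c(1, 1, 1), c(0, 1, 2))))
  set.seed(2)
  for (i in 1:10) {
    x <- sample(0:2, 30, replace = TRUE)
    y <- sample(0:2, 30, replace = TRUE)
    x[sample(30, 3)] <- NA
    expect_equal(ld_r2(x, y),
                 cor(x, y, use = "pairwise.complete.obs")^2)
  }
})

test_that("LD pruning removes one of each duplicate pair and spares independents", {
  set.seed(3)
  base <- matrix(rbinom(20 * 10, 2, 0.5), 20, 10)
  dup <- cbind(base[, 1:5], base[, 1], base[, 6:10])  # col 6 duplicates col 1
  res <- ld_prune(make_ds(dup), qc_params(ld_window = 11, ld_step = 11))
  expect_length(res$removed, 1)
  expect_true(res$removed %in% c("s001", "s006"))

  indep <- random_ds(200, 20, seed = 4)
  r2max <- max(cor(indep$genotypes)[upper.tri(diag(20))]^2)
  res2 <- ld_prune(indep, qc_params(ld_r2_max = max(0.8, r2max + 0.01)))
  expect_length(res2$removed, 0)
})

test_that("LD pruning matches an exhaustive greedy oracle on a planted toy", {
  set.seed(5)
  g <- matrix(rbinom(50 * 50, 2, runif(50, 0.2, 0.8)[rep(1:50, each = 50)]),
              50, 50)
  for (j in c(10, 25, 40)) g[, j] <- g[, j - 1]  # planted duplicates
  ds <- make_ds(g)
  params <- qc_params(ld_window = 50, ld_step = 50)
  res <- ld_prune(ds, params)

  # oracle: independent greedy loop over the single full window
  keep <- rep(TRUE, 50)
  maf <- pmin(allele_freqs(ds), 1 - allele_freqs(ds))
  repeat {
    idx <- which(keep)
    r2 <- cor(g[, idx])^2; diag(r2) <- 0; r2[!is.finite(r2)] <- 0
    if (max(r2) <= 0.8) break
    hit <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
    i1 <- idx[hit[1]]; i2 <- idx[hit[2]]
    victim <- if (maf[i1] < maf[i2]) i1 else if (maf[i2] < maf[i1]) i2 else max(i1, i2)
    keep[victim] <- FALSE
  }
  expect_equal(res$dataset$variants$snp_id, ds$variants$snp_id[keep])
})

test_that("the QC chain reports per-stage accounting and is idempotent", {
  clean <- random_ds(20, 40, seed = 6)
  res <- run_qc(clean, qc_params())
  expect_true(all(res$report$removed_samples == 0))
  # constructed violations: one per rule
  set.seed(7)
  g <- matrix(rbinom(40 * 30, 2, 0.5), 40, 30)
  g[1, 1:20] <- NA                       # sample > 10% missing (20/30)
  g[-1, 2] <- NA                         # SNP missing in all remaining samples
  g[-1, 3] <- 0L; g[2, 3] <- 1L          # MAF 1/78 < 0.05
  g[-1, 4] <- 1L                         # all-het after sample removal
  g[, 6] <- g[, 5]                       # duplicate pair for LD pruning
  ds <- make_ds(g)
  res2 <- run_qc(ds, qc_params())
  expect_equal(res2$report$removed_samples, c(1, 0, 0, 0, 0))
  expect_equal(res2$report$removed_snps[2:5], c(1, 1, 1, 1))
  expect_equal(res2$report$retained_samples[5], 39)
  expect_equal(res2$report$retained_snps[5], 26)
  # idempotence
  res3 <- run_qc(res2$dataset, qc_params())
  expect_equal(sum(res3$report$removed_samples) + sum(res3$report$removed_snps), 0)
  expect_identical(res3$dataset$genotypes, res2$dataset$genotypes)
})
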