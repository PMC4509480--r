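test_that("variance-components theta reproduces the published worked examples", {
  # regional totals n = 146 (north), 107 (south); southern frequency is the
  # complement of its printed minor allele frequency so both groups are
  # oriented to a common allele; heterozygosity at its HWE expectation
  north <- allele_counts_from_freq(0.4856, 146)
  south <- allele_counts_from_freq(1 - 0.1682, 107)
  expect_equal(per_snp_fst(north, south)$theta, 0.2256, tolerance = 0.005 / 0.2256)

  north2 <- allele_counts_from_freq(0.4757, 146)
  south2 <- allele_counts_from_freq(1 - 0.1934, 107)
  expect_equal(per_snp_fst(north2, south2)$theta, 0.2037, tolerance = 0.005 / 0.2037)
})

test_that("fixed difference with no heterozygotes gives theta = 1", {
  c1 <- allele_counts_raw(50, 100, 0)  # fixed for allele_b
  c2 <- allele_counts_raw(50, 0, 0)    # fixed for allele_a
  res <- per_snp_fst(c1, c2)
  expect_equal(res$theta, 1)
})

test_that("components are invariant under simultaneous allele relabeling", {
  set.seed(31)
  for (i in 1:10) {
    n1 <- sample(10:100, 1); n2 <- sample(10:100, 1)
    g1 <- rbinom(n1, 2, runif(1, 0.1, 0.9))
    g2 <- rbinom(n2, 2, runif(1, 0.1, 0.9))
    cnt <- function(g) allele_counts_raw(length(g), sum(g), sum(g == 1))
    flip <- function(g) 2L - g
    a <- per_snp_fst(cnt(g1), cnt(g2))
    b <- per_snp_fst(cnt(flip(g1)), cnt(flip(g2)))
    expect_equal(a$a, b$a, tolerance = 1e-12)
    expect_equal(a$b, b$b, tolerance = 1e-12)
    expect_equal(a$c, b$c, tolerance = 1e-12)
  }
})

test_that("identical frequencies with equal sizes give non-positive theta", {
  c1 <- allele_counts_from_freq(0.3, 50)
  c2 <- allele_counts_from_freq(0.3, 50)
  res <- per_snp_fst(c1, c2)
  expect_lte(res$theta, 0)
})

test_that("degenerate monomorphic-in-both sites yield zero components, NA theta", {
  c1 <- allele_counts_raw(20, 0, 0)
  c2 <- allele_counts_raw(30, 0, 0)
  res <- per_snp_fst(c1, c2)
  expect_equal(c(res$a, res$b, res$c), c(0, 0, 0))
  expect_true(is.na(res$theta))
})

test_that("per-SNP table matches the scalar estimator and missingness-aware sizes", {
  ds <- random_ds(40, 50, seed = 32, miss = 0.1)
  g1 <- ds$samples[1:20]; g2 <- ds$samples[21:40]
  tab <- snp_fst_table(ds, g1, g2)
  for (j in c(1, 17, 50)) {
    col1 <- ds$genotypes[1:20, j]; col1 <- col1[!is.na(col1)]
    col2 <- ds$genotypes[21:40, j]; col2 <- col2[!is.na(col2)]
    ref <- naive_wc(length(col1), length(col2),
                    mean(col1) / 2, mean(col2) / 2,
                    mean(col1 == 1), mean(col2 == 1))
    expect_equal(tab$a[j], ref$a, tolerance = 1e-12)
    expect_equal(tab$theta[j], ref$theta, tolerance = 1e-12)
    expect_equal(tab$n1[j], length(col1))
  }
})

test_that("genome-wide ratio of sums collapses to theta on one SNP and sums components", {
  ds1 <- random_ds(30, 1, seed = 33)
  gw <- genomewide_fst(ds1, 1:15, 16:30)
  tab <- snp_fst_table(ds1, 1:15, 16:30)
  expect_equal(gw$point, tab$theta[1])

  ds <- random_ds(30, 200, seed = 34, miss = 0.05)
  gw2 <- genomewide_fst(ds, 1:15, 16:30)
  tab2 <- snp_fst_table(ds, 1:15, 16:30)
  ok <- is.finite(tab2$a)
  expect_equal(gw2$point,
               sum(tab2$a[ok]) / sum(tab2$a[ok] + tab2$b[ok] + tab2$c[ok]))
  expect_equal(gw2$n_snps_used, sum(ok))
})

test_that("identical cloned groups give near-zero genome-wide estimates", {
  base <- random_ds(25, 300, seed = 35)
  g <- rbind(base$genotypes, base$genotypes)
  ds <- genotype_dataset(g, c(paste0("a", 1:25), paste0("b", 1:25)),
                         base$variants)
  gw <- genomewide_fst(ds, 1:25, 26:50)
  expect_lte(gw$point, 0)
})

test_that("bootstrap replicates replay exactly from the recorded seed", {
  ds <- random_ds(30, 40, seed = 36)
  fit <- bootstrap_fst(ds, 1:15, 16:30, n_boot = 10, seed = 99,
                       return_replicates = TRUE)
  tab <- snp_fst_table(ds, 1:15, 16:30)
  a <- tab$a; d <- tab$a + tab$b + tab$c
  set.seed(99)
  idx <- matrix(sample.int(40, 40 * 10, replace = TRUE), 10, 40)
  ref <- rowSums(matrix(a[idx], 10, 40)) / rowSums(matrix(d[idx], 10, 40))
  expect_equal(fit$replicates, ref)
  expect_equal(fit$ci_lower, unname(quantile(ref, 0.025)))
  expect_equal(fit$boot_se, sd(ref))
})

test_that("a genome of identical SNPs has a zero-width bootstrap interval", {
  col <- c(rep(0L, 10), rep(2L, 10))
  ds <- make_ds(matrix(col, 20, 30))
  fit <- bootstrap_fst(ds, 1:10, 11:20, n_boot = 50, seed = 1)
  expect_equal(fit$ci_lower, fit$ci_upper)
  expect_equal(fit$boot_se, 0)
  expect_equal(fit$point, 1)
})

test_that("pairwise matrix is symmetric with an empty diagonal", {
  sim <- simulate_balding_nichols(bn_config(c(20, 20, 20), 300, 0.01, seed = 37))
  res <- pairwise_fst_matrix(sim$dataset, sim$pop_labels)
  expect_equal(res$point, t(res$point))
  expect_true(all(is.na(diag(res$point))))
  expect_equal(sum(!is.na(res$point)), 6)
})

test_that("three-group estimates usually rank like the simulation truth", {
  # deme-specific drift so expected pairwise theta (f_k + f_l)/2 reproduces
  # the regional magnitudes 0.00112 / 0.00083 / 0.00059
  f_pop <- c(N = 0.00136, C = 0.0003, S = 0.00088)
  truth <- c(NC = (f_pop[1] + f_pop[2]) / 2,
             NS = (f_pop[1] + f_pop[3]) / 2,
             CS = (f_pop[2] + f_pop[3]) / 2)
  hits <- 0
  n_runs <- 8
  for (run in seq_len(n_runs)) {
    set.seed(400 + run)
    L <- 20000
    p <- runif(L, 0.1, 0.5)
    freq <- do.call(rbind, lapply(f_pop, function(f) {
      pmin(pmax(p + rnorm(L, 0, sqrt(f * p * (1 - p))), 0.01), 0.99)
    }))
    n_per <- c(146, 149, 107)
    g <- do.call(rbind, lapply(1:3, function(k) {
      matrix(rbinom(n_per[k] * L, 2, rep(freq[k, ], each = n_per[k])),
             n_per[k], L)
    }))
    ds <- make_ds(g)
    labels <- rep(c("N", "C", "S"), n_per)
    m <- pairwise_fst_matrix(ds, labels)$point
    est <- c(m["N", "C"], m["N", "S"], m["C", "S"])
    if (identical(order(est), order(unname(truth)))) hits <- hits + 1
  }
  expect_gte(hits, 7)
})

test_that("top-percentile scan honors ties and strict thresholds", {
  tab <- data.frame(snp_id = sprintf("s%03d", 1:100),
                    theta = seq(1, 0.01, length.out = 100))
  expect_equal(nrow(top_differentiated(tab, top_fraction = 0.01)), 1)
  expect_equal(top_differentiated(tab, top_fraction = 0.01)$snp_id, "s001")
  # 3-way tie at the boundary value
  tab_tie <- tab
  tab_tie$theta[1:3] <- 1
  expect_equal(nrow(top_differentiated(tab_tie, top_fraction = 0.01)), 3)
  # threshold mode is strict
  tab2 <- data.frame(snp_id = c("a", "b", "c"), theta = c(0.06, 0.05, 0.04))
  expect_equal(top_differentiated(tab2, abs_threshold = 0.05)$snp_id, "a")
})

test_that("threshold scan of the packaged table returns its printed rows", {
  tab <- top_fst_table()
  tab$theta <- tab$fst
  hits <- top_differentiated(tab, abs_threshold = 0.05)
  expect_setequal(hits$snp_id, tab$snp_id[tab$fst > 0.05])
  expect_true("rs4149264" %in% hits$snp_id)
  expect_equal(hits$snp_id[1], "rs4149264")  # highest value first
})

test_that("minor-allele discordance counts match a per-SNP oracle", {
  g <- rbind(matrix(c(0L, 1L, 1L, 0L), 2, 2),   # group1 freq (0.25, 0.25)
             matrix(c(2L, 1L, 0L, 1L), 2, 2))   # group2 freq (0.75, 0.25)
  ds <- make_ds(g)
  res <- minor_allele_discordance(ds, 1:2, 3:4)
  expect_equal(res$count, 1)
  expect_equal(res$snp_ids, "s001")

  for (seed in 1:3) {
    ds_r <- random_ds(30, 60, seed = 100 + seed, miss = 0.05)
    p1 <- allele_freqs(ds_r, 1:15); p2 <- allele_freqs(ds_r, 16:30)
    oracle <- sum((p1 <= 0.5) != (p2 <= 0.5), na.rm = TRUE)
    expect_equal(minor_allele_discordance(ds_r, 1:15, 16:30)$count, oracle)
  }
})
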