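# in-code fixtures shared across the suite

# small dataset from an explicit genotype matrix (rows = samples)
make_ds <- function(geno, chrom = NULL, pos = NULL) {
  geno <- as.matrix(geno)
  L <- ncol(geno)
  variants <- data.frame(
    snp_id = sprintf("s%03d", seq_len(L)),
    chrom = if (is.null(chrom)) rep("1", L) else chrom,
    pos = if (is.null(pos)) seq_len(L) * 100L else pos,
    allele_a = "A", allele_b = "G", stringsAsFactors = FALSE)
  genotype_dataset(geno, sprintf("ind%03d", seq_len(nrow(geno))), variants)
}

# random dataset with optional missingness, for property-style loops
random_ds <- function(n, L, seed, miss = 0) {
  set.seed(seed)
  g <- matrix(rbinom(n * L, 2, runif(L, 0.1, 0.9)[rep(seq_len(L), each = n)]),
              n, L)
  if (miss > 0) g[runif(n * L) < miss] <- NA
  make_ds(g)
}

# independent enumeration oracle for the exact Hardy-Weinberg test:
# direct conditional probability via log-factorials, no recurrence shared
# with the implementation
hwe_enum_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_b <- 2 * n_bb + n_ab
  n_a <- 2 * n - n_b
  log_prob <- function(h) {
    hb <- (n_b - h) / 2
    ha <- (n_a - h) / 2
    lfactorial(n) - lfactorial(ha) - lfactorial(h) - lfactorial(hb) +
      h * log(2) + lfactorial(n_a) + lfactorial(n_b) - lfactorial(2 * n)
  }
  hets <- seq(n_b %% 2, min(n_a, n_b), by = 2)
  probs <- exp(vapply(hets, log_prob, numeric(1)))
  p_obs <- probs[match(n_ab, hets)]
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

# brute-force double-loop admixture log-likelihood
naive_admix_loglik <- function(G, Q, F_mat) {
  total <- 0
  for (i in seq_len(nrow(G))) {
    for (j in seq_len(ncol(G))) {
      if (is.na(G[i, j])) next
      p <- min(max(sum(Q[i, ] * F_mat[, j]), 1e-10), 1 - 1e-10)
      total <- total + G[i, j] * log(p) + (2 - G[i, j]) * log(1 - p)
    }
  }
  total
}

# reference Weir-Cockerham components computed scalar-by-scalar from counts
naive_wc <- function(n1, n2, p1, p2, h1, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}
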