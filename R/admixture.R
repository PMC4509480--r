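#' Admixture model log-likelihood
#'
#' Binomial mixture likelihood of genotypes given ancestry proportions Q
#' (samples x K, rows summing to 1) and component allele frequencies F
#' (K x SNPs): each of an individual's two allele copies at SNP j carries
#' allele_b with probability `sum_k q_ik f_kj`. Missing genotypes contribute
#' nothing. Probabilities are clamped to `[1e-10, 1 - 1e-10]` before taking
#' logs.
#'
#' @param genotypes samples x SNPs matrix of codes in `{0, 1, 2, NA}`.
#' @param Q samples x K ancestry matrix.
#' @param F_mat K x SNPs component frequency matrix.
#' @return the log-likelihood (0 when all genotypes are missing).
#' @export
admixture_loglik <- function(genotypes, Q, F_mat) {
  check_admix_dims(genotypes, Q, F_mat)
  P <- pmin(pmax(Q %*% F_mat, 1e-10), 1 - 1e-10)
  ll <- genotypes * log(P) + (2 - genotypes) * log(1 - P)
  sum(ll[!is.na(genotypes)])
}

check_admix_dims <- function(genotypes, Q, F_mat) {
  if (nrow(Q) != nrow(genotypes) || ncol(Q) != nrow(F_mat) ||
      ncol(F_mat) != ncol(genotypes)) {
    stop("dimension mismatch: genotypes ", nrow(genotypes), "x", ncol(genotypes),
         ", Q ", nrow(Q), "x", ncol(Q), ", F ", nrow(F_mat), "x", ncol(F_mat))
  }
}

#' One EM update of the admixture model
#'
#' E-step: each observed allele copy is attributed to ancestry components by
#' Bayes' rule; M-step: Q rows become the normalized expected ancestry
#' counts and F the ratio of expected allele_b counts to expected totals.
#' The update never decreases the log-likelihood.
#'
#' @inheritParams admixture_loglik
#' @return list with updated `Q` and `F_mat`.
#' @export
em_step <- function(genotypes, Q, F_mat) {
  check_admix_dims(genotypes, Q, F_mat)
  K <- ncol(Q)
  W <- !is.na(genotypes)
  G <- genotypes
  G[!W] <- 0L
  G2 <- 2L - genotypes
  G2[!W] <- 0L
  P <- pmin(pmax(Q %*% F_mat, 1e-10), 1 - 1e-10)
  ratio_b <- G / P
  ratio_a <- G2 / (1 - P)
  Qnew <- matrix(0, nrow(Q), K)
  Fnum <- matrix(0, K, ncol(F_mat))
  Fden <- matrix(0, K, ncol(F_mat))
  for (k in seq_len(K)) {
    # expected allele_b / allele_a copies attributed to component k
    Eb <- (Q[, k] %o% F_mat[k, ]) * ratio_b
    Ea <- (Q[, k] %o% (1 - F_mat[k, ])) * ratio_a
    Qnew[, k] <- rowSums(Eb + Ea)
    Fnum[k, ] <- colSums(Eb)
    Fden[k, ] <- colSums(Eb + Ea)
  }
  Qnew <- Qnew / pmax(rowSums(Qnew), 1e-300)
  Fnew <- ifelse(Fden > 0, Fnum / Fden, F_mat)
  Fnew <- pmin(pmax(Fnew, 1e-10), 1 - 1e-10)
  list(Q = Qnew, F_mat = Fnew)
}

#' Fit admixture proportions by EM
#'
#' Maximum-likelihood estimation of ancestry proportions Q and component
#' allele frequencies F under the binomial admixture model, by plain EM
#' (monotone in the log-likelihood). Q is initialized Dirichlet(1) per
#' sample and F Uniform(0.05, 0.95); several random restarts guard against
#' local optima and the best log-likelihood is kept.
#'
#' @param ds a `genotype_dataset`.
#' @param K number of ancestry components (>= 1).
#' @param seed integer seed; same seed, same result.
#' @param tol stop when the log-likelihood gain falls below this.
#' @param max_iter iteration cap per restart.
#' @param n_restarts random restarts (best kept).
#' @return an `admixture_result`: `Q` (samples x K, rownames = sample IDs),
#'   `F_mat` (K x SNPs), `loglik_trace`, `loglik`, `K`, `seed`, `n_iter`,
#'   `converged`.
#' @export
fit_admixture <- function(ds, K, seed = 1, tol = 1e-6, max_iter = 2000,
                          n_restarts = 3) {
  stopifnot(K >= 1)
  if (K > n_samples(ds)) {
    warning("K exceeds the number of samples; fitting anyway")
  }
  G <- ds$genotypes
  best <- NULL
  for (rs in seq_len(n_restarts)) {
    set.seed(derive_seed(seed, rs))
    n <- nrow(G); L <- ncol(G)
    Q <- matrix(stats::rgamma(n * K, 1), n, K)
    Q <- Q / rowSums(Q)
    F_mat <- matrix(stats::runif(K * L, 0.05, 0.95), K, L)
    trace <- numeric(0)
    ll <- admixture_loglik(G, Q, F_mat)
    converged <- FALSE
    iter <- 0
    while (iter < max_iter) {
      iter <- iter + 1
      up <- em_step(G, Q, F_mat)
      Q <- up$Q; F_mat <- up$F_mat
      ll_new <- admixture_loglik(G, Q, F_mat)
      trace <- c(trace, ll_new)
      if (ll_new - ll < tol) {
        converged <- TRUE
        ll <- ll_new
        break
      }
      ll <- ll_new
    }
    if (is.null(best) || ll > best$loglik) {
      best <- list(Q = Q, F_mat = F_mat, loglik = ll, loglik_trace = trace,
                   n_iter = iter, converged = converged, restart = rs)
    }
  }
  rownames(best$Q) <- ds$samples
  structure(c(best, list(K = as.integer(K), seed = as.integer(seed))),
            class = "admixture_result")
}

#' @export
print.admixture_result <- function(x, ...) {
  cat("admixture_result: K =", x$K, ",", nrow(x$Q), "samples,",
      ncol(x$F_mat), "SNPs\n")
  cat(sprintf("  loglik %.2f after %d iterations (converged: %s)\n",
              x$loglik, x$n_iter, x$converged))
  invisible(x)
}

#' Align admixture components to reference labels
#'
#' Resolves label switching: finds the permutation of components that
#' minimizes the mean absolute difference between `Q` and a reference
#' matrix (e.g. true one-hot labels), searching all permutations (intended
#' for the small K used in fine-structure analysis).
#'
#' @param Q fitted samples x K ancestry matrix.
#' @param Q_ref reference samples x K matrix.
#' @return list with the permuted `Q`, the `permutation`, and `mae`.
#' @export
align_components <- function(Q, Q_ref) {
  K <- ncol(Q)
  stopifnot(ncol(Q_ref) == K, nrow(Q_ref) == nrow(Q))
  perms <- permutations_of(K)
  best <- NULL
  for (i in seq_len(nrow(perms))) {
    mae <- mean(abs(Q[, perms[i, ], drop = FALSE] - Q_ref))
    if (is.null(best) || mae < best$mae) {
      best <- list(Q = Q[, perms[i, ], drop = FALSE],
                   permutation = perms[i, ], mae = mae)
    }
  }
  best
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    out <- rbind(out, cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                            sub[, seq(pos, k - 1)[seq_len(k - pos)],
                                drop = FALSE]))
  }
  out
}

#' Compare one ancestry component between two regions
#'
#' Per-region means of the chosen component plus a two-sided Welch
#' two-sample test for their difference.
#'
#' @param Q samples x K ancestry matrix with sample IDs as rownames.
#' @param metadata data frame with `sample_id` and `region`.
#' @param component component index.
#' @param region_a,region_b region labels to compare.
#' @return list with `mean_a`, `mean_b`, `p_value` (`NA` when a region has
#'   fewer than two samples).
#' @export
compare_components_by_region <- function(Q, metadata, component,
                                         region_a, region_b) {
  idx <- match(rownames(Q), metadata$sample_id)
  region <- metadata$region[idx]
  xa <- Q[region %in% region_a, component]
  xb <- Q[region %in% region_b, component]
  if (length(xa) == 0 || length(xb) == 0) {
    stop("region not present among the samples")
  }
  p <- if (length(xa) >= 2 && length(xb) >= 2 &&
           (stats::sd(xa) > 0 || stats::sd(xb) > 0)) {
    stats::t.test(xa, xb)$p.value
  } else if (length(xa) >= 2 && length(xb) >= 2) {
    1  # identical constant groups: no evidence of a difference
  } else {
    NA_real_
  }
  list(mean_a = mean(xa), mean_b = mean(xb), p_value = p)
}
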