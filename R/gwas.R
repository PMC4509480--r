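#' Allelic chi-square association test
#'
#' Standard 1-df Pearson chi-square on the 2x2 case/control allele-count
#' table, `N (ad - bc)^2` over the product of the margins, with the p-value
#' from the chi-square upper tail. A zero margin makes the SNP untestable:
#' the statistic is 0, p = 1, and the result is flagged.
#'
#' @param case_b,case_a allele counts in cases (allele_b, allele_a).
#' @param control_b,control_a allele counts in controls.
#' @param snp_id optional identifier carried into the result.
#' @return an `association_result`: `snp_id`, `chi_square`, `p_value`,
#'   `test`, `counts` (the 2x2 table), `untestable`.
#' @export
allelic_chisq <- function(case_b, case_a, control_b, control_a,
                          snp_id = NA_character_) {
  counts <- matrix(c(case_b, control_b, case_a, control_a), 2, 2,
                   dimnames = list(c("case", "control"), c("b", "a")))
  n <- sum(counts)
  margins_ok <- all(rowSums(counts) > 0) && all(colSums(counts) > 0)
  if (!margins_ok) {
    return(structure(list(snp_id = snp_id, chi_square = 0, p_value = 1,
                          test = "allelic", counts = counts, untestable = TRUE),
                     class = "association_result"))
  }
  num <- n * (counts[1, 1] * counts[2, 2] - counts[1, 2] * counts[2, 1])^2
  den <- prod(rowSums(counts)) * prod(colSums(counts))
  chi <- num / den
  structure(list(snp_id = snp_id, chi_square = chi,
                 p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 test = "allelic", counts = counts, untestable = FALSE),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf("%s test%s: chi^2 = %.4f, p = %.4g\n", x$test,
              if (is.na(x$snp_id)) "" else paste0(" (", x$snp_id, ")"),
              x$chi_square, x$p_value))
  invisible(x)
}

#' Cochran-Armitage trend test
#'
#' 1-df trend statistic on the 2x3 genotype-by-phenotype table with additive
#' weights (0, 1, 2). Under exact Hardy-Weinberg proportions in both groups
#' it coincides with the allelic chi-square.
#'
#' @param case_counts,control_counts length-3 genotype counts
#'   (0, 1, 2 copies of allele_b).
#' @param snp_id optional identifier.
#' @return an `association_result` with `test = "trend"`.
#' @export
trend_test <- function(case_counts, control_counts, snp_id = NA_character_) {
  stopifnot(length(case_counts) == 3, length(control_counts) == 3)
  w <- c(0, 1, 2)
  r <- sum(case_counts)
  s <- sum(control_counts)
  n <- r + s
  if (n == 0) stop("empty table")
  tot <- case_counts + control_counts
  num <- sum(w * (s * case_counts - r * control_counts)) / n
  var_num <- (r * s / n) *
    (sum(w^2 * tot) / n - (sum(w * tot) / n)^2)
  counts <- rbind(case = case_counts, control = control_counts)
  if (var_num <= 0 || r == 0 || s == 0) {
    return(structure(list(snp_id = snp_id, chi_square = 0, p_value = 1,
                          test = "trend", counts = counts, untestable = TRUE),
                     class = "association_result"))
  }
  chi <- num^2 / var_num
  structure(list(snp_id = snp_id, chi_square = chi,
                 p_value = stats::pchisq(chi, df = 1, lower.tail = FALSE),
                 test = "trend", counts = counts, untestable = FALSE),
            class = "association_result")
}

#' Per-SNP association scan
#'
#' Vectorized allelic (or trend) test of every SNP against a binary
#' phenotype; missing genotypes are excluded per SNP.
#'
#' @param ds a `genotype_dataset`.
#' @param phenotype 0/1 vector aligned with `ds$samples`.
#' @param test `"allelic"` (default) or `"trend"`.
#' @return data frame with `snp_id`, `chi_square`, `p_value`, `untestable`.
#' @export
association_scan <- function(ds, phenotype, test = c("allelic", "trend")) {
  test <- match.arg(test)
  stopifnot(length(phenotype) == n_samples(ds), all(phenotype %in% c(0, 1)))
  g_case <- ds$genotypes[phenotype == 1, , drop = FALSE]
  g_ctrl <- ds$genotypes[phenotype == 0, , drop = FALSE]
  if (test == "allelic") {
    n_case <- colSums(!is.na(g_case))
    n_ctrl <- colSums(!is.na(g_ctrl))
    cb <- colSums(g_case, na.rm = TRUE)
    ca <- 2 * n_case - cb
    ub <- colSums(g_ctrl, na.rm = TRUE)
    ua <- 2 * n_ctrl - ub
    n <- cb + ca + ub + ua
    num <- n * (cb * ua - ca * ub)^2
    den <- (cb + ca) * (ub + ua) * (cb + ub) * (ca + ua)
    untestable <- den == 0
    chi <- ifelse(untestable, 0, num / den)
  } else {
    w <- c(0, 1, 2)
    case_counts <- sapply(0:2, function(v) colSums(g_case == v, na.rm = TRUE))
    ctrl_counts <- sapply(0:2, function(v) colSums(g_ctrl == v, na.rm = TRUE))
    r <- rowSums(case_counts)
    s <- rowSums(ctrl_counts)
    n <- r + s
    tot <- case_counts + ctrl_counts
    num <- (case_counts %*% w * s - ctrl_counts %*% w * r) / n
    ex2 <- (tot %*% (w^2)) / n
    ex <- (tot %*% w) / n
    var_num <- (r * s / n) * (ex2 - ex^2)
    untestable <- as.vector(var_num <= 0 | r == 0 | s == 0)
    chi <- ifelse(untestable, 0, as.vector(num)^2 / as.vector(var_num))
  }
  data.frame(snp_id = ds$variants$snp_id, chi_square = chi,
             p_value = ifelse(untestable, 1,
                              stats::pchisq(chi, 1, lower.tail = FALSE)),
             untestable = untestable, stringsAsFactors = FALSE)
}

#' Genomic control
#'
#' The inflation factor lambda is the median observed chi-square divided by
#' the null 1-df median; adjusted statistics divide by `max(lambda, 1)`.
#'
#' @param chi_square vector of 1-df chi-square statistics.
#' @return list with `lambda`, `chi_adjusted`, `p_adjusted`.
#' @export
genomic_control <- function(chi_square) {
  stopifnot(length(chi_square) >= 1)
  lambda <- stats::median(chi_square) / 0.4549  # median of chi-square(1 df)
  adj <- chi_square / max(lambda, 1)
  list(lambda = lambda, chi_adjusted = adj,
       p_adjusted = stats::pchisq(adj, 1, lower.tail = FALSE))
}

#' Case-control simulation study of stratification effects
#'
#' For each replicate: simulate a stratified case-control dataset, test every
#' SNP, and accumulate the false-positive rate over null SNPs and power over
#' causal SNPs at each significance level, plus the genomic inflation factor
#' from the null SNPs. Metrics are averaged over replicates.
#'
#' @param cfg a [case_control_config()].
#' @param n_replicates independent replicates.
#' @param seed integer seed (replicate seeds are derived from it).
#' @param test association test passed to [association_scan()].
#' @return a `gwas_sim_metrics` object: `fpr_per_alpha`, `power_per_alpha`
#'   (named means over replicates, with `*_sd` companions), `lambda_gc`,
#'   `lambda_gc_sd`, `n_null`, `n_causal`, `n_replicates`, `seed`,
#'   `scenario` (the config echoed back).
#' @export
run_gwas_simulation <- function(cfg, n_replicates = 1, seed = 1,
                                test = "allelic") {
  alphas <- cfg$alpha_levels
  fpr <- matrix(NA_real_, n_replicates, length(alphas))
  pwr <- matrix(NA_real_, n_replicates, length(alphas))
  lam <- numeric(n_replicates)
  for (rep_i in seq_len(n_replicates)) {
    cfg_r <- cfg
    cfg_r$seed <- derive_seed(seed, rep_i)
    sim <- simulate_case_control(cfg_r)
    scan <- association_scan(sim$dataset, sim$phenotype, test = test)
    null_p <- scan$p_value[sim$truth$null_snps]
    lam[rep_i] <- genomic_control(scan$chi_square[sim$truth$null_snps])$lambda
    for (ai in seq_along(alphas)) {
      fpr[rep_i, ai] <- mean(null_p < alphas[ai])
      if (length(sim$truth$causal_snps) > 0) {
        pwr[rep_i, ai] <- mean(scan$p_value[sim$truth$causal_snps] < alphas[ai])
      }
    }
  }
  alpha_names <- paste0("alpha_", alphas)
  structure(list(
    fpr_per_alpha = stats::setNames(colMeans(fpr), alpha_names),
    fpr_sd = stats::setNames(apply(fpr, 2, stats::sd), alpha_names),
    power_per_alpha = stats::setNames(colMeans(pwr), alpha_names),
    power_sd = stats::setNames(apply(pwr, 2, stats::sd), alpha_names),
    lambda_gc = mean(lam), lambda_gc_sd = stats::sd(lam),
    n_null = length(setdiff(seq_len(cfg$n_snps),
                            if (is.null(cfg$causal_snps)) integer(0)
                            else cfg$causal_snps$snp)),
    n_causal = if (is.null(cfg$causal_snps)) 0L else nrow(cfg$causal_snps),
    n_replicates = as.integer(n_replicates), seed = as.integer(seed),
    scenario = cfg), class = "gwas_sim_metrics")
}

#' @export
print.gwas_sim_metrics <- function(x, ...) {
  cat("gwas_sim_metrics over", x$n_replicates, "replicate(s):\n")
  cat("  FPR:", paste(sprintf("%s=%.4g", names(x$fpr_per_alpha),
                              x$fpr_per_alpha), collapse = ", "), "\n")
  if (x$n_causal > 0) {
    cat("  power:", paste(sprintf("%s=%.4g", names(x$power_per_alpha),
                                  x$power_per_alpha), collapse = ", "), "\n")
  }
  cat(sprintf("  lambda_GC = %.4f (%d null, %d causal SNPs)\n",
              x$lambda_gc, x$n_null, x$n_causal))
  invisible(x)
}
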