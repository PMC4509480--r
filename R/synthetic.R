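#' Balding-Nichols simulation configuration
#'
#' Subpopulation allele frequencies are drawn around an ancestral frequency
#' `p` with Beta(p(1-F)/F, (1-p)(1-F)/F) so that their variance is
#' F p (1 - p): F is exactly the differentiation parameter the Weir-Cockerham
#' estimator targets. Defaults emulate the regional regime the package is
#' designed around: two or three subpopulations with genome-wide F in the
#' 1e-3 range, post-QC-like ancestral minor allele frequencies in (0.05, 0.5),
#' and tens of thousands of independent SNPs.
#'
#' @param n_per_pop integer vector of diploid sample sizes, one per
#'   subpopulation.
#' @param n_snps number of SNPs.
#' @param fst_true differentiation parameter in `[0, 1)`.
#' @param ancestral_maf_range interval within (0, 0.5] for the uniform
#'   ancestral frequency draw.
#' @param missing_rate per-genotype missingness probability in `[0, 1)`.
#' @param seed integer seed; the same seed yields byte-identical datasets.
#' @return a `bn_config` list.
#' @export
bn_config <- function(n_per_pop = c(146, 107), n_snps = 41400,
                      fst_true = 0.001,
                      ancestral_maf_range = c(0.05, 0.5),
                      missing_rate = 0, seed = 1) {
  stopifnot(length(n_per_pop) >= 1, all(n_per_pop >= 1))
  if (fst_true < 0 || fst_true >= 1) stop("fst_true must lie in [0, 1)")
  if (ancestral_maf_range[1] <= 0 || ancestral_maf_range[2] > 0.5 ||
      ancestral_maf_range[1] > ancestral_maf_range[2]) {
    stop("ancestral_maf_range must be an interval within (0, 0.5]")
  }
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must lie in [0, 1)")
  structure(list(n_per_pop = as.integer(n_per_pop), n_snps = as.integer(n_snps),
                 fst_true = fst_true, ancestral_maf_range = ancestral_maf_range,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "bn_config")
}

# deterministic substream seeds below 2^31, so multi-stage simulations driven
# by one global seed stay reproducible component by component
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483629)
}

#' Simulate genotypes under the Balding-Nichols model
#'
#' For each SNP an ancestral frequency `p ~ Uniform(ancestral_maf_range)` is
#' drawn; each subpopulation's frequency is Beta-distributed around `p` with
#' variance `F p (1-p)` (equal to `p` exactly when `F = 0`); genotypes are
#' Binomial(2, subpopulation frequency). Sampled SNPs are independent (no
#' linkage disequilibrium).
#'
#' @param cfg a [bn_config()].
#' @return list with `dataset` (a `genotype_dataset`), `truth` (list with
#'   `p_ancestral` and the `n_pops x n_snps` matrix `pop_freq`), and
#'   `pop_labels` (subpopulation of each sample).
#' @export
simulate_balding_nichols <- function(cfg) {
  stopifnot(inherits(cfg, "bn_config"))
  set.seed(cfg$seed)
  L <- cfg$n_snps
  K <- length(cfg$n_per_pop)
  p <- stats::runif(L, cfg$ancestral_maf_range[1], cfg$ancestral_maf_range[2])
  f <- cfg$fst_true
  pop_freq <- matrix(0, K, L)
  for (k in seq_len(K)) {
    pop_freq[k, ] <- if (f > 0) {
      stats::rbeta(L, p * (1 - f) / f, (1 - p) * (1 - f) / f)
    } else p
  }
  geno <- matrix(0L, sum(cfg$n_per_pop), L)
  row0 <- 0L
  for (k in seq_len(K)) {
    nk <- cfg$n_per_pop[k]
    geno[row0 + seq_len(nk), ] <- matrix(
      stats::rbinom(nk * L, 2L, rep(pop_freq[k, ], each = nk)), nk, L)
    row0 <- row0 + nk
  }
  pop_labels <- rep(paste0("pop", seq_len(K)), cfg$n_per_pop)
  samples <- paste0(pop_labels, "_", unlist(lapply(cfg$n_per_pop, seq_len)))
  variants <- data.frame(
    snp_id = sprintf("snp%06d", seq_len(L)), chrom = "1",
    pos = seq_len(L) * 1000L, allele_a = "A", allele_b = "B",
    stringsAsFactors = FALSE)
  ds <- genotype_dataset(geno, samples, variants)
  if (cfg$missing_rate > 0) {
    ds <- inject_missingness(ds, cfg$missing_rate, derive_seed(cfg$seed, 7L))
  }
  list(dataset = ds,
       truth = list(p_ancestral = p, pop_freq = pop_freq,
                    fst_true = cfg$fst_true),
       pop_labels = pop_labels)
}

#' Latitudinal cline simulation configuration
#'
#' Extends [bn_config()] with per-deme latitudes and a linear
#' allele-frequency cline: each deme's frequency is shifted by
#' `slope * (latitude - mean latitude)` and clipped to `[0.01, 0.99]`.
#' Defaults place one deme at each state of the packaged regional lookup with
#' an effect size at which the cline, not drift, dominates the leading axis
#' of genetic variation.
#'
#' @param latitudes per-deme latitudes in decimal degrees (`|lat| <= 90`);
#'   default: the packaged state latitudes.
#' @param states optional deme names aligned with `latitudes`.
#' @param regions optional region labels aligned with `latitudes`.
#' @param n_per_deme diploid samples per deme (recycled).
#' @param n_snps,fst_true,ancestral_maf_range,missing_rate,seed as in
#'   [bn_config()].
#' @param slope allele-frequency change per degree latitude.
#' @return a `cline_config` list.
#' @export
cline_config <- function(latitudes = NULL, states = NULL, regions = NULL,
                         n_per_deme = 20, n_snps = 3000, fst_true = 5e-4,
                         slope = 0.012, ancestral_maf_range = c(0.05, 0.5),
                         missing_rate = 0, seed = 1) {
  if (is.null(latitudes)) {
    tab <- state_region_table()
    latitudes <- tab$latitude
    if (is.null(states)) states <- tab$state
    if (is.null(regions)) regions <- tab$region
  }
  if (any(abs(latitudes) > 90)) stop("latitudes must lie in [-90, 90]")
  if (!is.finite(slope)) stop("slope must be finite")
  n_demes <- length(latitudes)
  if (is.null(states)) states <- paste0("deme", seq_len(n_demes))
  if (is.null(regions)) regions <- rep(NA_character_, n_demes)
  base <- bn_config(n_per_pop = rep_len(n_per_deme, n_demes), n_snps = n_snps,
                    fst_true = fst_true,
                    ancestral_maf_range = ancestral_maf_range,
                    missing_rate = missing_rate, seed = seed)
  structure(c(base, list(latitudes = latitudes, states = states,
                         regions = regions, slope = slope)),
            class = c("cline_config", "bn_config"))
}

#' Simulate genotypes with a latitudinal allele-frequency cline
#'
#' Balding-Nichols subpopulation frequencies per deme, plus a deterministic
#' linear shift along latitude. With `slope = 0` this reduces exactly to
#' [simulate_balding_nichols()].
#'
#' @param cfg a [cline_config()].
#' @return list with `dataset`, `metadata` (sample_id/state/region/latitude),
#'   and `truth` (ancestral and per-deme frequencies, slope).
#' @export
simulate_cline <- function(cfg) {
  stopifnot(inherits(cfg, "cline_config"))
  set.seed(cfg$seed)
  L <- cfg$n_snps
  K <- length(cfg$latitudes)
  p <- stats::runif(L, cfg$ancestral_maf_range[1], cfg$ancestral_maf_range[2])
  f <- cfg$fst_true
  centered_lat <- cfg$latitudes - mean(cfg$latitudes)
  pop_freq <- matrix(0, K, L)
  for (k in seq_len(K)) {
    base <- if (f > 0) {
      stats::rbeta(L, p * (1 - f) / f, (1 - p) * (1 - f) / f)
    } else p
    pop_freq[k, ] <- pmin(pmax(base + cfg$slope * centered_lat[k], 0.01), 0.99)
  }
  geno <- matrix(0L, sum(cfg$n_per_pop), L)
  row0 <- 0L
  for (k in seq_len(K)) {
    nk <- cfg$n_per_pop[k]
    geno[row0 + seq_len(nk), ] <- matrix(
      stats::rbinom(nk * L, 2L, rep(pop_freq[k, ], each = nk)), nk, L)
    row0 <- row0 + nk
  }
  deme_idx <- rep(seq_len(K), cfg$n_per_pop)
  samples <- sprintf("d%02d_%03d", deme_idx, unlist(lapply(cfg$n_per_pop, seq_len)))
  variants <- data.frame(
    snp_id = sprintf("snp%06d", seq_len(L)), chrom = "1",
    pos = seq_len(L) * 1000L, allele_a = "A", allele_b = "B",
    stringsAsFactors = FALSE)
  ds <- genotype_dataset(geno, samples, variants)
  if (cfg$missing_rate > 0) {
    ds <- inject_missingness(ds, cfg$missing_rate, derive_seed(cfg$seed, 7L))
  }
  metadata <- data.frame(sample_id = samples,
                         state = cfg$states[deme_idx],
                         region = cfg$regions[deme_idx],
                         latitude = cfg$latitudes[deme_idx],
                         stringsAsFactors = FALSE)
  list(dataset = ds, metadata = metadata,
       truth = list(p_ancestral = p, pop_freq = pop_freq, slope = cfg$slope,
                    latitudes = cfg$latitudes))
}

#' Set genotypes missing at random
#'
#' Each entry is independently replaced by `NA` with probability `rate`.
#'
#' @param ds a `genotype_dataset`.
#' @param rate missingness probability in `[0, 1)`.
#' @param seed integer seed.
#' @return the dataset with missingness injected.
#' @export
inject_missingness <- function(ds, rate, seed = 1) {
  if (rate < 0 || rate >= 1) stop("rate must lie in [0, 1)")
  if (rate == 0) return(ds)
  set.seed(seed)
  g <- ds$genotypes
  g[stats::runif(length(g)) < rate] <- NA_integer_
  genotype_dataset(g, ds$samples, ds$variants)
}

#' Case-control simulation configuration
#'
#' Cases and controls are sampled from a mixture of Balding-Nichols
#' subpopulations; unequal mixing fractions between the case and control arms
#' create population stratification. Disease status follows a multiplicative
#' per-allele odds model at the designated causal SNPs. Scenario parameters
#' are configurable; defaults mirror the regional differentiation regime
#' (F = 0.001) at a genome-wide marker count with balanced arms.
#'
#' @param n_cases,n_controls arm sizes.
#' @param case_pop_fractions,control_pop_fractions mixing proportions over
#'   subpopulations; each must sum to 1 (within 1e-12).
#' @param causal_snps data frame with columns `snp` (index) and
#'   `relative_risk` (> 0, per copy of allele_b), or `NULL` for a pure null.
#' @param baseline_prevalence disease probability for a genotype with zero
#'   copies of every risk allele.
#' @param alpha_levels significance thresholds evaluated downstream.
#' @param n_snps,fst_true,ancestral_maf_range,missing_rate,seed as in
#'   [bn_config()].
#' @return a `case_control_config` list.
#' @export
case_control_config <- function(n_cases = 1000, n_controls = 1000,
                                case_pop_fractions = c(0.5, 0.5),
                                control_pop_fractions = c(0.5, 0.5),
                                causal_snps = NULL,
                                baseline_prevalence = 0.1,
                                alpha_levels = c(0.05, 1e-4),
                                n_snps = 41400, fst_true = 0.001,
                                ancestral_maf_range = c(0.05, 0.5),
                                missing_rate = 0, seed = 1) {
  if (abs(sum(case_pop_fractions) - 1) > 1e-12 ||
      abs(sum(control_pop_fractions) - 1) > 1e-12) {
    stop("population fractions must sum to 1")
  }
  if (length(case_pop_fractions) != length(control_pop_fractions)) {
    stop("case and control fraction vectors must have equal length")
  }
  if (!is.null(causal_snps)) {
    causal_snps <- as.data.frame(causal_snps)
    stopifnot(all(c("snp", "relative_risk") %in% names(causal_snps)))
    if (any(causal_snps$relative_risk <= 0)) stop("relative_risk must be > 0")
  }
  if (baseline_prevalence <= 0 || baseline_prevalence >= 1) {
    stop("baseline_prevalence must lie in (0, 1)")
  }
  base <- bn_config(n_per_pop = rep(1L, length(case_pop_fractions)),
                    n_snps = n_snps, fst_true = fst_true,
                    ancestral_maf_range = ancestral_maf_range,
                    missing_rate = missing_rate, seed = seed)
  base$n_per_pop <- NULL
  structure(c(base, list(n_cases = as.integer(n_cases),
                         n_controls = as.integer(n_controls),
                         case_pop_fractions = case_pop_fractions,
                         control_pop_fractions = control_pop_fractions,
                         causal_snps = causal_snps,
                         baseline_prevalence = baseline_prevalence,
                         alpha_levels = alpha_levels)),
            class = "case_control_config")
}

#' Simulate a stratified case-control genotype study
#'
#' Each case (control) individual's subpopulation is drawn from the case
#' (control) mixing fractions and its genotypes from that subpopulation's
#' Balding-Nichols frequencies. When causal SNPs are configured, disease
#' status is assigned by a multiplicative per-allele odds-of-disease model
#' (probability `baseline_prevalence * prod(RR^g)`, capped at 1) with
#' rejection sampling until each arm is filled; with no causal SNPs the
#' disease probability is genotype-independent and arms are filled directly.
#'
#' @param cfg a [case_control_config()].
#' @param max_attempts_factor bound on rejection draws, as a multiple of the
#'   arm size divided by the acceptance probability floor.
#' @return list with `dataset`, `phenotype` (1 = case, 0 = control, aligned
#'   with samples), `pop_labels`, and `truth` (subpopulation frequencies,
#'   causal SNP indices, null SNP indices).
#' @export
simulate_case_control <- function(cfg, max_attempts_factor = 200) {
  stopifnot(inherits(cfg, "case_control_config"))
  set.seed(cfg$seed)
  L <- cfg$n_snps
  K <- length(cfg$case_pop_fractions)
  p <- stats::runif(L, cfg$ancestral_maf_range[1], cfg$ancestral_maf_range[2])
  f <- cfg$fst_true
  pop_freq <- matrix(0, K, L)
  for (k in seq_len(K)) {
    pop_freq[k, ] <- if (f > 0) {
      stats::rbeta(L, p * (1 - f) / f, (1 - p) * (1 - f) / f)
    } else p
  }
  causal_idx <- if (is.null(cfg$causal_snps)) integer(0) else
    as.integer(cfg$causal_snps$snp)
  rr <- if (length(causal_idx)) cfg$causal_snps$relative_risk else numeric(0)

  draw_arm <- function(n_target, fractions, want_case) {
    pops <- integer(n_target)
    causal_geno <- matrix(0L, n_target, length(causal_idx))
    if (length(causal_idx) == 0) {
      # acceptance probability is genotype-free: fill the arm directly
      pops <- sample.int(K, n_target, replace = TRUE, prob = fractions)
      return(list(pops = pops, causal_geno = causal_geno))
    }
    filled <- 0L
    attempts <- 0L
    max_attempts <- ceiling(max_attempts_factor * n_target /
                              min(cfg$baseline_prevalence,
                                  1 - cfg$baseline_prevalence))
    while (filled < n_target) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("rejection sampling failed to fill the ",
             if (want_case) "case" else "control",
             " arm after ", max_attempts, " attempts; ",
             "prevalence incompatible with the requested sample size")
      }
      k <- sample.int(K, 1, prob = fractions)
      g <- stats::rbinom(length(causal_idx), 2L, pop_freq[k, causal_idx])
      pr <- min(cfg$baseline_prevalence * prod(rr^g), 1)
      is_case <- stats::runif(1) < pr
      if (is_case == want_case) {
        filled <- filled + 1L
        pops[filled] <- k
        causal_geno[filled, ] <- g
      }
    }
    list(pops = pops, causal_geno = causal_geno)
  }

  cases <- draw_arm(cfg$n_cases, cfg$case_pop_fractions, TRUE)
  controls <- draw_arm(cfg$n_controls, cfg$control_pop_fractions, FALSE)
  pops <- c(cases$pops, controls$pops)
  n_total <- cfg$n_cases + cfg$n_controls
  geno <- matrix(0L, n_total, L)
  for (k in seq_len(K)) {
    rows <- which(pops == k)
    if (length(rows) == 0) next
    geno[rows, ] <- matrix(
      stats::rbinom(length(rows) * L, 2L, rep(pop_freq[k, ], each = length(rows))),
      length(rows), L)
  }
  if (length(causal_idx)) {
    geno[seq_len(cfg$n_cases), causal_idx] <- cases$causal_geno
    geno[cfg$n_cases + seq_len(cfg$n_controls), causal_idx] <- controls$causal_geno
  }
  phenotype <- rep(c(1L, 0L), c(cfg$n_cases, cfg$n_controls))
  samples <- c(sprintf("case_%04d", seq_len(cfg$n_cases)),
               sprintf("ctrl_%04d", seq_len(cfg$n_controls)))
  variants <- data.frame(
    snp_id = sprintf("snp%06d", seq_len(L)), chrom = "1",
    pos = seq_len(L) * 1000L, allele_a = "A", allele_b = "B",
    stringsAsFactors = FALSE)
  ds <- genotype_dataset(geno, samples, variants)
  if (cfg$missing_rate > 0) {
    ds <- inject_missingness(ds, cfg$missing_rate, derive_seed(cfg$seed, 7L))
  }
  list(dataset = ds, phenotype = phenotype,
       pop_labels = paste0("pop", pops),
       truth = list(pop_freq = pop_freq, causal_snps = causal_idx,
                    null_snps = setdiff(seq_len(L), causal_idx),
                    relative_risk = rr))
}

#' Write a simulated study to disk
#'
#' Emits PED/MAP genotypes, a metadata TSV when available, and a truth JSON
#' recording the generator's parameters and latent frequencies.
#'
#' @param sim result of one of the `simulate_*` functions.
#' @param prefix output path prefix.
#' @return invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, prefix) {
  files <- c(ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map"),
             truth = paste0(prefix, "_truth.json"))
  write_ped_map(sim$dataset, files[["ped"]], files[["map"]])
  if (!is.null(sim$metadata)) {
    files <- c(files, metadata = paste0(prefix, "_metadata.tsv"))
    utils::write.table(sim$metadata, files[["metadata"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  truth <- sim$truth
  truth$pop_freq <- NULL  # bulky; frequencies are reproducible from the seed
  jsonlite::write_json(truth, files[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(files)
}
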