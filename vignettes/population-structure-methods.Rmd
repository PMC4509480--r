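---
title: "Methods: fine-scale population structure, F_ST estimation and stratification effects"
author: "finestruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fine-scale population structure, F_ST estimation and stratification effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(finestruct)
```

## Scope and data model

`finestruct` analyses fine-scale population structure in diploid biallelic
SNP genotypes, the setting of regional panels such as the Peninsular
Malaysian/Singaporean Malay samples: a few hundred individuals from named
states grouped into North/Centre/South regions, tens of thousands of
post-QC SNPs, and genome-wide differentiation on the order of F_ST ~ 1e-3.
The central container is the `genotype_dataset`: a samples-by-SNPs matrix of
minor-allele counts (0/1/2, `NA` for missing) plus variant records. The
genotype code counts copies of `allele_b`, fixed dataset-wide as the minor
allele (lexicographic tie-break), matching how published tables report each
SNP by its minor allele. All downstream statistics recompute per-SNP sample
sizes from non-missing genotypes, because the QC policy tolerates up to 10%
missingness rather than requiring complete data.

Input and output use PLINK text PED/MAP; sample metadata
(`sample_id`, `state`, `region`, `latitude`[, `longitude`]) is a delimited
table. A packaged lookup (`state_region_table()`) records the 13 sampled
state locations, their regional assignment, latitudes in decimal degrees
and post-QC subject counts (146/149/107 by region). The source table prints
one subject count spanning its first three northern states and repeats one
latitude; the lookup records both as printed and leaves the two
indeterminate counts `NA`.

## Quality control

`run_qc()` applies, in order: sample missingness, SNP missingness, minor
allele frequency, an exact Hardy-Weinberg test, and LD pruning. Thresholds
default to the assembly rules of merged array panels — missingness > 0.10
(strictly) removes, MAF < 0.05 (strictly) removes, HWE p < 0.002 (strictly)
removes, pairwise genotype r² > 0.8 (strictly) prunes. Boundary cases sit
on the retained side by construction because the rules are stated as strict
inequalities in the direction of removal.

The Hardy-Weinberg test is the exact conditional test: given the allele
counts, heterozygote counts follow a hypergeometric-type distribution, and
the two-sided p-value sums the probabilities of all heterozygote counts
whose conditional probability does not exceed the observed one
(probability-mass ordering, no mid-p). It is computed by the stable ratio
recurrence over admissible heterozygote counts; the test suite checks it
against an independent log-factorial enumeration to 12 decimal places,
exhaustively for n ≤ 40 and on seeded random tables with counts up to 200.
Whether the original assembly used the exact or chi-square version is not
stated anywhere authoritative; the exact test is the PLINK-era default and
is what we implement.

LD pruning is windowed and greedy: a window of `ld_window` SNPs (default
50) advances by `ld_step` (default 5); within a window, while any surviving
pair exceeds r² = 0.8, the largest-r² pair is resolved by dropping its
lower-MAF member (ties: the later position). Only the r² threshold is given
by the assembly description; window/step follow the de facto convention and
are configurable. Windows never straddle chromosome boundaries. The
procedure is deterministic and idempotent, and `run_qc()`'s report carries
per-stage removal accounting so the chain's arithmetic can be audited.

## PCA

Standardization is the Patterson convention: center each SNP at its mean
genotype, scale by `sqrt(p(1-p))` with the shrunk estimate
`p = (1 + count_b) / (2 + 2n)`, impute missing entries to the column mean
(zero after centering), and drop constant SNPs. Scores are eigenvectors of
the sample-by-sample covariance of the standardized matrix, PC1 first. An
eigenvector's sign is arbitrary, so each PC is oriented to make its
largest-magnitude entry positive; tests and downstream correlations either
rely on this fixed convention or compare absolute values.

Iterative outlier removal (`detect_outliers()`, 6 SD on any top PC,
refitting after each removal) is available but disabled by default: the
motivating analysis excluded "several outliers" without stating a rule, so
our rule is an explicit stand-in an analyst must opt into.

## F_ST: variance components, ratio of sums, SNP bootstrap

Per SNP, differentiation between two populations is estimated by the
Weir–Cockerham variance components a (between populations), b (between
individuals within populations) and c (within individuals), with
θ = a/(a+b+c); the two-population form is the special case that the
Weir–Hill generalization reduces to at r = 2. Heterozygosity enters through
the observed heterozygote counts when genotypes are available; when only
allele frequencies are known (as in printed tables),
`allele_counts_from_freq()` substitutes the Hardy-Weinberg expectation
2np(1−p). With regional sizes 146/107 and frequencies oriented to a common
allele (a region's printed MAF refers to its own minor allele, so the
southern frequency is the complement of its printed MAF when the regions'
minor alleles differ), this reproduces the two published worked values
0.2256 and 0.2037 to within ±0.005 — the check in the acceptance suite.
A ratio-of-averages (Hudson-style) estimator does not reproduce them, which
is why the variance-components form with HWE-expected heterozygosity is the
default here.

The genome-wide estimate combines per-SNP components as Σa / Σ(a+b+c)
(ratio of sums), not as a mean of per-SNP ratios: near F = 0 the per-SNP
ratios are wildly unstable and their mean is badly biased. Negative
estimates are reported unclipped — an unbiased estimator must be allowed to
go negative for true F near 1e-3, and clipping would bias the regional
comparisons upward.

Confidence intervals come from a SNP bootstrap (default 1,000 replicates):
the sampled individuals are treated as fixed and L SNPs are redrawn with
replacement, each replicate re-forming the ratio of sums; the CI is the
2.5/97.5 percentile of the replicates. An individual-level bootstrap is
available behind `unit = "individual"` for sensitivity analysis. The
parenthetical "CI =" values printed next to the published pairwise
estimates are orders of magnitude smaller than any plausible interval
width; we make no attempt to reproduce them and report percentile bounds
and the bootstrap SE instead.

`top_differentiated()` ranks SNPs by θ with two cut modes: a top-fraction
cut that includes all SNPs tied with the boundary value, and a strict
absolute threshold (θ > 0.05 reproduces the published top-SNP table from
the packaged fixture). `minor_allele_discordance()` counts SNPs whose
within-group minor allele differs between groups, resolving exact 0.5
frequencies to `allele_b`.

## Admixture by EM

Ancestry proportions follow the standard binomial admixture likelihood:
each of an individual's two allele copies at SNP j carries allele_b with
probability Σ_k q_ik f_kj. We fit by plain EM (the FRAPPE-style updates):
allele copies are attributed to components by Bayes' rule, Q rows become
normalized expected ancestry counts, F the ratio of expected allele_b
counts to expected totals. EM is monotone in the log-likelihood — asserted
at every iteration in the tests — which the quasi-Newton acceleration of
the standalone tool is not; at the package's scale (hundreds of samples,
thousands of SNPs) the simplicity is worth more than the speed. Q is
initialized Dirichlet(1), F Uniform(0.05, 0.95), with 3 random restarts by
default (best log-likelihood kept) to mitigate local optima; convergence is
declared when the log-likelihood gain drops below `tol` (default 1e-6).
Probabilities are clamped to [1e-10, 1−1e-10] before logs. Label switching
is resolved in analysis (not in the fitter) by `align_components()`, which
searches component permutations for the best mean absolute agreement with a
reference.

Per-region component means are compared with a two-sided Welch two-sample
test (`compare_components_by_region()`); the test behind the published
north/south contrast is unnamed, and Welch is the conservative default for
unequal variances. Region averages are per-sample means of Q, the natural
reading of "average ancestry per region".

## Geography

`pc_vs_latitude()` correlates PC scores with a coordinate axis. The default
analysis unit is the state mean — a dozen points, matching the
few-populations regime in which the published latitude correlation
(R² ≈ 0.39 at P = 0.029) was computed; per-sample mode is available. Note a
property of the state-mean unit: with 13 points the *null* expectation of
r² is 1/(n−1) ≈ 0.083, so "no correlation" at state resolution still shows
r² near 0.08 on average; null-axis checks in the acceptance suite therefore
use per-sample resolution, where the null expectation is ~0.004. Pearson's
r and the two-sided t-transform p-value (n−2 df) are computed directly and
cross-checked against `cor.test` in the tests.

Distances are haversine on a spherical Earth of radius 6371.0 km (sub-0.5%
error at peninsular scale), delegated to `geosphere`. `fst_vs_distance()`
correlates pairwise F_ST with pairwise distance by simple Pearson over the
unordered pairs — reproducing the published analysis form — and reports a
Mantel permutation p alongside (via `vegan`), because pairs sharing a
population are not independent and the parametric p is anti-conservative;
the Mantel companion is reported, never silently substituted.

## Synthetic data: what it emulates and what it does not

`simulate_balding_nichols()` draws, per SNP, an ancestral frequency
p ~ Uniform(0.05, 0.5) (the post-QC MAF spectrum) and per-subpopulation
frequencies Beta(p(1−F)/F, (1−p)(1−F)/F), whose variance is exactly
F·p(1−p) — the estimand of the Weir–Cockerham estimator — then genotypes
Binomial(2, p_k). Defaults emulate the study regime: subpopulation sizes
146/149/107, 41,400 SNPs, F in the 6e-4 to 1.1e-3 range. One global seed
drives everything; substream seeds are derived deterministically so a
multi-stage simulation is reproducible stage by stage.

`simulate_cline()` adds a deterministic frequency shift
slope·(latitude − mean latitude) per deme, clipped to [0.01, 0.99], with
one deme per packaged state by default. The default effect size
(slope 0.012 per degree, F = 5e-4, 20 samples per deme, 3,000 SNPs) was
chosen once as a regime in which the latitudinal gradient, not drift,
dominates PC1 — the regime the cline analysis is designed to detect; with
~5 degrees of latitude span this is a ±3% frequency shift, comparable to
documented continental clines. Under it, the state-mean PC1–latitude
correlation is significant in essentially every seeded run.

`simulate_case_control()` samples each case's subpopulation from the case
mixing fractions and each control's from the control fractions; unequal
fractions are what create stratification. Disease status follows a
multiplicative per-allele odds model at configured causal SNPs
(probability `prevalence · Π RR^g`, capped at 1) with rejection sampling
until both arms fill, and an explicit error after bounded attempts when the
prevalence is incompatible with the requested arm sizes. With no causal
SNPs the acceptance probability is genotype-free and the arms are filled
directly. The exact scenario grid of the original simulation study is not
publicly printed; scenario defaults (41,400 null SNPs, 1,000/1,000 arms,
F = 0.001 mirroring the observed north–south differentiation,
α ∈ {0.05, 1e-4}) are documented stand-ins, and every parameter is
configurable.

None of the generators model linkage disequilibrium, relatedness, sex
chromosomes or genotyping batch effects. Passing tests therefore
demonstrate correctness of the estimators and the direction and rough
magnitude of stratification effects under independent-SNP mixtures — not
robustness to LD structure or cryptic relatedness in real panels.

## Association testing and genomic control

The default per-SNP test is the 1-df allelic chi-square on the 2×2
case/control allele table (the era-typical case-control default); the
Cochran–Armitage trend test with additive weights is available. The two
coincide exactly when the pooled genotype counts sit at Hardy-Weinberg
proportions (the identity is about the pooled sample, not the two groups
separately — the tests verify the correct pooled-HWE form of the identity).
Zero-margin tables are flagged untestable with p = 1 rather than dropped,
so false-positive denominators stay honest. Genomic control uses
λ = median(χ²)/0.4549 (the 1-df null median to four decimals, fixed in
code), floored at 1 for adjustment so deflation is never manufactured.

`run_gwas_simulation()` ties the pieces together: per replicate it
simulates a scenario, tests every SNP, and accumulates the false-positive
rate over null SNPs and power over causal SNPs at each α, plus λ_GC from
null statistics. The published simulation study reports only that
stratification effects were "greater than expected", so the package's
checks are property-based: a calibrated null (FPR ≈ α, λ ≈ 1), inflation
under imbalance (FPR > α, λ > 1, both increasing with imbalance and F),
and restoration by genomic control. Genomic control is slightly
conservative under strong inflation (λ ≈ 4 scenarios adjust to FPR ≈ 0.048
rather than 0.050), which is the expected behaviour of median scaling, not
an artifact.

## Numerical choices and problem sizes

Tolerances: EM stops on log-likelihood gain < 1e-6 (tests use 1e-5 with an
iteration cap); admixture probabilities clamp at 1e-10; HWE tie comparison
uses a 1 + 1e-12 relative guard, standard for probability-mass-ordering
exact tests. Undefined LD r² (constant column on the pairwise-complete
subset) is treated as 0 for pruning decisions, i.e. uninformative pairs are
never pruned on. Degenerate F_ST sites (both groups fixed for the same
allele) report zero components and missing θ, and are excluded from the
genome-wide sums along with any SNP lacking two genotyped individuals per
group.

Problem sizes in the tests and acceptance script are the package's choices
for a thorough-but-quick desk run: genome-wide recovery at the full
41,400-SNP scale; bootstrap calibration at L = 5,000 over 100 runs;
stratification scenarios at 20,000 SNPs; admixture recovery at
F = 0.1, 100 samples, 2,000 SNPs (the strong-differentiation regime where
the ancestry labels are identifiable — at F ~ 1e-3 the components are
intentionally weakly identified, as `analysis/05_admixture.R` demonstrates);
cline detection over 20 seeds at the default generator settings.

## Known limitations

Two-population variance components only (regional pairs are analysed
pairwise; no joint r > 2 θ). No LD-aware simulation. The EM fitter has no
cross-validation for choosing K, no supervised mode, and no acceleration.
Association testing has no covariate adjustment (no logistic PC-corrected
model); genomic control is included precisely because it is the simplest
post-hoc correction whose behaviour under the simulated stratification can
be verified end to end.
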