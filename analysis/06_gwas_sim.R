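#!/usr/bin/env Rscript
# Effect of population stratification on case-control association:
# a calibrated unstratified null versus an ancestry-imbalanced scenario,
# with genomic-control correction. Scaled to 10,000 SNPs per scenario.

suppressPackageStartupMessages(library(finestruct))
dir.create("results", showWarnings = FALSE)

scenarios <- list(
  null = case_control_config(n_cases = 1000, n_controls = 1000,
                             n_snps = 10000, fst_true = 0.001, seed = 31),
  stratified = case_control_config(n_cases = 1000, n_controls = 1000,
                                   case_pop_fractions = c(0.7, 0.3),
                                   control_pop_fractions = c(0.3, 0.7),
                                   n_snps = 10000, fst_true = 0.01, seed = 32))

summary_rows <- list()
for (name in names(scenarios)) {
  sim <- simulate_case_control(scenarios[[name]])
  scan <- association_scan(sim$dataset, sim$phenotype)
  gc <- genomic_control(scan$chi_square)
  row <- data.frame(scenario = name,
                    fpr_alpha05 = mean(scan$p_value < 0.05),
                    fpr_alpha1e4 = mean(scan$p_value < 1e-4),
                    lambda_gc = gc$lambda,
                    fpr_alpha05_gc_adjusted = mean(gc$p_adjusted < 0.05))
  summary_rows[[name]] <- row
  print(row, row.names = FALSE)
}
out <- do.call(rbind, summary_rows)
write.table(out, "results/gwas_sim_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nstratification inflates the false-positive rate by",
    sprintf("%.1fx", out$fpr_alpha05[2] / out$fpr_alpha05[1]),
    "at alpha = 0.05; genomic control brings it back to",
    sprintf("%.3f", out$fpr_alpha05_gc_adjusted[2]), "\n")
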