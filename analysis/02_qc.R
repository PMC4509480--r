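#!/usr/bin/env Rscript
# Quality control of the simulated regional panel: sample/SNP missingness,
# MAF floor, exact Hardy-Weinberg test, LD pruning. Mirrors the filter chain
# used to assemble merged array datasets (thresholds: >10% missingness,
# MAF < 0.05, HWE p < 0.002, r^2 > 0.8).

suppressPackageStartupMessages(library(finestruct))
ds <- read_ped_map("results/sim/regional.ped", "results/sim/regional.map")
res <- run_qc(ds, qc_params())
write.table(res$report, "results/qc_report.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_ped_map(res$dataset, "results/sim/regional_qc.ped",
              "results/sim/regional_qc.map")
print(res$report, row.names = FALSE)
cat("post-QC:", n_samples(res$dataset), "samples x",
    n_variants(res$dataset), "SNPs\n")
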