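#!/usr/bin/env Rscript
# Generate the synthetic study datasets used by the downstream analysis
# scripts: a two-region genotype panel at the north-south differentiation
# magnitude, and a latitudinal-cline panel over the packaged state
# coordinates. Writes PED/MAP + metadata + truth JSON under results/sim/.

suppressPackageStartupMessages(library(finestruct))
seed <- 2024
dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)

# regional two-population panel: the genome-wide differentiation magnitude
# between the northern (n=146) and southern (n=107) regional samples,
# scaled to 8,000 SNPs so every later step runs in seconds
bn <- simulate_balding_nichols(
  bn_config(n_per_pop = c(146, 107), n_snps = 8000, fst_true = 0.00111661,
            missing_rate = 0.02, seed = seed))
write_simulation(bn, "results/sim/regional")
md <- data.frame(sample_id = bn$dataset$samples,
                 state = ifelse(bn$pop_labels == "pop1", "North-state", "South-state"),
                 region = ifelse(bn$pop_labels == "pop1", "North", "South"),
                 latitude = ifelse(bn$pop_labels == "pop1", 5.5, 1.5))
write.table(md, "results/sim/regional_metadata.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("regional panel:", n_samples(bn$dataset), "samples x",
    n_variants(bn$dataset), "SNPs\n")

# latitudinal cline over the 13 packaged state locations
cline <- simulate_cline(cline_config(n_snps = 3000, seed = seed + 1))
write_simulation(cline, "results/sim/cline")
cat("cline panel:", n_samples(cline$dataset), "samples across",
    length(unique(cline$metadata$state)), "states\n")
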