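#!/usr/bin/env Rscript
# Phase the simulated genome into its two subgenomes from differential
# 13-mers (genome-wide count > 100, >= 2-fold enriched within a
# homoeologous chromosome pair) and compare the partition against the
# generator's truth.

suppressPackageStartupMessages(library(subgenomics))

truth <- read_truth("results/sim/truth.json")
rep <- phase_subgenomes("results/sim/genome.fa",
                        truth$homoeolog_chromosome_pairs,
                        phasing_params(k = 13, min_total_count = 100,
                                       min_fold = 2),
                        outdir = "results/phase")

asg <- setNames(rep$assignment$subgenome, rep$assignment$chrom)
truth_lab <- truth$subgenome_of_chromosome
agree <- mean(asg[names(truth_lab)] == truth_lab)
cat("Differential 13-mers selected:", rep$n_kmers, "\n")
cat("Assignment sizes:", paste(names(table(asg)), table(asg),
                               collapse = ", "), "\n")
cat("Agreement with truth (up to label swap):",
    max(agree, 1 - agree), "\n")
cat("Outputs: ", rep$files$assignment, ",", rep$files$z_matrix, "\n")
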