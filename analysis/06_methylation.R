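#!/usr/bin/env Rscript
# Methylation analysis: per-cytosine binomial calls, gene-body binomial
# tests against the genome-wide background, selection of CG
# body-methylated homoeologous pairs, regional metaprofiles, and the
# DmCG/C epimutation rate compared with Ks.

suppressPackageStartupMessages(library(subgenomics))

truth <- read_truth("results/sim/truth.json")
cx <- read_cx("results/sim/cytosines.tsv")
called <- call_sites(cx, p_err = 0.01)
bg <- methylation_background(called)
cat("Genome-wide methylated-site proportions:",
    paste(names(bg), signif(bg, 3), collapse = ", "), "\n")

genes <- read_gff_genes("results/sim/genes.gff3")
stats <- gene_methylation_stats(called, genes)
dir.create("results", showWarnings = FALSE)
write_tsv_c(as.data.frame(stats), "results/gene_methylation_stats.tsv",
            "per-gene per-context methylation statistics with binomial tail P")

kept <- select_body_methylated_pairs(stats, truth$homoeolog_pairs)
cat("CG body-methylated homoeologous pairs:", nrow(kept), "of",
    nrow(truth$homoeolog_pairs), "\n")

mp <- metaprofile(cx, genes)
write_tsv_c(as.data.frame(mp$profile), "results/metaprofile.tsv",
            "methylation metaprofile: mean level per context/region/bin")
pr <- mp$profile[mp$profile$context == "CG", ]
cat(sprintf("CG level upstream/body/downstream: %.2f / %.2f / %.2f\n",
            mean(pr$level[pr$region == "upstream"]),
            mean(pr$level[pr$region == "body"]),
            mean(pr$level[pr$region == "downstream"])))

# DmCG/C vs Ks on the CDS pairs, with an elevated epimutation rate
calls_cg <- simulate_pair_cg_calls("results/sim/cds_A.fa",
                                   "results/sim/cds_B.fa", truth,
                                   epi_factor = 5, seed = 42L)
sa <- Biostrings::readDNAStringSet("results/sim/cds_A.fa")
sb <- Biostrings::readDNAStringSet("results/sim/cds_B.fa")
pr2 <- truth$homoeolog_pairs
dm <- vapply(seq_len(nrow(pr2)), function(i) {
  ca <- calls_cg[calls_cg$gene == pr2$gene_A[i], ]
  cb <- calls_cg[calls_cg$gene == pr2$gene_B[i], ]
  if (!nrow(ca)) return(NA_real_)
  dmcg_rate(as.character(sa[[pr2$gene_A[i]]]),
            as.character(sb[[pr2$gene_B[i]]]), ca, cb)$dm
}, 0)
cmp <- compare_dm_vs_ks(dm[!is.na(dm)], unname(truth$true_ks))
cat(sprintf("DmCG/C vs Ks: median %.3f vs %.3f, direction '%s', p = %.3g\n",
            cmp$median_dm, cmp$median_ks, cmp$direction, cmp$p))
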