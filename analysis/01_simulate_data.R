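#!/usr/bin/env Rscript

# Stage 1: generate the emulated study dataset.
#
# Produces a 15-block 2x2 reciprocal-cross design (120 offspring), NB
# counts with planted ancestry / parent-of-origin / sex / batch / family
# effects, and pedigree-structured genotypes, then writes them under
# results/data/ in the plain formats the rest of the workflow reads.

suppressPackageStartupMessages(library(reciprocross))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

design <- simulate_design(15, seed = seed)
cfg <- sim_config()
sim <- simulate_counts(cfg, design, seed = seed + 1)
geno <- simulate_genotypes(cfg, design, n_loci = 10000, seed = seed + 2)

write_metadata(design, "results/data/meta.tsv")
write_counts(sim$counts, "results/data/counts.tsv")
write.table(sim$truth, "results/data/truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write_genotypes_vcf(geno$genotypes, "results/data/genotypes.vcf")

cat(sprintf("design: %d offspring (%d F / %d M), %d per cross type\n",
            nrow(design), sum(design$sex == "F"), sum(design$sex == "M"),
            sum(design$cross == "HH")))
cat(sprintf("counts: %d genes x %d samples; planted %d ancestry (%.0f%% up), %d maternal, %d paternal, %d sex genes\n",
            nrow(sim$counts), ncol(sim$counts), cfg$n_ancestry_genes,
            100 * cfg$up_fraction, cfg$n_maternal_genes,
            cfg$n_paternal_genes, cfg$n_sex_genes))
cat(sprintf("genotypes: %d loci for %d offspring written as VCF\n",
            ncol(geno$genotypes), nrow(geno$genotypes)))
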