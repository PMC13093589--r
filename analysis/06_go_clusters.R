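#!/usr/bin/env Rscript

# Stage 6: GO-term summarization.
#
# In the full workflow the input is the tabular export of an external
# semantic-similarity reduction of the DEG GO terms (term, DEG occurrence
# count, 2-D semantic coordinates).  That reduction needs the GO graph, so
# this driver builds a synthetic term map with the same schema: nine
# semantic neighbourhoods of GO-style biological-process terms.  The knee
# rule picks the cluster count, k-means assigns terms, and each cluster is
# named by its most widely shared term and labelled by word frequency.

suppressPackageStartupMessages(library(reciprocross))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[1]) else 1L

themes <- list(
  c("anatomical structure development", "cellular developmental process",
    "cell differentiation", "animal organ development", "tissue development",
    "muscle structure development", "epithelium development",
    "animal organ morphogenesis"),
  c("multicellular organism development", "system development",
    "nervous system development", "embryo development", "neuron development",
    "skeletal system development", "pattern specification process",
    "tube development"),
  c("behavior", "locomotory behavior", "adult locomotory behavior",
    "system process", "muscle system process", "muscle contraction",
    "blood circulation", "circulatory system process"),
  c("organelle organization", "cytoskeleton organization",
    "membrane organization", "mitochondrion organization",
    "organelle assembly", "cellular component biogenesis",
    "actin cytoskeleton organization", "cell projection organization"),
  c("response to chemical", "response to stress", "response to external stimulus",
    "cellular response to stimulus", "response to organic substance",
    "signal transduction", "response to abiotic stimulus",
    "response to endogenous stimulus"),
  c("transport", "cellular localization", "macromolecule localization",
    "organic substance transport", "transmembrane transport",
    "vesicle-mediated transport", "intracellular transport",
    "nitrogen compound transport"),
  c("negative regulation of response to stimulus",
    "regulation of response to stress",
    "negative regulation of signaling", "regulation of defense response",
    "positive regulation of response to stimulus",
    "negative regulation of cell communication",
    "positive regulation of signaling", "regulation of MAPK cascade"),
  c("regulation of multicellular organismal development",
    "regulation of developmental growth", "regulation of system process",
    "regulation of neuron differentiation",
    "negative regulation of developmental process",
    "regulation of muscle system process", "regulation of cell morphogenesis",
    "regulation of muscle organ development"),
  c("cellular metabolic process", "primary metabolic process",
    "organic substance metabolic process", "protein metabolic process",
    "macromolecule metabolic process", "biosynthetic process",
    "nitrogen compound metabolic process",
    "organonitrogen compound metabolic process")
)

terms <- withr::with_seed(seed + 20, {
  centers <- as.matrix(expand.grid(c(-6, 0, 6), c(-6, 0, 6)))
  do.call(rbind, lapply(seq_along(themes), function(i) {
    nm <- themes[[i]]
    data.frame(
      go_id = sprintf("GO:%07d", i * 1000 + seq_along(nm)),
      name = nm,
      count = sort(pmax(1, rnbinom(length(nm), mu = 20, size = 2)),
                   decreasing = TRUE),
      pc1 = rnorm(length(nm), centers[i, 1], 0.5),
      pc2 = rnorm(length(nm), centers[i, 2], 0.5),
      stringsAsFactors = FALSE
    )
  }))
})
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
write.table(terms, "results/data/go_terms_synthetic.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
terms <- read_terms("results/data/go_terms_synthetic.tsv")

k <- choose_k(as.matrix(terms[, c("pc1", "pc2")]), 1:15, seed = seed + 21)
cat(sprintf("knee rule chooses k = %d clusters\n", k))

sol <- cluster_terms(terms, k, seed = seed + 22)
write.table(sol$assignments, "results/go_term_clusters.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sol$clusters, "results/go_cluster_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("clusters named by their most widely shared term:\n")
for (i in seq_len(nrow(sol$clusters))) {
  cat(sprintf("  #%d (%d terms): %s [dominant word: %s]\n",
              sol$clusters$cluster[i], sol$clusters$n_terms[i],
              sol$clusters$name[i], sol$clusters$dominant_word[i]))
}
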