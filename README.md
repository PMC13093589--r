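# reciprocross

Analysis toolkit for 2x2 reciprocal-cross RNA-seq experiments that ask
whether a single generation of captive (hatchery) breeding leaves a
heritable mark on offspring gene expression.

## The problem and who this is for

Conservation hatcheries breed wild-caught fish for one generation and
release the offspring.  If adaptation to captivity is fast, the
offspring of two hatchery-reared (H) parents should express hundreds of
genes differently from the offspring of two natural-origin (N) parents,
even when both are reared in a common environment.  A 2x2 reciprocal
cross — every block mates an H and an N female to an H and an N male,
giving HH, HN, NH and NN families (mother first) — separates a heritable
ancestry response from maternal/paternal carry-over and from family
noise: under additive inheritance the reciprocal crosses sit midway
between the pure crosses, while a maternal effect makes offspring track
their mother's origin.

The package is aimed at molecular ecologists running (or simulating)
such designs.  It provides, as plain R functions over matrices and data
frames:

* a **design/count/genotype simulator** with planted ancestry,
  maternal, paternal, sex, batch and family effects and a truth table
  (`simulate_design`, `sim_config`, `simulate_counts`,
  `simulate_genotypes`);
* **negative-binomial differential expression**: median-of-ratios size
  factors, trend-shrunk moment dispersions, an IRLS Wald GLM (C++
  core), BH-FDR, and a design-corrected sibling-correlation estimator
  (`run_de`, `fit_nb_glm`, `sibling_correlation`);
* the **randomization nulls**: a constrained ancestry-gradient reshuffle
  and a conservative label permutation with add-one empirical p-values
  (`ancestry_gradient`, `null_permutation`);
* the **inheritance-mode decomposition** scoring each DEG as additive,
  maternal, paternal or ambiguous from its cross-type means
  (`standardized_log_means`, `classify_mode`, `direction_bias_test`);
* **popgen checks** from VCF genotypes: missingness/MAF filters,
  KING-robust kinship, Weir-Cockerham FST (`filter_genotypes`,
  `king_kinship`, `mean_fst`);
* **GO-term summarization** of a semantic map: log-scale knee rule,
  seeded k-means, cluster naming and word-frequency labels
  (`choose_k`, `cluster_terms`, `word_labels`).

The core statistic throughout is the per-gene NB Wald test
`z = beta / SE(beta)` on the group coefficient of
`~ cross_date + sex + group` with gene dispersion `alpha` fixed at its
moderated moment estimate, and DEGs called at BH-adjusted p < 0.05.

## Worked example: the analysis workflow

The `analysis/` directory holds six numbered drivers that run the whole
chain on a simulated 15-block study (120 offspring, 2000 genes, 10,000
SNPs), writing tables under `results/`:

```sh
Rscript analysis/01_simulate_data.R 1        # design + counts + VCF
Rscript analysis/02_differential_expression.R
Rscript analysis/03_randomization_tests.R 1
Rscript analysis/04_inheritance_modes.R
Rscript analysis/05_relatedness_fst.R
Rscript analysis/06_go_clusters.R 1
```

Output of stage 2 on seed 1:

```
HH vs NN: 408 DEGs at FDR 0.05 (233 up in HH, 175 up in NN)
HN vs NH (equal ancestry): 6 DEGs
F vs M: 4 DEGs
sibling correlation consensus: 0.130 (design-induced null -0.054 already removed)
```

The pure-cross contrast finds hundreds of genes while the
equal-ancestry reciprocal contrast finds almost none — the signature of
a heritable ancestry response rather than batch or family artefacts.
Stage 3 confirms it against the randomization nulls:

```
observed 408 DEGs (233 up); permutation p (total) = 0.0050, p (up) = 0.0050 over 200 shuffles
```

and the gradient table shows mean DEG counts rising from 0.4 (one
pure-cross fish per group) to 408 (the empirical split).  Stage 4
decomposes the DEGs — `90.4% additive, 2.9% maternal, 3.7% paternal` —
and stage 5 rules out relatedness and stock structure
(`mean full-sib kinship 0.249`, `FST(HH, NN) = 0.0089`).

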