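---
title: "Models and methods for reciprocal-cross differential expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for reciprocal-cross differential expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reciprocross)
```

## The scientific question and the design

When a wild fish spends a single generation in a hatchery, do its
offspring inherit a changed transcriptome?  The design this package
analyses answers that with a 2x2 reciprocal-cross layout: each crossing
block mates one first-generation hatchery (H) female and one
natural-origin (N) female to one H male and one N male, producing all
four cross types — HH, HN, NH, NN, with the mother's origin written
first.  Fifteen independent blocks, each contributing one family per
cross type and two sequenced offspring (one female, one male) per
family, give 120 offspring reared in a common environment.

The layout separates three explanations for an HH-vs-NN expression
difference that are confounded in a simple two-group comparison:

* a *heritable ancestry* response scales with the number of hatchery
  parents, so the reciprocal crosses (one hatchery parent each) sit
  midway between the pure crosses;
* a *maternal* (or paternal) carry-over effect tracks one parent's
  environment, so offspring sharing a mother's origin match each other;
* *family or batch noise* shows up as often between the equal-ancestry
  reciprocal crosses as between the pure crosses.

## The count model

`simulate_counts()` draws gene *g*, sample *j* as negative binomial with
gene dispersion $\alpha_g$ (variance $\mu + \alpha\mu^2$) and

$$\log_2 \mu_{gj} = b_g + \log_2 s_j + \beta_g a_j + m_g\,[\text{mother}=H]
 + p_g\,[\text{father}=H] + s_g\,[\text{sex}=F] + d_{g,\mathrm{date}(j)}
 + u_{g,\mathrm{fam}(j)}$$

with ancestry dose $a_j \in \{0, \tfrac12, 1\}$ (the number of hatchery
parents over two), so planted ancestry genes are additive by
construction and heterozygous crosses sit at the midpoint.  The same
generator writes a truth table so every downstream stage can be scored
as a recovery problem.

Key defaults and why:

* **2000 genes, 15 blocks** — the simulated panel is deliberately small
  so the full randomization stages run in seconds; the study-scale
  transcriptome is ~25x larger.
* **300 ancestry genes, |log2 effect| = 2, 75% upregulated in HH** —
  hundreds of responsive genes with a strong bias toward upregulation in
  hatchery-ancestry offspring is the empirical pattern the design
  targets.
* **3 maternal + 2 paternal genes** — contrasts of the reciprocal
  crosses in this system find essentially nothing (five genes), so the
  faithful default plants essentially nothing; recovery tests pass
  larger explicit configurations.
* **4 sex genes** — swim-up fry barely differ by sex.
* **family_sd = 0.195** — calibrated so the sibling-correlation
  estimator below recovers ~0.13, the weak within-family correlation
  that justifies a fixed-effects analysis.
* **dispersion ~ Gamma(shape 2, mean 0.15), baseline log2 expression ~
  N(7, 1.5), library factors ~ lognormal (0.25 log2 sd)** — no
  empirical estimates of these exist for this system at swim-up stage;
  they are documented choices in the typical bulk RNA-seq range, not
  fits.

Genotypes come from an explicit pedigree: per block, four parents drawn
from pool allele frequencies, Mendelian transmission to each offspring.
Full sibs share two parents (kinship 0.25), families within a block
share exactly one (0.125).  The hatchery/natural pools differ by a small
frequency shift (default 0.015).  Note a design-level subtlety: the
measured Weir–Cockerham $\theta$ between the two *family-structured*
offspring groups is the pool-level differentiation **plus** ~0.008 of
pedigree co-ancestry (each group descends from only 30 founders), so the
default shift places the measured total near 0.0087 — the weak
differentiation expected within one population, far below what
introgression from another stock would produce.

## Differential expression

The DE stage is written in-house (IRLS core in C++) because the
randomization stages call it thousands of times and every component is
verified against an independent oracle in the test suite.  It is a
standard NB pipeline:

1. **Size factors**: median-of-ratios to the per-gene geometric mean,
   rescaled to geometric mean 1.  Exact agreement with a brute-force
   transcription is a test.
2. **Dispersion**: method-of-moments $(s^2 - \bar\mu)/\bar\mu^2$ on
   normalized counts within covariate cells (all samples sharing cross
   date, sex and contrast group), pooled by degrees of freedom.  Raw
   per-gene moment estimates at ~44 df are noisy, and because the Wald
   tail is convex in an underestimated dispersion that noise inflates
   the false-positive rate (measured ~6.1% at nominal 5%); estimates are
   therefore shrunk toward a mean-expression trend (20%-trimmed bin
   means) with 10 prior degrees of freedom, the conventional
   moderated-dispersion default, restoring ~5.5%.  `shrink = FALSE`
   recovers the raw estimator.
3. **GLM**: log-link NB with fixed $\alpha_g$, log size factors as
   offsets, IRLS with expected-information weights, at most 50
   iterations, relative deviance tolerance 1e-8.  Non-converged or
   all-zero genes are flagged, excluded from FDR adjustment, and
   counted.  In the small-dispersion large-count limit the Wald p-value
   matches a Poisson GLM to 1e-6 (a test).
4. **Wald test**: contrast coefficient over its expected-information
   standard error, standard-normal p, Benjamini–Hochberg FDR, DEG call
   at adjusted p < 0.05.  Positive log2 fold change means higher in the
   first group (`run_de(counts, meta, "HH", "NN")` reports upregulation
   in HH as positive; published tables that use NN as the reference
   level are the sign mirror of this).

No independent filtering and no fold-change shrinkage are applied: both
change DEG counts in ways that are hard to reason about inside
permutation loops, and the randomization stages need the plain
statistic.

**Sibling correlation.**  Each family contributes two siblings, so
samples are not strictly independent.  Rather than fit a random-effects
model, the pipeline reports the consensus within-family correlation of
covariate-residualized log normalized counts (inverse Fisher-z of the
10%-trimmed mean of per-gene z values).  One correction matters:
projecting out covariates that siblings share (cross type, cross date)
makes their residuals negatively correlated by the hat-matrix term
$-H_{ij}/\sqrt{(1-H_{ii})(1-H_{jj})}$ — about −0.056 for this design —
even for independent data.  That design-determined null value is
subtracted on the z scale; without the correction the estimator is
biased low by ~0.06.  At the calibrated family effect the estimator
returns ~0.13, small enough that the fixed-effects analysis is a
reasonable approximation (its main cost is a mild anticonservativeness
of the pure-cross contrast, visible in the simulations as extra false
positives when family effects are on).

## Randomization procedures

Two reshuffling designs ask whether the observed DEG count could arise
without ancestry driving it.  Samples are canonically sorted by id
before any draw, so a seed gives the same partitions regardless of input
row order.

**Ancestry gradient.**  For each constraint N, two groups of 30 are
built: one with exactly N HH offspring and no NN, the other with exactly
N NN and no HH, remainders drawn from the pooled reciprocal-cross
offspring *without* replacement (a with-replacement variant is
available behind a flag, matching a published figure caption that
disagrees with its own methods text; the methods text wins by default).
The DE model inside each reshuffle keeps the cross-date and sex
covariates (whether the original analysis did is unstated; a flag drops
them).  At the maximum N the partition *is* the empirical pure-cross
contrast, so all replicates coincide and the percentile 95% CI (2.5th
to 97.5th percentile — the CI method is our choice) has zero width;
the pipeline asserts that equality exactly.

**Conservative permutation.**  The 60 pure-cross offspring are shuffled
into two groups of 30 ignoring ancestry; the empirical p-value for the
observed DEG count (and for its upregulated count) is
$(1 + \#\{\text{replicates} \ge \text{observed}\})/(R + 1)$.  The
add-one convention keeps the p-value valid and never zero; the plain
$\#/R$ convention is a flag.  One calibration subtlety: under a true
null the FDR-scale DEG count is almost surely zero, so its permutation
p piles up at 1 — valid but uninformative.  Calibration checks therefore
use the raw-p discovery count (`threshold = "raw"`), which varies
smoothly; its permutation p is uniform to a Kolmogorov–Smirnov check in
the test suite.

## Inheritance-mode decomposition

For each DEG, group means and standard errors of
$\log_2(\text{normalized count} + 1)$ are computed per cross type
(the +1 pseudocount is our choice; zero counts must map somewhere
finite).  Anchored on the observed pure-cross means, each candidate
model predicts the reciprocal-cross pair (HN, NH): additive predicts
(mid, mid); maternal predicts (HH, NN); paternal predicts (NN, HH).
The per-model score is the SE-weighted squared deviation of the
observed pair from the prediction, and the call is the argmin — turning
what is usually a visual argument into a per-gene statistic.  Two
guards produce an `ambiguous` call: the two best scores within 10% of
each other, and an HH–NN contrast below two combined standard errors.
The second guard matters: all three models predict identically when the
pure crosses do not differ, so without it null genes scatter uniformly
across the three modes instead of abstaining (measured: 95% ambiguous
with the guard, 26% spurious "maternal" without).

The direction-bias test is a 1-df goodness-of-fit chi-square of the
up/down DEG split against 50:50, plus the exact binomial p.  For a
290-up / 95-down split this statistic is 98.77; a published value of
125.35 for the same split does not match any standard 1-df computation
we could reconstruct, so the package reports its own formula and leaves
the discrepancy flagged rather than imitating an unknown construction.

The `visual_shift()` helper adds, per gene, the difference between the
gene-set grand HH mean and the gene's HH mean so all genes overlay on a
common anchor in trajectory plots; it changes no within-gene contrast
(asserted exactly in tests).

## Relatedness and differentiation

Genotype filters run in a fixed order — loci missing in >20% of
individuals, then individuals with >20% missing data, then invariant
and MAF < 0.01 loci with frequencies recomputed after the individual
removals — because each stage changes the denominators of the next; a
fixture in the test suite pins the order.  Kinship is the KING-robust
estimator $\phi = (N_{het,het} - 2N_{oppHom})/(N_{het}(i) +
N_{het}(j))$ over loci non-missing in both individuals, using the
summed-heterozygote denominator convention (the variant the common VCF
tooling reports) rather than the min-based within-family variant.  The
self-pair value is 0.5 by algebraic identity, full sibs ~0.25, half
sibs ~0.125; the implementation equals a brute-force per-pair counting
oracle exactly.  Differentiation is two-population Weir–Cockerham
$\theta$ per locus, averaged over loci with defined denominators,
negative values retained (dropping them biases the mean upward).

## GO-term summarization

The package consumes the tabular export of an external
semantic-similarity reduction (term, DEG occurrence count, 2-D semantic
coordinates); computing the reduction itself needs the GO graph and is
out of scope.  Terms are k-means-clustered on the coordinates (10
seeded restarts, best solution by total within-cluster sum of squares,
canonical sort by GO id for determinism).  The cluster count comes from
a knee rule: the WSS curve over candidate k is normalized to the unit
square and the k farthest from the chord joining the endpoints is
chosen — with one twist: the curve is taken on the **log** WSS scale.
On the raw scale the first two or three drops dominate the normalized
range and the chord rule lands on a coarse elbow (k = 4 for nine
well-separated blobs, in our measurements, for both grid and ring
layouts); on the log scale the flattening beyond the true cluster
count — the feature a human reads off an elbow plot — dominates, and
nine blobs yield k = 9.  The rule is scale-invariant either way and is
isolated behind `choose_k()` so it can be swapped.  Each cluster is
named by its member term carried by the most DEGs (count ties broken
alphabetically by GO id) and labelled by its modal word after
lowercasing, whitespace tokenization and removal of a small documented
stop-word list ({of, to, in, the, and, process, regulation} — whether
the original word-frequency labelling excluded function words is
unstated, so the list is our choice).

## What the simulations do and do not show

The generator reproduces the *structure* the inference chain relies on:
a balanced complete design, NB counts with additive ancestry dose,
parent-of-origin patterns, batch and family effects, direction bias,
and pedigree genotypes with weak pool differentiation.  It does not
emulate transcriptome-scale gene counts, correlated co-expression
modules, GC/length biases, isoform structure, or outlier samples — so
green tests certify the machinery (calibration, recovery,
monotonicity, estimator identities), not performance on any real
dataset.

One visible artefact of the small panel: planting 300 one-sided 4-fold
effects in 2000 genes shifts median-of-ratios size factors by ~0.12
log2, which drags null genes toward apparent downregulation in HH and
dilutes the genome-wide up-fraction below the planted 75% even though
the planted ancestry class itself is recovered at exactly 75%.  Real
transcriptomes, where DEGs are ~1% of genes, barely feel this; the
recovery checks therefore score direction on the detected ancestry
class.  Problem sizes used throughout the tests (2000-gene panels, 50
gradient replicates, 100-replicate permutation runs repeated 50 times
at a 500-gene scale) were chosen so the whole suite exercises every
stage at meaningful power in a few minutes.

## Known limitations

* The fixed-effects Wald test ignores the (weak) family correlation;
  with the calibrated family effect the pure-cross contrast runs
  slightly hot, which is why the permutation and gradient nulls — which
  inherit the same bias — are the primary evidence, not the raw DEG
  count.
* The knee rule assumes roughly equal-scale clusters; hierarchically
  structured maps will still draw the knee toward coarse splits.
* The KING estimator's negative values for unrelated pairs are a
  feature of the statistic, not an error; only relative structure is
  interpreted.
* Exact numeric parity with shrinkage-based DE packages is a non-goal;
  the pipeline's claims are calibration and recovery, verified against
  oracles, not replication of any particular tool's output.
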