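## Genotype filtering, KING-robust pairwise kinship and Weir-Cockerham
## FST on 0/1/2-coded biallelic dosage matrices.

#' Filter a genotype matrix
#'
#' Applies, in order: (1) remove loci missing in more than
#' `locus_missing_max` of individuals, (2) remove individuals with more
#' than `indiv_missing_max` missing data on the remaining loci, (3) with
#' allele frequencies recomputed on the remaining individuals, remove
#' invariant loci and loci with minor allele frequency below `maf_min`.
#'
#' @param geno samples x loci matrix (0/1/2/NA).
#' @param locus_missing_max,indiv_missing_max,maf_min thresholds.
#' @return list with `genotypes` (filtered matrix) and `report` (ids and
#'   counts removed at each stage; totals conserve the input dimensions).
#' @export
filter_genotypes <- function(geno, locus_missing_max = 0.20,
                             indiv_missing_max = 0.20, maf_min = 0.01) {
  validate_genotypes(geno)
  n0 <- nrow(geno); l0 <- ncol(geno)

  locus_miss <- colMeans(is.na(geno))
  drop_loci_miss <- colnames(geno)[locus_miss > locus_missing_max]
  geno <- geno[, locus_miss <= locus_missing_max, drop = FALSE]

  indiv_miss <- rowMeans(is.na(geno))
  drop_indiv <- rownames(geno)[indiv_miss > indiv_missing_max]
  indiv_report <- data.frame(sample_id = drop_indiv,
                             missing_fraction = indiv_miss[indiv_miss > indiv_missing_max],
                             row.names = NULL, stringsAsFactors = FALSE)
  geno <- geno[indiv_miss <= indiv_missing_max, , drop = FALSE]

  freq <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(freq, 1 - freq)
  bad_maf <- is.na(maf) | maf < maf_min   # invariant loci have maf 0 < maf_min
  drop_loci_maf <- colnames(geno)[bad_maf]
  geno <- geno[, !bad_maf, drop = FALSE]

  if (ncol(geno) == 0) stop("all loci removed by filtering")
  report <- list(
    loci_removed_missingness = drop_loci_miss,
    individuals_removed = indiv_report,
    loci_removed_maf = drop_loci_maf,
    n_loci_in = l0, n_loci_retained = ncol(geno),
    n_indiv_in = n0, n_indiv_retained = nrow(geno)
  )
  rc_log("filtered genotypes: %d/%d loci, %d/%d individuals retained",
         ncol(geno), l0, nrow(geno), n0)
  list(genotypes = geno, report = report)
}

#' KING-robust pairwise kinship
#'
#' For each ordered pair (i, j), over loci non-missing in both,
#' `phi = (N_het,het - 2 * N_oppHom) / (N_het(i) + N_het(j))`, where
#' `N_het,het` counts loci heterozygous in both, `N_oppHom` counts loci
#' with opposite homozygotes, and `N_het(.)` counts heterozygous loci of
#' each individual restricted to the shared non-missing set (the
#' between-family denominator convention of the `--relatedness2` output).
#' The self-pair value is exactly 0.5 by the estimator's identity; full
#' sibs are near 0.25, half sibs near 0.125.
#'
#' @param geno samples x loci matrix (0/1/2/NA).
#' @return symmetric kinship matrix; pairs without shared informative loci
#'   are `NA` with a warning.
#' @export
king_kinship <- function(geno) {
  validate_genotypes(geno)
  obs <- !is.na(geno)
  g <- geno; g[!obs] <- 0L
  het <- (g == 1L) & obs
  hom0 <- (g == 0L) & obs
  hom2 <- (g == 2L) & obs
  mode(obs) <- "numeric"; mode(het) <- "numeric"
  mode(hom0) <- "numeric"; mode(hom2) <- "numeric"

  n_hethet <- het %*% t(het)
  n_opp <- hom0 %*% t(hom2) + hom2 %*% t(hom0)
  het_shared <- het %*% t(obs)           # het in i, non-missing in j
  denom <- het_shared + t(het_shared)
  phi <- (n_hethet - 2 * n_opp) / denom
  if (any(denom == 0)) {
    warning(sum(denom == 0), " pair(s) with no shared informative loci set to NA")
    phi[denom == 0] <- NA_real_
  }
  dimnames(phi) <- list(rownames(geno), rownames(geno))
  phi
}

#' Weir-Cockerham FST between two groups
#'
#' Computes the two-population theta estimator per locus from observed
#' allele and heterozygote frequencies (sample sizes taken as non-missing
#' individuals per group) and averages over loci with a defined
#' denominator; negative per-locus values are retained in the mean.
#'
#' @param geno samples x loci matrix (0/1/2/NA).
#' @param group_a,group_b disjoint sample-id vectors.
#' @return list with `mean_fst`, `per_locus` theta values and the number of
#'   loci contributing to the mean.
#' @export
mean_fst <- function(geno, group_a, group_b) {
  validate_genotypes(geno)
  if (length(intersect(group_a, group_b)) > 0) stop("groups must be disjoint")
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 individuals")
  stats_for <- function(ids) {
    x <- geno[ids, , drop = FALSE]
    n <- colSums(!is.na(x))
    p <- colMeans(x, na.rm = TRUE) / 2
    h <- colMeans(x == 1, na.rm = TRUE)
    list(n = n, p = p, h = h)
  }
  s1 <- stats_for(group_a); s2 <- stats_for(group_b)
  r <- 2
  n1 <- s1$n; n2 <- s2$n
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * s1$p + n2 * s2$p) / (r * nbar)
  s2v <- (n1 * (s1$p - pbar)^2 + n2 * (s2$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * s1$h + n2 * s2$h) / (r * nbar)

  a <- (nbar / nc) *
    (s2v - (pbar * (1 - pbar) - ((r - 1) / r) * s2v - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2v - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  theta <- ifelse(is.finite(denom) & denom > 0, a / denom, NA_real_)
  usable <- !is.na(theta)
  list(mean_fst = mean(theta[usable]), per_locus = theta, n_loci = sum(usable))
}
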