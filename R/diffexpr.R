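## Negative-binomial differential expression: median-of-ratios size factors,
## method-of-moments dispersion within covariate cells, IRLS Wald test and
## BH-FDR.  Implemented in-house (with a compiled IRLS core) because the
## randomization stage re-runs the full test thousands of times on
## simulated data, and every stage must be checkable against simple
## oracles.  Numeric parity with shrinkage-based DE packages is a non-goal.

#' Median-of-ratios size factors
#'
#' For genes with nonzero counts in every sample, each sample's factor is
#' the median ratio of its counts to the per-gene geometric means; factors
#' are rescaled to geometric mean 1.
#'
#' @param counts genes x samples count matrix.
#' @return positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  validate_counts(counts)
  all_pos <- rowSums(counts == 0) == 0
  if (!any(all_pos))
    stop("no gene has nonzero counts in all samples; filter low-count genes first")
  pos <- counts[all_pos, , drop = FALSE]
  geo <- exp(rowMeans(log(pos)))
  raw <- apply(pos / geo, 2, median)
  sf <- raw / exp(mean(log(raw)))
  names(sf) <- colnames(counts)
  sf
}

#' Method-of-moments NB dispersion per gene
#'
#' Within each covariate cell (all samples sharing one combination of the
#' design factors), computes the moment estimate `(s^2 - m) / m^2` on
#' normalized counts and pools cells by their degrees of freedom; the
#' result is floored at `alpha_floor`.
#'
#' By default the per-gene estimates are shrunk toward a mean-expression
#' trend (the 20%-trimmed mean of the raw estimates within ten
#' equal-occupancy bins of mean normalized count), combining the per-gene
#' value and the trend with weights proportional to the gene's residual
#' degrees of freedom and `prior_df`.  Raw moment estimates at a few dozen
#' degrees of freedom are noisy, and because the Wald tail is convex in an
#' underestimated dispersion that noise inflates the false-positive rate;
#' moderation with a modest prior (10 degrees of freedom, the conventional
#' default in moderated-dispersion DE analysis) restores calibration.
#' `shrink = FALSE` gives the raw per-gene estimates.
#'
#' @param counts genes x samples count matrix.
#' @param factors size factors from [size_factors()].
#' @param cells factor assigning samples to covariate cells (default: one
#'   cell containing all samples).
#' @param alpha_floor minimum returned dispersion.
#' @param shrink moderate per-gene estimates toward the trend (default TRUE).
#' @param prior_df weight, in degrees of freedom, of the trend value.
#' @return numeric vector of per-gene dispersions.
#' @export
estimate_dispersion <- function(counts, factors, cells = NULL, alpha_floor = 1e-8,
                                shrink = TRUE, prior_df = 10) {
  if (ncol(counts) < 3) stop("need at least 3 samples to estimate dispersion")
  norm <- sweep(counts, 2, factors, "/")
  if (is.null(cells)) cells <- factor(rep("all", ncol(counts)))
  cells <- droplevels(as.factor(cells))
  num <- matrix(0, nrow(counts), 1)[, 1]
  den <- num
  for (lev in levels(cells)) {
    idx <- which(cells == lev)
    nc <- length(idx)
    if (nc < 2) next
    x <- norm[, idx, drop = FALSE]
    m <- rowMeans(x)
    v <- (rowMeans(x^2) - m^2) * nc / (nc - 1)
    ok <- m > 0
    z <- ifelse(ok, (v - m) / m^2, 0)
    w <- (nc - 1) * ok
    num <- num + w * z
    den <- den + w
  }
  if (all(den == 0)) stop("no covariate cell has >= 2 samples")
  alpha <- ifelse(den > 0, num / den, alpha_floor)
  if (shrink && nrow(counts) >= 20) {
    grand <- rowMeans(norm)
    bins <- cut(rank(grand, ties.method = "first"),
                breaks = 10, labels = FALSE)
    trend <- stats::ave(alpha, bins,
                        FUN = function(x) mean(pmax(x, 0), trim = 0.2))
    alpha <- (den * alpha + prior_df * trend) / (den + prior_df)
  }
  pmax(alpha, alpha_floor)
}

#' Fit per-gene NB GLMs and Wald-test one contrast
#'
#' Fits, per gene, a log-link negative-binomial GLM with fixed dispersion
#' and log size factors as offsets, by iteratively reweighted least squares
#' (max 50 iterations, relative deviance tolerance 1e-8).  The Wald
#' statistic is the contrast coefficient over its standard error, with a
#' standard-normal p-value.  Genes that never converge (or are all-zero)
#' get missing p-values and are excluded from FDR adjustment, with a logged
#' count.
#'
#' @param counts genes x samples count matrix.
#' @param meta sample metadata matching `colnames(counts)`.
#' @param design_terms character vector of covariate column names (fitted
#'   before the contrast, e.g. `c("cross_date", "sex")`).
#' @param contrast_term name of a two-level factor column in `meta`; the
#'   reported effect is its second level versus its first (reference).
#' @param dispersions optional per-gene dispersions (default: estimated
#'   within cells defined by all design factors).
#' @param factors optional size factors.
#' @param max_iter,tol IRLS controls.
#' @return data.frame with `gene_id`, `log2_fold_change`, `lfc_se`,
#'   `wald_stat`, `p_value`, `converged`.
#' @export
fit_nb_glm <- function(counts, meta, design_terms, contrast_term,
                       dispersions = NULL, factors = NULL,
                       max_iter = 50, tol = 1e-8) {
  validate_counts(counts)
  stopifnot(all(colnames(counts) == meta$sample_id))
  if (!is.factor(meta[[contrast_term]]))
    meta[[contrast_term]] <- factor(meta[[contrast_term]])
  if (nlevels(droplevels(meta[[contrast_term]])) != 2)
    stop("contrast_term must have exactly 2 levels on these samples")
  meta[[contrast_term]] <- droplevels(meta[[contrast_term]])
  for (term in design_terms)
    if (!is.numeric(meta[[term]])) meta[[term]] <- droplevels(factor(meta[[term]]))

  X <- model.matrix(reformulate(c(design_terms, contrast_term)), meta)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased term(s): ",
         paste(aliased, collapse = ", "))
  }
  contrast_col <- grep(paste0("^", contrast_term), colnames(X))
  if (length(contrast_col) != 1)
    stop("could not locate the contrast column in the design matrix")

  if (is.null(factors)) factors <- size_factors(counts)
  if (is.null(dispersions)) {
    cells <- interaction(meta[, c(design_terms, contrast_term), drop = FALSE],
                         drop = TRUE)
    dispersions <- estimate_dispersion(counts, factors, cells)
  }

  fit <- nb_glm_fit_engine(counts, X, log(factors), dispersions,
                           contrast_col - 1L, as.integer(max_iter), tol)
  ln2 <- log(2)
  stat <- fit$beta / fit$se
  res <- data.frame(
    gene_id = rownames(counts),
    log2_fold_change = fit$beta / ln2,
    lfc_se = fit$se / ln2,
    wald_stat = stat,
    p_value = 2 * pnorm(-abs(stat)),
    converged = !is.na(fit$converged) & fit$converged == 1L,
    stringsAsFactors = FALSE
  )
  n_failed <- sum(!res$converged)
  if (n_failed > 0)
    rc_log("%d gene(s) excluded from testing (all-zero or non-converged)", n_failed)
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment with enforced monotonicity; missing values are passed
#' through and do not count toward the number of tests.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Run a two-group differential-expression contrast
#'
#' Composes size factors, dispersion estimation, the NB Wald test and BH
#' adjustment for a contrast of two disjoint sample groups.  Positive
#' log2 fold changes mean higher expression in `group_a`; with
#' `run_de(counts, meta, "HH", "NN")` a positive value is upregulation in
#' HH offspring (the mirror of result tables that use the pure
#' natural-origin cross as reference).
#'
#' @param counts genes x samples count matrix.
#' @param meta sample metadata.
#' @param group_a,group_b sample-id vectors, or single cross codes
#'   ("HH" etc.) selecting all offspring of that cross.
#' @param design_terms covariates retained in the fit.
#' @param fdr FDR threshold for calling DEGs.
#' @return list with `results` (per-gene table including `p_adj`),
#'   `n_deg`, `n_up`, `n_down`, `deg_ids`, `fdr`.
#' @export
run_de <- function(counts, meta, group_a, group_b,
                   design_terms = c("cross_date", "sex"), fdr = 0.05) {
  expand <- function(g) {
    if (length(g) == 1 && g %in% CROSS_LEVELS)
      return(meta$sample_id[meta$cross == g])
    g
  }
  ids_a <- expand(group_a)
  ids_b <- expand(group_b)
  if (length(intersect(ids_a, ids_b)) > 0)
    stop("groups must be disjoint")
  if (length(ids_a) < 2 || length(ids_b) < 2)
    stop("each group needs at least 2 samples")
  keep <- c(ids_a, ids_b)
  if (!all(keep %in% meta$sample_id)) stop("unknown sample id(s) in groups")
  sub_meta <- meta[match(keep, meta$sample_id), , drop = FALSE]
  lab_a <- if (length(group_a) == 1 && group_a %in% CROSS_LEVELS) group_a else "groupA"
  lab_b <- if (length(group_b) == 1 && group_b %in% CROSS_LEVELS) group_b else "groupB"
  sub_meta$de_group <- factor(ifelse(sub_meta$sample_id %in% ids_a, lab_a, lab_b),
                              levels = c(lab_b, lab_a))
  sub_counts <- counts[, sub_meta$sample_id, drop = FALSE]

  res <- fit_nb_glm(sub_counts, sub_meta, design_terms, "de_group")
  res$p_adj <- bh_adjust(ifelse(res$converged, res$p_value, NA))
  sig <- !is.na(res$p_adj) & res$p_adj < fdr
  list(
    results = res,
    n_deg = sum(sig),
    n_up = sum(sig & res$log2_fold_change > 0),
    n_down = sum(sig & res$log2_fold_change < 0),
    deg_ids = res$gene_id[sig],
    fdr = fdr,
    groups = list(a = ids_a, b = ids_b)
  )
}

#' Consensus sibling correlation of log expression
#'
#' For each gene, takes log2 normalized counts, residualizes them against
#' cross date, sex and cross type, and correlates the two siblings of each
#' full-sib family across families.  The consensus is the inverse Fisher-z
#' of the 10%-trimmed mean of per-gene Fisher-z values, corrected for the
#' residualization-induced correlation: projecting out covariates that
#' siblings share (cross type, cross date) makes their residuals
#' negatively correlated by the hat-matrix term
#' `-H_ij / sqrt((1 - H_ii)(1 - H_jj))` (about -0.06 for the full design)
#' even when expression is independent, so that design-determined null
#' value is subtracted on the Fisher-z scale.  A low consensus supports
#' treating samples as independent in the fixed-effects DE model.
#'
#' @param counts genes x samples count matrix.
#' @param meta sample metadata (families = `family_code`, 2 offspring each).
#' @param factors optional size factors.
#' @param trim trim fraction for the mean of Fisher-z values.
#' @return list with `consensus` and the per-gene correlations `per_gene`.
#' @export
sibling_correlation <- function(counts, meta, factors = NULL, trim = 0.1) {
  validate_counts(counts)
  stopifnot(all(colnames(counts) == meta$sample_id))
  if (is.null(factors)) factors <- size_factors(counts)
  logn <- log2(sweep(counts, 2, factors, "/") + 1)

  fam_sizes <- table(meta$family_code)
  fams <- names(fam_sizes)[fam_sizes == 2]
  if (length(fams) < 3) stop("need at least 3 families with exactly 2 offspring")

  covars <- intersect(c("cross_date", "sex", "cross"), names(meta))
  covars <- covars[vapply(covars, function(v) length(unique(meta[[v]])) > 1, TRUE)]
  X <- if (length(covars) > 0) {
    model.matrix(reformulate(covars), meta)
  } else {
    matrix(1, nrow(meta), 1)
  }
  qx <- qr(X)
  Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  resid <- logn - (logn %*% Q) %*% t(Q)

  pick <- function(rank) {
    vapply(fams, function(f) {
      idx <- which(meta$family_code == f)
      idx[order(meta$sex[idx], meta$sample_id[idx])][rank]
    }, 1L)
  }
  i1 <- pick(1); i2 <- pick(2)
  a <- resid[, i1, drop = FALSE]
  b <- resid[, i2, drop = FALSE]
  Fm <- length(fams)
  ma <- rowMeans(a); mb <- rowMeans(b)
  sa <- sqrt(rowSums((a - ma)^2)); sb <- sqrt(rowSums((b - mb)^2))
  r <- rowSums((a - ma) * (b - mb)) / (sa * sb)
  r <- r[is.finite(r)]
  z <- atanh(pmin(pmax(r, -0.9999), 0.9999))

  # design-induced null correlation of sibling residuals
  h_diag <- rowSums(Q^2)
  h_pair <- rowSums(Q[i1, , drop = FALSE] * Q[i2, , drop = FALSE])
  rho0 <- mean(-h_pair / sqrt((1 - h_diag[i1]) * (1 - h_diag[i2])))

  consensus <- tanh(mean(z, trim = trim) - atanh(rho0))
  list(consensus = consensus, per_gene = r, n_families = Fm,
       design_null = rho0)
}
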