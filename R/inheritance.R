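## Decomposition of DEG expression patterns across the four cross types.
## A reciprocal-cross design separates total-ancestry (additive) responses
## from parent-of-origin responses: under a maternal effect offspring
## sharing a mother's environment share expression; under an additive
## response the reciprocal crosses sit midway between the pure crosses.

#' Standardized log group means per gene
#'
#' Computes `log2(normalized count + 1)` per sample and, for each gene, the
#' mean and standard error within each of the four cross groups, plus the
#' direction of the HH-vs-NN difference.
#'
#' @param counts genes x samples count matrix.
#' @param factors size factors.
#' @param meta sample metadata; all four cross types must be present.
#' @param genes optional gene-id subset (e.g. the DEG list).
#' @return list with `means` (per-gene group means/SEs and `direction`) and
#'   `log_values` (the per-sample standardized log matrix for those genes).
#' @export
standardized_log_means <- function(counts, factors, meta, genes = NULL) {
  validate_counts(counts)
  stopifnot(all(colnames(counts) == meta$sample_id))
  present <- CROSS_LEVELS %in% as.character(unique(meta$cross))
  if (!all(present))
    stop("missing cross group(s): ", paste(CROSS_LEVELS[!present], collapse = ", "))
  if (is.null(genes)) genes <- rownames(counts)
  missing_genes <- setdiff(genes, rownames(counts))
  if (length(missing_genes) > 0)
    stop("unknown gene id(s): ", paste(utils::head(missing_genes, 5), collapse = ", "))
  logn <- log2(sweep(counts[genes, , drop = FALSE], 2, factors, "/") + 1)

  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (g in CROSS_LEVELS) {
    idx <- which(meta$cross == g)
    x <- logn[, idx, drop = FALSE]
    m <- rowMeans(x)
    se <- sqrt((rowMeans(x^2) - m^2) * length(idx) / (length(idx) - 1)) /
      sqrt(length(idx))
    out[[paste0("mean_", g)]] <- m
    out[[paste0("se_", g)]] <- se
  }
  delta <- out$mean_HH - out$mean_NN
  out$direction <- ifelse(delta > 0, "up_in_HH",
                          ifelse(delta < 0, "up_in_NN", "tie"))
  list(means = out, log_values = logn)
}

#' Shift per-gene values to a common HH mean (visualization aid)
#'
#' Adds, per gene, the difference between the gene-set grand HH mean and
#' that gene's HH mean, so all genes' HH means coincide and per-gene
#' trajectories across cross types can be overlaid.  Within-gene group
#' differences are preserved exactly.
#'
#' @param log_values genes x samples matrix of standardized log counts.
#' @param meta sample metadata matching the columns.
#' @return shifted matrix of the same shape.
#' @export
visual_shift <- function(log_values, meta) {
  stopifnot(all(colnames(log_values) == meta$sample_id))
  hh <- which(meta$cross == "HH")
  gene_hh <- rowMeans(log_values[, hh, drop = FALSE])
  log_values + (mean(gene_hh) - gene_hh)
}

#' Classify each gene's inheritance pattern
#'
#' Given observed group means (HH, HN, NH, NN), each candidate model
#' predicts the reciprocal-cross means from the pure-cross means:
#' additive -> both at the midpoint; maternal -> HN matches HH and NH
#' matches NN (offspring share the mother's environment); paternal -> the
#' mirror.  The per-model score is the SE-weighted sum of squared
#' deviations of the observed (HN, NH) means from the prediction; the call
#' is the argmin, or `ambiguous` when the two best scores are within
#' `tie_tol` (relative).  Because all three models predict the same
#' reciprocal-cross means when the pure crosses do not differ, genes whose
#' HH-NN contrast is below `signal_z` combined standard errors are also
#' called `ambiguous`: there is no signal to decompose.
#'
#' @param group_means `means` table from [standardized_log_means()].
#' @param tie_tol relative tie tolerance between the two best scores.
#' @param signal_z minimum HH-NN contrast, in combined-SE units, for a
#'   mode call to be attempted.
#' @return data.frame with per-gene `call` and per-model scores.
#' @export
classify_mode <- function(group_means, tie_tol = 0.1, signal_z = 2) {
  gm <- group_means
  if (any(gm$se_HN <= 0) || any(gm$se_NH <= 0))
    stop("zero standard error: group means are degenerate")
  score <- function(pred_hn, pred_nh) {
    ((gm$mean_HN - pred_hn) / gm$se_HN)^2 + ((gm$mean_NH - pred_nh) / gm$se_NH)^2
  }
  mid <- (gm$mean_HH + gm$mean_NN) / 2
  scores <- cbind(
    additive = score(mid, mid),
    maternal = score(gm$mean_HH, gm$mean_NN),
    paternal = score(gm$mean_NN, gm$mean_HH)
  )
  calls <- apply(scores, 1, function(s) {
    o <- order(s)
    if (s[o[2]] <= (1 + tie_tol) * s[o[1]]) "ambiguous" else colnames(scores)[o[1]]
  })
  no_signal <- abs(gm$mean_HH - gm$mean_NN) <
    signal_z * sqrt(gm$se_HH^2 + gm$se_NN^2)
  calls[no_signal] <- "ambiguous"
  data.frame(gene_id = gm$gene_id, call = calls,
             score_additive = scores[, "additive"],
             score_maternal = scores[, "maternal"],
             score_paternal = scores[, "paternal"],
             direction = gm$direction,
             stringsAsFactors = FALSE)
}

#' Summarize inheritance-mode calls
#'
#' @param calls output of [classify_mode()].
#' @return list with the call x direction contingency table and the
#'   fraction of genes called additive.
#' @export
mode_summary <- function(calls) {
  if (nrow(calls) == 0) stop("no mode calls to summarize")
  if (all(calls$call == "ambiguous"))
    stop("no unambiguous mode calls to summarize")
  tab <- table(call = calls$call, direction = calls$direction)
  list(table = tab, fraction_additive = mean(calls$call == "additive"),
       n = nrow(calls))
}

#' Test for a direction bias in DEG counts
#'
#' One-degree-of-freedom goodness-of-fit chi-square of the up/down split
#' against 50:50, plus the exact two-sided binomial p-value.
#'
#' @param n_up,n_down numbers of up- and downregulated DEGs.
#' @return list with `chisq`, `p_chisq`, `p_binom`, `fraction_up`.
#' @export
direction_bias_test <- function(n_up, n_down) {
  n <- n_up + n_down
  if (n < 1) stop("need at least one gene")
  expected <- n / 2
  chisq <- (n_up - expected)^2 / expected + (n_down - expected)^2 / expected
  list(
    chisq = chisq,
    p_chisq = pchisq(chisq, df = 1, lower.tail = FALSE),
    p_binom = binom.test(n_up, n, 0.5)$p.value,
    fraction_up = n_up / n
  )
}
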