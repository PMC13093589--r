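## Constrained reshuffling procedures for DEG counts.  Two designs:
## (1) an ancestry gradient in which each of two reshuffled groups is
## forced to contain exactly N focal-type offspring (pure hatchery in one
## group, pure natural in the other) with the remainder drawn from the
## reciprocal crosses, and (2) a conservative permutation that ignores the
## pure-cross labels entirely.  Samples are canonically sorted by id before
## any draw so a given seed is portable across input row orderings.

#' Build one constrained two-group partition
#'
#' Group A receives exactly `n_focal` HH offspring and no NN offspring;
#' group B exactly `n_focal` NN offspring and no HH.  The remaining slots
#' of both groups are filled from the pooled reciprocal-cross (HN, NH)
#' offspring, without replacement by default.  At the maximum constraint
#' the partition is the empirical pure-cross contrast and is deterministic.
#' Uses the current RNG state.
#'
#' @param meta sample metadata for a complete design.
#' @param n_focal number of focal pure-cross offspring per group.
#' @param with_replacement fill the remainder slots with replacement
#'   (variant described for the gradient figure caption); default FALSE.
#' @return list with sample-id vectors `group_a`, `group_b`.
#' @export
constrained_partition <- function(meta, n_focal, with_replacement = FALSE) {
  meta <- meta[order(meta$sample_id), , drop = FALSE]
  hh <- meta$sample_id[meta$cross == "HH"]
  nn <- meta$sample_id[meta$cross == "NN"]
  pool <- meta$sample_id[meta$cross %in% c("HN", "NH")]
  size <- length(hh)
  if (length(nn) != size) stop("design must have equal HH and NN counts")
  if (n_focal < 1 || n_focal > size)
    stop(sprintf("n_focal must be in [1, %d]", size))
  n_fill <- 2 * (size - n_focal)
  if (!with_replacement && n_fill > length(pool))
    stop(sprintf("cannot fill %d remainder slots from %d reciprocal-cross offspring",
                 n_fill, length(pool)))
  a <- if (n_focal == size) hh else sort(sample(hh, n_focal))
  b <- if (n_focal == size) nn else sort(sample(nn, n_focal))
  if (n_fill > 0) {
    fill <- if (with_replacement) sample(pool, n_fill, replace = TRUE)
            else sample(pool, n_fill)
    a <- c(a, fill[seq_len(n_fill / 2)])
    b <- c(b, fill[(n_fill / 2 + 1):n_fill])
  }
  list(group_a = a, group_b = b)
}

#' DEG counts along an ancestry gradient
#'
#' For each constraint level N, repeatedly partitions the offspring with
#' [constrained_partition()] and counts DEGs between the two groups with
#' [run_de()] (design: covariates + group).  Reports the mean replicate
#' DEG count and a percentile 95% CI per level.  At the maximum N the
#' partition is the empirical HH-vs-NN contrast, so all replicates are
#' identical and the CI has zero width.
#'
#' @param counts genes x samples count matrix.
#' @param meta sample metadata.
#' @param constraints integer vector of N levels.
#' @param replicates replicates per level.
#' @param fdr FDR threshold for DEG calls.
#' @param design_terms covariates kept inside the reshuffled fits.
#' @param seed optional integer seed.
#' @param with_replacement see [constrained_partition()].
#' @return list with `summary` (per level: mean, CI bounds, replicates) and
#'   `replicate_counts` (levels x replicates matrix).
#' @export
ancestry_gradient <- function(counts, meta,
                              constraints = c(1, 5, 10, 15, 20, 25, 30),
                              replicates = 1000, fdr = 0.05,
                              design_terms = c("cross_date", "sex"),
                              seed = NULL, with_replacement = FALSE) {
  if (replicates < 2) stop("need at least 2 replicates")
  run <- function() {
    out <- matrix(NA_real_, length(constraints), replicates,
                  dimnames = list(constraints, NULL))
    for (i in seq_along(constraints)) {
      for (r in seq_len(replicates)) {
        part <- constrained_partition(meta, constraints[i], with_replacement)
        de <- run_de(counts, meta, part$group_a, part$group_b,
                     design_terms = design_terms, fdr = fdr)
        out[i, r] <- de$n_deg
      }
    }
    out
  }
  reps <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  summary <- data.frame(
    n_focal = constraints,
    mean_degs = rowMeans(reps),
    ci_lower = apply(reps, 1, quantile, 0.025),
    ci_upper = apply(reps, 1, quantile, 0.975),
    replicates = replicates
  )
  list(summary = summary, replicate_counts = reps)
}

#' Conservative permutation null for the pure-cross DEG count
#'
#' Pools the HH and NN offspring only, repeatedly splits them into two
#' equal groups at random (ignoring ancestry), and counts DEGs per split.
#' The empirical p-value for the observed HH-vs-NN DEG count (and for its
#' upregulated-gene count) uses the add-one convention
#' `(1 + #(replicate >= observed)) / (R + 1)` so it can never be zero; the
#' plain `#(replicate >= observed) / R` convention is available via
#' `add_one = FALSE`.
#'
#' @param counts genes x samples count matrix.
#' @param meta sample metadata.
#' @param replicates number of random splits.
#' @param fdr FDR threshold for DEG calls.
#' @param design_terms covariates kept inside the reshuffled fits.
#' @param seed optional integer seed.
#' @param add_one use the add-one p-value convention (default TRUE).
#' @param threshold count genes by `"adjusted"` p below `fdr` (DEG calls,
#'   the default) or by `"raw"` p below `fdr`.  The raw-threshold count
#'   varies smoothly under the null, which makes it the statistic of
#'   choice for calibration checks; the FDR-scale DEG count is almost
#'   surely zero on null data, so its permutation p-value piles up at 1.
#' @return list with observed counts, replicate count vectors, and
#'   empirical p-values `p_degs`, `p_up`.
#' @export
null_permutation <- function(counts, meta, replicates = 1000, fdr = 0.05,
                             design_terms = c("cross_date", "sex"),
                             seed = NULL, add_one = TRUE,
                             threshold = c("adjusted", "raw")) {
  threshold <- match.arg(threshold)
  if (replicates < 2) stop("need at least 2 replicates")
  focal <- meta[meta$cross %in% c("HH", "NN"), , drop = FALSE]
  focal <- focal[order(focal$sample_id), , drop = FALSE]
  ids <- focal$sample_id
  if (length(ids) %% 2 != 0) stop("pooled HH+NN sample count must be even")
  half <- length(ids) / 2

  count_de <- function(de) {
    if (threshold == "adjusted") return(c(de$n_deg, de$n_up))
    r <- de$results
    sig <- r$converged & !is.na(r$p_value) & r$p_value < fdr
    c(sum(sig), sum(sig & r$log2_fold_change > 0))
  }
  observed <- run_de(counts, meta, "HH", "NN",
                     design_terms = design_terms, fdr = fdr)
  obs_counts <- count_de(observed)

  run <- function() {
    deg <- up <- numeric(replicates)
    for (r in seq_len(replicates)) {
      shuffled <- sample(ids)
      de <- run_de(counts, meta, shuffled[seq_len(half)],
                   shuffled[(half + 1):length(ids)],
                   design_terms = design_terms, fdr = fdr)
      cnt <- count_de(de)
      deg[r] <- cnt[1]
      up[r] <- cnt[2]
    }
    list(deg = deg, up = up)
  }
  reps <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  emp_p <- function(rep_vals, obs) {
    b <- sum(rep_vals >= obs)
    if (add_one) (1 + b) / (replicates + 1) else b / replicates
  }
  list(
    observed_degs = obs_counts[1],
    observed_up = obs_counts[2],
    replicate_degs = reps$deg,
    replicate_up = reps$up,
    p_degs = emp_p(reps$deg, obs_counts[1]),
    p_up = emp_p(reps$up, obs_counts[2]),
    replicates = replicates,
    add_one = add_one,
    threshold = threshold
  )
}
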