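test_that("size factors respect symmetry, scaling and the median-of-ratios oracle", {
  m <- toy_counts(rep(c(10L, 25L, 3L), 4), 3, 4)
  expect_equal(unname(size_factors(m)), rep(1, 4))

  m2 <- m
  m2[, 2] <- m2[, 2] * 2L
  sf <- size_factors(m2)
  expect_equal(unname(sf[2] / sf[1]), 2)

  set.seed(11)
  r <- toy_counts(rpois(300, 40) + 1L, 50, 6)
  # brute-force median-of-ratios
  geo <- exp(rowMeans(log(r)))
  raw <- apply(r, 2, function(col) median(col / geo))
  oracle <- raw / exp(mean(log(raw)))
  expect_equal(unname(size_factors(r)), unname(oracle))

  all_zero_row <- toy_counts(c(0L, 0L, 5L, 7L), 2, 2)
  all_zero_row[1, ] <- 0L
  all_zero_row[2, ] <- 0L
  expect_error(size_factors(all_zero_row), "filter")
})

test_that("dispersion estimates hit the floor for Poisson and constant genes", {
  set.seed(12)
  pois <- toy_counts(rpois(120, 200), 1, 120)
  a <- estimate_dispersion(pois, rep(1, 120))
  expect_lte(a[1], 0.05)
  const <- toy_counts(rep(50L, 120), 1, 120)
  expect_equal(unname(estimate_dispersion(const, rep(1, 120))[1]), 1e-8)
})

test_that("NB dispersion is recovered from moment estimation at n = 120", {
  set.seed(13)
  nb <- toy_counts(rnbinom(120, mu = 200, size = 1 / 0.5), 1, 120)
  a <- estimate_dispersion(nb, rep(1, 120))
  expect_gt(a[1], 0.3)
  expect_lt(a[1], 0.8)
})

test_that("the NB Wald test agrees with a Poisson GLM in the small-dispersion limit", {
  set.seed(14)
  n <- 40
  grp <- factor(rep(c("a", "b"), each = n / 2))
  mu <- ifelse(grp == "b", 1300, 1000)
  y <- rpois(n, mu)
  counts <- toy_counts(y, 1, n)
  meta <- data.frame(sample_id = colnames(counts), grp = grp)
  fit <- fit_nb_glm(counts, meta, character(0), "grp",
                    dispersions = 1e-12, factors = rep(1, n))
  oracle <- summary(stats::glm(y ~ grp, family = stats::poisson()))$coefficients
  expect_equal(fit$log2_fold_change[1] * log(2), oracle["grpb", "Estimate"],
               tolerance = 1e-7)
  expect_equal(fit$p_value[1], oracle["grpb", "Pr(>|z|)"], tolerance = 1e-6)
})

test_that("planted effects are recovered within Wald uncertainty and zero genes flagged", {
  d <- simulate_design(15, seed = 15)
  cfg <- sim_config(n_genes = 300, n_ancestry_genes = 30,
                    n_maternal_genes = 0, n_paternal_genes = 0, n_sex_genes = 0,
                    family_sd = 0)
  sim <- simulate_counts(cfg, d, seed = 16)
  sim$counts[1, ] <- 0L   # degenerate gene
  de <- run_de(sim$counts, d, "HH", "NN")
  res <- merge(de$results, sim$truth, by = "gene_id")
  anc <- res[res$class == "ancestry" & res$converged, ]
  expect_true(all(sign(anc$log2_fold_change) == sign(anc$log2_effect)))
  expect_true(mean(abs(anc$log2_fold_change - anc$log2_effect) <
                     3 * anc$lfc_se) > 0.95)
  g1 <- de$results[de$results$gene_id == rownames(sim$counts)[1], ]
  expect_false(g1$converged)
  expect_true(is.na(g1$p_adj))
})

test_that("rank-deficient designs fail with the aliased term named", {
  d <- simulate_design(2, seed = 17)
  d$dup <- d$cross_date   # aliased covariate
  cfg <- sim_config(n_genes = 50, n_ancestry_genes = 0, n_maternal_genes = 0,
                    n_paternal_genes = 0, n_sex_genes = 0)
  sim <- simulate_counts(cfg, d, seed = 18)
  expect_error(run_de(sim$counts, d, "HH", "NN",
                      design_terms = c("cross_date", "dup")),
               "rank deficient")
})

test_that("BH adjustment matches hand computation and preserves order properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  set.seed(19)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  expect_equal(bh_adjust(c(0.01, NA, 0.5)), c(0.02, NA, 0.5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("run_de enforces its group contract and sign convention", {
  d <- simulate_design(15, seed = 20)
  cfg <- sim_config(n_genes = 200, n_ancestry_genes = 20,
                    n_maternal_genes = 0, n_paternal_genes = 0, n_sex_genes = 0)
  sim <- simulate_counts(cfg, d, seed = 21)
  expect_error(run_de(sim$counts, d, "HH", "HH"), "disjoint")
  de <- run_de(sim$counts, d, "HH", "NN")
  res <- merge(de$results, sim$truth, by = "gene_id")
  up <- res[res$class == "ancestry" & res$log2_effect > 0, ]
  # positive log2FC = higher in group A (HH); the NN-as-reference table
  # convention used elsewhere is the mirror of this
  expect_true(all(up$log2_fold_change > 0))
  expect_equal(de$n_deg, de$n_up + de$n_down)
})

test_that("statistical power increases with planted effect size", {
  d <- simulate_design(15, seed = 22)
  frac_detected <- vapply(c(0.5, 1, 2), function(eff) {
    cfg <- sim_config(n_genes = 400, n_ancestry_genes = 40,
                      ancestry_effect = eff, n_maternal_genes = 0,
                      n_paternal_genes = 0, n_sex_genes = 0)
    sim <- simulate_counts(cfg, d, seed = 23)
    de <- run_de(sim$counts, d, "HH", "NN")
    anc <- sim$truth$gene_id[sim$truth$class == "ancestry"]
    mean(anc %in% de$deg_ids)
  }, 0)
  expect_true(all(diff(frac_detected) >= 0))
  expect_gt(frac_detected[3], frac_detected[1])
})

test_that("sibling correlation is near zero without family effects and one for clones", {
  d <- simulate_design(15, seed = 24)
  cfg <- sim_config(n_genes = 800, n_ancestry_genes = 0, n_maternal_genes = 0,
                    n_paternal_genes = 0, n_sex_genes = 0,
                    family_sd = 0, batch_sd = 0)
  sim <- simulate_counts(cfg, d, seed = 25)
  expect_lt(abs(sibling_correlation(sim$counts, d)$consensus), 0.05)

  clone <- sim$counts
  for (f in unique(d$family_code)) {
    idx <- which(d$family_code == f)
    clone[, idx[2]] <- clone[, idx[1]]
  }
  expect_gt(sibling_correlation(clone, d)$consensus, 0.95)
})

test_that("the calibrated family effect reproduces the weak sibling correlation", {
  d <- simulate_design(15, seed = 26)
  sim <- simulate_counts(sim_config(), d, seed = 27)
  r <- sibling_correlation(sim$counts, d)$consensus
  expect_gt(r, 0.08)
  expect_lt(r, 0.18)
})
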