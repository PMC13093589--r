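# Hand-built genotype fixture: locus A is 40% missing, locus B invariant,
# individual I5 exceeds 20% missing data once A is gone; C-F stay.
filter_fixture <- function() {
  g <- rbind(
    I1 = c(NA, 0L, 0L, 1L, 2L, 0L),
    I2 = c(NA, 0L, 1L, 0L, 1L, 1L),
    I3 = c(0L, 0L, 2L, 1L, 0L, 0L),
    I4 = c(1L, 0L, 1L, 2L, 1L, 1L),
    I5 = c(2L, 0L, NA, NA, NA, 0L)
  )
  colnames(g) <- paste0("chr1:", 1:6)
  g
}

test_that("genotype filters remove exactly the designed loci and individuals", {
  fx <- filter_fixture()
  out <- suppressMessages(filter_genotypes(fx))
  expect_equal(out$report$loci_removed_missingness, "chr1:1")
  expect_equal(out$report$individuals_removed$sample_id, "I5")
  expect_equal(out$report$individuals_removed$missing_fraction, 0.6)
  expect_equal(out$report$loci_removed_maf, "chr1:2")
  expect_equal(colnames(out$genotypes), paste0("chr1:", 3:6))
  expect_equal(rownames(out$genotypes), paste0("I", 1:4))
  # report totals conserve input dimensions
  expect_equal(length(out$report$loci_removed_missingness) +
                 length(out$report$loci_removed_maf) +
                 out$report$n_loci_retained,
               out$report$n_loci_in)
  expect_equal(nrow(out$report$individuals_removed) +
                 out$report$n_indiv_retained, out$report$n_indiv_in)
})

test_that("clean matrices pass the filters untouched", {
  set.seed(60)
  g <- matrix(sample(0:2, 200, replace = TRUE), 10, 20)
  rownames(g) <- sprintf("i%02d", 1:10)
  colnames(g) <- sprintf("chr1:%d", 1:20)
  keep_poly <- apply(g, 2, function(x) length(unique(x)) > 1)
  g <- g[, keep_poly]
  out <- suppressMessages(filter_genotypes(g))
  expect_identical(out$genotypes, g)
})

test_that("allele frequencies for the MAF filter are computed after individual removal", {
  # locus 6's minor allele is carried only by the high-missingness individual
  g <- filter_fixture()
  g[, 6] <- c(0L, 0L, 0L, 0L, 2L)
  out <- suppressMessages(filter_genotypes(g))
  expect_true("chr1:6" %in% out$report$loci_removed_maf)
  expect_equal(out$report$n_loci_retained, 3)
})

test_that("KING kinship satisfies its estimator identities", {
  toy <- rbind(i = c(0L, 1L, 2L, 1L), j = c(2L, 1L, 0L, 1L))
  colnames(toy) <- paste0("chr1:", 1:4)
  phi <- king_kinship(toy)
  expect_equal(phi["i", "i"], 0.5)     # self-pair identity
  expect_equal(phi["i", "j"], -0.5)    # hand count: (2 - 2*2) / (2 + 2)

  # duplicated individual
  dup <- rbind(a = c(0L, 1L, 1L, 2L, 0L), b = c(0L, 1L, 1L, 2L, 0L))
  colnames(dup) <- paste0("chr1:", 1:5)
  expect_equal(king_kinship(dup)["a", "b"], 0.5)
})

test_that("KING kinship equals the brute-force counting oracle on random matrices", {
  set.seed(61)
  for (rep in 1:3) {
    g <- matrix(sample(c(0L, 1L, 2L, NA), 500, replace = TRUE,
                       prob = c(0.3, 0.3, 0.3, 0.1)), 10, 50)
    rownames(g) <- sprintf("i%02d", 1:10)
    colnames(g) <- sprintf("chr1:%d", 1:50)
    expect_equal(king_kinship(g), king_oracle(g))
  }
})

test_that("kinship is invariant to locus order and to ref/alt relabeling", {
  set.seed(62)
  g <- matrix(sample(c(0L, 1L, 2L, NA), 400, replace = TRUE), 8, 50)
  rownames(g) <- sprintf("i%d", 1:8)
  colnames(g) <- sprintf("chr1:%d", 1:50)
  base <- king_kinship(g)
  perm <- sample(ncol(g))
  expect_equal(king_kinship(g[, perm]), base)
  flipped <- g
  flipped[, 1:25] <- 2L - flipped[, 1:25]
  expect_equal(king_kinship(flipped), base)
})

test_that("pairs without shared informative loci warn and go missing", {
  g <- rbind(a = c(0L, 1L, NA, NA), b = c(NA, NA, 1L, 2L),
             c = c(0L, 1L, 1L, 2L))
  colnames(g) <- paste0("chr1:", 1:4)
  expect_warning(phi <- king_kinship(g), "no shared informative loci")
  expect_true(is.na(phi["a", "b"]))
  expect_false(is.na(phi["a", "c"]))
})

test_that("FST behaves at its limits and matches the per-locus oracle", {
  set.seed(63)
  # identical allele frequencies: near-zero differentiation
  g0 <- matrix(rbinom(100 * 1000, 2, 0.4), 100, 1000)
  rownames(g0) <- sprintf("i%03d", 1:100)
  colnames(g0) <- sprintf("chr1:%d", 1:1000)
  f0 <- mean_fst(g0, rownames(g0)[1:50], rownames(g0)[51:100])
  expect_lt(abs(f0$mean_fst), 0.01)

  # fixed difference: per-locus theta = 1
  gf <- rbind(matrix(0L, 10, 1), matrix(2L, 10, 1))
  rownames(gf) <- sprintf("i%02d", 1:20)
  colnames(gf) <- "chr1:1"
  ff <- mean_fst(gf, rownames(gf)[1:10], rownames(gf)[11:20])
  expect_equal(unname(ff$per_locus[1]), 1)

  # vectorized implementation equals the scalar transcription
  set.seed(64)
  ga <- matrix(rbinom(20 * 200, 2, runif(200, 0.1, 0.9)[rep(1:200, each = 20)]),
               20, 200, byrow = FALSE)
  ga[sample(length(ga), 50)] <- NA
  rownames(ga) <- sprintf("i%02d", 1:20)
  colnames(ga) <- sprintf("chr1:%d", 1:200)
  ids_a <- rownames(ga)[1:10]; ids_b <- rownames(ga)[11:20]
  f <- mean_fst(ga, ids_a, ids_b)
  oracle <- wc_theta_oracle(ga[ids_a, ], ga[ids_b, ])
  expect_equal(unname(f$per_locus), oracle, tolerance = 1e-6)

  expect_error(mean_fst(ga, ids_a, c(ids_b, ids_a[1])), "disjoint")
})
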