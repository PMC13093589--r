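# Independent oracles and small fixture builders shared across tests.

# Brute-force Benjamini-Hochberg step-up: for the i-th smallest p, the
# adjusted value is the minimum of m * p_(k) / k over all ranks k >= i,
# capped at 1.  O(m^2) by construction, structurally unlike the cummin
# implementation it checks.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (k in i:m) best <- min(best, m * p[o[k]] / k)
    adj_sorted[i] <- min(best, 1)
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Brute-force KING-robust kinship: explicit per-pair counting over the
# shared non-missing loci.
king_oracle <- function(g) {
  n <- nrow(g)
  phi <- matrix(NA_real_, n, n, dimnames = list(rownames(g), rownames(g)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      sh <- which(!is.na(g[i, ]) & !is.na(g[j, ]))
      gi <- g[i, sh]; gj <- g[j, sh]
      n_hethet <- sum(gi == 1 & gj == 1)
      n_opp <- sum(abs(gi - gj) == 2)
      den <- sum(gi == 1) + sum(gj == 1)
      if (den > 0) phi[i, j] <- (n_hethet - 2 * n_opp) / den
    }
  }
  phi
}

# Scalar per-locus transcription of the two-population Weir-Cockerham
# theta from observed allele/heterozygote frequencies.
wc_theta_oracle <- function(g1, g2) {
  stopifnot(ncol(g1) == ncol(g2))
  sapply(seq_len(ncol(g1)), function(l) {
    x1 <- g1[, l]; x2 <- g2[, l]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 == 0 || n2 == 0) return(NA_real_)
    p1 <- mean(x1) / 2; p2 <- mean(x2) / 2
    h1 <- mean(x1 == 1); h2 <- mean(x2 == 1)
    r <- 2
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    if (!is.finite(a + b + cc) || a + b + cc <= 0) return(NA_real_)
    a / (a + b + cc)
  })
}

# Small labelled count matrix.
toy_counts <- function(values, n_genes, n_samples) {
  m <- matrix(values, n_genes, n_samples)
  rownames(m) <- sprintf("g%02d", seq_len(n_genes))
  colnames(m) <- sprintf("s%02d", seq_len(n_samples))
  storage.mode(m) <- "integer"
  m
}

# Gaussian blobs around given centers, 2-D.
make_blobs <- function(centers, n_per = 20, sd = 0.3) {
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))
  }))
}

# Group-means row in the shape classify_mode() expects.
gm_row <- function(hh, hn, nh, nn, se = 0.1, gene_id = "g1") {
  data.frame(gene_id = gene_id,
             mean_HH = hh, se_HH = se, mean_HN = hn, se_HN = se,
             mean_NH = nh, se_NH = se, mean_NN = nn, se_NN = se,
             direction = ifelse(hh > nn, "up_in_HH",
                                ifelse(hh < nn, "up_in_NN", "tie")),
             stringsAsFactors = FALSE)
}
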