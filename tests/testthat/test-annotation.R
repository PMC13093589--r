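two_blob_terms <- function() {
  set.seed(70)
  n <- 12
  data.frame(
    go_id = sprintf("GO:%07d", 1:(2 * n)),
    name = c("anatomical structure development", "cellular developmental process",
             "cell differentiation", "animal organ development",
             "tissue development", "epithelium development",
             "muscle structure development", "animal organ morphogenesis",
             "anatomical structure morphogenesis", "embryo development",
             "neuron development", "skeletal system development",
             "behavior", "locomotory behavior", "adult locomotory behavior",
             "system process", "muscle system process", "muscle contraction",
             "blood circulation", "circulatory system process",
             "cell activation", "leukocyte activation",
             "response to stress", "signal transduction"),
    count = c(60, 47, 46, 40, 27, 17, 17, 19, 35, 16, 14, 10,
              18, 11, 6, 22, 12, 7, 8, 8, 8, 8, 37, 26),
    pc1 = c(rnorm(n, -5, 0.4), rnorm(n, 5, 0.4)),
    pc2 = c(rnorm(n, 0, 0.4), rnorm(n, 0, 0.4)),
    stringsAsFactors = FALSE
  )
}

test_that("the knee rule recovers the planted blob count", {
  set.seed(71)
  two <- make_blobs(rbind(c(0, 0), c(8, 8)))
  expect_equal(choose_k(two, 1:10, seed = 72), 2L)
  expect_equal(choose_k(matrix(1, 30, 2), 1:10, seed = 72), 1L)
})

test_that("the knee rule is invariant to rescaling the coordinates", {
  set.seed(73)
  pts <- make_blobs(rbind(c(0, 0), c(6, 0), c(3, 5)))
  k1 <- choose_k(pts, 1:10, seed = 74)
  k2 <- choose_k(pts * 1000, 1:10, seed = 74)
  expect_equal(k1, 3L)
  expect_equal(k1, k2)
})

test_that("clustering names each cluster by its most widely shared term", {
  terms <- two_blob_terms()
  sol <- cluster_terms(terms, k = 2, seed = 75)
  expect_equal(sort(sol$clusters$name),
               sort(c("anatomical structure development", "response to stress")))
  expect_true(all(table(sol$assignments$cluster) == 12))
  # the count-60 term names its own blob
  dev_cluster <- sol$assignments$cluster[
    sol$assignments$name == "anatomical structure development"]
  expect_equal(sol$clusters$name[sol$clusters$cluster == dev_cluster],
               "anatomical structure development")
  expect_error(cluster_terms(terms, k = 100), "exceeds")
})

test_that("clustering is deterministic under canonical ordering", {
  terms <- two_blob_terms()
  a <- cluster_terms(terms, k = 2, seed = 76)
  b <- cluster_terms(terms[sample(nrow(terms)), ], k = 2, seed = 76)
  expect_equal(a$assignments, b$assignments, ignore_attr = TRUE)
  expect_equal(a$clusters$name, b$clusters$name)
})

test_that("a single term forms its own named cluster", {
  one <- data.frame(go_id = "GO:0000001", name = "behavior", count = 5,
                    pc1 = 0, pc2 = 0)
  sol <- cluster_terms(one, k = 1, seed = 77)
  expect_equal(sol$clusters$name, "behavior")
  expect_equal(sol$assignments$cluster, 1L)
})

test_that("the returned solution is at least as tight as single-start fits", {
  terms <- two_blob_terms()
  sol <- cluster_terms(terms, k = 3, seed = 78)
  pts <- as.matrix(terms[order(terms$go_id), c("pc1", "pc2")])
  singles <- withr::with_seed(79, {
    replicate(5, kmeans(pts, 3, nstart = 1)$tot.withinss)
  })
  expect_true(all(sol$tot_withinss <= singles + 1e-8))
})

test_that("word labelling finds the modal token and honours small clusters", {
  terms <- data.frame(go_id = c("GO:1", "GO:2"),
                      name = c("neuron development", "embryo development"),
                      count = c(3, 2), pc1 = 0, pc2 = 0)
  wl <- word_labels(terms)
  expect_equal(wl$dominant_word, "development")
  expect_equal(wl$top_terms, c("neuron development", "embryo development"))

  single <- terms[1, ]
  expect_equal(word_labels(single)$top_terms, "neuron development")

  five <- data.frame(go_id = sprintf("GO:%d", 1:5),
                     name = c("behavior", "locomotory behavior",
                              "adult locomotory behavior", "muscle system process",
                              "muscle contraction"),
                     count = 5:1, pc1 = 0, pc2 = 0)
  wl5 <- word_labels(five, n_top = 6)
  expect_length(wl5$top_terms, 5)
  expect_equal(wl5$dominant_word, "behavior")
})

test_that("stop-words are excluded from the frequency count", {
  terms <- data.frame(go_id = c("GO:1", "GO:2", "GO:3"),
                      name = c("regulation of transport",
                               "regulation of growth", "vesicle transport"),
                      count = c(3, 2, 1), pc1 = 0, pc2 = 0)
  expect_equal(word_labels(terms)$dominant_word, "transport")
})
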