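## Summarisation of a GO-term semantic map (the tabular export of a
## semantic-similarity reduction): k-means on the 2-D coordinates, a knee
## rule for choosing k, cluster naming by the most widely shared term, and
## word-frequency labelling.

GO_STOPWORDS <- c("of", "to", "in", "the", "and", "process", "regulation")

#' Choose the number of k-means clusters by the knee rule
#'
#' Computes the within-cluster sum of squares across `k_range` (10 seeded
#' restarts each) and locates the bend of the curve: both axes of the
#' log-WSS curve are rescaled to \[0, 1\] and the chosen k maximises the
#' perpendicular distance from the straight line joining the curve's
#' endpoints.  The bend is assessed on the log scale because for
#' well-separated clusters the flattening of the curve beyond the true
#' cluster count — the feature a reader of an elbow plot keys on — is
#' otherwise swamped by the first few large drops.  Scale-invariant in the
#' coordinates (rescaling shifts log-WSS by a constant).
#'
#' @param points numeric matrix of 2-D coordinates.
#' @param k_range candidate cluster counts.
#' @param seed optional integer seed.
#' @param nstart k-means restarts per k.
#' @return chosen k (1 for degenerate all-identical input).
#' @export
choose_k <- function(points, k_range = 1:15, seed = NULL, nstart = 10) {
  points <- as.matrix(points)
  n_distinct <- nrow(unique(points))
  if (n_distinct == 1) return(1L)
  k_range <- sort(unique(pmin(k_range, n_distinct)))
  if (nrow(points) < max(k_range) + 1)
    stop("need more points than the largest candidate k")
  run <- function() {
    vapply(k_range, function(k) {
      if (k == 1) sum(scale(points, scale = FALSE)^2)
      else kmeans(points, centers = k, nstart = nstart, iter.max = 50)$tot.withinss
    }, 0)
  }
  wss <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (diff(range(wss)) == 0) return(min(k_range))
  log_wss <- log(pmax(wss, max(wss) * 1e-10))
  x <- (k_range - min(k_range)) / diff(range(k_range))
  y <- (log_wss - min(log_wss)) / diff(range(log_wss))
  # perpendicular distance from the line through the first and last point
  dx <- x[length(x)] - x[1]; dy <- y[length(y)] - y[1]
  dist <- abs(dx * (y[1] - y) - (x[1] - x) * dy) / sqrt(dx^2 + dy^2)
  as.integer(k_range[which.max(dist)])
}

#' Cluster GO terms on their semantic coordinates
#'
#' Runs seeded k-means (10 restarts, best by total within-cluster sum of
#' squares) on `(pc1, pc2)` after canonically sorting the table by GO id,
#' so identical seeds give identical solutions regardless of input row
#' order.  Each cluster is named by its member term shared by the largest
#' number of DEGs (ties broken alphabetically by GO id) and labelled with
#' its most frequent word.
#'
#' @param terms validated GO-term table (see [validate_terms()]).
#' @param k number of clusters.
#' @param seed optional integer seed.
#' @param nstart k-means restarts.
#' @param n_top number of top terms to report per cluster.
#' @return list with `assignments` (per-term cluster) and `clusters`
#'   (per-cluster name, size, dominant word, top terms by count).
#' @export
cluster_terms <- function(terms, k, seed = NULL, nstart = 10, n_top = 10) {
  validate_terms(terms)
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(terms)) stop("k exceeds the number of terms")
  terms <- terms[order(terms$go_id), , drop = FALSE]
  pts <- as.matrix(terms[, c("pc1", "pc2")])
  fit_once <- function() {
    if (k == 1) list(cluster = rep(1L, nrow(terms)),
                     tot.withinss = sum(scale(pts, scale = FALSE)^2))
    else kmeans(pts, centers = k, nstart = nstart, iter.max = 50)
  }
  km <- if (is.null(seed)) fit_once() else withr::with_seed(seed, fit_once())
  terms$cluster <- km$cluster

  clusters <- lapply(sort(unique(terms$cluster)), function(cl) {
    sub <- terms[terms$cluster == cl, , drop = FALSE]
    sub <- sub[order(-sub$count, sub$go_id), , drop = FALSE]
    wl <- word_labels(sub, n_top = min(n_top, nrow(sub)))
    data.frame(cluster = cl, name = sub$name[1], name_go_id = sub$go_id[1],
               n_terms = nrow(sub), max_count = sub$count[1],
               dominant_word = wl$dominant_word,
               top_terms = paste(wl$top_terms, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  list(assignments = terms[, c("go_id", "name", "count", "cluster")],
       clusters = do.call(rbind, clusters),
       tot_withinss = km$tot.withinss)
}

#' Dominant word and top terms of a term set
#'
#' Splits term names on whitespace, lowercases, drops a small documented
#' stop-word list, and returns the modal token (ties broken
#' alphabetically) together with the `n_top` terms carried by the most
#' DEGs (fewer when the cluster is smaller).
#'
#' @param terms term table rows (needs `name` and `count`).
#' @param n_top number of top terms to label.
#' @param stopwords tokens excluded from the frequency count.
#' @return list with `dominant_word` and `top_terms`.
#' @export
word_labels <- function(terms, n_top = 6, stopwords = GO_STOPWORDS) {
  if (nrow(terms) == 0) stop("cluster is empty")
  tokens <- tolower(unlist(strsplit(terms$name, "\\s+")))
  tokens <- tokens[nzchar(tokens) & !(tokens %in% stopwords)]
  dominant <- if (length(tokens) == 0) NA_character_ else {
    tab <- table(tokens)
    names(tab)[order(-tab, names(tab))][1]
  }
  ord <- order(-terms$count, terms$name)
  list(dominant_word = dominant,
       top_terms = terms$name[ord][seq_len(min(n_top, nrow(terms)))])
}
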