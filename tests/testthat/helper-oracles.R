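# Brute-force average-linkage agglomerator, independent of hclust: keeps the
# full item-level distance matrix and recomputes every cluster-pair mean
# distance at each step. Only viable for a handful of items, which is the
# point — it is the oracle, not the implementation.
brute_average_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h - 1e-12) {
          best_h <- h
          best <- c(j, i)
        }
      }
    }
    a <- clusters[[best[1]]]
    b <- clusters[[best[2]]]
    coph[a, b] <- best_h
    coph[b, a] <- best_h
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  dimnames(coph) <- dimnames(d)
  list(heights = heights, cophenetic = coph)
}
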