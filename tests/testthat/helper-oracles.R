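# Exhaustive spanning-tree minimum via Prüfer sequences: every labelled
# tree on n nodes corresponds to one of the n^(n-2) sequences, so scanning
# them all gives the true minimum total weight. Independent of the
# Kruskal implementation under test.
prufer_min_weight <- function(w) {
  n <- nrow(w)
  if (n == 2) return(w[1, 2])
  seqs <- do.call(expand.grid, rep(list(seq_len(n)), n - 2))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    pr <- as.integer(seqs[r, ])
    degree <- rep(1L, n)
    for (v in pr) degree[v] <- degree[v] + 1L
    total <- 0
    avail <- degree
    for (v in pr) {
      leaf <- which(avail == 1L)[1]
      total <- total + w[leaf, v]
      avail[leaf] <- 0L
      avail[v] <- avail[v] - 1L
    }
    ends <- which(avail == 1L)
    total <- total + w[ends[1], ends[2]]
    best <- min(best, total)
  }
  best
}
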