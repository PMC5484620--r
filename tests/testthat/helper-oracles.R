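# Independent oracles used across tests. These deliberately take the
# dumbest correct route (per-base loops, adjacency-matrix closures, direct
# hypergeometric sums) so they share no code with the implementation.

# per-base diff oracle for T-to-C counting
oracle_t_to_c <- function(read_seq, ref_seq) {
  rv <- strsplit(ref_seq, "")[[1]]
  dv <- strsplit(read_seq, "")[[1]]
  n <- 0L
  for (i in seq_along(rv)) {
    if (rv[i] == "T" && dv[i] == "C") n <- n + 1L
  }
  n
}

# O(n^2) interval clustering oracle: pairwise-overlap adjacency matrix,
# transitive closure, component spans
oracle_cluster <- function(starts, ends) {
  n <- length(starts)
  adj <- outer(seq_len(n), seq_len(n), function(i, j) {
    starts[i] < ends[j] & starts[j] < ends[i]
  })
  reach <- adj
  repeat {
    nxt <- (reach %*% reach) > 0 | reach
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[reach[i, ]] <- cid
    }
  }
  spans <- t(vapply(seq_len(cid), function(k) {
    c(min(starts[comp == k]), max(ends[comp == k]))
  }, numeric(2)))
  spans[order(spans[, 1]), , drop = FALSE]
}

# direct hypergeometric tail sum: P(X >= k) for X ~ Hypergeom(K, N-K, n)
oracle_hyper_tail <- function(k, K, N, n) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# uniform random DNA of length n
rand_seq <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# small spec for fast tests
tiny_spec <- function(...) {
  simulation_spec(n_transcripts = 40L, mrnaseq_depth = 2e4, seed = 11L, ...)
}

# overlap-based site recovery: fraction of `a` rows overlapped by >= 1 `b` row
overlap_fraction <- function(a, b) {
  hit <- vapply(seq_len(nrow(a)), function(i) {
    any(b$transcript_id == a$transcript_id[i] &
          b$start < a$end[i] & b$end > a$start[i])
  }, logical(1))
  mean(hit)
}
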