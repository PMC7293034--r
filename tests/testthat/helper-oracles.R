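# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity so they stay
# independent of the package's vectorized implementations.

# V-plot by an explicit (fragment x reference) double loop.
brute_vplot <- function(frags, refs, W, len_range) {
  nL <- len_range[2] - len_range[1] + 1
  nO <- 2 * W + 1
  m <- matrix(0, nL, nO,
              dimnames = list(seq(len_range[1], len_range[2]), seq(-W, W)))
  f <- frags$fragments
  for (i in seq_len(nrow(f))) {
    if (f$length[i] < len_range[1] || f$length[i] > len_range[2]) next
    for (j in seq_len(nrow(refs))) {
      if (f$chrom[i] != refs$chrom[j]) next
      off <- f$center[i] - refs$pos[j]
      if (refs$strand[j] == "-") off <- -off
      if (abs(f$center[i] - refs$pos[j]) <= W) {
        r <- f$length[i] - len_range[1] + 1
        c <- off + W + 1
        m[r, c] <- m[r, c] + 1
      }
    }
  }
  m
}

# Best 2-partition of points (rows) minimizing the total within-cluster
# sum of pairwise distances, by exhaustive enumeration.
brute_best_2partition <- function(m) {
  n <- nrow(m)
  d <- as.matrix(dist(m))
  best <- NULL
  best_cost <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {   # fix point 1 in cluster 1
    in1 <- c(TRUE, as.logical(bitwAnd(mask, 2^(seq_len(n - 1) - 1))))
    if (all(in1) || !any(in1)) next
    cost <- sum(d[in1, in1]) / 2 + sum(d[!in1, !in1]) / 2
    if (cost < best_cost) {
      best_cost <- cost
      best <- in1
    }
  }
  best
}

# Uniform random fragments on a toy chromosome.
random_fragment_set <- function(n, seed, chrom = "chrS", span = 1e5,
                                len_min = 30, len_max = 200) {
  set.seed(seed)
  start <- sample.int(span, n, replace = TRUE) + 500L
  len <- sample.int(len_max - len_min + 1L, n, replace = TRUE) + len_min - 1L
  fragment_set(chrom, start, start + len, label = "random")
}

# Partition as an order-independent set of sets, for comparing cluster
# assignments up to relabelling.
partition_sets <- function(assignment, ids = names(assignment)) {
  unname(lapply(split(ids, assignment), sort))
}
canonical_partition <- function(assignment, ids = names(assignment)) {
  p <- partition_sets(assignment, ids)
  p[order(vapply(p, `[`, character(1), 1))]
}
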