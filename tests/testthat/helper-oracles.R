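# Independent oracles used to check the dynamic-programming and linkage
# implementations on small instances.

# Exhaustive warping-path minimisation: enumerates every admissible path
# (endpoints pinned, steps (1,0), (0,1), (1,1)) by recursion with
# branch-and-bound pruning, which never discards an optimal path.
oracle_dtw <- function(a, b, metric = "sqeuclidean") {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!is.matrix(a)) a <- matrix(a, ncol = 1)
  N <- nrow(a); M <- nrow(b)
  best <- Inf
  rec <- function(i, j, cost) {
    cost <- cost + local_distance(a[i, ], b[j, ], metric)
    if (cost >= best) return(invisible())
    if (i == N && j == M) {
      best <<- cost
      return(invisible())
    }
    if (i < N && j < M) rec(i + 1, j + 1, cost)
    if (i < N) rec(i + 1, j, cost)
    if (j < M) rec(i, j + 1, cost)
  }
  rec(1L, 1L, 0)
  best
}

# Naive complete-linkage agglomeration over a square distance matrix.
# Returns merge heights (in merge order) and the partition after each
# merge, canonicalised by order of first appearance.
oracle_complete_linkage <- function(D) {
  n <- nrow(D)
  members <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  partitions <- list()
  while (length(members) > 1L) {
    k <- length(members)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        h <- max(D[members[[i]], members[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    merged <- c(members[[best[2]]], members[[best[3]]])
    members <- c(members[-c(best[2], best[3])], list(merged))
    heights <- c(heights, best[1])
    lab <- integer(n)
    for (g in seq_along(members)) lab[members[[g]]] <- g
    partitions[[length(partitions) + 1L]] <- canonical_partition(lab)
  }
  list(heights = heights, partitions = partitions)
}

# Relabel a partition by order of first appearance so that two label
# vectors describing the same grouping compare equal.
canonical_partition <- function(labels) {
  match(labels, unique(labels))
}

make_test_profile <- function(values, name = "p", bin_size = 50L) {
  dgw_profile(values, region = data.frame(
    chrom = "chrT", start = 0L,
    end = length(values) * bin_size, name = name, strand = "*",
    stringsAsFactors = FALSE), bin_size = bin_size)
}

random_profile_set <- function(n, len_range = c(5L, 12L), name_prefix = "r") {
  profile_set(lapply(seq_len(n), function(i) {
    len <- sample(len_range[1]:len_range[2], 1L)
    make_test_profile(round(runif(len, 0, 20)) + 1,
                      name = paste0(name_prefix, i))
  }))
}
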