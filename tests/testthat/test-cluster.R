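raw_cfg <- function(...) dtw_config(normalize_heights = FALSE, ...)

test_that("pairwise distances honour flip awareness and worker count", {
  a <- make_test_profile(c(0, 1, 4, 2, 0), "a")
  b <- make_test_profile(rev(c(0, 1, 4, 2, 0)), "b")
  cc <- make_test_profile(c(5, 5, 0, 0, 1), "c")
  pset <- profile_set(list(a, b, cc))
  dm <- pairwise_distances(pset, raw_cfg())
  M <- as.matrix(dm$dist)
  expect_equal(M["a", "b"], 0)            # reversal recognised
  expect_true(dm$flipped[1])
  expect_gt(M["a", "c"], 0)
  # identical profiles are all at distance zero
  same <- profile_set(lapply(1:3, function(i)
    make_test_profile(c(1, 3, 1), paste0("s", i))))
  expect_true(all(as.vector(pairwise_distances(same, raw_cfg())$dist) == 0))
  # two profiles give the single flip-aware distance
  two <- pairwise_distances(pset[1:2], raw_cfg())
  expect_equal(as.vector(two$dist),
               flip_aware_distance(a, b, raw_cfg())$distance)
})

test_that("the distance matrix is independent of the worker count", {
  set.seed(41)
  pset <- random_profile_set(12)
  d1 <- pairwise_distances(pset, raw_cfg(), workers = 1L)
  d2 <- pairwise_distances(pset, raw_cfg(), workers = 3L)
  expect_equal(as.vector(d1$dist), as.vector(d2$dist))
  expect_equal(d1$flipped, d2$flipped)
})

test_that("complete linkage reproduces the hand-worked three-leaf tree", {
  pset <- profile_set(lapply(1:3, function(i)
    make_test_profile(c(1, 1, 1), paste0("p", i))))
  dm <- pairwise_distances(pset, raw_cfg())
  dm$dist[] <- c(1, 10, 10)  # d(1,2)=1, d(1,3)=10, d(2,3)=10
  dend <- build_dendrogram(dm, pset)
  expect_equal(dend$hclust$height, c(1, 10))
  expect_equal(sort(dend$hclust$merge[1, ]), c(-2, -1))
})

test_that("dendrograms have exactly n-1 nodes and sane cuts", {
  set.seed(43)
  for (n in c(2L, 3L, 17L, 50L)) {
    pset <- random_profile_set(n, name_prefix = paste0("n", n, "_"))
    dend <- build_dendrogram(pairwise_distances(pset, raw_cfg()), pset)
    expect_equal(nrow(dend$hclust$merge), n - 1L)
    expect_equal(length(unique(cut_dendrogram(dend, n_clusters = 1L))), 1L)
    expect_equal(length(unique(cut_dendrogram(dend, n_clusters = n))), n)
    expect_error(cut_dendrogram(dend, n_clusters = n + 1L), "between")
    expect_error(cut_dendrogram(dend), "exactly one")
  }
})

test_that("linkage agrees with a brute-force complete-linkage oracle", {
  set.seed(47)
  for (rep in 1:8) {
    n <- sample(3:6, 1)
    pset <- random_profile_set(n)
    dm <- pairwise_distances(pset, raw_cfg())
    dm$dist[] <- runif(length(dm$dist), 1, 100)  # random, tie-free heights
    dend <- build_dendrogram(dm, pset)
    oracle <- oracle_complete_linkage(as.matrix(dm$dist))
    expect_equal(dend$hclust$height, oracle$heights, tolerance = 1e-12)
    for (k in seq_len(n - 1L)) {
      got <- canonical_partition(cut_dendrogram(dend, n_clusters = n - k))
      expect_equal(got, oracle$partitions[[k]])
    }
  }
})

test_that("permuting the input permutes labels but not the partition", {
  set.seed(53)
  pset <- random_profile_set(10)
  dend <- build_dendrogram(pairwise_distances(pset, raw_cfg()), pset)
  lab <- cut_dendrogram(dend, n_clusters = 3L)
  perm <- sample(length(pset))
  pset2 <- pset[perm]
  dend2 <- build_dendrogram(pairwise_distances(pset2, raw_cfg()), pset2)
  lab2 <- cut_dendrogram(dend2, n_clusters = 3L)
  # same grouping once mapped back to the original order
  expect_equal(canonical_partition(lab[perm]), canonical_partition(lab2))
})

test_that("leaf prototypes are the profiles themselves", {
  pset <- profile_set(list(make_test_profile(c(1, 5, 2), "a"),
                           make_test_profile(c(2, 2, 2), "b")))
  dend <- build_dendrogram(pairwise_distances(pset, raw_cfg()), pset)
  leaf <- compute_prototype(dend, -1L)
  expect_equal(leaf$values[, 1], c(1, 5, 2))
  expect_equal(leaf$weight, 1L)
})

test_that("prototype of identical or mirrored profiles is the shape itself", {
  a <- c(0, 1, 4, 1, 0, 0)
  same <- profile_set(list(make_test_profile(a, "x"),
                           make_test_profile(a, "y")))
  dend <- build_dendrogram(pairwise_distances(same, raw_cfg()), same)
  expect_equal(node_prototypes(dend)[[1]]$values[, 1], a)
  flipped <- profile_set(list(make_test_profile(a, "x"),
                              make_test_profile(rev(a), "y")))
  dendf <- build_dendrogram(pairwise_distances(flipped, raw_cfg()), flipped)
  # the lighter child is flip-canonicalised onto the first child
  expect_equal(node_prototypes(dendf)[[1]]$values[, 1], a)
})

test_that("prototype averaging is weighted towards the heavier child", {
  heavy <- matrix(c(0, 4, 0), ncol = 1)
  light <- matrix(c(0, 0, 4), ncol = 1)
  avg <- dgwarp:::average_prototypes(light, 1L, heavy, 3L, raw_cfg())
  # hand-derived: optimal path (1,1),(1,2),(2,3),(3,3) on (heavy, light),
  # weighted values (0, 0, 4, 1), pooled by heavy index -> (0, 4, 1)
  expect_equal(avg[, 1], c(0, 4, 1))
})

test_that("prototype weights equal the leaf counts under each node", {
  set.seed(59)
  pset <- random_profile_set(9)
  dend <- build_dendrogram(pairwise_distances(pset, raw_cfg()), pset)
  protos <- node_prototypes(dend)
  sizes <- integer(nrow(dend$hclust$merge))
  size_of <- function(id) if (id < 0) 1L else sizes[id]
  for (k in seq_len(nrow(dend$hclust$merge))) {
    sizes[k] <- size_of(dend$hclust$merge[k, 1]) +
      size_of(dend$hclust$merge[k, 2])
    expect_equal(protos[[k]]$weight, sizes[k])
  }
  expect_equal(protos[[length(protos)]]$weight, length(pset))
})

test_that("warping a prototype onto itself is the identity", {
  set.seed(61)
  pset <- random_profile_set(6)
  dend <- build_dendrogram(pairwise_distances(pset, raw_cfg()), pset)
  proto <- node_prototypes(dend)[[5]]
  w <- warp_onto_prototype(proto$values, proto, raw_cfg())
  expect_equal(w$values, proto$values)
  expect_false(w$flipped)
})

test_that("warped profiles have the prototype's length", {
  set.seed(67)
  pset <- random_profile_set(5)
  dend <- build_dendrogram(pairwise_distances(pset, raw_cfg()), pset)
  proto <- node_prototypes(dend)[[4]]
  for (p in pset) {
    w <- warp_onto_prototype(p, proto, raw_cfg())
    expect_equal(nrow(w$values), proto$length)
  }
})

test_that("clustering artefacts serialize to parseable text", {
  set.seed(71)
  pset <- random_profile_set(6)
  dm <- pairwise_distances(pset, raw_cfg())
  dend <- build_dendrogram(dm, pset)
  out <- withr::local_tempdir()
  write_distance_matrix(dm, file.path(out, "dist"))
  sq <- utils::read.table(file.path(out, "dist_square.tsv"), header = TRUE,
                          sep = "\t", check.names = FALSE)
  expect_equal(dim(sq), c(6L, 7L))
  expect_equal(as.numeric(sq[1, 3]), as.matrix(dm$dist)[1, 2],
               tolerance = 1e-8)
  write_linkage(dend, file.path(out, "linkage.tsv"))
  lk <- utils::read.table(file.path(out, "linkage.tsv"), header = TRUE)
  expect_equal(nrow(lk), 5L)
  expect_equal(lk$size[5], 6L)
  write_newick(dend, file.path(out, "tree.nwk"))
  tree <- ape::read.tree(file.path(out, "tree.nwk"))
  expect_equal(sort(tree$tip.label), sort(names(pset)))
  write_prototypes(node_prototypes(dend), file.path(out, "protos.tsv"))
  expect_gt(file.size(file.path(out, "protos.tsv")), 0)
})
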