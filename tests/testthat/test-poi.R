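test_that("genomic points map to bins by the half-open floor rule", {
  r <- data.frame(chrom = "chr1", start = 100, end = 300, name = "p",
                  strand = "*", stringsAsFactors = FALSE)
  expect_equal(locate_poi_in_profile(100, r, 50), 0L)
  expect_equal(locate_poi_in_profile(225, r, 50), 2L)
  expect_true(is.na(locate_poi_in_profile(300, r, 50)))  # end is exclusive
  expect_true(is.na(locate_poi_in_profile(99, r, 50)))
  # flipped display reflects the index
  expect_equal(locate_poi_in_profile(100, r, 50, flipped = TRUE), 3L)
})

test_that("indices map through warping paths by the lower median", {
  diag_path <- cbind(1:5, 1:5)
  for (i in 0:4) expect_equal(map_index_through_path(diag_path, i), i)
  fan <- rbind(c(1, 1), c(2, 2), c(3, 5), c(3, 6), c(3, 7), c(4, 8))
  expect_equal(map_index_through_path(fan, 2L), 5L)  # targets {5,6,7} -> median 6, 0-based 5
  expect_equal(map_index_through_path(fan, 3L), 7L)
  # flipped source index is reflected before lookup
  expect_equal(map_index_through_path(diag_path, 0L, flipped = TRUE,
                                      source_length = 5L), 4L)
  expect_error(map_index_through_path(diag_path, 5L), "i <")
})

test_that("path mapping is monotone in the source index", {
  set.seed(83)
  for (rep in 1:20) {
    a <- runif(sample(5:10, 1)); b <- runif(sample(5:10, 1))
    p <- dtw_align(a, b, dtw_config(normalize_heights = FALSE,
                                    band_width = 0L))$path
    mapped <- vapply(seq_along(a) - 1L, function(i)
      map_index_through_path(p, i, source_length = length(a)), numeric(1))
    expect_true(all(diff(mapped) >= 0))
  }
})

test_that("entropy change quantifies concentration after warping", {
  # identity warp: no change
  pos <- c(0.5, 2.5, 4.5, 6.5, 8.5)
  expect_equal(entropy_change(pos, pos, n_bins = 10), 0)
  # uniform over 10 bins vs uniform over 5 of 10 bins:
  # (ln 10 - ln 5) / ln 10 = 30.103% decrease
  raw <- seq(0.5, 9.5, by = 1)
  warped <- rep(seq(0.5, 4.5, by = 1), 2)
  expect_equal(entropy_change(raw, warped, n_bins = 10),
               (log(10) - log(5)) / log(10) * 100, tolerance = 1e-10)
  # all raw positions in one bin: undefined, reported as NA
  expect_warning(out <- entropy_change(c(1.1, 1.2), c(1, 5), n_bins = 10),
                 "undefined")
  expect_true(is.na(out))
})

test_that("entropy change is invariant to uniform axis scaling", {
  set.seed(89)
  raw <- runif(30, 0, 40); lens <- rep(40, 30)
  warped <- runif(30, 0, 40)
  a <- entropy_change(raw, warped, n_bins = 20, source_lengths = lens,
                      target_length = 40)
  b <- entropy_change(raw * 3, warped, n_bins = 20,
                      source_lengths = lens * 3, target_length = 40)
  expect_equal(a, b)
})

test_that("positional histograms expose counts and entropy bounds", {
  h <- poi_histogram(c(0, 1, 2, 3), n_bins = 4)
  expect_equal(h$counts, rep(1L, 4))
  expect_equal(h$entropy, log(4))
  h1 <- poi_histogram(rep(0.5, 10), n_bins = 4)
  expect_equal(h1$entropy, 0)
})

test_that("the bootstrap summarises per-cluster changes reproducibly", {
  x <- c(1.2, 3.4, 0.5, 2.2, NA, 4.1)
  b1 <- bootstrap_mean_entropy_change(x, n_boot = 2000L, rng_seed = 11L)
  b2 <- bootstrap_mean_entropy_change(x, n_boot = 2000L, rng_seed = 11L)
  expect_identical(b1, b2)
  expect_equal(b1$n_clusters, 5L)
  expect_equal(b1$mean, mean(x, na.rm = TRUE))
  expect_lte(b1$ci_lower, b1$mean)
  expect_gte(b1$ci_upper, b1$mean)
  expect_error(bootstrap_mean_entropy_change(NA_real_), "no defined")
})

test_that("enrichment curves behave at the uniform and concentrated extremes", {
  mk_regions <- function(starts, width = 1000L, chrom = "chr1") {
    data.frame(chrom = chrom, start = starts, end = starts + width,
               name = paste0("r", seq_along(starts), "_", starts),
               strand = "*", stringsAsFactors = FALSE)
  }
  clusters <- list(a = mk_regions(0L), b = mk_regions(10000L))
  # counts (1, 3) over equal-size clusters
  tf <- data.frame(chrom = "chr1",
                   start = c(100L, 10100L, 10300L, 10500L),
                   end = c(200L, 10200L, 10400L, 10600L),
                   name = paste0("tf", 1:4), strand = "*",
                   stringsAsFactors = FALSE)
  enr <- tf_cluster_enrichment(clusters, tf)
  expect_equal(enr$table$normalized, c(0.25, 0.75))
  expect_equal(enr$cumulative, c(0.25, 1))
  # all peaks in one cluster: every bar zero except the last
  tf_one <- tf
  tf_one$start <- c(100L, 300L, 500L, 700L)
  tf_one$end <- tf_one$start + 100L
  enr_one <- tf_cluster_enrichment(clusters, tf_one)
  expect_equal(enr_one$cumulative, c(0, 1))
  expect_equal(enr_one$area, (2 - 1) / (2 * 2))  # (K-1)/(2K) for K = 2
})

test_that("area vanishes only at uniformity and grows with concentration", {
  mk <- function(starts) data.frame(
    chrom = "chr1", start = starts, end = starts + 1000L,
    name = paste0("r", starts), strand = "*", stringsAsFactors = FALSE)
  clusters <- list(mk(0L), mk(20000L), mk(40000L), mk(60000L))
  place <- function(counts) {
    starts <- unlist(mapply(function(base, k)
      if (k > 0) base + seq_len(k) * 17L else integer(0),
      c(0L, 20000L, 40000L, 60000L), counts, SIMPLIFY = FALSE))
    data.frame(chrom = "chr1", start = starts, end = starts + 10L,
               name = paste0("p", seq_along(starts)), strand = "*",
               stringsAsFactors = FALSE)
  }
  uniform <- tf_cluster_enrichment(clusters, place(c(5, 5, 5, 5)))
  expect_equal(uniform$area, 0)
  mild <- tf_cluster_enrichment(clusters, place(c(2, 4, 6, 8)))
  strong <- tf_cluster_enrichment(clusters, place(c(0, 0, 4, 16)))
  expect_gt(mild$area, 0)
  expect_gt(strong$area, mild$area)
  expect_lt(strong$area, 0.5)
})

test_that("warping concentrates planted markers on simulated clusters", {
  res <- marker_alignment_simulation(n_clusters = 20L, members = 15L,
                                     rng_seed = 5L)
  expect_equal(nrow(res), 20L)
  expect_gte(mean(res$entropy_warped < res$entropy_raw), 0.9)
  expect_true(all(res$entropy_raw >= 0))
})
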