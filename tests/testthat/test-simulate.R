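test_that("synthetic seeds have the documented shape classes", {
  seeds <- make_synthetic_seeds()
  expect_s3_class(seeds, "dgw_profiles")
  expect_equal(length(seeds), 5L)
  expect_equal(unname(n_bins(seeds)), rep(40L, 5))
  # bit-identical across calls (the texture streams are fixed)
  again <- make_synthetic_seeds()
  for (i in 1:5) expect_identical(seeds[[i]]$values, again[[i]]$values)
  # local maxima above half the global maximum, on a 3-bin smoothed
  # profile to ignore single-bin texture
  count_major_maxima <- function(p) {
    v <- stats::filter(p$values[, 1], rep(1 / 3, 3))
    v[is.na(v)] <- 0
    above <- v > max(v) / 2
    sum(diff(c(FALSE, above)) == 1)
  }
  expect_equal(count_major_maxima(seeds[[1]]), 2L)  # bimodal
  expect_equal(count_major_maxima(seeds[[4]]), 1L)  # unimodal
  expect_equal(count_major_maxima(seeds[[5]]), 1L)  # broad domain
  # realistic read-count amplitudes
  peaks <- vapply(seeds, function(p) max(p$values), numeric(1))
  expect_true(all(peaks >= 50 & peaks <= 500))
  # all five pairwise distinguishable after height normalization
  dm <- pairwise_distances(seeds, dtw_config())
  expect_true(all(dm$dist > 0))
})

test_that("seed bins scale with the requested resolution", {
  seeds80 <- make_synthetic_seeds(n_bins = 80L, bin_size = 25L)
  expect_equal(unname(n_bins(seeds80)), rep(80L, 5))
  expect_equal(seeds80[[1]]$region$end - seeds80[[1]]$region$start, 2000L)
})

test_that("corruption with all rates zero is the exact identity", {
  seed <- make_synthetic_seeds()[[2]]
  out <- corrupt_profile(seed, simulation_params(v = 0, p = 0, fp = 0))
  expect_identical(out$profile$values, seed$values)
  expect_false(out$flipped)
  expect_equal(out$index_map, seq_len(nrow(seed$values)))
})

test_that("a certain flip reverses the profile and its index map", {
  seed <- make_synthetic_seeds()[[1]]
  out <- corrupt_profile(seed, simulation_params(v = 0, p = 0, fp = 1))
  expect_true(out$flipped)
  expect_identical(out$profile$values[, 1], rev(seed$values[, 1]))
  expect_equal(out$index_map, rev(seq_len(nrow(seed$values))))
})

test_that("corruption that deletes every bin errors after one retry", {
  one_bin <- dgw_profile(5, region = data.frame(
    chrom = "chrT", start = 0L, end = 50L, name = "tiny", strand = "*"))
  params <- simulation_params(v = 0, p = 0.98, fp = 0,
                              p_delete = 0.98, p_duplicate = 0)
  set.seed(4)
  expect_error(corrupt_profile(one_bin, params), "every bin")
})

test_that("expected corrupted length matches the mutation process", {
  # per bin: removal with p/2, duplication with p/2, each extra copy
  # re-duplicating with probability p, so
  # E[length] = N * (1 - p/2 + (p/2) / (1 - p))
  seed <- make_test_profile(rep(10, 40))
  p <- 0.3
  analytic <- 40 * (1 - p / 2 + (p / 2) / (1 - p))
  set.seed(101)
  lens <- replicate(20000, {
    length(corrupt_profile(seed, simulation_params(v = 0, p = p,
                                                   fp = 0))$index_map)
  })
  expect_equal(mean(lens), analytic, tolerance = 0.005)
})

test_that("a simulated dataset has 500 balanced, reproducible profiles", {
  params <- simulation_params(v = 0.1, p = 0.1, fp = 0.1, rng_seed = 9L)
  sim <- simulate_dataset(params)
  expect_equal(length(sim$profiles), 500L)
  expect_equal(unname(table(sim$labels)), rep(100L, 5), ignore_attr = TRUE)
  sim2 <- simulate_dataset(params)
  expect_identical(lapply(sim$profiles, `[[`, "values"),
                   lapply(sim2$profiles, `[[`, "values"))
  expect_identical(sim$flipped, sim2$flipped)
  # excluding the seeds drops one member per class
  sim3 <- simulate_dataset(params, include_seeds = FALSE)
  expect_equal(length(sim3$profiles), 495L)
})

test_that("multi-class MCC scores confusion matrices as defined", {
  # identical partitions score 1 under any labelling
  expect_equal(mcc_multiclass(rep(1:2, each = 50), rep(c(2, 1), each = 50)), 1)
  expect_equal(mcc_multiclass(rep(letters[1:3], 10), rep(c(3, 1, 2), 10)), 1)
  # confusion matrix ((40,10),(10,40)) gives R_K = 0.6
  true <- rep(1:2, each = 50)
  clus <- c(rep(1, 40), rep(2, 10), rep(1, 10), rep(2, 40))
  expect_equal(mcc_multiclass(true, clus), 0.6)
  # invariance to relabeling of either side
  expect_equal(mcc_multiclass(3 - true, clus), 0.6)
  expect_equal(mcc_multiclass(true, ifelse(clus == 1, "x", "y")), 0.6)
  expect_error(mcc_multiclass(1:3, 1:4), "length")
  expect_error(mcc_multiclass(rep(1, 5), c(1, 2, 1, 2, 1)), "2 true classes")
})

test_that("MCC null behaviour matches its Monte-Carlo distribution", {
  set.seed(77)
  true <- rep(1:5, each = 100)
  vals_mapped <- replicate(1000, mcc_multiclass(true, sample(1:5, 500,
                                                             replace = TRUE)))
  vals_raw <- replicate(1000, mcc_multiclass(true, sample(1:5, 500,
                                                          replace = TRUE),
                                             map_clusters = FALSE))
  # without cluster-to-class mapping the null is centred at zero
  expect_lt(abs(mean(vals_raw)), 0.01)
  # the maximum-assignment mapping induces a small positive bias
  expect_gt(mean(vals_mapped), 0.03)
  expect_lt(mean(vals_mapped), 0.08)
})

test_that("the benchmark grid reports both pipelines per cell", {
  seeds <- make_synthetic_seeds()
  grid <- run_benchmark_grid(v_values = 0.1, p_values = 0.1, fp = 0.1,
                             n_per_seed = 19L, n_replicates = 2L,
                             seeds = seeds, rng_seed = 3L)
  expect_equal(nrow(grid), 2L)
  expect_true(all(c("mcc_dgw", "mcc_baseline") %in% names(grid)))
  expect_true(all(grid$mcc_dgw >= -1 & grid$mcc_dgw <= 1))
  # deterministic given the base seed
  grid2 <- run_benchmark_grid(v_values = 0.1, p_values = 0.1, fp = 0.1,
                              n_per_seed = 19L, n_replicates = 2L,
                              seeds = seeds, rng_seed = 3L)
  expect_identical(grid, grid2)
})
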