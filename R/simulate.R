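#' Parameters of the peak corruption process
#'
#' Describes how simulated peaks are derived from a seed profile:
#' multiplicative Gaussian noise on the bin counts, per-bin
#' deletion/duplication producing local shrinkage and stretching, and
#' whole-profile orientation flips emulating anti-sense transcription.
#'
#' The per-bin mutation probability `p` is split evenly between removal
#' and duplication (`p_delete = p_duplicate = p / 2` unless overridden);
#' a duplicated copy is itself subject to further duplication with
#' probability `p`, so local stretches have geometrically distributed
#' length.
#'
#' @param v Noise level: the standard deviation of the multiplicative
#'   Gaussian factor `g ~ N(1, sd = v)` applied to each bin (truncated at
#'   0 since counts cannot go negative).
#' @param p Per-bin mutation probability in `[0, 1)`.
#' @param fp Probability of reversing the whole simulated peak.
#' @param n_per_seed Simulated copies per seed (default 99, so 5 seeds
#'   plus their copies give a 500-peak dataset).
#' @param rng_seed Integer seed making [simulate_dataset()] deterministic.
#' @param p_delete,p_duplicate Optional unequal split of `p`.
#' @return A `dgw_sim_params` list.
#' @export
simulation_params <- function(v = 0.1, p = 0.1, fp = 0.1, n_per_seed = 99L,
                              rng_seed = NULL, p_delete = p / 2,
                              p_duplicate = p / 2) {
  stopifnot(v >= 0, p >= 0, p < 1, fp >= 0, fp <= 1, n_per_seed >= 0,
            p_delete >= 0, p_duplicate >= 0, p_delete + p_duplicate < 1)
  structure(list(v = v, p = p, fp = fp, n_per_seed = as.integer(n_per_seed),
                 rng_seed = rng_seed, p_delete = p_delete,
                 p_duplicate = p_duplicate),
            class = "dgw_sim_params")
}

# Gaussian bump evaluated on bin centres.
gauss_bump <- function(x, centre, width, amplitude) {
  amplitude * exp(-(x - centre)^2 / (2 * width^2))
}

# Mirror-symmetric, clipped, autocorrelated multiplicative texture: the
# bin-level roughness of real read-count profiles. Symmetry about the
# profile midpoint keeps a seed and its reversal close in the no-warp
# (bin-by-bin) metric, so orientation flips stay a within-class feature.
seed_texture <- function(n_bins, sd, rho, clip, stream_seed) {
  half <- ceiling(n_bins / 2)
  z <- with_local_seed(stream_seed, {
    w <- stats::rnorm(half + 10L)
    as.numeric(stats::filter(w, filter = rho, method = "recursive"))[-(1:10)]
  })
  z <- z / stats::sd(z) * sd
  z <- pmax(pmin(z, clip), -clip)
  u <- exp(z)
  c(u, rev(u)[(n_bins %% 2L + 1L):half])
}

#' Synthetic seed peak profiles
#'
#' Five seed shapes over `n_bins` bins (2 kb at the default 50 bp bin
#' size), emulating read-count profiles at gene starts: three bimodal
#' seeds (two sub-peaks with a trough between them, the typical
#' promoter-flanking histone-mark pattern) and two unimodal seeds of
#' very different widths (a narrow peak and a broad flat domain). Each
#' seed is a parametric bump mixture multiplied by a fixed,
#' seed-specific, autocorrelated bin-level texture (real bin counts are
#' jagged, not smooth), rounded to integer counts with bump amplitudes
#' in a realistic 50-300 count range.
#'
#' The five shapes are deliberately separated in features that survive
#' time warping, because warping erases bump positions and widths:
#' number of major peaks, sub-peak height ratio, the sustained "floor"
#' level of troughs and flanks (an empty trough cannot be faked by a
#' filled one under any monotone alignment), satellite bumps below the
#' half-maximum, sharp domain boundaries, and the bin-level texture
#' itself. Bump centres and the texture are mirror-symmetric about the
#' profile midpoint, so a seed and its reversal differ only in sub-peak
#' amplitudes and orientation flips remain a within-class perturbation
#' even for shape-naive (no-warp) comparisons.
#'
#' @param n_bins Bins per seed (default 40).
#' @param bin_size Bin width in bp (default 50).
#' @param texture_sd Log-scale standard deviation of the multiplicative
#'   texture, one value per seed (recycled; 0 gives smooth bump
#'   mixtures). The broad-domain seed defaults to a milder texture, as
#'   broad enrichment domains are smoother than sharp promoter peaks.
#' @param rng_seed Base seed of the texture streams; the default texture
#'   is part of the seed definition, so the defaults are bit-identical
#'   across runs.
#' @return A `dgw_profiles` set of 5 single-track profiles named
#'   `seed_1` ... `seed_5`.
#' @export
make_synthetic_seeds <- function(n_bins = 40L, bin_size = 50L,
                                 texture_sd = c(0.3, 0.3, 0.25, 0.3, 0.1),
                                 rng_seed = 40L) {
  x <- seq_len(n_bins)
  ctr <- (n_bins + 1) / 2
  sc <- n_bins / 40  # bump parameters are stated for the 40-bin layout
  texture_sd <- rep_len(texture_sd, 5L)
  b <- function(centre, width, amplitude)
    gauss_bump(x, centre * sc, width * sc, amplitude)
  shapes <- list(
    # tall equal bimodal at the region edges, wide empty trough
    seed_1 = b(6, 2.0, 280) + b(41 - 6, 2.0, 265),
    # asymmetric bimodal (second peak ~55% of the first) whose trough is
    # filled at ~45% of peak height
    seed_2 = b(13, 2.3, 300) + b(41 - 13, 3.0, 170) +
             b(18, 3.2, 130) + b(41 - 18, 3.2, 130),
    # moderately asymmetric bimodal riding on an elevated pedestal with
    # low flanking satellites
    seed_3 = b(16, 2.8, 200) + b(41 - 16, 2.8, 140) +
             b(3, 4.5, 55) + b(41 - 3, 4.5, 55) +
             b(6, 2.5, 60) + b(41 - 6, 2.5, 60),
    # narrow central unimodal with mirrored sub-half-max satellites and
    # deep valleys between them
    seed_4 = b(ctr / sc, 2.0, 280) + b(8, 2.0, 126) + b(41 - 8, 2.0, 126),
    # broad flat domain with sharp boundaries
    seed_5 = ifelse(abs(x - ctr) <= 9.5 * sc, 130, 0))
  vals <- lapply(seq_along(shapes), function(i) {
    u <- if (texture_sd[i] > 0)
      seed_texture(n_bins, texture_sd[i], rho = 0.4, clip = 0.4,
                   stream_seed = rng_seed + i)
    else rep(1, n_bins)
    pmax(0, round(shapes[[i]] * u))
  })
  names(vals) <- names(shapes)
  offset <- 0L
  out <- lapply(names(vals), function(nm) {
    reg <- data.frame(chrom = "chrSIM", start = offset,
                      end = offset + n_bins * as.integer(bin_size),
                      name = nm, strand = "*", stringsAsFactors = FALSE)
    offset <<- offset + n_bins * as.integer(bin_size)
    dgw_profile(vals[[nm]], region = reg, bin_size = bin_size,
                track_names = "sim")
  })
  profile_set(out)
}

#' Corrupt a seed profile
#'
#' Applies the simulation's corruption process to one profile, using the
#' ambient RNG (seed the stream with `set.seed()` or call it from
#' [simulate_dataset()]): per-bin multiplicative Gaussian noise
#' `max(0, N(1, sd = v))`, then a left-to-right scan in which each bin mutates
#' with probability `p` (removal or duplication, duplicated copies
#' re-duplicating with probability `p`), then a whole-profile flip with
#' probability `fp`.
#'
#' @param seed_profile A `dgw_profile` to corrupt.
#' @param params A [simulation_params()].
#' @param .retry Internal: resample once if the corruption deletes every
#'   bin, then error.
#' @return List with `profile` (the corrupted `dgw_profile`), `flipped`,
#'   and `index_map`: for each output bin, the 1-based seed bin it
#'   derives from (useful to track planted landmarks).
#' @export
corrupt_profile <- function(seed_profile, params, .retry = TRUE) {
  stopifnot(inherits(seed_profile, "dgw_profile"),
            inherits(params, "dgw_sim_params"))
  vals <- seed_profile$values
  n <- nrow(vals)
  if (params$v > 0) {
    g <- pmax(0, stats::rnorm(n, mean = 1, sd = params$v))
    vals <- vals * g
  }
  pm <- params$p_delete + params$p_duplicate
  copies <- rep(1L, n)
  if (pm > 0) {
    for (i in seq_len(n)) {
      if (stats::runif(1) < pm) {
        if (stats::runif(1) < params$p_delete / pm) {
          copies[i] <- 0L
        } else {
          k <- 2L
          while (stats::runif(1) < pm) k <- k + 1L
          copies[i] <- k
        }
      }
    }
  }
  index_map <- rep(seq_len(n), copies)
  if (!length(index_map)) {
    if (.retry) return(corrupt_profile(seed_profile, params, .retry = FALSE))
    stop("corruption removed every bin of '", seed_profile$region$name, "'")
  }
  out_vals <- vals[index_map, , drop = FALSE]
  flipped <- FALSE
  if (params$fp > 0 && stats::runif(1) < params$fp) {
    out_vals <- out_vals[rev(seq_len(nrow(out_vals))), , drop = FALSE]
    index_map <- rev(index_map)
    flipped <- TRUE
  }
  region <- seed_profile$region
  region$end <- region$start + nrow(out_vals) * seed_profile$bin_size
  prof <- dgw_profile(out_vals, region = region,
                      bin_size = seed_profile$bin_size,
                      track_names = seed_profile$track_names)
  list(profile = prof, flipped = flipped, index_map = index_map)
}

#' Simulate a labelled peak dataset
#'
#' Produces `n_per_seed` corrupted copies of each seed and (by default)
#' includes the unmodified seeds themselves, yielding
#' `n_seeds * (n_per_seed + 1)` labelled profiles — 500 with the default
#' five seeds and 99 copies each. Deterministic given
#' `params$rng_seed`.
#'
#' @param params A [simulation_params()].
#' @param seeds Seed profiles (default [make_synthetic_seeds()]).
#' @param include_seeds Include the unmodified seeds in the output.
#' @return A `dgw_sim`: list with `profiles` (a `dgw_profiles`),
#'   `labels` (integer true seed class per profile), `flipped` (logical),
#'   `index_maps` (per-profile seed-bin maps) and `params`.
#' @export
simulate_dataset <- function(params = simulation_params(),
                             seeds = make_synthetic_seeds(),
                             include_seeds = TRUE) {
  stopifnot(inherits(params, "dgw_sim_params"), inherits(seeds, "dgw_profiles"))
  with_local_seed(params$rng_seed, {
    profiles <- list(); labels <- integer(0); flipped <- logical(0)
    index_maps <- list()
    for (s in seq_along(seeds)) {
      seed_p <- seeds[[s]]
      if (include_seeds) {
        p <- seed_p
        p$region$name <- sprintf("%s_orig", seed_p$region$name)
        profiles[[length(profiles) + 1L]] <- p
        labels <- c(labels, s); flipped <- c(flipped, FALSE)
        index_maps[[length(index_maps) + 1L]] <- seq_len(nrow(p$values))
      }
      for (r in seq_len(params$n_per_seed)) {
        cp <- corrupt_profile(seed_p, params)
        cp$profile$region$name <- sprintf("%s_rep%03d", seed_p$region$name, r)
        profiles[[length(profiles) + 1L]] <- cp$profile
        labels <- c(labels, s); flipped <- c(flipped, cp$flipped)
        index_maps[[length(index_maps) + 1L]] <- cp$index_map
      }
    }
    structure(list(profiles = profile_set(profiles), labels = labels,
                   flipped = flipped, index_maps = index_maps,
                   params = params),
              class = "dgw_sim")
  })
}

#' @export
print.dgw_sim <- function(x, ...) {
  cat(sprintf(paste0("<dgw_sim> %d profiles from %d seeds ",
                     "(v=%g, p=%g, fp=%g), %d flipped\n"),
              length(x$profiles), length(unique(x$labels)),
              x$params$v, x$params$p, x$params$fp, sum(x$flipped)))
  invisible(x)
}

#' Multi-class Matthews Correlation Coefficient
#'
#' Scores a clustering against the true classes with the multi-class
#' generalization of the MCC (the R_K statistic on the confusion matrix):
#' 1 is a perfect classification, about 0 a random one, and negative
#' values indicate systematic disagreement (bounded below by -1).
#'
#' Cluster labels are arbitrary, so by default clusters are first mapped
#' to true classes by a maximum-weight assignment on shared counts
#' (Hungarian algorithm) before the confusion matrix is scored; the score
#' is then invariant to any relabelling of clusters or classes. Note that
#' this matching step gives the null (random clusters) a small positive
#' bias; set `map_clusters = FALSE` to score labels that already live on
#' the same label set.
#'
#' @param true_labels,cluster_labels Equal-length label vectors.
#' @param map_clusters Map clusters to classes by maximum assignment
#'   first (default `TRUE`).
#' @return The MCC in `[-1, 1]`. Degenerate confusion matrices (a single
#'   predicted or true class) score 0.
#' @examples
#' mcc_multiclass(rep(1:2, each = 50), rep(c(2, 1), each = 50))  # 1
#' @export
mcc_multiclass <- function(true_labels, cluster_labels, map_clusters = TRUE) {
  if (length(true_labels) != length(cluster_labels))
    stop("label vectors differ in length")
  tf <- factor(true_labels); cf <- factor(cluster_labels)
  if (nlevels(tf) < 2L) stop("need at least 2 true classes")
  C <- table(tf, cf)
  K <- max(nlevels(tf), nlevels(cf))
  M <- matrix(0, K, K)
  M[seq_len(nrow(C)), seq_len(ncol(C))] <- C
  if (map_clusters) {
    assign <- .cpp_hungarian(-M)  # column assigned to each row (class)
    M <- M[, assign, drop = FALSE]
  }
  rk_statistic(M)
}

# R_K over a square confusion matrix (true classes in rows).
rk_statistic <- function(M) {
  s <- sum(M)
  c_ <- sum(diag(M))
  t_ <- rowSums(M)  # per-class truth totals
  p_ <- colSums(M)  # per-class prediction totals
  num <- c_ * s - sum(t_ * p_)
  den <- sqrt((s^2 - sum(p_^2)) * (s^2 - sum(t_^2)))
  if (den == 0) return(0)
  num / den
}

#' Cluster a profile set end to end
#'
#' The warping pipeline used by the simulation benchmark: pairwise
#' flip-aware DTW distances, complete-linkage dendrogram, cut at
#' `n_clusters`.
#'
#' @param pset A `dgw_profiles` set.
#' @param config A [dtw_config()].
#' @param n_clusters Number of clusters to cut at.
#' @param workers Parallel workers for the distance matrix.
#' @return Integer cluster labels (attribute `"dendrogram"` holds the
#'   `dgw_dendrogram`).
#' @export
dgw_cluster <- function(pset, config = dtw_config(), n_clusters = 5L,
                        workers = 1L) {
  dm <- pairwise_distances(pset, config, workers = workers)
  dend <- build_dendrogram(dm, pset)
  labels <- cut_dendrogram(dend, n_clusters = n_clusters)
  attr(labels, "dendrogram") <- dend
  labels
}

#' Shape-naive baseline clustering
#'
#' The comparator for the benchmark: profiles are height-normalized,
#' zero-padded to the longest length, compared by squared Euclidean
#' distance bin-by-bin (no warping, no flip awareness), and clustered by
#' complete linkage.
#'
#' @inheritParams dgw_cluster
#' @return Integer cluster labels.
#' @export
baseline_cluster <- function(pset, n_clusters = 5L) {
  stopifnot(inherits(pset, "dgw_profiles"))
  mats <- lapply(pset, function(p) prep_values(p, dtw_config()))
  max_len <- max(vapply(mats, nrow, integer(1)))
  flat <- t(vapply(mats, function(m) {
    padded <- rbind(m, matrix(0, max_len - nrow(m), ncol(m)))
    as.vector(padded)
  }, numeric(max_len * ncol(mats[[1L]]))))
  d <- stats::dist(flat, method = "euclidean")^2
  hc <- stats::hclust(d, method = "complete")
  stats::cutree(hc, k = n_clusters)
}

#' MCC benchmark over a corruption grid
#'
#' Re-runs the simulation and clustering for every `(v, p)` combination,
#' scoring both the warping pipeline and the shape-naive baseline with
#' the multi-class MCC against the generating seed classes.
#'
#' @param v_values,p_values Grid of noise variances and mutation
#'   probabilities.
#' @param fp Flip probability (fixed across the grid, default 0.1).
#' @param n_clusters Clusters to cut at (default 5, the generating truth).
#' @param n_per_seed Simulated copies per seed.
#' @param n_replicates Independent replicate datasets per grid cell.
#' @param config A [dtw_config()].
#' @param seeds Seed profiles.
#' @param rng_seed Base seed; each cell/replicate derives its own stream.
#' @param workers Parallel workers for distance matrices.
#' @return Data frame with columns `v`, `p`, `replicate`, `mcc_dgw`,
#'   `mcc_baseline` and the per-cell `rng_seed` used.
#' @export
run_benchmark_grid <- function(v_values = c(0, 0.1, 0.25, 0.4),
                               p_values = c(0, 0.1, 0.25, 0.4),
                               fp = 0.1, n_clusters = 5L, n_per_seed = 99L,
                               n_replicates = 1L, config = dtw_config(),
                               seeds = make_synthetic_seeds(),
                               rng_seed = 1L, workers = 1L) {
  grid <- expand.grid(replicate = seq_len(n_replicates), p = p_values,
                      v = v_values)[, c("v", "p", "replicate")]
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cell_seed <- derive_seed(rng_seed, g)
    params <- simulation_params(v = grid$v[g], p = grid$p[g], fp = fp,
                                n_per_seed = n_per_seed,
                                rng_seed = cell_seed)
    sim <- simulate_dataset(params, seeds = seeds)
    lab_dgw <- dgw_cluster(sim$profiles, config, n_clusters = n_clusters,
                           workers = workers)
    lab_base <- baseline_cluster(sim$profiles, n_clusters = n_clusters)
    rows[[g]] <- data.frame(
      v = grid$v[g], p = grid$p[g], replicate = grid$replicate[g],
      mcc_dgw = mcc_multiclass(sim$labels, lab_dgw),
      mcc_baseline = mcc_multiclass(sim$labels, lab_base),
      rng_seed = cell_seed)
  }
  do.call(rbind, rows)
}
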