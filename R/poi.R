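#' Locate a genomic point inside a binned profile
#'
#' Maps a genomic position (0-based) to the bin index of a region's
#' profile: `floor((position - start) / bin_size)` if the point lies in
#' the half-open region `[start, end)`, else `NA`. For a profile that a
#' given analysis displays flipped, the index is reflected to
#' `n_bins - 1 - i`.
#'
#' @param position Genomic position (0-based bp).
#' @param region One-row region data frame.
#' @param bin_size Bin width in bp.
#' @param flipped Reflect the index for a flipped display.
#' @return 0-based bin index, or `NA` if the point is outside the region.
#' @examples
#' r <- data.frame(chrom = "chr1", start = 100, end = 300,
#'                 name = "p", strand = "*")
#' locate_poi_in_profile(225, r, 50)  # bin 2
#' @export
locate_poi_in_profile <- function(position, region, bin_size = 50L,
                                  flipped = FALSE) {
  validate_region(region)
  if (position < region$start || position >= region$end) return(NA_integer_)
  i <- as.integer(floor((position - region$start) / bin_size))
  if (flipped) {
    n_bins <- as.integer(ceiling((region$end - region$start) / bin_size))
    i <- n_bins - 1L - i
  }
  i
}

#' Map a bin index through a warping path
#'
#' Follows one source bin through an alignment: all target indices paired
#' with it on the warping path are collected and their lower median is
#' returned. For an alignment computed in the flipped orientation the
#' source index is reflected first.
#'
#' @param path K x 2 matrix of 1-based index pairs (source, target), as
#'   in a `dgw_alignment` or [warp_onto_prototype()] result.
#' @param i 0-based source bin index.
#' @param flipped Was the source aligned in reversed orientation?
#' @param source_length Number of source bins (needed to reflect `i`).
#' @return 0-based target bin index.
#' @export
map_index_through_path <- function(path, i, flipped = FALSE,
                                   source_length = max(path[, 1L])) {
  stopifnot(i >= 0, i < source_length)
  if (flipped) i <- source_length - 1L - i
  hits <- path[path[, 1L] == i + 1L, 2L]
  if (!length(hits)) stop("source index ", i, " not on the warping path")
  sort(hits)[ceiling(length(hits) / 2)] - 1L
}

shannon_entropy <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log(p))
}

positional_histogram <- function(positions, n_bins, axis_length) {
  breaks <- seq(0, axis_length, length.out = n_bins + 1L)
  positions <- pmin(pmax(positions, 0), axis_length - 1e-9)
  counts <- tabulate(findInterval(positions, breaks,
                                  rightmost.closed = TRUE, left.open = FALSE),
                     nbins = n_bins)
  counts
}

#' Positional histogram of points of interest
#'
#' Histograms landmark positions (e.g. TSS bin indices) over a positional
#' axis of `n_bins` equal-width bins and reports the Shannon entropy
#' (natural log, with the convention `0 * log(0) = 0`) of the normalized
#' histogram.
#'
#' @param positions Numeric positions on the axis `[0, axis_length)`.
#' @param n_bins Number of histogram bins.
#' @param axis_length Length of the positional axis (default `n_bins`,
#'   i.e. positions are bin indices).
#' @return A `dgw_poi_histogram`: list with `counts`, `n_bins` and
#'   `entropy` (in `[0, log(n_bins)]`).
#' @export
poi_histogram <- function(positions, n_bins, axis_length = n_bins) {
  stopifnot(length(positions) >= 1L, n_bins >= 1L)
  counts <- positional_histogram(positions, n_bins, axis_length)
  structure(list(counts = counts, n_bins = n_bins,
                 entropy = shannon_entropy(counts)),
            class = "dgw_poi_histogram")
}

#' Entropy change of landmark positions after warping
#'
#' Quantifies how much warping concentrates landmark positions: raw
#' positions are first rescaled to the common warped axis
#' (`position / source_length * target_length`), both position sets are
#' histogrammed with `n_bins` equal-width bins, and the relative entropy
#' decrease `(H_raw - H_warped) / H_raw * 100` is returned (positive =
#' landmarks are more concentrated after warping).
#'
#' @param raw_positions Landmark positions on the raw profiles (bin
#'   indices).
#' @param warped_positions Corresponding positions on the warped axis.
#' @param n_bins Histogram bins (a natural choice is the prototype
#'   length).
#' @param source_lengths Per-position raw profile lengths used for
#'   rescaling; `NULL` if `raw_positions` are already on the warped axis.
#' @param target_length Length of the warped axis (default `n_bins`).
#' @return Percent entropy decrease, or `NA` (with a warning) when the
#'   raw entropy is 0 so the relative change is undefined.
#' @export
entropy_change <- function(raw_positions, warped_positions, n_bins,
                           source_lengths = NULL, target_length = n_bins) {
  stopifnot(length(raw_positions) >= 1L, length(warped_positions) >= 1L)
  if (!is.null(source_lengths))
    raw_positions <- raw_positions / source_lengths * target_length
  h_raw <- shannon_entropy(positional_histogram(raw_positions, n_bins,
                                                target_length))
  h_warped <- shannon_entropy(positional_histogram(warped_positions, n_bins,
                                                   target_length))
  if (h_raw == 0) {
    warning("raw positions fall into a single histogram bin; ",
            "relative entropy change is undefined")
    return(NA_real_)
  }
  (h_raw - h_warped) / h_raw * 100
}

#' Bootstrap summary of per-cluster entropy changes
#'
#' Resamples clusters with replacement to attach a 95% percentile
#' confidence interval to the mean entropy decrease across clusters.
#'
#' @param per_cluster_changes Entropy changes (percent), one per cluster;
#'   `NA`s are dropped.
#' @param n_boot Bootstrap resamples (default 10000).
#' @param rng_seed Seed for the resampling.
#' @return List with `mean`, `ci_lower`, `ci_upper` (2.5/97.5
#'   percentiles) and `n_clusters`.
#' @export
bootstrap_mean_entropy_change <- function(per_cluster_changes,
                                          n_boot = 10000L, rng_seed = NULL) {
  x <- per_cluster_changes[!is.na(per_cluster_changes)]
  if (!length(x)) stop("no defined entropy changes to bootstrap")
  means <- with_local_seed(rng_seed,
    vapply(seq_len(n_boot),
           function(i) mean(sample(x, length(x), replace = TRUE)),
           numeric(1)))
  qs <- stats::quantile(means, c(0.025, 0.975), names = FALSE)
  list(mean = mean(x), ci_lower = qs[1L], ci_upper = qs[2L],
       n_clusters = length(x))
}

#' Marker alignment simulation
#'
#' Desk-scale check that warping concentrates genomic landmarks: a marker
#' is planted at a fixed bin of a seed profile, the seed is corrupted
#' into a simulated cluster, every member is warped onto the cluster's
#' prototype, and the positional entropy of the marker is compared
#' before (rescaled raw positions) and after warping. Corruption moves
#' the marker through insertions, deletions and orientation flips; a
#' working alignment should pull the copies back together.
#'
#' @param n_clusters Number of simulated clusters (replicates).
#' @param members Corrupted copies per cluster.
#' @param marker_bin 0-based seed bin carrying the marker, or `NULL`
#'   (default) to place it on each seed's summit descent (the first bin
#'   after the global maximum that falls below 40% of it) — a
#'   structured, identifiable position, the way a TSS sits on the
#'   downstream flank of the 5' sub-peak of a promoter mark. A marker
#'   inside a featureless stretch (e.g. the interior of a flat domain)
#'   is not expected to align: the warping has no signal to anchor it.
#' @param params A [simulation_params()] describing the corruption.
#' @param seeds Seed profiles cycled over the replicates.
#' @param config A [dtw_config()].
#' @param rng_seed Seed for the whole experiment.
#' @return Data frame with one row per simulated cluster: `seed`,
#'   `entropy_raw`, `entropy_warped`, `change_pct` (percent decrease,
#'   as in [entropy_change()]).
#' @export
marker_alignment_simulation <- function(n_clusters = 100L, members = 20L,
                                        marker_bin = NULL,
                                        params = simulation_params(v = 0.1,
                                                                   p = 0.1,
                                                                   fp = 0.1),
                                        seeds = make_synthetic_seeds(),
                                        config = dtw_config(),
                                        rng_seed = 1L) {
  descent_bin <- vapply(seeds, function(p) {
    v <- rowSums(p$values)
    summit <- which.max(v)
    below <- which(v < 0.4 * max(v) & seq_along(v) > summit)
    if (!length(below)) length(v) - 1L else below[1L] - 1L
  }, numeric(1))
  rows <- vector("list", n_clusters)
  for (r in seq_len(n_clusters)) {
    s <- (r - 1L) %% length(seeds) + 1L
    mk <- if (is.null(marker_bin)) descent_bin[s] else marker_bin
    cl_params <- params
    cl_params$n_per_seed <- as.integer(members)
    cl_params$rng_seed <- derive_seed(rng_seed, r)
    sim <- simulate_dataset(cl_params, seeds = seeds[s],
                            include_seeds = FALSE)
    raw_pos <- integer(members); raw_len <- integer(members)
    for (m in seq_len(members)) {
      imap <- sim$index_maps[[m]]
      hits <- which(imap == mk + 1L)
      raw_pos[m] <- if (length(hits)) {
        sort(hits)[ceiling(length(hits) / 2)] - 1L
      } else {
        # marker bin deleted: fall back to the insertion point
        min(c(which(imap > mk + 1L), length(imap))) - 1L
      }
      raw_len[m] <- length(imap)
    }
    dend <- build_dendrogram(pairwise_distances(sim$profiles, config),
                             sim$profiles)
    proto <- node_prototypes(dend)[[members - 1L]]
    warped_pos <- vapply(seq_len(members), function(m) {
      w <- warp_onto_prototype(sim$profiles[[m]], proto, config)
      map_index_through_path(w$path, raw_pos[m], flipped = w$flipped,
                             source_length = raw_len[m])
    }, numeric(1))
    h_raw <- shannon_entropy(positional_histogram(
      raw_pos / raw_len * proto$length, proto$length, proto$length))
    h_warped <- shannon_entropy(positional_histogram(
      warped_pos, proto$length, proto$length))
    rows[[r]] <- data.frame(
      seed = s, entropy_raw = h_raw, entropy_warped = h_warped,
      change_pct = if (h_raw > 0) (h_raw - h_warped) / h_raw * 100
                   else NA_real_)
  }
  do.call(rbind, rows)
}

#' Cluster enrichment curve for a transcription factor
#'
#' Tests whether a TF's binding sites distribute uniformly over the
#' genomic territory of the clusters. Each TF peak is assigned to a
#' cluster if its midpoint falls in one of the cluster's regions; counts
#' are normalized by the total bp of each cluster's regions, rescaled to
#' sum to 1, ranked ascending, and accumulated. Under the uniform null
#' the cumulative curve follows the diagonal; the area between the
#' diagonal and the curve (in `[0, 0.5)`) measures how concentrated the
#' TF is in few clusters.
#'
#' @param cluster_regions Named list of region data frames (one per
#'   cluster), or a directory containing `cluster_<k>.bed` files as
#'   written by [write_cluster_beds()].
#' @param tf_peaks Region data frame or BED path of the TF's peaks.
#' @return A `dgw_enrichment`: list with the per-cluster table
#'   (`cluster`, `count`, `bp`, `normalized`, ranked ascending),
#'   `cumulative`, and `area`.
#' @export
tf_cluster_enrichment <- function(cluster_regions, tf_peaks) {
  if (is.character(cluster_regions) && length(cluster_regions) == 1L &&
      dir.exists(cluster_regions)) {
    beds <- sort(list.files(cluster_regions, pattern = "^cluster_.*\\.bed$",
                            full.names = TRUE))
    if (!length(beds)) stop("no cluster_*.bed files in ", cluster_regions)
    cluster_regions <- lapply(beds, read_regions)
    names(cluster_regions) <- sub("\\.bed$", "", basename(beds))
  }
  stopifnot(is.list(cluster_regions), length(cluster_regions) >= 2L)
  if (is.null(names(cluster_regions)) || any(names(cluster_regions) == ""))
    names(cluster_regions) <- paste0("cluster_", seq_along(cluster_regions))
  if (is.character(tf_peaks)) tf_peaks <- read_regions(tf_peaks)
  K <- length(cluster_regions)
  # midpoint of each TF peak, as a width-1 range
  mid <- floor((tf_peaks$start + tf_peaks$end) / 2)
  mid_gr <- GenomicRanges::GRanges(tf_peaks$chrom,
                                   IRanges::IRanges(mid + 1L, width = 1L))
  counts <- integer(K); bp <- numeric(K)
  assigned <- rep(FALSE, length(mid))
  for (k in seq_len(K)) {
    gr <- regions_to_granges(cluster_regions[[k]])
    hit <- IRanges::overlapsAny(mid_gr, gr) & !assigned
    counts[k] <- sum(hit)
    assigned <- assigned | hit
    bp[k] <- sum(cluster_regions[[k]]$end - cluster_regions[[k]]$start)
  }
  if (sum(counts) == 0) stop("no TF peak midpoint falls in any cluster region")
  norm <- counts / bp
  norm <- norm / sum(norm)
  ord <- order(norm)
  tab <- data.frame(cluster = names(cluster_regions)[ord],
                    count = counts[ord], bp = bp[ord],
                    normalized = norm[ord], stringsAsFactors = FALSE)
  cumulative <- cumsum(tab$normalized)
  area <- sum(seq_len(K) / K - cumulative) / K
  structure(list(table = tab, cumulative = cumulative, area = area),
            class = "dgw_enrichment")
}

#' @export
print.dgw_enrichment <- function(x, ...) {
  cat(sprintf("<dgw_enrichment> %d clusters, area vs uniform = %s\n",
              nrow(x$table), fmt_num(x$area)))
  invisible(x)
}
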