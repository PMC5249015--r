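#' End-to-end clustering run
#'
#' The batch pipeline: read regions and coverage, bin, filter, compute
#' all pairwise flip-aware warping distances, build the complete-linkage
#' dendrogram and per-node prototypes, cut, and export every artefact
#' (distance matrices, linkage table, Newick tree, prototypes, cluster
#' BED files, cluster labels) together with a JSON manifest recording the
#' full configuration, so a run can be reproduced from its output
#' directory alone.
#'
#' @param regions Region data frame or BED path. May be `NULL` when
#'   `profile_tsv` is given and carries its own synthetic regions.
#' @param alignment_sources Character vector of BAM/SAM paths (one track
#'   each); alternatively supply pre-binned profiles via `profile_tsv`.
#' @param profile_tsv Path to a profile table (see [read_profile_tsv()]);
#'   mutually exclusive with `alignment_sources`.
#' @param out_dir Output directory (created).
#' @param bin_size,fragment_length Binning parameters for BAM input.
#' @param config A [dtw_config()].
#' @param min_bins,max_bins,min_total_count Filters, see
#'   [filter_profiles()].
#' @param n_clusters,cut_height Dendrogram cut (exactly one).
#' @param workers Parallel workers for the distance matrix.
#' @return Invisibly, a list with the profiles, distance matrix,
#'   dendrogram, prototypes, labels and the manifest path.
#' @export
dgw_worker <- function(regions = NULL, alignment_sources = NULL,
                       profile_tsv = NULL, out_dir,
                       bin_size = 50L, fragment_length = 200L,
                       config = dtw_config(), min_bins = 5L,
                       max_bins = 1000L, min_total_count = 10,
                       n_clusters = NULL, cut_height = NULL,
                       workers = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(regions)) regions <- read_regions(regions)
  if (!is.null(profile_tsv)) {
    if (!is.null(alignment_sources))
      stop("give either alignment_sources or profile_tsv, not both")
    pset <- read_profile_tsv(profile_tsv, bin_size = bin_size,
                             regions = regions)
  } else {
    if (is.null(regions) || is.null(alignment_sources))
      stop("need regions plus alignment_sources, or a profile_tsv")
    pset <- build_profiles(regions, alignment_sources, bin_size = bin_size,
                           fragment_length = fragment_length)
  }
  n_input <- length(pset)
  pset <- filter_profiles(pset, min_bins = min_bins, max_bins = max_bins,
                          min_total_count = min_total_count)
  discarded <- attr(pset, "discarded")
  if (length(pset) < 2L)
    stop("fewer than 2 profiles survive filtering; nothing to cluster")
  if (is.null(n_clusters) && is.null(cut_height)) n_clusters <- 5L

  dm <- pairwise_distances(pset, config, workers = workers)
  dend <- build_dendrogram(dm, pset)
  protos <- node_prototypes(dend)
  labels <- cut_dendrogram(dend, n_clusters = n_clusters,
                           height = cut_height)

  write_distance_matrix(dm, file.path(out_dir, "distances"))
  write_linkage(dend, file.path(out_dir, "linkage.tsv"))
  write_newick(dend, file.path(out_dir, "dendrogram.nwk"))
  write_prototypes(protos, file.path(out_dir, "prototypes.tsv"))
  reg_out <- regions_of(pset)
  write_cluster_beds(labels, reg_out, file.path(out_dir, "clusters"))
  write_tsv_file(data.frame(name = names(pset), cluster = labels),
                 file.path(out_dir, "cluster_labels.tsv"))
  if (!is.null(discarded) && nrow(discarded))
    write_tsv_file(discarded, file.path(out_dir, "discarded.tsv"))

  manifest <- list(
    tool = "dgwarp", version = as.character(utils::packageVersion("dgwarp")),
    r_version = R.version.string,
    inputs = list(alignment_sources = alignment_sources,
                  profile_tsv = profile_tsv),
    bin_size = bin_size, fragment_length = fragment_length,
    config = unclass(config),
    filters = list(min_bins = min_bins, max_bins = max_bins,
                   min_total_count = min_total_count),
    cut = list(n_clusters = n_clusters, height = cut_height),
    workers = workers,
    counts = list(input = n_input, kept = length(pset),
                  discarded = n_input - length(pset),
                  clusters = length(unique(labels))))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", digits = NA)
  invisible(list(profiles = pset, distmat = dm, dendrogram = dend,
                 prototypes = protos, labels = labels,
                 manifest = manifest_path))
}

# Heat-map of a list of equal-width value matrices (one row per profile),
# written as PNG.
plot_profile_heatmap <- function(mats, path, main = "") {
  max_len <- max(vapply(mats, nrow, integer(1)))
  rows <- t(vapply(mats, function(m) {
    v <- rowMeans(m)
    c(v, rep(NA_real_, max_len - length(v)))
  }, numeric(max_len)))
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  graphics::image(x = seq_len(max_len), y = seq_len(nrow(rows)),
                  z = t(rows[nrow(rows):1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  xlab = "bin", ylab = "profile", main = main, useRaster = TRUE)
  invisible(path)
}

#' Static report for a clustering run
#'
#' Renders the artefacts a result browser would show, as static files:
#' per-cluster heat maps of the raw and prototype-warped profiles,
#' points-of-interest histograms with their entropy change (and a
#' bootstrap summary across clusters), and TF enrichment curves.
#'
#' @param run Result list from [dgw_worker()] (or its output directory is
#'   insufficient: the report needs the in-memory profiles).
#' @param out_dir Directory for the report files.
#' @param poi_beds Optional named list of BED paths (or region data
#'   frames) of landmark points, e.g. `list(TSS = "tss.bed")`; the point
#'   is taken as each record's start.
#' @param tf_beds Optional named list of BED paths (or region data
#'   frames) of TF peak sets.
#' @param rng_seed Seed for the bootstrap.
#' @return Invisibly, a list with the entropy table and enrichment areas.
#' @export
dgw_report <- function(run, out_dir, poi_beds = NULL, tf_beds = NULL,
                       rng_seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pset <- run$profiles; dend <- run$dendrogram; labels <- run$labels
  config <- dend$config
  clusters <- sort(unique(labels))
  regions <- regions_of(pset)

  # cluster prototypes = root prototype of each cluster's subtree,
  # recomputed on the member subset
  entropy_rows <- list()
  for (k in clusters) {
    members <- pset[labels == k]
    mats_raw <- lapply(members, prep_values, config = config,
                       warn_cosine = FALSE)
    if (length(members) >= 2L) {
      sub <- build_dendrogram(pairwise_distances(members, config), members)
      proto <- node_prototypes(sub)[[length(members) - 1L]]
    } else {
      proto <- compute_prototype(
        build_dendrogram(run$distmat, pset), -which(labels == k)[1L])
    }
    warped <- lapply(members, warp_onto_prototype, prototype = proto,
                     config = config)
    plot_profile_heatmap(mats_raw,
                         file.path(out_dir, sprintf("cluster_%d_raw.png", k)),
                         main = sprintf("cluster %d raw", k))
    plot_profile_heatmap(lapply(warped, `[[`, "values"),
                         file.path(out_dir, sprintf("cluster_%d_warped.png", k)),
                         main = sprintf("cluster %d warped", k))
    # POI histograms per landmark set
    if (!is.null(poi_beds)) {
      for (poi_name in names(poi_beds)) {
        poi <- poi_beds[[poi_name]]
        if (is.character(poi)) poi <- read_regions(poi)
        raw_pos <- c(); raw_len <- c(); warped_pos <- c()
        for (m in seq_along(members)) {
          prof <- members[[m]]
          hit <- which(poi$chrom == prof$region$chrom &
                         poi$start >= prof$region$start &
                         poi$start < prof$region$end)
          for (h in hit) {
            i <- locate_poi_in_profile(poi$start[h], prof$region,
                                       prof$bin_size)
            w <- warped[[m]]
            j <- map_index_through_path(w$path, i, flipped = w$flipped,
                                        source_length = nrow(prof$values))
            raw_pos <- c(raw_pos, i)
            raw_len <- c(raw_len, nrow(prof$values))
            warped_pos <- c(warped_pos, j)
          }
        }
        if (length(raw_pos) >= 2L) {
          ec <- entropy_change(raw_pos, warped_pos, n_bins = proto$length,
                               source_lengths = raw_len,
                               target_length = proto$length)
          entropy_rows[[length(entropy_rows) + 1L]] <- data.frame(
            cluster = k, poi = poi_name, n = length(raw_pos),
            entropy_decrease_pct = ec)
        }
      }
    }
  }
  entropy_table <- if (length(entropy_rows)) do.call(rbind, entropy_rows)
                   else NULL
  boot <- NULL
  if (!is.null(entropy_table)) {
    write_tsv_file(entropy_table, file.path(out_dir, "poi_entropy.tsv"))
    boot <- lapply(split(entropy_table, entropy_table$poi), function(df) {
      bootstrap_mean_entropy_change(df$entropy_decrease_pct,
                                    rng_seed = rng_seed)
    })
    write_tsv_file(data.frame(poi = names(boot),
                              mean = vapply(boot, `[[`, numeric(1), "mean"),
                              ci_lower = vapply(boot, `[[`, numeric(1), "ci_lower"),
                              ci_upper = vapply(boot, `[[`, numeric(1), "ci_upper")),
                   file.path(out_dir, "poi_entropy_bootstrap.tsv"))
  }

  areas <- NULL
  if (!is.null(tf_beds)) {
    cluster_regions <- lapply(clusters, function(k)
      regions[labels == k, , drop = FALSE])
    names(cluster_regions) <- paste0("cluster_", clusters)
    areas <- vapply(names(tf_beds), function(tf) {
      enr <- tf_cluster_enrichment(cluster_regions, tf_beds[[tf]])
      write_tsv_file(cbind(enr$table, cumulative = enr$cumulative),
                     file.path(out_dir, sprintf("enrichment_%s.tsv", tf)))
      enr$area
    }, numeric(1))
    write_tsv_file(data.frame(tf = names(areas), area = areas),
                   file.path(out_dir, "enrichment_areas.tsv"))
  }
  invisible(list(entropy = entropy_table, bootstrap = boot,
                 enrichment_areas = areas))
}
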