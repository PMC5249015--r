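#' Read peak regions from a BED file
#'
#' Reads BED3+ records (e.g. peak-caller output) into the region table
#' used throughout the package. Coordinates follow the BED convention:
#' 0-based, half-open. Records without a name field are named
#' `peak_<line>` after their line number.
#'
#' @param path BED file (3 or more columns).
#' @return Data frame with columns `chrom`, `start`, `end`, `name`,
#'   `strand` and one row per record, in file order.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t300\tpeakA", bed)
#' read_regions(bed)
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser|\\s*$)", lines)
  body <- lines[keep]
  lineno <- which(keep)
  if (!length(body)) stop("no BED records in ", path)
  # parsed field by field (not via a table reader): BED3+ records may mix
  # column counts within one file, and errors must name the line
  fields <- strsplit(body, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L)
      stop("malformed BED line ", lineno[i], ": fewer than 3 fields")
    if (is.na(suppressWarnings(as.numeric(f[2L]))) ||
        is.na(suppressWarnings(as.numeric(f[3L]))))
      stop("malformed BED line ", lineno[i], ": non-numeric coordinates")
  }
  field_or <- function(f, k, default) if (length(f) >= k) f[[k]] else default
  df <- data.frame(
    chrom = vapply(fields, `[[`, character(1), 1L),
    start = as.integer(vapply(fields, `[[`, character(1), 2L)),
    end = as.integer(vapply(fields, `[[`, character(1), 3L)),
    name = vapply(fields, field_or, character(1), 4L, NA_character_),
    strand = vapply(fields, field_or, character(1), 6L, "*"),
    stringsAsFactors = FALSE)
  df$strand[!(df$strand %in% c("+", "-"))] <- "*"
  missing_name <- is.na(df$name) | df$name == "" | df$name == "."
  df$name[missing_name] <- paste0("peak_", lineno[missing_name])
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop("invalid region at BED line ", lineno[bad[1L]],
         ": end (", df$end[bad[1L]], ") must exceed start (", df$start[bad[1L]], ")")
  if (anyDuplicated(df$name))
    stop("duplicate region names in ", path, ": ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  df
}

regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end),
    strand = ifelse(regions$strand %in% c("+", "-"), regions$strand, "*"),
    name = regions$name)
}

write_regions_bed <- function(regions, path) {
  gr <- regions_to_granges(regions)
  names(gr) <- regions$name
  gr$score <- 0L
  gr <- gr[order(regions$chrom, regions$start)]
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write one BED file per cluster
#'
#' Exports the regions assigned to each cluster as `cluster_<k>.bed` under
#' `out_dir`, with original coordinates, sorted by chromosome and start.
#' The files partition the input: their union is the input region set and
#' no region appears in two files.
#'
#' @param assignments Integer cluster labels, one per region.
#' @param regions Region data frame (as from [read_regions()]).
#' @param out_dir Output directory, created if needed.
#' @return Character vector of the paths written, named by cluster.
#' @export
write_cluster_beds <- function(assignments, regions, out_dir) {
  stopifnot(length(assignments) == nrow(regions))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (k in sort(unique(assignments))) {
    path <- file.path(out_dir, sprintf("cluster_%d.bed", k))
    write_regions_bed(regions[assignments == k, , drop = FALSE], path)
    paths[as.character(k)] <- path
  }
  paths
}

# Locate (and if necessary create) an indexed BAM for `path`; SAM input is
# converted on the fly, an unindexed BAM is indexed beside a temp copy.
as_indexed_bam <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = ".bam")
    path <- Rsamtools::asBam(path, sub("\\.bam$", "", dest),
                             overwrite = TRUE, indexDestination = TRUE)
    return(path)
  }
  if (!file.exists(paste0(path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", path))) {
    tmp <- tempfile(fileext = ".bam")
    file.copy(path, tmp)
    Rsamtools::indexBam(tmp)
    return(tmp)
  }
  path
}

#' Binned fragment coverage of a region
#'
#' Counts aligned fragments per fixed-width bin of a region. Single-end
#' reads are extended from their 5' end to `fragment_length` in their
#' strand direction, the usual surrogate for the sequenced fragment; a
#' fragment contributes 1 to every bin it overlaps by at least one base.
#' The last bin may be partial but counts as a full bin.
#'
#' @param alignment_source Path to a BAM (indexed, or indexable) or SAM
#'   file.
#' @param region One-row region data frame (0-based half-open).
#' @param bin_size Bin width in bp.
#' @param fragment_length Length to which each read is extended; must be
#'   at least the read length.
#' @return A single-track [dgw_profile()] with
#'   `ceiling((end - start) / bin_size)` bins.
#' @export
compute_binned_coverage <- function(alignment_source, region, bin_size = 50L,
                                    fragment_length = 200L) {
  validate_region(region)
  stopifnot(bin_size >= 1L, fragment_length >= 1L)
  bam <- as_indexed_bam(alignment_source)
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (!(region$chrom %in% names(hdr)))
    stop("chromosome '", region$chrom, "' absent from ", alignment_source)
  clipped_end <- min(region$end, unname(hdr[region$chrom]))
  if (clipped_end < region$end)
    warning("region '", region$name, "' extends past the end of ",
            region$chrom, "; clipped to ", clipped_end)
  # query widened so fragments reaching into the region from outside are seen
  q_start <- max(1L, region$start + 1L - fragment_length)
  which <- GenomicRanges::GRanges(region$chrom,
                                  IRanges::IRanges(q_start, clipped_end + fragment_length))
  param <- Rsamtools::ScanBamParam(
    what = c("pos", "strand", "qwidth"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE),
    which = which)
  reads <- Rsamtools::scanBam(bam, param = param)[[1L]]
  n_bins <- ceiling((region$end - region$start) / bin_size)
  if (!length(reads$pos) || all(is.na(reads$pos))) {
    vals <- numeric(n_bins)
  } else {
    ok <- !is.na(reads$pos)
    pos <- reads$pos[ok]; strand <- as.character(reads$strand[ok])
    qw <- reads$qwidth[ok]
    if (any(qw > fragment_length))
      stop("fragment_length (", fragment_length,
           ") is shorter than a read length (", max(qw), ")")
    # 1-based inclusive fragment intervals after 5'-end extension
    frag_start <- ifelse(strand == "-", pos + qw - fragment_length, pos)
    frag_end <- frag_start + fragment_length - 1L
    frags <- IRanges::IRanges(start = frag_start, end = frag_end)
    bin_start <- region$start + 1L + (seq_len(n_bins) - 1L) * bin_size
    bins <- IRanges::IRanges(start = bin_start,
                             end = pmin(bin_start + bin_size - 1L, region$end))
    vals <- IRanges::countOverlaps(bins, frags, minoverlap = 1L)
  }
  track <- tools::file_path_sans_ext(basename(alignment_source))
  dgw_profile(as.numeric(vals), region = region, bin_size = bin_size,
              track_names = track)
}

#' Build a profile set from a BED file and alignment files
#'
#' Convenience wrapper: reads regions, computes binned coverage per region
#' and alignment file, and stacks multiple alignment files as tracks.
#'
#' @param regions Region data frame or path to a BED file.
#' @param alignment_sources Character vector of BAM/SAM paths, one per
#'   track.
#' @inheritParams compute_binned_coverage
#' @return A `dgw_profiles` set with one track per alignment file.
#' @export
build_profiles <- function(regions, alignment_sources, bin_size = 50L,
                           fragment_length = 200L) {
  if (is.character(regions)) regions <- read_regions(regions)
  per_track <- lapply(alignment_sources, function(src) {
    profile_set(lapply(seq_len(nrow(regions)), function(i) {
      compute_binned_coverage(src, regions[i, , drop = FALSE],
                              bin_size = bin_size,
                              fragment_length = fragment_length)
    }))
  })
  if (length(per_track) == 1L) per_track[[1L]] else assemble_multitrack(per_track)
}
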