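#' Binned peak profiles
#'
#' A *profile* is one peak region together with its binned coverage: a
#' matrix with one row per fixed-width genomic bin and one column per
#' epigenomic track, all values non-negative. A *profile set* is an ordered
#' collection of profiles over a common bin size and track layout; its
#' order is the input order and is preserved by every operation in the
#' package.
#'
#' @param values Numeric vector (one track) or matrix (bins x tracks) of
#'   non-negative bin counts.
#' @param region One-row data frame with columns `chrom`, `start`, `end`,
#'   `name`, `strand` (0-based half-open coordinates), or `NULL` for a
#'   synthetic placeholder region.
#' @param bin_size Width of one bin in base pairs.
#' @param track_names Character vector naming the tracks; defaults to the
#'   matrix column names or `"track_1"`, ...
#' @return `dgw_profile()` returns a `dgw_profile` object;
#'   `profile_set()` a `dgw_profiles` list of them.
#' @examples
#' p <- dgw_profile(c(0, 2, 5, 2, 0))
#' n_bins(p)
#' @export
dgw_profile <- function(values, region = NULL, bin_size = 50L,
                        track_names = NULL) {
  values <- as_track_matrix(values)
  if (nrow(values) < 1L) stop("a profile needs at least one bin")
  if (anyNA(values) || any(values < 0))
    stop("profile values must be non-negative and finite")
  if (is.null(track_names)) {
    track_names <- colnames(values)
    if (is.null(track_names))
      track_names <- paste0("track_", seq_len(ncol(values)))
  }
  if (length(track_names) != ncol(values))
    stop("track_names length does not match the number of tracks")
  colnames(values) <- track_names
  if (is.null(region)) {
    region <- data.frame(chrom = "chrSIM", start = 0L,
                         end = nrow(values) * as.integer(bin_size),
                         name = "profile", strand = "*",
                         stringsAsFactors = FALSE)
  }
  validate_region(region)
  structure(list(region = region, values = values,
                 bin_size = as.integer(bin_size),
                 track_names = track_names),
            class = "dgw_profile")
}

validate_region <- function(region) {
  need <- c("chrom", "start", "end", "name", "strand")
  if (!is.data.frame(region) || nrow(region) != 1L ||
      !all(need %in% names(region)))
    stop("region must be a one-row data frame with columns ",
         paste(need, collapse = ", "))
  if (region$end <= region$start)
    stop("invalid region '", region$name, "': end (", region$end,
         ") must exceed start (", region$start, ")")
  invisible(region)
}

#' @rdname dgw_profile
#' @param profiles List of `dgw_profile` objects with identical bin size
#'   and track layout.
#' @export
profile_set <- function(profiles) {
  if (!length(profiles)) {
    return(structure(list(), class = "dgw_profiles"))
  }
  stopifnot(all(vapply(profiles, inherits, logical(1), "dgw_profile")))
  bs <- unique(vapply(profiles, function(p) p$bin_size, integer(1)))
  if (length(bs) != 1L) stop("profiles mix bin sizes: ", paste(bs, collapse = ", "))
  nt <- unique(vapply(profiles, function(p) ncol(p$values), integer(1)))
  if (length(nt) != 1L) stop("profiles mix track counts")
  nm <- vapply(profiles, function(p) p$region$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate region names: ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(profiles) <- nm
  structure(profiles, class = "dgw_profiles")
}

#' @rdname dgw_profile
#' @param x,p A `dgw_profile` or `dgw_profiles` object.
#' @export
n_bins <- function(p) {
  if (inherits(p, "dgw_profile")) return(nrow(p$values))
  vapply(p, function(q) nrow(q$values), integer(1))
}

#' @export
print.dgw_profile <- function(x, ...) {
  cat(sprintf("<dgw_profile> %s:%d-%d (%s)  %d bins x %d track(s), bin %d bp\n",
              x$region$chrom, x$region$start, x$region$end, x$region$name,
              nrow(x$values), ncol(x$values), x$bin_size))
  invisible(x)
}

#' @export
print.dgw_profiles <- function(x, ...) {
  nb <- n_bins(x)
  cat(sprintf("<dgw_profiles> %d profiles, %d track(s), bins %s, bin size %d bp\n",
              length(x), if (length(x)) ncol(x[[1]]$values) else 0L,
              if (length(x)) paste0(min(nb), "-", max(nb)) else "-",
              if (length(x)) x[[1]]$bin_size else NA_integer_))
  invisible(x)
}

#' @export
`[.dgw_profiles` <- function(x, i) {
  structure(unclass(x)[i], class = "dgw_profiles")
}

regions_of <- function(pset) {
  do.call(rbind, lapply(pset, function(p) p$region))
}

#' Reverse a profile end-to-end
#'
#' Reverses the bin order jointly across all tracks, the operation used to
#' model the opposite strand orientation of a peak.
#'
#' @param p A `dgw_profile`.
#' @return The reversed `dgw_profile`.
#' @export
reverse_profile <- function(p) {
  stopifnot(inherits(p, "dgw_profile"))
  p$values <- p$values[rev(seq_len(nrow(p$values))), , drop = FALSE]
  p
}

#' Scale each track of a profile to unit height
#'
#' Divides every track by its own maximum so that peak shape, not
#' enrichment level, drives the warping distance. Tracks are normalized
#' independently.
#'
#' @param p A `dgw_profile` or `dgw_profiles` set.
#' @return Object of the same class with per-track maxima equal to 1.
#' @examples
#' normalize_by_height(dgw_profile(c(2, 4, 8)))$values[, 1]
#' @export
normalize_by_height <- function(p) {
  if (inherits(p, "dgw_profiles"))
    return(profile_set(lapply(p, normalize_by_height)))
  stopifnot(inherits(p, "dgw_profile"))
  mx <- apply(p$values, 2L, max)
  if (any(mx <= 0))
    stop("cannot height-normalize profile '", p$region$name,
         "': track(s) ", paste(which(mx <= 0), collapse = ", "), " are all zero")
  p$values <- sweep(p$values, 2L, mx, "/")
  p
}

#' Filter profiles by length and total count
#'
#' Keeps profiles whose bin count lies strictly between `min_bins` and
#' `max_bins` and whose total count (summed over all bins and, by default,
#' all tracks) is at least `min_total_count`. Very short peaks carry
#' little shape information and very long ones dominate the warping cost,
#' while low-count peaks are mostly noise.
#'
#' @param pset A `dgw_profiles` set.
#' @param min_bins Profiles must have strictly more bins than this.
#' @param max_bins Profiles must have strictly fewer bins than this.
#' @param min_total_count Minimum summed count to keep a profile.
#' @param per_track If `TRUE`, apply `min_total_count` to each track
#'   separately (every track must reach it) instead of to the grand total.
#' @return The surviving subset, in the original order, with a
#'   `"discarded"` attribute: a data frame of dropped names and reasons.
#' @export
filter_profiles <- function(pset, min_bins = 5L, max_bins = 1000L,
                            min_total_count = 10, per_track = FALSE) {
  stopifnot(inherits(pset, "dgw_profiles"), min_bins < max_bins)
  nb <- n_bins(pset)
  reason <- character(length(pset))
  for (i in seq_along(pset)) {
    if (nb[i] <= min_bins) reason[i] <- sprintf("too short (%d bins <= %d)", nb[i], min_bins)
    else if (nb[i] >= max_bins) reason[i] <- sprintf("too long (%d bins >= %d)", nb[i], max_bins)
    else {
      tot <- if (per_track) min(colSums(pset[[i]]$values)) else sum(pset[[i]]$values)
      if (tot < min_total_count)
        reason[i] <- sprintf("low count (%s < %s)", fmt_num(tot), fmt_num(min_total_count))
    }
  }
  keep <- reason == ""
  out <- pset[keep]
  if (!any(keep)) warning("all profiles were filtered out")
  attr(out, "discarded") <- data.frame(
    name = names(pset)[!keep], reason = reason[!keep],
    stringsAsFactors = FALSE)
  out
}

#' Stack single-track profile sets into one multi-track set
#'
#' Column-binds per-track profile sets computed over identical regions so
#' that several epigenomic marks are aligned jointly with equal weight.
#'
#' @param track_sets List of `dgw_profiles`, one per track, over identical
#'   regions and bin size, in the desired track order.
#' @return One multi-track `dgw_profiles` set.
#' @export
assemble_multitrack <- function(track_sets) {
  stopifnot(is.list(track_sets), length(track_sets) >= 1L)
  ref <- track_sets[[1L]]
  stopifnot(inherits(ref, "dgw_profiles"))
  for (k in seq_along(track_sets)[-1L]) {
    s <- track_sets[[k]]
    if (length(s) != length(ref))
      stop("track ", k, " has ", length(s), " profiles, expected ", length(ref))
    for (i in seq_along(ref)) {
      a <- ref[[i]]$region; b <- s[[i]]$region
      if (!identical(unlist(a[c("chrom", "start", "end", "name")]),
                     unlist(b[c("chrom", "start", "end", "name")])))
        stop("region mismatch between tracks at '", a$name, "' vs '", b$name, "'")
      if (s[[i]]$bin_size != ref[[i]]$bin_size) stop("bin size mismatch between tracks")
    }
  }
  out <- lapply(seq_along(ref), function(i) {
    vals <- do.call(cbind, lapply(track_sets, function(s) s[[i]]$values))
    colnames(vals) <- unlist(lapply(track_sets, function(s) s[[i]]$track_names))
    dgw_profile(vals, region = ref[[i]]$region, bin_size = ref[[i]]$bin_size)
  })
  profile_set(out)
}

#' Read and write the plain-text profile table
#'
#' An alignment-free exchange format for binned profiles: one row per
#' region and track, tab-separated fields `region`, `track`, then the bin
#' values `bin_0 ... bin_{n-1}`. Rows of the same region carry its tracks
#' and must agree in length; profile lengths may differ between regions.
#'
#' @param path File to read or write.
#' @param bin_size Bin width in bp to attach to the profiles read.
#' @param regions Optional region data frame (columns `chrom`, `start`,
#'   `end`, `name`, `strand`) matched to rows by `name`; profiles without a
#'   matching region get a synthetic placeholder.
#' @return `read_profile_tsv()` returns a `dgw_profiles` set;
#'   `write_profile_tsv()` its input, invisibly.
#' @export
read_profile_tsv <- function(path, bin_size = 50L, regions = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines)) stop("no profile rows in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) < 3L)
      stop("malformed profile row ", i, ": fewer than 3 fields")
  }
  rnames <- vapply(parts, `[[`, character(1), 1L)
  tnames <- vapply(parts, `[[`, character(1), 2L)
  vals <- lapply(parts, function(f) {
    v <- suppressWarnings(as.numeric(f[-(1:2)]))
    if (anyNA(v)) stop("non-numeric bin value in profile row for '", f[[1L]], "'")
    v
  })
  out <- list()
  for (rn in unique(rnames)) {
    rows <- which(rnames == rn)
    lens <- lengths(vals[rows])
    if (length(unique(lens)) != 1L)
      stop("tracks of region '", rn, "' differ in length")
    m <- do.call(cbind, vals[rows])
    colnames(m) <- tnames[rows]
    reg <- NULL
    if (!is.null(regions) && rn %in% regions$name)
      reg <- regions[match(rn, regions$name), , drop = FALSE]
    if (is.null(reg))
      reg <- data.frame(chrom = "chrSIM", start = 0L,
                        end = nrow(m) * as.integer(bin_size), name = rn,
                        strand = "*", stringsAsFactors = FALSE)
    out[[rn]] <- dgw_profile(m, region = reg, bin_size = bin_size)
  }
  profile_set(out)
}

#' @rdname read_profile_tsv
#' @param pset A `dgw_profiles` set to write.
#' @export
write_profile_tsv <- function(pset, path) {
  stopifnot(inherits(pset, "dgw_profiles"))
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pset) {
    for (t in seq_len(ncol(p$values))) {
      writeLines(paste(c(p$region$name, p$track_names[t],
                         fmt_num(p$values[, t], digits = 10L)),
                       collapse = "\t"), con)
    }
  }
  invisible(pset)
}
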