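#' Configuration of the warping distance
#'
#' Collects the knobs of the band-constrained, flip-aware Dynamic Time
#' Warping (DTW) used for all pairwise peak comparisons.
#'
#' The warping path minimizes the plain sum of local distances under the
#' step pattern (1,1), (1,0), (0,1) with unit weights, endpoints pinned to
#' the first and last bins of both sequences. With `band_width = k > 0`
#' the path is restricted to a Sakoe-Chiba corridor around the slanted
#' diagonal `j ~ i * M / N` with effective half-width
#' `max(k, |N - M| + 1)`, which bounds how far any stretch can be
#' compressed and reduces the cost of one alignment to
#' `O(k * max(N, M))`. `band_width = 0` disables the constraint.
#'
#' @param metric Local distance between bin vectors: `"sqeuclidean"`
#'   (squared Euclidean) or `"cosine"` (`1 - x.y / (|x||y|)`, with
#'   `d(x, 0) = 1` and `d(0, 0) = 0`). Cosine with a single track is
#'   degenerate (it can only take the values 0 and 2), so single-track
#'   cosine falls back to squared Euclidean on height-normalized values,
#'   with a warning.
#' @param band_width Sakoe-Chiba half-width in bins; 0 = unconstrained.
#'   Default 12.
#' @param flip_aware If `TRUE` (default), every comparison is also run
#'   against the reversed second sequence and the smaller distance is
#'   kept, accommodating strand asymmetry of epigenomic marks.
#' @param normalize_heights If `TRUE` (default), each track of each
#'   profile is divided by its peak height before computing distances, so
#'   that shapes rather than enrichment levels are compared.
#' @param height_stat Peak-height estimator used by the normalization:
#'   `"top4"` (default) divides by the mean of the 4 largest bins, a
#'   robust height that is stable against single-bin count noise;
#'   `"max"` divides by the single largest bin (so the maximum becomes
#'   exactly 1, as [normalize_by_height()] does).
#' @param gamma Multiplicative compression penalty: the local cost of the
#'   r-th consecutive non-diagonal step in the same direction is scaled by
#'   `gamma^r`. `gamma = 1` (default) disables the penalty.
#' @param normalize_distance If `TRUE`, [dtw_align()] divides the reported
#'   distance by the path length. Off by default: the clustering operates
#'   on the raw path sum.
#' @return A `dgw_config` list.
#' @export
dtw_config <- function(metric = c("sqeuclidean", "cosine"),
                       band_width = 12L, flip_aware = TRUE,
                       normalize_heights = TRUE,
                       height_stat = c("top4", "max"), gamma = 1,
                       normalize_distance = FALSE) {
  metric <- match.arg(metric)
  height_stat <- match.arg(height_stat)
  stopifnot(band_width >= 0L, gamma >= 1)
  structure(list(metric = metric, band_width = as.integer(band_width),
                 flip_aware = isTRUE(flip_aware),
                 normalize_heights = isTRUE(normalize_heights),
                 height_stat = height_stat,
                 gamma = as.double(gamma),
                 normalize_distance = isTRUE(normalize_distance)),
            class = "dgw_config")
}

peak_height <- function(v, stat) {
  if (stat == "max") return(max(v))
  mean(sort(v, decreasing = TRUE)[seq_len(min(4L, length(v)))])
}

metric_code <- function(metric) match(metric, c("sqeuclidean", "cosine")) - 1L

#' Local distance between two bin vectors
#'
#' The pointwise distance accumulated along a warping path: squared
#' Euclidean `sum((x - y)^2)` or cosine `1 - x.y / (|x||y|)` (with
#' `d(x, 0) = 1` against a zero vector and `d(0, 0) = 0`).
#'
#' @param x,y Numeric vectors of equal length (one value per track).
#' @param metric `"sqeuclidean"` or `"cosine"`.
#' @return A non-negative scalar.
#' @examples
#' local_distance(3, 1)              # 4
#' local_distance(c(1, 0), c(0, 1), "cosine")  # 1
#' @export
local_distance <- function(x, y, metric = c("sqeuclidean", "cosine")) {
  metric <- match.arg(metric)
  if (length(x) != length(y))
    stop("dimensionality mismatch: ", length(x), " vs ", length(y))
  if (metric == "sqeuclidean") return(sum((x - y)^2))
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 && ny == 0) return(0)
  if (nx == 0 || ny == 0) return(1)
  max(0, 1 - sum(x * y) / (nx * ny))
}

# Extract the bins x tracks value matrix, applying the configured
# preprocessing (height normalization; single-track cosine fallback).
prep_values <- function(p, config, warn_cosine = TRUE) {
  v <- if (inherits(p, "dgw_profile")) p$values else as_track_matrix(p)
  if (config$metric == "cosine" && ncol(v) == 1L) {
    if (warn_cosine)
      warning("cosine distance is degenerate for a single track; ",
              "using squared Euclidean on height-normalized values")
    config$normalize_heights <- TRUE
  }
  if (config$normalize_heights) {
    mx <- apply(v, 2L, peak_height, stat = config$height_stat %||% "top4")
    if (any(mx <= 0)) stop("cannot height-normalize an all-zero track")
    v <- sweep(v, 2L, mx, "/")
  }
  v
}

# Effective metric after the single-track cosine fallback.
effective_metric <- function(values, config) {
  if (config$metric == "cosine" && ncol(values) == 1L) "sqeuclidean" else config$metric
}

#' Align two profiles by Dynamic Time Warping (fixed orientation)
#'
#' Computes the optimal warping path between two binned profiles under the
#' configured local metric and Sakoe-Chiba band, together with the total
#' distance (the sum of local distances along the path). Multi-track
#' profiles are aligned jointly: the local distance is taken between the
#' per-bin vectors, giving every track equal weight.
#'
#' @param a,b `dgw_profile` objects (or numeric vectors/matrices, coerced
#'   with one row per bin).
#' @param config A [dtw_config()].
#' @param keep_matrix If `TRUE`, the accumulated-cost matrix is attached
#'   (for debugging and alignment-density plots).
#' @return A `dgw_alignment`: list with elements `distance` (non-negative
#'   scalar), `path` (K x 2 matrix of 1-based index pairs from `(1, 1)` to
#'   `(N, M)`), `flipped` (`FALSE` here) and, optionally, `cost_matrix`.
#' @examples
#' dtw_align(c(1, 2, 3), c(1, 3), dtw_config(band_width = 0,
#'   normalize_heights = FALSE))$distance  # 1
#' @export
dtw_align <- function(a, b, config = dtw_config(), keep_matrix = FALSE) {
  va <- prep_values(a, config)
  vb <- prep_values(b, config, warn_cosine = FALSE)
  if (ncol(va) != ncol(vb))
    stop("track count mismatch: ", ncol(va), " vs ", ncol(vb))
  met <- metric_code(effective_metric(va, config))
  res <- .cpp_dtw(va, vb, met, config$band_width, config$gamma,
                  TRUE, isTRUE(keep_matrix))
  dist <- res$distance
  if (config$normalize_distance) dist <- dist / nrow(res$path)
  out <- list(distance = dist, path = res$path, flipped = FALSE,
              lengths = c(nrow(va), nrow(vb)))
  if (isTRUE(keep_matrix)) out$cost_matrix <- res$cost_matrix
  structure(out, class = "dgw_alignment")
}

#' Strand-flip-aware warping distance
#'
#' Aligns `a` against `b` and against the reversal of `b` (bin order
#' reversed jointly across tracks) and returns the better of the two
#' alignments. A tie keeps the annotated orientation (`flipped = FALSE`).
#'
#' @inheritParams dtw_align
#' @return A `dgw_alignment` whose `flipped` element records whether the
#'   reversed orientation of `b` won; its `path` indexes the reversed `b`
#'   when it did.
#' @examples
#' flip_aware_distance(c(1, 2, 3), c(3, 2, 1),
#'   dtw_config(normalize_heights = FALSE))$flipped  # TRUE
#' @export
flip_aware_distance <- function(a, b, config = dtw_config()) {
  fwd <- dtw_align(a, b, config)
  vb <- if (inherits(b, "dgw_profile")) b$values else as_track_matrix(b)
  brev <- vb[rev(seq_len(nrow(vb))), , drop = FALSE]
  rev_aln <- dtw_align(a, brev, config)
  if (rev_aln$distance < fwd$distance) {
    rev_aln$flipped <- TRUE
    rev_aln
  } else fwd
}

#' @export
print.dgw_alignment <- function(x, ...) {
  cat(sprintf("<dgw_alignment> %d x %d bins, path length %d, distance %s%s\n",
              x$lengths[1], x$lengths[2], nrow(x$path), fmt_num(x$distance),
              if (x$flipped) ", flipped" else ""))
  invisible(x)
}

#' Dump an alignment for plotting
#'
#' Writes the accumulated-cost matrix and the warping path of one
#' alignment as TSV files, for alignment-density figures.
#'
#' @param alignment A `dgw_alignment` computed with `keep_matrix = TRUE`.
#' @param prefix Output path prefix; `<prefix>_cost.tsv` and
#'   `<prefix>_path.tsv` are written.
#' @return The two paths, invisibly.
#' @export
write_alignment_debug <- function(alignment, prefix) {
  stopifnot(inherits(alignment, "dgw_alignment"))
  if (is.null(alignment$cost_matrix))
    stop("alignment was computed without keep_matrix = TRUE")
  cost_path <- paste0(prefix, "_cost.tsv")
  path_path <- paste0(prefix, "_path.tsv")
  utils::write.table(alignment$cost_matrix, cost_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_tsv_file(data.frame(i = alignment$path[, 1], j = alignment$path[, 2]),
                 path_path)
  invisible(c(cost_path, path_path))
}
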