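#' Pairwise flip-aware warping distances
#'
#' Computes all `N (N - 1) / 2` flip-aware DTW distances between the
#' profiles of a set. The per-pair computation is pure, so the result is
#' independent of the worker count and of evaluation order; with
#' `workers > 1` rows of the condensed matrix are distributed over forked
#' processes and reassembled deterministically.
#'
#' @param pset A `dgw_profiles` set (at least 2 profiles).
#' @param config A [dtw_config()].
#' @param workers Number of parallel workers (forked; 1 = serial).
#' @return A `dgw_distmat`: list with `dist` (a [stats::dist] condensed
#'   matrix labelled by profile names) and `flipped` (logical vector in
#'   the same condensed order: did the reversed orientation of the second
#'   profile of the pair win).
#' @export
pairwise_distances <- function(pset, config = dtw_config(), workers = 1L) {
  stopifnot(inherits(pset, "dgw_profiles"), length(pset) >= 2L)
  n <- length(pset)
  mats <- vector("list", n)
  warned <- FALSE
  for (i in seq_len(n)) {
    mats[[i]] <- tryCatch(
      prep_values(pset[[i]], config, warn_cosine = !warned),
      error = function(e) stop("profile '", names(pset)[i], "': ",
                               conditionMessage(e)))
    if (config$metric == "cosine" && ncol(mats[[i]]) == 1L) warned <- TRUE
  }
  met <- metric_code(effective_metric(mats[[1L]], config))
  workers <- max(1L, as.integer(workers))
  if (workers == 1L || n < 4L) {
    res <- .cpp_pairwise_flip(mats, met, config$band_width, config$gamma,
                              config$flip_aware, integer(0))
    d <- res$distance
    flipped <- res$flipped
  } else {
    chunks <- split(seq_len(n - 1L),
                    cut(seq_len(n - 1L), workers, labels = FALSE))
    parts <- parallel::mclapply(chunks, function(rows) {
      .cpp_pairwise_flip(mats, met, config$band_width, config$gamma,
                         config$flip_aware, as.integer(rows))
    }, mc.cores = workers)
    d <- unlist(lapply(parts, `[[`, "distance"), use.names = FALSE)
    flipped <- unlist(lapply(parts, `[[`, "flipped"), use.names = FALSE)
  }
  dd <- structure(d, Size = n, Labels = names(pset), Diag = FALSE,
                  Upper = FALSE, method = "dgw", class = "dist")
  structure(list(dist = dd, flipped = flipped, config = config),
            class = "dgw_distmat")
}

#' @export
print.dgw_distmat <- function(x, ...) {
  n <- attr(x$dist, "Size")
  cat(sprintf("<dgw_distmat> %d profiles, %d pairs, %d flipped\n",
              n, length(x$dist), sum(x$flipped)))
  invisible(x)
}

#' Complete-linkage dendrogram over a profile set
#'
#' Agglomerative hierarchical clustering of the pre-computed pairwise
#' warping distances, using complete linkage to avoid chaining. The tree
#' has exactly `N - 1` internal nodes, each representing a candidate
#' cluster of the leaves below it.
#'
#' @param dm A `dgw_distmat` from [pairwise_distances()].
#' @param profiles The `dgw_profiles` the distances were computed from
#'   (kept for prototype computation; optional).
#' @return A `dgw_dendrogram`: list with the underlying [stats::hclust]
#'   object (`hclust`), the distance matrix, the profiles and the config.
#' @export
build_dendrogram <- function(dm, profiles = NULL) {
  stopifnot(inherits(dm, "dgw_distmat"))
  if (any(!is.finite(dm$dist))) stop("non-finite pairwise distances")
  hc <- stats::hclust(dm$dist, method = "complete")
  structure(list(hclust = hc, distmat = dm, profiles = profiles,
                 config = dm$config),
            class = "dgw_dendrogram")
}

#' @export
print.dgw_dendrogram <- function(x, ...) {
  n <- length(x$hclust$order)
  cat(sprintf("<dgw_dendrogram> %d leaves, %d internal nodes, heights %s-%s\n",
              n, n - 1L, fmt_num(min(x$hclust$height)),
              fmt_num(max(x$hclust$height))))
  invisible(x)
}

#' Cut a dendrogram into clusters
#'
#' @param dend A `dgw_dendrogram`.
#' @param n_clusters Number of clusters (1 to the number of leaves), or
#' @param height Cut height instead.
#' @return Integer cluster labels named by profile, stable across runs
#'   (labels follow [stats::cutree] numbering, by order of appearance in
#'   the tree).
#' @export
cut_dendrogram <- function(dend, n_clusters = NULL, height = NULL) {
  stopifnot(inherits(dend, "dgw_dendrogram"))
  if (is.null(n_clusters) == is.null(height))
    stop("give exactly one of n_clusters or height")
  n <- length(dend$hclust$order)
  if (!is.null(n_clusters)) {
    if (n_clusters < 1L || n_clusters > n)
      stop("n_clusters must be between 1 and ", n)
    stats::cutree(dend$hclust, k = n_clusters)
  } else {
    stats::cutree(dend$hclust, h = height)
  }
}

# -- prototypes ------------------------------------------------------------

# Weighted flip-aware DTW average of two prototypes.
# The heavier child keeps its orientation; the lighter child adopts the
# orientation minimizing the warping distance (ties keep its own). The
# value at each path step is the weight-average of the aligned bin
# vectors; steps sharing the same heavy-child index are mean-pooled, and
# the result is linearly resampled to the weighted mean of the child
# lengths ("scaled").
average_prototypes <- function(va, wa, vb, wb, config) {
  if (wb > wa) {
    tmp <- va; va <- vb; vb <- tmp
    tw <- wa; wa <- wb; wb <- tw
  }
  cfg <- config
  cfg$normalize_heights <- FALSE  # children are already on the working scale
  cfg$normalize_distance <- FALSE
  aln <- dtw_align(va, vb, cfg)
  if (config$flip_aware) {
    vb_r <- vb[rev(seq_len(nrow(vb))), , drop = FALSE]
    aln_r <- dtw_align(va, vb_r, cfg)
    if (aln_r$distance < aln$distance) {
      aln <- aln_r
      vb <- vb_r
    }
  }
  path <- aln$path
  avg <- (wa * va[path[, 1L], , drop = FALSE] +
          wb * vb[path[, 2L], , drop = FALSE]) / (wa + wb)
  pooled <- rowsum(avg, group = path[, 1L], reorder = TRUE) /
    as.vector(table(path[, 1L]))
  rownames(pooled) <- NULL
  new_len <- max(1L, round((wa * nrow(va) + wb * nrow(vb)) / (wa + wb)))
  resample_linear(pooled, new_len)
}

#' Prototypes for every dendrogram node
#'
#' A prototype is a sequence representative of all profiles attached to a
#' node. Leaves are represented by their own (preprocessed) profile;
#' an internal node by the weighted flip-aware DTW average of its two
#' child prototypes, with weights equal to the child leaf counts and
#' length the (rounded) weighted mean of the child lengths. Prototypes
#' live on the same working scale as the distances (height-normalized
#' when the config says so).
#'
#' @param dend A `dgw_dendrogram` built with profiles attached (or pass
#'   `profiles`).
#' @param profiles Optional `dgw_profiles` overriding the ones stored in
#'   the dendrogram.
#' @return `node_prototypes()` returns a list of `dgw_prototype` objects
#'   (fields `values`, `weight`, `length`), one per internal node in merge
#'   order; `compute_prototype()` one prototype, where `node` is a
#'   positive merge-row index or a negative leaf index (`-i` = leaf `i`).
#' @export
node_prototypes <- function(dend, profiles = NULL) {
  stopifnot(inherits(dend, "dgw_dendrogram"))
  profiles <- profiles %||% dend$profiles
  if (is.null(profiles)) stop("no profiles attached to the dendrogram")
  config <- dend$config %||% dtw_config()
  merge <- dend$hclust$merge
  leaf_vals <- lapply(profiles, prep_values, config = config,
                      warn_cosine = FALSE)
  protos <- vector("list", nrow(merge))
  get_child <- function(id) {
    if (id < 0L) list(values = leaf_vals[[-id]], weight = 1L)
    else protos[[id]]
  }
  for (k in seq_len(nrow(merge))) {
    a <- get_child(merge[k, 1L]); b <- get_child(merge[k, 2L])
    vals <- average_prototypes(a$values, a$weight, b$values, b$weight, config)
    protos[[k]] <- structure(
      list(values = vals, weight = a$weight + b$weight, length = nrow(vals)),
      class = "dgw_prototype")
  }
  protos
}

#' @rdname node_prototypes
#' @param node Node id: positive = internal node (merge row), negative =
#'   leaf.
#' @export
compute_prototype <- function(dend, node, profiles = NULL) {
  stopifnot(inherits(dend, "dgw_dendrogram"))
  profiles <- profiles %||% dend$profiles
  if (is.null(profiles)) stop("no profiles attached to the dendrogram")
  if (node < 0L) {
    if (-node > length(profiles)) stop("no leaf ", -node)
    vals <- prep_values(profiles[[-node]], dend$config %||% dtw_config(),
                        warn_cosine = FALSE)
    return(structure(list(values = vals, weight = 1L, length = nrow(vals)),
                     class = "dgw_prototype"))
  }
  if (node > nrow(dend$hclust$merge)) stop("no internal node ", node)
  node_prototypes(dend, profiles)[[node]]
}

#' @export
print.dgw_prototype <- function(x, ...) {
  cat(sprintf("<dgw_prototype> %d bins x %d track(s), %d leaves\n",
              nrow(x$values), ncol(x$values), x$weight))
  invisible(x)
}

#' Warp a profile onto a prototype
#'
#' Flip-aware alignment of one profile to a prototype, then averaging of
#' the profile values mapped to each prototype bin. The result has the
#' prototype's length, so all members of a cluster become directly
#' comparable (and plottable) on the prototype axis.
#'
#' @param profile A `dgw_profile` (or numeric vector/matrix).
#' @param prototype A `dgw_prototype` (or numeric vector/matrix).
#' @param config A [dtw_config()]; preprocessing matches
#'   [pairwise_distances()].
#' @return List with `values` (prototype-length matrix), `flipped`, and
#'   the alignment `path` (profile index, prototype index; profile
#'   indices refer to the reversed profile when `flipped`).
#' @export
warp_onto_prototype <- function(profile, prototype, config = dtw_config()) {
  vp <- prep_values(profile, config, warn_cosine = FALSE)
  vt <- if (inherits(prototype, "dgw_prototype")) prototype$values
        else as_track_matrix(prototype)
  cfg <- config
  cfg$normalize_heights <- FALSE
  cfg$normalize_distance <- FALSE
  aln <- dtw_align(vp, vt, cfg)
  flipped <- FALSE
  if (config$flip_aware) {
    vr <- vp[rev(seq_len(nrow(vp))), , drop = FALSE]
    aln_r <- dtw_align(vr, vt, cfg)
    if (aln_r$distance < aln$distance) {
      aln <- aln_r; vp <- vr; flipped <- TRUE
    }
  }
  path <- aln$path
  pooled <- rowsum(vp[path[, 1L], , drop = FALSE], group = path[, 2L],
                   reorder = TRUE) / as.vector(table(path[, 2L]))
  out_vals <- matrix(0, nrow = nrow(vt), ncol = ncol(vp),
                     dimnames = list(NULL, colnames(vp)))
  out_vals[sort(unique(path[, 2L])), ] <- pooled
  list(values = out_vals, flipped = flipped, path = path,
       distance = aln$distance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- serialization ---------------------------------------------------------

#' Export clustering artefacts as plain text
#'
#' Writers for the distance matrix (condensed and square TSV), the
#' linkage table, a Newick rendering of the dendrogram, and prototype
#' sequences in the profile TSV dialect.
#'
#' @param dm A `dgw_distmat`.
#' @param path,prefix Output locations.
#' @return The path(s) written, invisibly.
#' @export
write_distance_matrix <- function(dm, prefix) {
  stopifnot(inherits(dm, "dgw_distmat"))
  n <- attr(dm$dist, "Size")
  labels <- attr(dm$dist, "Labels")
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  cond <- data.frame(a = labels[pairs[, 1L]], b = labels[pairs[, 2L]],
                     distance = fmt_num(as.vector(dm$dist)[
                       (pairs[, 1L] - 1L) * n - pairs[, 1L] * (pairs[, 1L] - 1L) / 2 +
                         pairs[, 2L] - pairs[, 1L]], digits = 10L),
                     flipped = dm$flipped[
                       (pairs[, 1L] - 1L) * n - pairs[, 1L] * (pairs[, 1L] - 1L) / 2 +
                         pairs[, 2L] - pairs[, 1L]])
  p1 <- paste0(prefix, "_condensed.tsv")
  write_tsv_file(cond, p1)
  sq <- as.matrix(dm$dist)
  sqdf <- data.frame(name = labels, apply(sq, 2L, fmt_num, digits = 10L),
                     check.names = FALSE)
  colnames(sqdf) <- c("name", labels)
  p2 <- paste0(prefix, "_square.tsv")
  write_tsv_file(sqdf, p2)
  invisible(c(p1, p2))
}

#' @rdname write_distance_matrix
#' @param dend A `dgw_dendrogram`.
#' @export
write_linkage <- function(dend, path) {
  stopifnot(inherits(dend, "dgw_dendrogram"))
  hc <- dend$hclust
  sizes <- integer(nrow(hc$merge))
  size_of <- function(id) if (id < 0L) 1L else sizes[id]
  for (k in seq_len(nrow(hc$merge)))
    sizes[k] <- size_of(hc$merge[k, 1L]) + size_of(hc$merge[k, 2L])
  write_tsv_file(data.frame(node = seq_len(nrow(hc$merge)),
                            child1 = hc$merge[, 1L], child2 = hc$merge[, 2L],
                            height = fmt_num(hc$height, digits = 10L),
                            size = sizes), path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
write_newick <- function(dend, path) {
  stopifnot(inherits(dend, "dgw_dendrogram"))
  hc <- dend$hclust
  if (is.null(hc$labels)) hc$labels <- paste0("leaf_", seq_along(hc$order))
  phy <- ape::as.phylo(hc)
  phy$node.label <- paste0("node_", seq_len(phy$Nnode))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @param protos List of prototypes from [node_prototypes()].
#' @export
write_prototypes <- function(protos, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(protos)) {
    p <- protos[[k]]
    for (t in seq_len(ncol(p$values)))
      writeLines(paste(c(sprintf("node_%d", k),
                         colnames(p$values)[t] %||% sprintf("track_%d", t),
                         fmt_num(p$values[, t], digits = 10L)),
                       collapse = "\t"), con)
  }
  invisible(path)
}
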