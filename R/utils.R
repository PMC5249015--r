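# Internal helpers shared across modules.

# Evaluate `expr` under a locally seeded RNG, restoring the caller's RNG
# state afterwards. `seed = NULL` leaves the ambient RNG untouched.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed derived from a base seed and a stream index,
# kept inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483647)
}

#' @importFrom stats approx
resample_linear <- function(values, new_length) {
  values <- as_track_matrix(values)
  n <- nrow(values)
  if (new_length == n) return(values)
  if (n == 1L) return(values[rep(1L, new_length), , drop = FALSE])
  at <- seq(1, n, length.out = new_length)
  out <- apply(values, 2L, function(v) approx(seq_len(n), v, xout = at)$y)
  matrix(out, nrow = new_length, dimnames = list(NULL, colnames(values)))
}

# Coerce a numeric vector or matrix to the internal bins x tracks matrix.
as_track_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  matrix(as.double(x), ncol = 1L)
}

write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

fmt_num <- function(x, digits = 6L) {
  formatC(x, digits = digits, format = "g")
}
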