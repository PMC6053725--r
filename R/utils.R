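# Shared low-level helpers: rounding, entropy, seeded RNG scopes, interval
# conversion between the package's 0-based half-open convention and IRanges.

.datatable.aware <- TRUE

#' Round half away from zero ("round half up" for positive values)
#'
#' Commercial rounding: `round_half_up(23.4) == 23`, `round_half_up(45.6) ==
#' 46`, `round_half_up(25.2) == 25`, `round_half_up(0.5) == 1`. Used wherever
#' a fraction of a count must be converted to a whole number (train/test
#' split sizes, top-k feature counts), because banker's rounding in
#' [base::round()] does not reproduce those sizes.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @export
round_half_up <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# Shannon entropy (bits) of a count vector. Zero counts contribute 0.
entropy_bits <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0L) return(0)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed deterministically from a master seed and a label, kept
# below 2^31 so it is a valid R integer seed.
derive_seed <- function(seed, label) {
  h <- digest::digest(list(as.integer(seed), as.character(label)),
                      algo = "crc32")
  as.integer(strtoi(substr(h, 1, 7), base = 16L) %% 2147483647L)
}

# data.frame/data.table(chrom, start, end) in 0-based half-open coords ->
# GRanges (1-based closed).
to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# Interval matrix utilities. Intervals are n x 2 integer matrices
# [start, end) ; helpers tolerate NULL (= missing segment).
interval_matrix <- function(start, end) {
  cbind(start = as.numeric(start), end = as.numeric(end))
}

interval_len <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(0)
  sum(pmax(0, iv[, 2] - iv[, 1]))
}

# Clip intervals to [0, chrom_length); keeps zero-length rows.
clip_intervals <- function(iv, chrom_length) {
  if (is.null(iv)) return(NULL)
  s <- pmin(pmax(iv[, 1], 0), chrom_length)
  e <- pmin(pmax(iv[, 2], 0), chrom_length)
  interval_matrix(s, pmax(s, e))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
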