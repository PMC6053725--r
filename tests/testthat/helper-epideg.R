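# Shared fixtures and independent oracles. Oracles are deliberately written
# as naive loops so they stay independent of the vectorized implementations
# they check.

make_gene <- function(exons, strand = "+", gene_id = "g1", chrom = "chr1",
                      cds_start = NA, cds_end = NA) {
  gene_model(gene_id = gene_id, chrom = chrom, strand = strand,
             exons = do.call(rbind, exons), cds_start = cds_start,
             cds_end = cds_end)
}

iv <- function(s, e) matrix(c(s, e), ncol = 2)

# brute-force read counting: all-pairs >= 1 bp overlap against an interval
# union, each read counted once
oracle_count <- function(reads, segment, chrom) {
  n <- 0L
  for (i in seq_len(nrow(reads))) {
    if (reads$chrom[i] != chrom) next
    hit <- FALSE
    for (j in seq_len(nrow(segment)))
      if (reads$start[i] < segment[j, 2] && reads$end[i] > segment[j, 1])
        hit <- TRUE
    n <- n + hit
  }
  n
}

# brute-force information gain on already-discrete codes
oracle_info_gain <- function(x, y) {
  ent <- function(v) {
    p <- table(v) / length(v)
    -sum(p * log2(p))
  }
  hy <- ent(y)
  hcond <- 0
  for (lev in unique(x)) {
    sel <- x == lev
    hcond <- hcond + mean(sel) * ent(y[sel])
  }
  hy - hcond
}

# exhaustive Mann-Whitney pair count (ties = 1/2)
oracle_auc <- function(prob, labels) {
  pos <- prob[labels == "up"]
  neg <- prob[labels != "up"]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + if (p > q) 1 else if (p == q) 0.5 else 0
  s / (length(pos) * length(neg))
}

# brute-force nearest gene within a cap (gap distance, ties -> smallest id)
oracle_nearest <- function(peak, gene_tab, max_distance) {
  gap <- function(s1, e1, s2, e2) {
    if (e1 > s2 && e2 > s1) return(0)
    max(s2 - e1, s1 - e2)
  }
  best <- NULL
  best_d <- Inf
  for (i in seq_len(nrow(gene_tab))) {
    if (gene_tab$chrom[i] != peak$chrom) next
    d <- gap(peak$start, peak$end, gene_tab$start[i], gene_tab$end[i])
    if (d < best_d ||
        (d == best_d && !is.null(best) && gene_tab$gene_id[i] < best)) {
      best <- gene_tab$gene_id[i]
      best_d <- d
    }
  }
  if (best_d <= max_distance) list(gene_id = best, distance = best_d)
  else NULL
}

# small simulated bundle, memoized across test files (cheap read depth: the
# structural tests below do not depend on depth)
.bundle_cache <- new.env(parent = emptyenv())
small_bundle <- function() {
  if (is.null(.bundle_cache$b)) {
    cfg <- simulation_config(n_genes = 150, read_depth = 30000L, seed = 424L)
    .bundle_cache$b <- generate_dataset(cfg)
  }
  .bundle_cache$b
}
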