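# Segment-signal features: normalized read densities per gene segment and
# the derived differential quantities (diff, log2FC), assembled into the
# genes x features matrix with the {genotype}{mark}{quantity}_{segment}
# naming scheme (e.g. CK9A_UTR5, CK9diff_UTR5, CK9log2FC_UTR5).

#' Count reads overlapping a segment
#'
#' bedtools-multicov semantics: a read interval is counted when it overlaps
#' the segment by at least one base (half-open coordinates, so an abutting
#' read does not count). A segment given as an interval union counts each
#' read once however many parts it touches. Strand is ignored.
#'
#' @param reads data.table(chrom, start, end) of read intervals.
#' @param segment two-column `[start, end)` interval matrix (one segment,
#'   possibly several intervals).
#' @param chrom chromosome of the segment.
#' @return nonnegative integer count.
#' @export
count_reads <- function(reads, segment, chrom) {
  if (is.null(segment) || nrow(segment) == 0L) return(0L)
  sel <- reads$chrom == chrom & reads$end > min(segment[, 1]) &
    reads$start < max(segment[, 2])
  r <- as.data.frame(reads)[sel, , drop = FALSE]
  if (nrow(r) == 0L) return(0L)
  hit <- rep(FALSE, nrow(r))
  for (i in seq_len(nrow(segment)))
    hit <- hit | (r$start < segment[i, 2] & r$end > segment[i, 1])
  sum(hit)
}

# Flatten segment sets once into a table of intervals (one row per interval,
# zero-length intervals dropped) for vectorized counting.
flatten_segments <- function(segment_sets) {
  n_iv <- sum(vapply(segment_sets, function(ss)
    sum(vapply(ss, nrow, integer(1))), integer(1)))
  chrom <- gene_id <- kind <- character(n_iv)
  start <- end <- numeric(n_iv)
  i <- 0L
  for (gid in names(segment_sets)) {
    ss <- segment_sets[[gid]]
    ch <- attr(ss, "chrom")
    for (k in names(ss)) {
      iv <- ss[[k]]
      idx <- i + seq_len(nrow(iv))
      chrom[idx] <- ch
      gene_id[idx] <- gid
      kind[idx] <- k
      start[idx] <- iv[, 1]
      end[idx] <- iv[, 2]
      i <- i + nrow(iv)
    }
  }
  dt <- data.table::data.table(chrom = chrom, start = start, end = end,
                               gene_id = gene_id, kind = kind)
  dt <- dt[dt$end > dt$start, ]
  # integer id per (gene, kind) so per-hit grouping avoids string keys
  dt$grp <- data.table::frank(dt, gene_id, kind, ties.method = "dense")
  dt
}

# Vectorized counting of many segments against one read track, one count per
# (gene, segment kind). Uses GRanges overlap machinery; reads touching two
# intervals of the same segment union are deduplicated per segment.
count_segment_matrix <- function(reads, segment_sets,
                                 segs = flatten_segments(segment_sets)) {
  counts <- unique(data.table::data.table(
    gene_id = segs$gene_id, kind = segs$kind, grp = segs$grp), by = "grp")
  counts$n <- 0L
  if (nrow(reads) > 0L && nrow(segs) > 0L) {
    q <- to_granges(segs)
    s <- to_granges(reads)
    ov <- GenomicRanges::findOverlaps(q, s, minoverlap = 1L)
    if (length(ov) > 0L) {
      # one read counted once per (gene, kind) union
      dt <- unique(data.table::data.table(
        grp = segs$grp[S4Vectors::queryHits(ov)],
        read = S4Vectors::subjectHits(ov)))
      tab <- dt[, list(n = .N), by = "grp"]
      counts$n <- tab$n[match(counts$grp, tab$grp)]
      counts$n[is.na(counts$n)] <- 0L
    }
  }
  counts$grp <- NULL
  counts
}

#' Length-and-depth normalized read density
#'
#' Reads per kilobase of segment per million track reads (RPKM-style):
#' `count / ((segment_length/1000) * (total_reads/1e6))`.
#'
#' @param count read count over the segment.
#' @param segment_length segment length in bp (> 0; zero-length segments
#'   yield a missing value).
#' @param total_reads total mapped reads in the track (> 0).
#' @return nonnegative real, or `NA` for zero-length segments.
#' @export
normalize_density <- function(count, segment_length, total_reads) {
  if (any(total_reads <= 0)) stop("total_reads must be positive")
  out <- count / ((segment_length / 1000) * (total_reads / 1e6))
  out[segment_length <= 0] <- NA_real_
  out
}

#' Scaled difference of two densities
#'
#' `(x_eth - x_air) / mean(x_eth, x_air)`: the difference of the two
#' condition signals divided by their average, bounded in `[-2, 2]` with the
#' bounds attained when one signal is zero; defined as 0 when both are 0.
#'
#' @param x_air,x_eth nonnegative densities (air and ethylene condition).
#' @return real in `[-2, 2]`.
#' @export
diff_metric <- function(x_air, x_eth) {
  if (any(x_air < 0, na.rm = TRUE) || any(x_eth < 0, na.rm = TRUE))
    stop("diff_metric inputs must be nonnegative")
  m <- (x_air + x_eth) / 2
  out <- (x_eth - x_air) / m
  out[!is.na(m) & m == 0] <- 0
  out
}

#' Pseudocounted log2 fold change (treated / control)
#'
#' @param x_air,x_eth nonnegative densities.
#' @param pseudocount positive stabilizer added to both (default `1e-3`).
#' @return `log2((x_eth + pseudocount) / (x_air + pseudocount))`.
#' @export
log2fc <- function(x_air, x_eth, pseudocount = 1e-3) {
  stopifnot(pseudocount > 0)
  log2((x_eth + pseudocount) / (x_air + pseudocount))
}

QUANTITY_TAGS <- c("A", "C", "diff", "log2FC")

#' Compose a feature name
#'
#' `{genotype}{mark}{quantity}_{segment}`, where quantity is a condition tag
#' (e.g. `A` for air, `C` for ethylene) or a differential tag (`diff`,
#' `log2FC`).
#'
#' @param genotype,mark,quantity,segment vocabulary entries.
#' @param vocab list with `genotypes`, `marks`, `quantities`, `segments`
#'   character vectors used for validation.
#' @return character feature name.
#' @export
build_feature_name <- function(genotype, mark, quantity, segment,
                               vocab = default_vocabulary()) {
  ok <- genotype %in% vocab$genotypes & mark %in% vocab$marks &
    quantity %in% vocab$quantities & segment %in% vocab$segments
  if (!all(ok))
    stop("unknown vocabulary entry in ",
         paste(genotype, mark, quantity, segment, sep = "/"))
  paste0(genotype, mark, quantity, "_", segment)
}

#' Default feature-name vocabulary
#' @param genotypes,marks,conditions,segments vocabulary entries.
#' @return list of vocabularies; `quantities` = conditions plus `diff` and
#'   `log2FC`.
#' @export
default_vocabulary <- function(genotypes = c("C", "e"),
                               marks = c("K9", "K14", "K23"),
                               conditions = c("A", "C"),
                               segments = SEGMENT_KINDS) {
  list(genotypes = genotypes, marks = marks, conditions = conditions,
       quantities = c(conditions, "diff", "log2FC"), segments = segments)
}

track_key <- function(genotype, mark, condition)
  paste(genotype, mark, condition, sep = ".")

#' Build the segment-signal feature matrix
#'
#' For every genotype x mark the matrix carries, over every segment kind:
#' the per-condition normalized densities, their scaled difference (`diff`)
#' and pseudocounted `log2FC` (second condition vs first; with the default
#' condition names, ethylene vs air). Genes missing a segment get missing
#' values in that segment's columns but remain as rows.
#'
#' @param tracks named list keyed `"{genotype}.{mark}.{condition}"`; each
#'   element a list with `reads` (data.table chrom/start/end) and optional
#'   `total_reads` (defaults to `nrow(reads)`).
#' @param segment_sets result of [extract_all_segments()].
#' @param vocab vocabulary from [default_vocabulary()].
#' @param pseudocount for [log2fc()].
#' @return numeric matrix, rownames gene ids (sorted), colnames feature
#'   names; attribute `"track_totals"` records normalization constants.
#' @export
build_segment_feature_matrix <- function(tracks, segment_sets,
                                         vocab = default_vocabulary(),
                                         pseudocount = 1e-3) {
  gene_ids <- sort(names(segment_sets))
  segs <- vocab$segments
  conds <- vocab$conditions
  stopifnot(length(conds) == 2L)

  # segment lengths per gene x kind
  seg_len <- matrix(NA_real_, length(gene_ids), length(segs),
                    dimnames = list(gene_ids, segs))
  for (gid in gene_ids) {
    ss <- segment_sets[[gid]]
    for (kind in intersect(names(ss), segs))
      seg_len[gid, kind] <- interval_len(ss[[kind]])
  }

  flat <- flatten_segments(segment_sets)
  n_feat <- length(vocab$genotypes) * length(vocab$marks) *
    length(vocab$quantities) * length(segs)
  mat <- matrix(NA_real_, length(gene_ids), n_feat,
                dimnames = list(gene_ids, rep("", n_feat)))
  totals <- list()
  col <- 0L
  for (g in vocab$genotypes) for (mk in vocab$marks) {
    dens <- list()
    for (cond in conds) {
      key <- track_key(g, mk, cond)
      tr <- tracks[[key]]
      if (is.null(tr)) stop("missing track: ", key)
      total <- tr$total_reads %||% nrow(tr$reads)
      totals[[key]] <- total
      cnt <- count_segment_matrix(tr$reads, segment_sets, segs = flat)
      d <- matrix(NA_real_, length(gene_ids), length(segs),
                  dimnames = list(gene_ids, segs))
      idx <- cbind(match(cnt$gene_id, gene_ids), match(cnt$kind, segs))
      keep <- stats::complete.cases(idx)   # kinds outside the vocabulary
      d[idx[keep, , drop = FALSE]] <- cnt$n[keep]
      d <- normalize_density(d, seg_len, total)
      dens[[cond]] <- d
    }
    quants <- list(dens[[conds[1L]]], dens[[conds[2L]]],
                   diff_metric(dens[[conds[1L]]], dens[[conds[2L]]]),
                   log2fc(dens[[conds[1L]]], dens[[conds[2L]]], pseudocount))
    names(quants) <- vocab$quantities
    for (q in vocab$quantities) for (kind in segs) {
      col <- col + 1L
      mat[, col] <- quants[[q]][, kind]
      colnames(mat)[col] <- build_feature_name(g, mk, q, kind, vocab)
    }
  }
  if (anyDuplicated(colnames(mat)))
    stop("duplicate feature names in segment feature matrix")
  attr(mat, "track_totals") <- totals
  mat
}

#' Impute missing feature values
#'
#' Missing values (absent segments, genes with no nearby peaks) carry a
#' "no signal" meaning here, so they are imputed as 0 before model fitting.
#' A per-column missingness report is attached.
#'
#' @param mat feature matrix with possible `NA`s.
#' @param value imputation value (default 0).
#' @return matrix without `NA`s; attribute `"missingness"` holds the per
#'   column fraction that was imputed.
#' @export
impute_missing <- function(mat, value = 0) {
  miss <- colMeans(is.na(mat))
  mat[is.na(mat)] <- value
  attr(mat, "missingness") <- miss
  mat
}
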