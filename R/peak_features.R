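# Peak-derived gene features: nearest-gene assignment within 5 kb, the four
# per-track aggregates (numberpeaks, avg_peaksize, avg_FE, avg_distance),
# and differential peaks via the M statistic (median-M normalization +
# conditional binomial Poisson-equality test).

#' Assign peaks to their nearest gene within a distance cap
#'
#' Each peak is assigned to the single nearest gene whose full-gene span
#' lies within `max_distance` bp (gap distance; 0 when overlapping, strand
#' ignored). Equidistant ties go to the lexicographically smallest gene id.
#' Peaks with no gene within range stay unassigned.
#'
#' @param peaks data.table(chrom, start, end, ...) of peaks, 0-based
#'   half-open.
#' @param genes list of [gene_model()] objects.
#' @param max_distance bp cap (default 5000).
#' @return data.table with one row per assigned peak: peak columns plus
#'   `gene_id` and `distance`. Attribute `"n_unassigned"` counts dropped
#'   peaks.
#' @export
assign_peaks_to_genes <- function(peaks, genes, max_distance = 5000) {
  peaks <- data.table::as.data.table(peaks)
  gene_tab <- data.table::data.table(
    chrom = vapply(genes, `[[`, character(1), "chrom"),
    start = vapply(genes, function(g) g$exons[1L, 1], numeric(1)),
    end = vapply(genes, function(g) g$exons[nrow(g$exons), 2], numeric(1)),
    gene_id = vapply(genes, `[[`, character(1), "gene_id"))
  if (nrow(peaks) == 0L) {
    out <- cbind(peaks, data.table::data.table(gene_id = character(0),
                                               distance = numeric(0)))
    attr(out, "n_unassigned") <- 0L
    return(out)
  }
  pg <- to_granges(peaks)
  gg <- to_granges(gene_tab)
  # candidates = genes whose span lies within max_distance of the peak;
  # exact gap distances computed pairwise so ties can be broken explicitly
  wide <- GenomicRanges::resize(pg, GenomicRanges::width(pg) +
                                  2 * max_distance, fix = "center")
  hits <- GenomicRanges::findOverlaps(wide, gg, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  d <- GenomicRanges::distance(pg[qh], gg[sh], ignore.strand = TRUE)
  cand <- data.table::data.table(peak = qh, gene_id = gene_tab$gene_id[sh],
                                 distance = as.numeric(d))
  cand <- cand[!is.na(cand$distance) & cand$distance <= max_distance, ]
  # deterministic tie-break: smallest gene_id among equidistant nearest
  data.table::setorderv(cand, c("peak", "distance", "gene_id"))
  cand <- cand[!duplicated(cand$peak), ]
  out <- cbind(peaks[cand$peak, ], cand[, c("gene_id", "distance")])
  attr(out, "n_unassigned") <- nrow(peaks) - nrow(cand)
  out
}

#' Per-gene aggregates over assigned peaks
#'
#' Arithmetic means over the peaks assigned to each gene: count
#' (`numberpeaks_{track}`), mean peak width (`avg_peaksize_{track}`), mean
#' fold enrichment (`avg_FE_{track}`) and mean peak-to-gene distance
#' (`avg_distance_{track}`). Genes with no assigned peak get missing values.
#'
#' @param assignment output of [assign_peaks_to_genes()]; must carry a
#'   `fold_enrichment` column.
#' @param track label appended to the four feature names (e.g. `"CK9A"`).
#' @param gene_ids full gene universe for the rows.
#' @return numeric matrix genes x 4.
#' @export
peak_gene_features <- function(assignment, track, gene_ids) {
  cols <- paste0(c("numberpeaks_", "avg_peaksize_", "avg_FE_",
                   "avg_distance_"), track)
  mat <- matrix(NA_real_, length(gene_ids), 4L,
                dimnames = list(gene_ids, cols))
  if (nrow(assignment) > 0L) {
    ag <- data.table::as.data.table(assignment)[, list(
      n = .N, size = mean(end - start), fe = mean(fold_enrichment),
      dist = mean(distance)), by = "gene_id"]
    i <- match(ag$gene_id, gene_ids)
    keep <- !is.na(i)
    mat[i[keep], ] <- as.matrix(ag[keep, c("n", "size", "fe", "dist")])
  }
  mat
}

#' M value of a peak: log2 density ratio, treated over control
#' @param density_eth,density_air positive read densities (post
#'   pseudocount/normalization), treated condition first.
#' @return `log2(density_eth / density_air)`.
#' @export
m_value <- function(density_eth, density_air) {
  if (any(density_air <= 0) || any(density_eth <= 0))
    stop("m_value requires positive densities")
  log2(density_eth / density_air)
}

#' Pair peaks found in both conditions ("common" peaks)
#'
#' Overlapping peak intervals between the two condition peak sets are
#' paired (first overlap wins, deterministic order); the pair keeps the
#' union interval and both condition counts.
#'
#' @param peaks_air,peaks_eth data.tables with chrom/start/end and a `count`
#'   column of reads in the peak (plus optional fold_enrichment columns).
#' @return data.table(chrom, start, end, count_air, count_eth).
#' @export
pair_common_peaks <- function(peaks_air, peaks_eth) {
  a <- data.table::as.data.table(peaks_air)
  e <- data.table::as.data.table(peaks_eth)
  if (nrow(a) == 0L || nrow(e) == 0L)
    return(data.table::data.table(chrom = character(0), start = numeric(0),
                                  end = numeric(0), count_air = numeric(0),
                                  count_eth = numeric(0)))
  ov <- GenomicRanges::findOverlaps(to_granges(a), to_granges(e))
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  keep <- !duplicated(qh) & !duplicated(sh)
  qh <- qh[keep]; sh <- sh[keep]
  data.table::data.table(
    chrom = a$chrom[qh],
    start = pmin(a$start[qh], e$start[sh]),
    end = pmax(a$end[qh], e$end[sh]),
    count_air = a$count[qh], count_eth = e$count[sh])
}

#' Rescale the treated condition so the median M over common peaks is zero
#'
#' A single global factor `2^(-median M)` applied to the treated (second
#' condition) counts — the median-shift simplification of an M-A
#' normalization over peaks present in both conditions.
#'
#' @param common data.table from [pair_common_peaks()].
#' @param pseudocount added before ratios (default 0.5).
#' @return list with `common` (extra columns `count_eth_norm`, `M`),
#'   `factor`, and the achieved `median_M` (0 unless no common peaks).
#' @export
normalize_densities <- function(common, pseudocount = 0.5) {
  common <- data.table::as.data.table(common)
  if (nrow(common) == 0L) {
    warning("no common peaks; normalization factor 1")
    common$count_eth_norm <- numeric(0)
    common$M <- numeric(0)
    return(list(common = common, factor = 1, median_M = NA_real_))
  }
  m_raw <- m_value(common$count_eth + pseudocount,
                   common$count_air + pseudocount)
  f <- 2^(-stats::median(m_raw))
  common$count_eth_norm <- common$count_eth * f
  # algebraically identical to recomputing log2 on the rescaled counts, but
  # keeps the median shift exact in floating point
  common$M <- m_raw - stats::median(m_raw)
  list(common = common, factor = f, median_M = stats::median(common$M))
}

# Exact two-sided binomial test that two (rate-adjusted) Poisson counts have
# equal means, conditional on their total: X_eth | total ~ Binom(total, p0)
# with p0 = f/(1+f) for normalization factor f.
poisson_equality_p <- function(count_eth, count_air, factor = 1) {
  p0 <- factor / (1 + factor)
  n <- count_eth + count_air
  mapply(function(x, n) {
    if (n == 0) return(1)
    stats::binom.test(round(x), round(n), p = p0)$p.value
  }, count_eth, n)
}

#' Call differential peaks by M value and Poisson-equality p-value
#'
#' Keeps common peaks with `|M| >= m_threshold` and a conditional-binomial
#' p-value `<= p_threshold` (two-sided test of equal Poisson means on the
#' raw count pair, success probability adjusted by the normalization
#' factor).
#'
#' @param normalized list from [normalize_densities()].
#' @param m_threshold minimum `|M|` (default 0.4).
#' @param p_threshold maximum p (default 0.05).
#' @return data.table of retained peaks with `M`, `p_value` and
#'   `fold_enrichment = 2^M` (treated-vs-control enrichment).
#' @export
call_differential_peaks <- function(normalized, m_threshold = 0.4,
                                    p_threshold = 0.05) {
  common <- data.table::as.data.table(normalized$common)
  if (nrow(common) == 0L) {
    common$p_value <- numeric(0)
    common$fold_enrichment <- numeric(0)
    return(common)
  }
  common$p_value <- poisson_equality_p(common$count_eth, common$count_air,
                                       factor = normalized$factor)
  keep <- abs(common$M) >= m_threshold & common$p_value <= p_threshold
  out <- common[keep, ]
  out$fold_enrichment <- 2^out$M
  out
}

#' Per-gene aggregates over differential peaks
#'
#' Same four aggregates as [peak_gene_features()] (names suffixed with the
#' differential track label, e.g. `numberpeaks_CK9diff`), with the fold
#' enrichment being the M-derived treated-vs-control ratio `2^M`.
#'
#' @param diff_peaks output of [call_differential_peaks()].
#' @param genes gene models for assignment.
#' @param track differential track label (e.g. `"CK9diff"`).
#' @param gene_ids gene universe.
#' @param max_distance assignment cap (default 5000).
#' @return numeric matrix genes x 4.
#' @export
differential_peak_gene_features <- function(diff_peaks, genes, track,
                                            gene_ids, max_distance = 5000) {
  assignment <- assign_peaks_to_genes(diff_peaks, genes, max_distance)
  peak_gene_features(assignment, track, gene_ids)
}

#' Build the full peak feature block for all tracks
#'
#' Four aggregates per condition track (genotype x mark x condition) plus
#' four per differential track (genotype x mark), columns in deterministic
#' vocabulary order.
#'
#' @param peak_tracks named list keyed `"{genotype}.{mark}.{condition}"`,
#'   each a data.table with chrom/start/end/fold_enrichment/count.
#' @param genes gene models.
#' @param vocab vocabulary from [default_vocabulary()].
#' @param max_distance assignment cap.
#' @param m_threshold,p_threshold differential-peak thresholds.
#' @return numeric matrix genes x (8 per genotype x mark).
#' @export
build_peak_feature_matrix <- function(peak_tracks, genes,
                                      vocab = default_vocabulary(),
                                      max_distance = 5000,
                                      m_threshold = 0.4, p_threshold = 0.05) {
  gene_ids <- sort(vapply(genes, `[[`, character(1), "gene_id"))
  conds <- vocab$conditions
  blocks <- list()
  for (g in vocab$genotypes) for (mk in vocab$marks) {
    for (cond in conds) {
      key <- track_key(g, mk, cond)
      pk <- peak_tracks[[key]]
      if (is.null(pk)) stop("missing peak track: ", key)
      asg <- assign_peaks_to_genes(pk, genes, max_distance)
      blocks[[length(blocks) + 1L]] <-
        peak_gene_features(asg, paste0(g, mk, cond), gene_ids)
    }
    common <- pair_common_peaks(peak_tracks[[track_key(g, mk, conds[1L])]],
                                peak_tracks[[track_key(g, mk, conds[2L])]])
    norm <- if (nrow(common) == 0L) {
      list(common = common, factor = 1, median_M = NA_real_)
    } else normalize_densities(common)
    dp <- call_differential_peaks(norm, m_threshold, p_threshold)
    blocks[[length(blocks) + 1L]] <-
      differential_peak_gene_features(dp, genes, paste0(g, mk, "diff"),
                                      gene_ids, max_distance)
  }
  do.call(cbind, blocks)
}
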