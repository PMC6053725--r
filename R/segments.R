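# Gene-anatomy segments: derive the named promoter/UTR/exon/intron segments
# of a protein-coding gene model. All coordinates are 0-based half-open.

SEGMENT_KINDS <- c(
  "TSS1500", "TSS200", "TSSplus200", "TTS200", "UTR5", "UTR3",
  "first_exon", "first_intron", "exon_body", "intron_body",
  "last_intron", "last_exon", "single_exon", "single_intron",
  "full_transcript", "full_gene"
)

#' Construct a gene model
#'
#' A minimal transcript-level gene model: strand, ordered exons and an
#' optional coding region from which the UTRs can be derived.
#'
#' @param gene_id,transcript_id identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix of exon `[start, end)` intervals, 0-based
#'   half-open, non-overlapping, sorted by genomic coordinate.
#' @param cds_start,cds_end optional genomic bounds `[cds_start, cds_end)` of
#'   the coding region; `NA` when the annotation carries no CDS, in which
#'   case the UTR segments are reported as missing.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons,
                       transcript_id = gene_id,
                       cds_start = NA_real_, cds_end = NA_real_) {
  exons <- interval_matrix(exons[, 1], exons[, 2])
  if (nrow(exons) == 0L) stop("gene model must have at least one exon")
  if (any(exons[, 2] <= exons[, 1])) stop("exons must have positive length")
  o <- order(exons[, 1])
  exons <- exons[o, , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1] < exons[-nrow(exons), 2]))
    stop("exons must be non-overlapping")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(
    list(gene_id = gene_id, transcript_id = transcript_id,
         chrom = chrom, strand = strand, exons = exons,
         cds_start = as.numeric(cds_start), cds_end = as.numeric(cds_end)),
    class = "gene_model"
  )
}

# Introns = genomic gaps between consecutive exons (genomic order).
gene_introns <- function(gene) {
  ex <- gene$exons
  n <- nrow(ex)
  if (n < 2L) return(interval_matrix(numeric(0), numeric(0)))
  interval_matrix(ex[-n, 2], ex[-1L, 1])
}

# Intersect an interval union with a single window [lo, hi).
intersect_window <- function(iv, lo, hi) {
  s <- pmax(iv[, 1], lo)
  e <- pmin(iv[, 2], hi)
  keep <- e > s
  if (!any(keep)) return(NULL)
  interval_matrix(s[keep], e[keep])
}

#' Extract the named segments of a gene model
#'
#' Derives the up-to-16 named segments used for feature extraction:
#' promoter-proximal windows (`TSS1500`, `TSS200`, `TSSplus200`, `TTS200`),
#' `UTR5`/`UTR3` (when a CDS is annotated), first/last/body exons and
#' introns, `single_exon`/`single_intron` for one-element genes,
#' `full_transcript` (union of exons) and `full_gene` (exon span including
#' introns). All segments are strand-aware: "first" means first in
#' transcription order, and the TSS windows are mirrored on the minus
#' strand. Segments that do not exist for a gene (e.g. introns of a
#' single-exon gene) are missing (`NULL`), not zero-length.
#'
#' @param gene a [gene_model()].
#' @param chromosome_length length of the chromosome in bp; upstream and
#'   downstream windows are clipped to `[0, chromosome_length)`.
#' @return named list of class `segment_set`; each present segment is a
#'   two-column matrix of `[start, end)` intervals (interval union), absent
#'   segments are omitted. Attributes keep `gene_id`, `chrom`, `strand`.
#' @export
extract_segments <- function(gene, chromosome_length) {
  stopifnot(inherits(gene, "gene_model"))
  ex <- gene$exons
  n_ex <- nrow(ex)
  if (chromosome_length < max(ex[, 2]))
    stop("chromosome_length smaller than the gene's rightmost exon end")
  introns <- gene_introns(gene)
  n_in <- nrow(introns)
  plus <- gene$strand == "+"
  tss <- if (plus) ex[1L, 1] else ex[n_ex, 2]
  tts <- if (plus) ex[n_ex, 2] else ex[1L, 1]

  seg <- list()
  if (plus) {
    seg$TSS1500    <- interval_matrix(tss - 1500, tss)
    seg$TSS200     <- interval_matrix(tss - 200, tss)
    seg$TSSplus200 <- interval_matrix(tss, tss + 200)
    seg$TTS200     <- interval_matrix(tts, tts + 200)
  } else {
    seg$TSS1500    <- interval_matrix(tss, tss + 1500)
    seg$TSS200     <- interval_matrix(tss, tss + 200)
    seg$TSSplus200 <- interval_matrix(tss - 200, tss)
    seg$TTS200     <- interval_matrix(tts - 200, tts)
  }

  # UTRs from the annotated CDS: transcript portions outside [cds_start,
  # cds_end), split by strand into 5' and 3'.
  if (!is.na(gene$cds_start) && !is.na(gene$cds_end) &&
      gene$cds_end > gene$cds_start) {
    left  <- intersect_window(ex, -Inf, gene$cds_start)
    right <- intersect_window(ex, gene$cds_end, Inf)
    seg$UTR5 <- if (plus) left else right
    seg$UTR3 <- if (plus) right else left
  }

  # Exon/intron anatomy in transcription order.
  first_idx <- function(n) if (plus) 1L else n
  last_idx  <- function(n) if (plus) n else 1L
  if (n_ex == 1L) {
    seg$single_exon <- ex
  } else {
    seg$first_exon <- ex[first_idx(n_ex), , drop = FALSE]
    seg$last_exon  <- ex[last_idx(n_ex), , drop = FALSE]
    if (n_ex >= 3L) {
      body <- ex[-c(1L, n_ex), , drop = FALSE]
      seg$exon_body <- body
    }
  }
  if (n_in >= 1L) {
    seg$first_intron <- introns[first_idx(n_in), , drop = FALSE]
    seg$last_intron  <- introns[last_idx(n_in), , drop = FALSE]
    if (n_in == 1L) seg$single_intron <- introns
    if (n_in >= 3L) seg$intron_body <- introns[-c(1L, n_in), , drop = FALSE]
  }

  seg$full_transcript <- ex
  seg$full_gene <- interval_matrix(ex[1L, 1], ex[n_ex, 2])

  seg <- lapply(seg, clip_intervals, chrom_length = chromosome_length)
  seg <- seg[!vapply(seg, is.null, logical(1))]
  seg <- seg[intersect(SEGMENT_KINDS, names(seg))]
  structure(seg, class = "segment_set",
            gene_id = gene$gene_id, chrom = gene$chrom,
            strand = gene$strand)
}

#' Extract segments for a list of gene models
#'
#' @param genes list of [gene_model()] objects.
#' @param chrom_lengths named numeric vector of chromosome lengths.
#' @return named list of `segment_set`s keyed by `gene_id`.
#' @export
extract_all_segments <- function(genes, chrom_lengths) {
  out <- lapply(genes, function(g) {
    len <- chrom_lengths[[g$chrom]]
    if (is.null(len) || is.na(len))
      stop("no chromosome length for ", g$chrom)
    extract_segments(g, len)
  })
  names(out) <- vapply(genes, `[[`, character(1), "gene_id")
  out
}

#' Flatten segment sets to a BED-style table
#'
#' One row per interval with the name field `{gene_id}|{segment_kind}`,
#' suitable for writing as BED.
#'
#' @param segment_sets result of [extract_all_segments()].
#' @param genes the matching list of gene models (for chrom/strand).
#' @return data.table with columns chrom, start, end, name, score, strand.
#' @export
segments_to_bed <- function(segment_sets, genes) {
  chrom <- vapply(genes, `[[`, character(1), "chrom")
  strand <- vapply(genes, `[[`, character(1), "strand")
  ids <- vapply(genes, `[[`, character(1), "gene_id")
  names(chrom) <- names(strand) <- ids
  rows <- list()
  for (gid in names(segment_sets)) {
    ss <- segment_sets[[gid]]
    for (kind in names(ss)) {
      iv <- ss[[kind]]
      rows[[length(rows) + 1L]] <- data.table::data.table(
        chrom = chrom[[gid]], start = iv[, 1], end = iv[, 2],
        name = paste0(gid, "|", kind), score = 0L, strand = strand[[gid]]
      )
    }
  }
  data.table::rbindlist(rows)
}
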