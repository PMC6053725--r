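# Readers and writers for the standard interchange formats the pipeline
# consumes and emits: GFF3/GTF/BED12 gene models, BED6 read intervals,
# ENCODE narrowPeak, and plain TSV tables. rtracklayer handles GFF/GTF
# parsing (and its 1-based closed -> 0-based half-open conversion happens
# here, at the boundary); BED-family files are plain tab tables.

#' Read gene models from GFF3, GTF or BED12
#'
#' When a gene has several annotated transcripts the longest one (by summed
#' exon length) is used. BED12 input takes exons from the block fields and
#' the coding region from thickStart/thickEnd.
#'
#' @param path annotation file.
#' @param format `"auto"` (by extension), `"gff3"`, `"gtf"` or `"bed12"`.
#' @return list of [gene_model()] objects.
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "gtf", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      gff = , gff3 = "gff3",
      gtf = "gtf",
      bed = , bed12 = "bed12",
      stop("cannot guess annotation format from extension: ", ext))
  }
  if (format == "bed12") read_bed12_models(path) else read_gff_models(path, format)
}

read_gff_models <- function(path, format) {
  gr <- rtracklayer::import(path, format = format)
  df <- as.data.frame(gr)
  type <- as.character(df$type)
  getattr <- function(d, nm) if (nm %in% names(d)) as.character(d[[nm]]) else rep(NA_character_, nrow(d))

  if (format == "gtf") {
    tx_of <- getattr(df, "transcript_id")
    gene_of <- getattr(df, "gene_id")
  } else {
    # GFF3: exon/CDS Parent points at the transcript; transcript Parent at
    # the gene. Parent may be a CharacterList.
    par <- df$Parent
    par <- vapply(seq_len(nrow(df)), function(i) {
      p <- par[[i]]
      if (length(p) == 0L) NA_character_ else as.character(p[[1L]])
    }, character(1))
    id <- getattr(df, "ID")
    tx_rows <- type %in% c("mRNA", "transcript")
    tx_gene <- par[tx_rows]
    names(tx_gene) <- id[tx_rows]
    tx_of <- par
    gene_of <- unname(tx_gene[par])
  }

  ex_rows <- which(type == "exon")
  cds_rows <- which(type == "CDS")
  if (length(ex_rows) == 0L) stop("annotation contains no exon records")
  ex_tx <- tx_of[ex_rows]
  models <- list()
  for (tx in unique(ex_tx)) {
    rows <- ex_rows[ex_tx == tx]
    exs <- interval_matrix(df$start[rows] - 1, df$end[rows])
    crows <- cds_rows[tx_of[cds_rows] == tx]
    cs <- if (length(crows)) min(df$start[crows] - 1) else NA_real_
    ce <- if (length(crows)) max(df$end[crows]) else NA_real_
    gid <- if (format == "gtf") gene_of[rows[1L]] else gene_of[ex_rows[ex_tx == tx][1L]]
    if (is.na(gid)) gid <- tx
    models[[tx]] <- gene_model(
      gene_id = gid, transcript_id = tx,
      chrom = as.character(df$seqnames[rows[1L]]),
      strand = as.character(df$strand[rows[1L]]),
      exons = exs, cds_start = cs, cds_end = ce
    )
  }
  pick_longest_per_gene(models)
}

pick_longest_per_gene <- function(models) {
  gid <- vapply(models, `[[`, character(1), "gene_id")
  len <- vapply(models, function(m) interval_len(m$exons), numeric(1))
  keep <- vapply(split(seq_along(models), gid), function(idx) {
    idx[order(-len[idx], vapply(models[idx], `[[`, character(1),
                                "transcript_id"))][1L]
  }, integer(1))
  out <- models[sort(keep)]
  names(out) <- vapply(out, `[[`, character(1), "gene_id")
  out[order(names(out))]
}

read_bed12_models <- function(path) {
  bed <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(bed) < 12L) stop("BED12 requires 12 columns, got ", ncol(bed))
  data.table::setnames(bed, 1:12, c(
    "chrom", "start", "end", "name", "score", "strand", "thickStart",
    "thickEnd", "itemRgb", "blockCount", "blockSizes", "blockStarts"))
  models <- lapply(seq_len(nrow(bed)), function(i) {
    r <- bed[i]
    sizes <- as.numeric(strsplit(sub(",$", "", r$blockSizes), ",")[[1L]])
    offs <- as.numeric(strsplit(sub(",$", "", r$blockStarts), ",")[[1L]])
    st <- r$start + offs
    cs <- if (r$thickEnd > r$thickStart) as.numeric(r$thickStart) else NA_real_
    ce <- if (r$thickEnd > r$thickStart) as.numeric(r$thickEnd) else NA_real_
    gene_model(gene_id = r$name, chrom = r$chrom, strand = r$strand,
               exons = interval_matrix(st, st + sizes),
               cds_start = cs, cds_end = ce)
  })
  names(models) <- vapply(models, `[[`, character(1), "gene_id")
  pick_longest_per_gene(models)
}

#' Write gene models as BED12
#' @param genes list of [gene_model()].
#' @param path output file.
#' @export
write_bed12 <- function(genes, path) {
  rows <- lapply(genes, function(g) {
    ex <- g$exons
    gs <- ex[1L, 1]
    ts <- if (!is.na(g$cds_start)) g$cds_start else gs
    te <- if (!is.na(g$cds_end)) g$cds_end else gs
    data.table::data.table(
      chrom = g$chrom, start = gs, end = ex[nrow(ex), 2], name = g$gene_id,
      score = 0L, strand = g$strand, thickStart = ts, thickEnd = te,
      itemRgb = 0L, blockCount = nrow(ex),
      blockSizes = paste0(paste(format(ex[, 2] - ex[, 1], scientific = FALSE,
                                       trim = TRUE), collapse = ","), ","),
      blockStarts = paste0(paste(format(ex[, 1] - gs, scientific = FALSE,
                                        trim = TRUE), collapse = ","), ","))
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Write gene models as GFF3 (gene/mRNA/exon/CDS records)
#' @param genes list of [gene_model()].
#' @param path output file.
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3")
  for (g in genes) {
    ex <- g$exons
    span <- c(ex[1L, 1] + 1, ex[nrow(ex), 2])
    lines <- c(lines,
      sprintf("%s\tepideg\tgene\t%d\t%d\t.\t%s\t.\tID=%s", g$chrom,
              span[1], span[2], g$strand, g$gene_id),
      sprintf("%s\tepideg\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$chrom, span[1], span[2], g$strand, g$transcript_id,
              g$gene_id),
      sprintf("%s\tepideg\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
              g$chrom, ex[, 1] + 1, ex[, 2], g$strand, g$transcript_id,
              seq_len(nrow(ex)), g$transcript_id))
    if (!is.na(g$cds_start) && !is.na(g$cds_end) && g$cds_end > g$cds_start) {
      cds <- intersect_window(ex, g$cds_start, g$cds_end)
      if (!is.null(cds))
        lines <- c(lines,
          sprintf("%s\tepideg\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds%d;Parent=%s",
                  g$chrom, cds[, 1] + 1, cds[, 2], g$strand,
                  g$transcript_id, seq_len(nrow(cds)), g$transcript_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 file of aligned-read intervals
#' @param path BED file (>= 3 columns).
#' @return data.table(chrom, start, end[, name, score, strand]).
#' @export
read_bed_reads <- function(path) {
  bed <- data.table::fread(path, header = FALSE, sep = "\t")
  nms <- c("chrom", "start", "end", "name", "score", "strand")
  data.table::setnames(bed, seq_len(min(ncol(bed), 6L)),
                       nms[seq_len(min(ncol(bed), 6L))])
  bed
}

#' Write read intervals as BED6
#' @param reads data.table with chrom/start/end (name, score, strand filled
#'   with defaults when absent).
#' @param path output file.
#' @export
write_bed_reads <- function(reads, path) {
  dt <- data.table::as.data.table(reads)
  if (!"name" %in% names(dt)) dt$name <- sprintf("read%d", seq_len(nrow(dt)))
  if (!"score" %in% names(dt)) dt$score <- 0L
  if (!"strand" %in% names(dt)) dt$strand <- "."
  data.table::fwrite(
    dt[, c("chrom", "start", "end", "name", "score", "strand")], path,
    sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read an ENCODE narrowPeak file
#'
#' @param path narrowPeak (BED6+4) file.
#' @return data.table with chrom, start, end, name, score, strand,
#'   fold_enrichment (column 7), pvalue_log10, qvalue_log10, summit.
#' @export
read_narrowpeak <- function(path) {
  pk <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(pk) < 10L) stop("narrowPeak requires 10 columns, got ", ncol(pk))
  data.table::setnames(pk, 1:10, c(
    "chrom", "start", "end", "name", "score", "strand",
    "fold_enrichment", "pvalue_log10", "qvalue_log10", "summit"))
  pk
}

#' Write peaks as ENCODE narrowPeak
#' @param peaks data.table with at least chrom/start/end/fold_enrichment.
#' @param path output file.
#' @export
write_narrowpeak <- function(peaks, path) {
  dt <- data.table::as.data.table(peaks)
  if (!"name" %in% names(dt)) dt$name <- sprintf("peak%d", seq_len(nrow(dt)))
  if (!"score" %in% names(dt)) dt$score <- 0L
  if (!"strand" %in% names(dt)) dt$strand <- "."
  if (!"pvalue_log10" %in% names(dt)) dt$pvalue_log10 <- -1
  if (!"qvalue_log10" %in% names(dt)) dt$qvalue_log10 <- -1
  if (!"summit" %in% names(dt))
    dt$summit <- as.integer(floor((dt$end - dt$start) / 2))
  data.table::fwrite(
    dt[, c("chrom", "start", "end", "name", "score", "strand",
           "fold_enrichment", "pvalue_log10", "qvalue_log10", "summit")],
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read/write plain TSV tables (expression, labels, feature matrices)
#' @param path file path.
#' @return data.table.
#' @export
read_tsv_table <- function(path) data.table::fread(path, sep = "\t")

#' @rdname read_tsv_table
#' @param x table to write.
#' @export
write_tsv_table <- function(x, path) {
  data.table::fwrite(data.table::as.data.table(x), path, sep = "\t")
  invisible(path)
}
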