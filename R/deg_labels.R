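# DEG labeling from RPKM expression tables: the fold-change/expression
# threshold rule, replicate correlation QC, the top-expressed candidate
# pool, and the cross-genotype |FC| filter used for TP/FP evaluation.

#' Summarize an expression table into per-condition means
#'
#' @param expression data.table with `gene_id` and RPKM replicate columns
#'   named `rpkm_rep{i}_{condition}`.
#' @param conditions the two condition names (default `c("A", "C")`).
#' @return data.table(gene_id, rpkm_air, rpkm_eth, fc) where `fc` is the
#'   pseudocounted mean ratio condition2/condition1.
#' @export
expression_summary <- function(expression, conditions = c("A", "C"),
                               pseudocount = 1e-3) {
  expr <- data.table::as.data.table(expression)
  mean_cond <- function(cond) {
    cols <- grep(paste0("^rpkm_rep[0-9]+_", cond, "$"), names(expr),
                 value = TRUE)
    if (length(cols) == 0L)
      stop("no replicate columns found for condition ", cond)
    rowMeans(as.matrix(expr[, cols, with = FALSE]))
  }
  a <- mean_cond(conditions[1L])
  b <- mean_cond(conditions[2L])
  data.table::data.table(gene_id = expr$gene_id, rpkm_air = a, rpkm_eth = b,
                         fc = (b + pseudocount) / (a + pseudocount))
}

#' Call DEG labels by fold-change and expression thresholds
#'
#' A gene is `up` when mean RPKM in the treated condition exceeds the
#' control by more than `fc_threshold`-fold, `down` for the reverse, and in
#' either case only when the larger of the two condition means exceeds
#' `rpkm_threshold`; otherwise `none`.
#'
#' @param records output of [expression_summary()] (or a table with
#'   `gene_id`, `rpkm_air`, `rpkm_eth`).
#' @param fc_threshold fold-change cutoff (default 1.5, strict).
#' @param rpkm_threshold expression floor (default 1, strict).
#' @return data.table(gene_id, label in {up, down, none}, fc).
#' @export
call_degs <- function(records, fc_threshold = 1.5, rpkm_threshold = 1.0) {
  r <- data.table::as.data.table(records)
  a <- r$rpkm_air
  b <- r$rpkm_eth
  expressed <- pmax(a, b) > rpkm_threshold
  up <- expressed & a > 0 & (b / a > fc_threshold)
  up[expressed & a == 0 & b > 0] <- TRUE
  down <- expressed & b > 0 & (a / b > fc_threshold)
  down[expressed & b == 0 & a > 0] <- TRUE
  label <- rep("none", nrow(r))
  label[up] <- "up"
  label[down] <- "down"
  pc <- 1e-3
  data.table::data.table(gene_id = r$gene_id, label = label,
                         fc = (b + pc) / (a + pc))
}

#' Pearson correlation of log2 RPKM between two replicates
#'
#' @param rep1,rep2 RPKM vectors over the same genes (length >= 3).
#' @param pseudocount added before log2 (default 1).
#' @return Pearson r, or `NA` when a replicate has zero variance.
#' @export
replicate_correlation <- function(rep1, rep2, pseudocount = 1) {
  stopifnot(length(rep1) == length(rep2), length(rep1) >= 3L)
  x <- log2(rep1 + pseudocount)
  y <- log2(rep2 + pseudocount)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Select the top-expressed candidate pool
#'
#' Genes ranked by their larger condition-mean RPKM; the top
#' `round_half_up(fraction * N)` are kept. Ties at the cutoff break by gene
#' id, so the set is deterministic.
#'
#' @param records output of [expression_summary()].
#' @param fraction fraction of genes to keep (default 0.60).
#' @return character vector of gene ids (sorted).
#' @export
select_top_expressed <- function(records, fraction = 0.60) {
  stopifnot(fraction > 0, fraction <= 1)
  r <- data.table::as.data.table(records)
  score <- pmax(r$rpkm_air, r$rpkm_eth)
  o <- order(-score, r$gene_id)
  k <- round_half_up(fraction * nrow(r))
  sort(r$gene_id[o][seq_len(k)])
}

#' Genes passing an absolute fold-change filter
#'
#' Keeps genes whose fold change is more than `min_abs_fc`-fold in either
#' direction, with the direction attached — the evaluation label set for
#' cross-genotype TP/FP checks.
#'
#' @param records output of [expression_summary()].
#' @param min_abs_fc cutoff (default 4, strict).
#' @return data.table(gene_id, direction in {up, down}).
#' @export
abs_fc_filter <- function(records, min_abs_fc = 4.0) {
  r <- data.table::as.data.table(records)
  if (!"fc" %in% names(r))
    r$fc <- (r$rpkm_eth + 1e-3) / (r$rpkm_air + 1e-3)
  absfc <- pmax(r$fc, 1 / r$fc)
  keep <- absfc > min_abs_fc
  data.table::data.table(
    gene_id = r$gene_id[keep],
    direction = ifelse(r$fc[keep] > 1, "up", "down"))
}
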