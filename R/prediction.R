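# Candidate selection from probability-ranked genes: 200-gene bins, per-bin
# and cumulative precision against known labels, the 0.95 cumulative
# precision cutoff, direction agreement (TP/FP) against an evaluation label
# set, and the hypergeometric overlap test.

#' Rank genes by class probability and group into bins
#'
#' Genes are sorted by max-class probability (`max(p, 1-p)` for the
#' two-class problem) descending, ties broken by gene id, then cut into
#' consecutive bins of `bin_size` (the last bin may be smaller). The
#' predicted direction is `"up"` when `P(up) >= 0.5`, else `"down"`.
#'
#' @param probabilities named numeric vector, `P(up)` per gene.
#' @param bin_size genes per bin (default 200).
#' @return data.table(gene_id, prob_up, prob_max, predicted, bin) in rank
#'   order.
#' @export
rank_and_bin <- function(probabilities, bin_size = 200) {
  stopifnot(bin_size >= 1)
  if (length(probabilities) == 0L) stop("no probabilities to rank")
  dt <- data.table::data.table(
    gene_id = names(probabilities),
    prob_up = as.numeric(probabilities))
  dt$prob_max <- pmax(dt$prob_up, 1 - dt$prob_up)
  dt$predicted <- ifelse(dt$prob_up >= 0.5, "up", "down")
  data.table::setorderv(dt, c("prob_max", "gene_id"), order = c(-1L, 1L))
  dt$bin <- ceiling(seq_len(nrow(dt)) / bin_size)
  dt
}

#' Per-bin and cumulative precision against known labels
#'
#' Within each bin, precision = (known genes whose predicted direction
#' matches their known direction) / (known genes in the bin); bins without
#' known genes get a missing per-bin precision and leave the cumulative
#' value unchanged. Cumulative precision at bin b is the same ratio over
#' bins 1..b.
#'
#' @param ranked output of [rank_and_bin()].
#' @param known_labels data.table(gene_id, label/direction in
#'   {"up","down"}); genes outside `ranked` are ignored.
#' @return data.table(bin, n, n_known, n_match, precision, cum_known,
#'   cum_match, cum_precision).
#' @export
bin_precision <- function(ranked, known_labels) {
  kl <- data.table::as.data.table(known_labels)
  dir_col <- if ("direction" %in% names(kl)) "direction" else "label"
  kl <- kl[kl[[dir_col]] %in% c("up", "down"), ]
  known <- stats::setNames(kl[[dir_col]], kl$gene_id)
  r <- data.table::as.data.table(ranked)
  r$known_dir <- known[r$gene_id]
  r$is_known <- !is.na(r$known_dir)
  r$is_match <- r$is_known & r$predicted == r$known_dir
  out <- r[, list(n = .N, n_known = sum(is_known), n_match = sum(is_match)),
           by = "bin"]
  data.table::setorderv(out, "bin")
  out$precision <- ifelse(out$n_known > 0, out$n_match / out$n_known,
                          NA_real_)
  out$cum_known <- cumsum(out$n_known)
  out$cum_match <- cumsum(out$n_match)
  out$cum_precision <- ifelse(out$cum_known > 0,
                              out$cum_match / out$cum_known, NA_real_)
  out
}

#' Select genes by the cumulative-precision cutoff
#'
#' Keeps the longest prefix of bins whose cumulative precision is at least
#' `threshold`; the selected set is therefore always a whole number of bins.
#' If already the first bin fails, the selection is empty (with a warning).
#'
#' @param ranked output of [rank_and_bin()].
#' @param precision_table output of [bin_precision()].
#' @param threshold cumulative precision requirement (default 0.95).
#' @return data.table subset of `ranked` (the selected genes, rank order);
#'   attribute `"n_bins"` = number of bins kept.
#' @export
precision_cutoff <- function(ranked, precision_table, threshold = 0.95) {
  cp <- precision_table$cum_precision[order(precision_table$bin)]
  ok <- !is.na(cp) & cp >= threshold
  # longest prefix in which the cumulative precision stays >= threshold
  bad <- which(!ok)
  last <- if (length(bad)) bad[1L] - 1L else length(ok)
  if (last == 0L) {
    warning("first bin already below the precision threshold; ",
            "empty selection")
    sel <- ranked[0L, ]
  } else {
    sel <- ranked[ranked$bin <= last, ]
  }
  attr(sel, "n_bins") <- last
  sel
}

#' Direction agreement of selected predictions with an evaluation label set
#'
#' TP = selected genes whose predicted direction matches the evaluation
#' direction; FP = selected genes present in the evaluation set with the
#' opposite direction. Genes absent from the evaluation set count for
#' neither.
#'
#' @param selected data.table with gene_id and predicted (from
#'   [precision_cutoff()] / [rank_and_bin()]).
#' @param evaluation data.table(gene_id, direction).
#' @return list(tp, fp).
#' @export
direction_agreement <- function(selected, evaluation) {
  ev <- data.table::as.data.table(evaluation)
  dir_col <- if ("direction" %in% names(ev)) "direction" else "label"
  dirs <- stats::setNames(ev[[dir_col]], ev$gene_id)
  d <- dirs[selected$gene_id]
  known <- !is.na(d)
  list(tp = sum(known & selected$predicted == d),
       fp = sum(known & selected$predicted != d))
}

#' Hypergeometric overlap test
#'
#' Upper-tail probability of observing at least `overlap` known genes in a
#' selection of `selected_size` drawn from `population_size` containing
#' `known_size` known genes.
#'
#' @param selected_size,overlap,known_size,population_size counts.
#' @return `P(X >= overlap)` for hypergeometric X.
#' @export
overlap_test <- function(selected_size, overlap, known_size,
                         population_size) {
  if (overlap > min(selected_size, known_size) ||
      known_size > population_size || selected_size > population_size ||
      any(c(selected_size, overlap, known_size, population_size) < 0))
    stop("inconsistent counts for the hypergeometric test")
  stats::phyper(overlap - 1, known_size, population_size - known_size,
                selected_size, lower.tail = FALSE)
}
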