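# Model evaluation: stratified train/test split and k-fold CV (largest
# remainder allocation so split sizes are exact), confusion-matrix metrics
# (accuracy, precision, recall, F, MCC) and Mann-Whitney ROC/AUC.

# Allocate `total` among classes proportionally to counts by the largest
# remainder method (quota = n_c * total / N).
largest_remainder <- function(n_by_class, total) {
  quota <- n_by_class * total / sum(n_by_class)
  base <- floor(quota)
  left <- total - sum(base)
  if (left > 0L) {
    o <- order(-(quota - base), names(n_by_class))
    base[o[seq_len(left)]] <- base[o[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(base), names(n_by_class))
}

#' Stratified train/test split
#'
#' Training size is `round_half_up(fraction * N)` overall (2674 genes at 80%
#' gives exactly 2139 / 535); per-class training counts follow the largest
#' remainder method so class proportions are preserved while the total is
#' hit exactly. Assignment within a class is random under `seed`. A class
#' with a single member goes entirely to training with a warning.
#'
#' @param ids instance identifiers.
#' @param labels class labels aligned with `ids`.
#' @param fraction training fraction (default 0.8).
#' @param seed RNG seed.
#' @return list with `train`, `test` (id vectors), `fraction`, `seed`.
#' @export
stratified_split <- function(ids, labels, fraction = 0.8, seed = NULL) {
  stopifnot(length(ids) == length(labels), fraction > 0, fraction < 1)
  n_total <- round_half_up(fraction * length(ids))
  cls <- split(seq_along(ids), as.character(labels))
  singletons <- names(cls)[lengths(cls) < 2L]
  if (length(singletons))
    warning("class(es) with < 2 members assigned wholly to training: ",
            paste(singletons, collapse = ", "))
  alloc <- largest_remainder(lengths(cls), n_total)
  alloc[singletons] <- lengths(cls)[singletons]
  train_idx <- with_seed(seed, {
    unlist(lapply(names(cls), function(cl) {
      idx <- cls[[cl]]
      sample(idx)[seq_len(min(alloc[[cl]], length(idx)))]
    }), use.names = FALSE)
  })
  list(train = ids[sort(train_idx)],
       test = ids[sort(setdiff(seq_along(ids), train_idx))],
       fraction = fraction, seed = seed)
}

# Stratified fold assignment: shuffle within class, deal round-robin.
make_folds <- function(labels, folds, seed = NULL) {
  idx_by_class <- split(seq_along(labels), as.character(labels))
  fold <- integer(length(labels))
  with_seed(seed, {
    for (idx in idx_by_class) {
      sh <- sample(idx)
      fold[sh] <- rep_len(seq_len(folds), length(sh))
    }
  })
  fold
}

#' Confusion-matrix metrics
#'
#' Standard formulas; `f_measure` is the positive-class F1 and `f_weighted`
#' the support-weighted mean of the two per-class F1 values. Ratios with a
#' zero denominator are reported as 0 and flagged.
#'
#' @param tp,fp,fn,tn confusion counts (positive class = "up").
#' @return list with accuracy, precision, recall, f_measure, f_weighted,
#'   mcc, the counts, and `undefined` (names of zero-denominator metrics).
#' @export
compute_metrics <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0, tp + fp + fn + tn > 0)
  undefined <- character(0)
  safe <- function(num, den, what) {
    if (den == 0) {
      undefined <<- c(undefined, what)
      return(0)
    }
    num / den
  }
  n <- tp + fp + fn + tn
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  f_pos <- safe(2 * precision * recall, precision + recall, "f_measure")
  prec_neg <- safe(tn, tn + fn, "precision_neg")
  rec_neg <- safe(tn, tn + fp, "recall_neg")
  f_neg <- safe(2 * prec_neg * rec_neg, prec_neg + rec_neg, "f_neg")
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- safe(tp * tn - fp * fn, mcc_den, "mcc")
  list(accuracy = (tp + tn) / n, precision = precision, recall = recall,
       f_measure = f_pos,
       f_weighted = ((tp + fn) * f_pos + (fp + tn) * f_neg) / n,
       mcc = mcc, tp = tp, fp = fp, fn = fn, tn = tn,
       undefined = unique(undefined))
}

#' ROC curve and AUC (Mann-Whitney form)
#'
#' AUC is the probability that a random positive outranks a random negative,
#' ties counted 1/2 — computed from midranks, identical to the normalized
#' Mann-Whitney U. ROC points are emitted at every distinct threshold.
#'
#' @param probabilities scores, larger = more positive.
#' @param labels class labels; positive class `"up"`.
#' @return list with `auc` and `roc` (data.table threshold/fpr/tpr).
#' @export
roc_auc <- function(probabilities, labels) {
  pos <- as.character(labels) == "up"
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L)
    stop("roc_auc needs both classes present")
  r <- rank(probabilities, ties.method = "average")
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  o <- order(-probabilities)
  thr_change <- c(diff(probabilities[o]) != 0, TRUE)
  roc <- data.table::data.table(
    threshold = probabilities[o][thr_change],
    fpr = cumsum(!pos[o])[thr_change] / n_neg,
    tpr = cumsum(pos[o])[thr_change] / n_pos)
  roc <- rbind(data.table::data.table(threshold = Inf, fpr = 0, tpr = 0),
               roc)
  list(auc = auc, roc = roc)
}

#' Stratified k-fold cross-validation
#'
#' Feature selection, when requested, happens inside each training fold only
#' (no information leaks into the held-out fold). Reports per-fold and
#' pooled confusion metrics plus the AUC over pooled out-of-fold
#' probabilities. Folds that end up with one class in training are skipped
#' with a warning.
#'
#' @param classifier name for [train_classifier()].
#' @param x feature matrix (rownames = instance ids).
#' @param y labels aligned with rows (positive class `"up"`).
#' @param folds number of folds (default 10).
#' @param seed RNG seed (fold assignment and any classifier randomness).
#' @param selector optional: `"infogain"`, `"relieff"` or `"cfs"`.
#' @param top_fraction fraction of features kept by ranking selectors.
#' @param threshold probability cutoff for the confusion matrix (0.5).
#' @param ... passed to [train_classifier()].
#' @return list: `pooled` metrics (see [compute_metrics()]), `auc`, `roc`,
#'   `per_fold` data.table, `probabilities` (out-of-fold, named by id),
#'   `selected` (features chosen per fold).
#' @export
cross_validate <- function(classifier, x, y, folds = 10, seed = NULL,
                           selector = NULL, top_fraction = NULL,
                           threshold = 0.5, ...) {
  stopifnot(folds >= 2L, nrow(x) == length(y))
  y <- as.character(y)
  fold <- make_folds(y, folds, seed = seed)
  oof <- rep(NA_real_, length(y))
  per_fold <- list()
  selected <- list()
  for (f in sort(unique(fold))) {
    tr <- fold != f
    te <- !tr
    if (length(unique(y[tr])) < 2L) {
      warning("fold ", f, " skipped: single-class training data")
      next
    }
    xtr <- x[tr, , drop = FALSE]
    feats <- colnames(x)
    if (!is.null(selector)) {
      feats <- switch(selector,
        infogain = select_top_fraction(info_gain_ranking(xtr, y[tr]),
                                       ncol(x), top_fraction %||% 0.05),
        relieff = select_top_fraction(relieff(xtr, y[tr]), ncol(x),
                                      top_fraction %||% 0.05),
        cfs = {
          s <- cfs_select(xtr, y[tr])$features
          if (length(s) == 0L) colnames(x) else s
        },
        stop("unknown selector: ", selector))
      xtr <- xtr[, feats, drop = FALSE]
    }
    model <- train_classifier(classifier, xtr, y[tr],
                              seed = if (is.null(seed)) NULL
                                     else derive_seed(seed, f), ...)
    p <- predict(model, x[te, feats, drop = FALSE])
    oof[te] <- p
    pred <- ifelse(p >= threshold, "up", "down")
    per_fold[[length(per_fold) + 1L]] <- data.table::data.table(
      fold = f,
      tp = sum(pred == "up" & y[te] == "up"),
      fp = sum(pred == "up" & y[te] != "up"),
      fn = sum(pred != "up" & y[te] == "up"),
      tn = sum(pred != "up" & y[te] != "up"))
    selected[[length(selected) + 1L]] <- feats
  }
  pf <- data.table::rbindlist(per_fold)
  pooled <- compute_metrics(sum(pf$tp), sum(pf$fp), sum(pf$fn), sum(pf$tn))
  scored <- !is.na(oof)
  roc <- if (length(unique(y[scored])) == 2L) roc_auc(oof[scored], y[scored])
         else list(auc = NA_real_, roc = NULL)   # skipped folds can do this
  names(oof) <- rownames(x)
  list(pooled = pooled, auc = roc$auc, roc = roc$roc, per_fold = pf,
       probabilities = oof, selected = selected)
}
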