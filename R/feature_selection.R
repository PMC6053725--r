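# Feature selection: information gain, ReliefF, and correlation-based
# subset selection (CFS), plus the top-k% rule used to trim ranked lists.

#' Information gain of a feature about the class (bits)
#'
#' `H(labels) - H(labels | feature)` with continuous features discretized by
#' the supervised MDL binning ([discretize_feature()]). Constant features
#' and features with no MDL-acceptable split score 0.
#'
#' @param x feature values.
#' @param y class labels.
#' @param max_levels passed to [discretize_feature()].
#' @return nonnegative real (bits).
#' @export
info_gain <- function(x, y, max_levels = 10) {
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2L) return(0)
  b <- discretize_feature(x, y, max_levels = max_levels)
  tab <- table(b, y)
  n <- sum(tab)
  h_y <- entropy_bits(colSums(tab))
  h_cond <- sum(rowSums(tab) / n * row_entropy(unclass(tab)))
  max(0, h_y - h_cond)
}

#' Rank all features by information gain
#'
#' @param x feature matrix (genes x features, no missing values).
#' @param y class labels aligned with rows.
#' @return data.table(feature, score) sorted by decreasing score, ties
#'   broken by feature name.
#' @export
info_gain_ranking <- function(x, y) {
  scores <- vapply(seq_len(ncol(x)), function(j) info_gain(x[, j], y),
                   numeric(1))
  rank_table(colnames(x), scores)
}

rank_table <- function(features, scores) {
  dt <- data.table::data.table(feature = features, score = scores)
  data.table::setorderv(dt, c("score", "feature"), order = c(-1L, 1L))
  dt
}

#' ReliefF feature weights
#'
#' Instance-based weighting: every instance serves as a sampling point; for
#' each, the `k_neighbors` nearest hits (same class) and nearest misses per
#' other class (weighted by class prior) pull feature weights down/up by the
#' range-normalized value difference. Distances are range-normalized
#' Manhattan. Constant features get weight 0; single-class data gives
#' all-zero weights.
#'
#' @param x feature matrix.
#' @param y class labels.
#' @param k_neighbors neighbors per class (default 10).
#' @return data.table(feature, score) sorted decreasing.
#' @export
relieff <- function(x, y, k_neighbors = 10) {
  y <- as.factor(y)
  n <- nrow(x)
  p <- ncol(x)
  w <- numeric(p)
  classes <- levels(droplevels(y))
  if (length(classes) < 2L || n < 2L)
    return(rank_table(colnames(x), w))
  rng <- apply(x, 2L, function(v) diff(range(v)))
  rng[rng == 0] <- Inf                  # constant feature: diff == 0
  xs <- sweep(x, 2L, rng, "/")
  d <- as.matrix(stats::dist(xs, method = "manhattan"))
  diag(d) <- Inf
  prior <- table(y)[classes] / n
  for (i in seq_len(n)) {
    ci <- as.character(y[i])
    for (cl in classes) {
      idx <- which(as.character(y) == cl & seq_len(n) != i)
      if (length(idx) == 0L) next
      k <- min(k_neighbors, length(idx))
      nb <- idx[order(d[i, idx])][seq_len(k)]
      contrib <- colMeans(abs(
        sweep(xs[nb, , drop = FALSE], 2L, xs[i, ], "-")))
      if (cl == ci) w <- w - contrib / n
      else w <- w + (prior[[cl]] / (1 - prior[[ci]])) * contrib / n
    }
  }
  rank_table(colnames(x), w)
}

# Symmetrical uncertainty between two discrete code vectors (bits-based,
# in [0, 1]).
symmetrical_uncertainty <- function(a, b) {
  tab <- table(a, b)
  ha <- entropy_bits(rowSums(tab))
  hb <- entropy_bits(colSums(tab))
  if (ha + hb == 0) return(0)
  hab <- entropy_bits(as.vector(tab))
  2 * (ha + hb - hab) / (ha + hb)
}

# CFS merit of a subset given feature-class and feature-feature correlation
# accessors.
cfs_merit <- function(subset, rcf, rff_fun) {
  k <- length(subset)
  if (k == 0L) return(0)
  mean_rcf <- mean(rcf[subset])
  if (k == 1L) return(mean_rcf)
  pairs <- utils::combn(subset, 2L)
  mean_rff <- mean(vapply(seq_len(ncol(pairs)),
                          function(j) rff_fun(pairs[1L, j], pairs[2L, j]),
                          numeric(1)))
  k * mean_rcf / sqrt(k + k * (k - 1) * mean_rff)
}

#' Correlation-based feature subset selection (CFS)
#'
#' Forward best-first search maximizing
#' `merit = k * mean(r_cf) / sqrt(k + k(k-1) * mean(r_ff))`, with both
#' feature-class and feature-feature correlations measured by symmetrical
#' uncertainty on MDL-discretized features. Search stops after
#' `max_stale` consecutive expansions without improvement.
#'
#' @param x feature matrix (>= 2 features).
#' @param y class labels.
#' @param max_stale best-first patience (default 5).
#' @return list with `features` (selected names, rank order of addition)
#'   and `merit`.
#' @export
cfs_select <- function(x, y, max_stale = 5) {
  stopifnot(ncol(x) >= 2L)
  y <- as.factor(y)
  p <- ncol(x)
  disc <- lapply(seq_len(p), function(j) discretize_feature(x[, j], y))
  rcf <- vapply(disc, function(b) symmetrical_uncertainty(b, y), numeric(1))
  rff_cache <- new.env(parent = emptyenv())
  rff_fun <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    v <- rff_cache[[key]]
    if (is.null(v)) {
      v <- symmetrical_uncertainty(disc[[i]], disc[[j]])
      rff_cache[[key]] <- v
    }
    v
  }
  best_set <- integer(0)
  best_merit <- 0
  frontier <- list(integer(0))
  stale <- 0L
  while (length(frontier) > 0L && stale < max_stale) {
    cur <- frontier[[1L]]
    frontier <- frontier[-1L]
    improved <- FALSE
    cand_sets <- lapply(setdiff(seq_len(p), cur), function(j) sort(c(cur, j)))
    merits <- vapply(cand_sets, cfs_merit, numeric(1), rcf = rcf,
                     rff_fun = rff_fun)
    if (length(merits) == 0L) break
    o <- order(-merits)
    top <- cand_sets[[o[1L]]]
    if (merits[o[1L]] > best_merit + 1e-12) {
      best_merit <- merits[o[1L]]
      best_set <- top
      improved <- TRUE
    }
    frontier <- c(list(top), frontier)
    stale <- if (improved) 0L else stale + 1L
  }
  list(features = colnames(x)[best_set], merit = best_merit)
}

#' Keep the top fraction of a ranked feature list
#'
#' The kept count is `round_half_up(fraction * total_feature_count)` — the
#' rounding rule that reproduces 5% of 468 = 23, 40% of 114 = 46 and 30% of
#' 84 = 25 simultaneously (floor and ceiling each fail one of them).
#'
#' @param ranked data.table(feature, score) sorted decreasing (a ranking
#'   from [info_gain_ranking()] or [relieff()]).
#' @param total_feature_count size of the full feature roster the fraction
#'   refers to.
#' @param fraction in (0, 1].
#' @return character vector of feature names.
#' @export
select_top_fraction <- function(ranked, total_feature_count, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  k <- round_half_up(fraction * total_feature_count)
  if (k < 1L) stop("top-fraction selection yields zero features")
  utils::head(ranked$feature, k)
}
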