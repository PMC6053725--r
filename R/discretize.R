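# Supervised discretization of continuous features by recursive binary
# entropy splits with the MDL acceptance criterion (Fayyad-Irani style).
# Used by the information-gain and correlation-based feature selectors.

# Entropy (bits) of each row of a class-count matrix.
row_entropy <- function(counts) {
  tot <- rowSums(counts)
  p <- counts / ifelse(tot == 0, 1, tot)
  lp <- ifelse(p > 0, log2(p), 0)
  -rowSums(p * lp)
}

# Best binary split of (sorted) class codes by MDL; returns the cut index or
# 0L when no split is accepted. `x` sorted ascending, `y` integer codes.
mdl_best_cut <- function(x, y, n_classes) {
  n <- length(x)
  if (n < 4L) return(0L)
  ind <- matrix(0L, n, n_classes)
  ind[cbind(seq_len(n), y)] <- 1L
  cum <- apply(ind, 2L, cumsum)
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = n)
  cand <- which(x[-n] < x[-1L])        # cut between i and i+1
  if (length(cand) == 0L) return(0L)
  left <- cum[cand, , drop = FALSE]
  total <- cum[n, ]
  right <- matrix(total, length(cand), n_classes, byrow = TRUE) - left
  nl <- rowSums(left)
  nr <- n - nl
  ent_l <- row_entropy(left)
  ent_r <- row_entropy(right)
  ent_s <- entropy_bits(total)
  cond <- (nl * ent_l + nr * ent_r) / n
  gain <- ent_s - cond
  best <- which.max(gain)
  # MDL acceptance
  k  <- sum(total > 0)
  k1 <- sum(left[best, ] > 0)
  k2 <- sum(right[best, ] > 0)
  delta <- log2(3^k - 2) -
    (k * ent_s - k1 * ent_l[best] - k2 * ent_r[best])
  if (gain[best] <= (log2(n - 1) + delta) / n) return(0L)
  cand[best]
}

#' MDL-supervised cut points for one continuous feature
#'
#' Recursive binary splitting on class-entropy gain, each split accepted
#' only when it passes the minimum-description-length criterion; features
#' with no acceptable split get no cuts (one bin, zero information gain).
#'
#' @param x numeric feature.
#' @param y class labels (factor or character).
#' @return numeric vector of cut points (possibly empty), ascending.
#' @export
mdl_cut_points <- function(x, y) {
  y <- as.integer(as.factor(y))
  ok <- !is.na(x)
  x <- x[ok]; y <- y[ok]
  o <- order(x)
  x <- x[o]; y <- y[o]
  n_classes <- max(y)
  cuts <- numeric(0)
  recurse <- function(lo, hi) {
    i <- mdl_best_cut(x[lo:hi], y[lo:hi], n_classes)
    if (i == 0L) return()
    cut_at <- lo + i - 1L
    cuts[[length(cuts) + 1L]] <<- (x[cut_at] + x[cut_at + 1L]) / 2
    recurse(lo, cut_at)
    recurse(cut_at + 1L, hi)
  }
  if (length(x) > 0L) recurse(1L, length(x))
  sort(cuts)
}

#' Discretize a feature for entropy-based scoring
#'
#' Features with at most `max_levels` distinct values are used as-is
#' (categorical); otherwise MDL cut points define the bins, with an
#' equal-frequency 10-bin fallback when requested for degenerate cases.
#'
#' @param x numeric feature.
#' @param y class labels (used by the supervised binning).
#' @param max_levels distinct-value threshold below which `x` is treated as
#'   already discrete (default 10).
#' @param fallback_bins when MDL accepts no cut and `fallback = TRUE`, use
#'   this many equal-frequency bins instead of a single bin.
#' @param fallback logical (default FALSE: no cut means one bin).
#' @return integer vector of bin codes (>= 1).
#' @export
discretize_feature <- function(x, y, max_levels = 10, fallback = FALSE,
                               fallback_bins = 10) {
  ux <- unique(x[!is.na(x)])
  if (length(ux) <= max_levels)
    return(match(x, sort(ux)))   # not factor(): distinct doubles can print
                                 # as the same character level
  cuts <- mdl_cut_points(x, y)
  if (length(cuts) == 0L && fallback) {
    qs <- unique(stats::quantile(x, probs = seq_len(fallback_bins - 1) /
                                   fallback_bins, na.rm = TRUE,
                                 names = FALSE))
    cuts <- qs
  }
  if (length(cuts) == 0L) return(rep(1L, length(x)))
  findInterval(x, cuts) + 1L
}
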