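# Probability-emitting classifiers for the up/down DEG task: ridge logistic
# regression (the headline model), least-squares classification via
# regression, a small logistic model tree, and bagged-tree / random-subspace
# ensembles over a package-internal CART learner.

CLASSIFIER_NAMES <- c("logistic", "classification_via_regression",
                      "random_forest", "lmt", "random_subspace")

# ---- ridge logistic (IRLS) -------------------------------------------------

fit_ridge_logistic <- function(x, y01, lambda = 1e-8, max_iter = 50,
                               tol = 1e-10) {
  x <- as.matrix(x)
  center <- colMeans(x)
  scale <- apply(x, 2L, stats::sd)
  scale[scale == 0] <- 1
  xs <- cbind(1, sweep(sweep(x, 2L, center), 2L, scale, "/"))
  p <- ncol(xs)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  for (it in seq_len(max_iter)) {
    eta <- drop(xs %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y01 - mu) / w
    xtw <- t(xs * w)
    beta_new <- tryCatch(
      solve(xtw %*% xs + pen, xtw %*% z),
      error = function(e) beta + NA)
    if (anyNA(beta_new)) break
    delta <- max(abs(beta_new - beta))
    beta <- drop(beta_new)
    if (delta < tol) break
  }
  list(beta = beta, center = center, scale = scale)
}

predict_ridge_logistic <- function(fit, x) {
  xs <- cbind(1, sweep(sweep(as.matrix(x), 2L, fit$center), 2L,
                       fit$scale, "/"))
  stats::plogis(drop(xs %*% fit$beta))
}

# ---- CART (Gini) -----------------------------------------------------------

# Grows a binary classification tree on a 0/1 target. Nodes are rows of a
# matrix: feature (0 = leaf), threshold, left, right, prob(positive).
fit_cart <- function(x, y01, min_node = 5L, max_depth = 12L, mtry = ncol(x)) {
  nodes <- list()
  new_node <- function() {
    nodes[[length(nodes) + 1L]] <<- c(feature = 0, threshold = 0,
                                      left = 0, right = 0, prob = 0)
    length(nodes)
  }
  set_node <- function(id, ...) {
    v <- nodes[[id]]
    upd <- c(...)
    v[names(upd)] <- upd
    nodes[[id]] <<- v
  }
  best_split <- function(idx) {
    yb <- y01[idx]
    n <- length(yb)
    pos <- sum(yb)
    if (pos == 0L || pos == n) return(NULL)
    parent_gini <- 2 * (pos / n) * (1 - pos / n)
    feats <- if (mtry >= ncol(x)) seq_len(ncol(x))
             else sample.int(ncol(x), mtry)
    best <- NULL
    best_gain <- 1e-12
    for (f in feats) {
      xv <- x[idx, f]
      o <- order(xv)
      xo <- xv[o]
      yo <- yb[o]
      cand <- which(xo[-n] < xo[-1L])
      cand <- cand[cand >= min_node & (n - cand) >= min_node]
      if (length(cand) == 0L) next
      cpos <- cumsum(yo)
      nl <- cand
      pl <- cpos[cand]
      nr <- n - nl
      pr <- pos - pl
      gini <- (nl / n) * 2 * (pl / nl) * (1 - pl / nl) +
        (nr / n) * 2 * (pr / nr) * (1 - pr / nr)
      gain <- parent_gini - gini
      j <- which.max(gain)
      if (gain[j] > best_gain) {
        best_gain <- gain[j]
        best <- list(feature = f,
                     threshold = unname(xo[cand[j]] + xo[cand[j] + 1L]) / 2)
      }
    }
    best
  }
  grow <- function(idx, depth) {
    id <- new_node()
    prob <- mean(y01[idx])
    set_node(id, prob = prob)
    if (depth < max_depth && length(idx) >= 2L * min_node) {
      sp <- best_split(idx)
      if (!is.null(sp)) {
        go_left <- x[idx, sp$feature] <= sp$threshold
        lid <- grow(idx[go_left], depth + 1L)
        rid <- grow(idx[!go_left], depth + 1L)
        set_node(id, feature = sp$feature, threshold = sp$threshold,
                 left = lid, right = rid)
      }
    }
    id
  }
  grow(seq_along(y01), 0L)
  do.call(rbind, nodes)
}

predict_cart <- function(tree, x) {
  x <- as.matrix(x)
  vapply(seq_len(nrow(x)), function(i) {
    id <- 1L
    repeat {
      nd <- tree[id, ]
      if (nd["feature"] == 0) return(nd[["prob"]])
      id <- if (x[i, nd["feature"]] <= nd["threshold"]) nd[["left"]]
            else nd[["right"]]
    }
  }, numeric(1))
}

# Leaf ids a CART routes each row to (for the logistic-model-tree leaves).
cart_leaf_of <- function(tree, x) {
  x <- as.matrix(x)
  as.integer(vapply(seq_len(nrow(x)), function(i) {
    id <- 1
    repeat {
      nd <- tree[id, ]
      if (nd["feature"] == 0) return(id)
      id <- if (x[i, nd["feature"]] <= nd["threshold"]) nd[["left"]]
            else nd[["right"]]
    }
  }, numeric(1)))
}

# ---- user-facing training --------------------------------------------------

#' Train a probability-emitting classifier
#'
#' Registered learners:
#' \describe{
#'   \item{logistic}{ridge-penalized logistic regression (IRLS, penalty
#'     `1e-8` for conditioning only).}
#'   \item{classification_via_regression}{least-squares regression on the
#'     0/1 class indicator; predictions clipped to `[0, 1]`.}
#'   \item{random_forest}{bagging of `n_trees` CART trees, each split drawn
#'     from `mtry = floor(sqrt(p))` random features; probabilities averaged.}
#'   \item{lmt}{logistic model tree: a depth-&le;2 CART whose leaves carry
#'     ridge-logistic models (leaves with fewer than 30 rows or one class
#'     fall back to the leaf rate / parent model).}
#'   \item{random_subspace}{10 CART trees, each trained on a random half of
#'     the features; probabilities averaged.}
#' }
#'
#' @param name one of `r paste(CLASSIFIER_NAMES, collapse = ", ")`.
#' @param x numeric feature matrix (no missing values).
#' @param y labels with positive class `"up"` (anything else is the negative
#'   class).
#' @param seed RNG seed for the stochastic ensembles.
#' @param n_trees,subspace_learners ensemble sizes.
#' @return object of class `epideg_model`; see [predict.epideg_model()].
#' @export
train_classifier <- function(name, x, y, seed = NULL, n_trees = 100L,
                             subspace_learners = 10L) {
  if (!name %in% CLASSIFIER_NAMES)
    stop("unknown classifier: ", name, " (expected one of ",
         paste(CLASSIFIER_NAMES, collapse = ", "), ")")
  x <- as.matrix(x)
  if (anyNA(x)) stop("feature matrix has missing values; impute first")
  y01 <- as.integer(as.character(y) == "up")
  if (length(unique(y01)) < 2L) stop("training labels have a single class")

  fit <- with_seed(seed, switch(
    name,
    logistic = fit_ridge_logistic(x, y01),
    classification_via_regression = {
      xc <- cbind(1, x)
      qr_fit <- qr(xc)
      list(coef = qr.coef(qr_fit, y01))
    },
    random_forest = {
      mtry <- max(1L, floor(sqrt(ncol(x))))
      lapply(seq_len(n_trees), function(i) {
        idx <- sample.int(nrow(x), replace = TRUE)
        fit_cart(x[idx, , drop = FALSE], y01[idx], mtry = mtry)
      })
    },
    lmt = {
      tree <- fit_cart(x, y01, min_node = 30L, max_depth = 2L)
      leaves <- cart_leaf_of(tree, x)
      models <- lapply(sort(unique(leaves)), function(id) {
        idx <- which(leaves == id)
        if (length(idx) >= 30L && length(unique(y01[idx])) == 2L)
          fit_ridge_logistic(x[idx, , drop = FALSE], y01[idx])
        else NULL                       # leaf falls back to its rate
      })
      names(models) <- as.character(sort(unique(leaves)))
      list(tree = tree, models = models)
    },
    random_subspace = {
      psub <- max(1L, floor(ncol(x) / 2))
      lapply(seq_len(subspace_learners), function(i) {
        fs <- sort(sample.int(ncol(x), psub))
        list(features = fs,
             tree = fit_cart(x[, fs, drop = FALSE], y01, mtry = psub))
      })
    }
  ))
  structure(list(name = name, fit = fit, features = colnames(x)),
            class = "epideg_model")
}

#' Predict class probabilities from a fitted model
#'
#' @param object an `epideg_model` from [train_classifier()].
#' @param newdata feature matrix with the training columns.
#' @param ... unused.
#' @return numeric vector of P(class = "up").
#' @export
predict.epideg_model <- function(object, newdata, ...) {
  x <- as.matrix(newdata)[, object$features, drop = FALSE]
  switch(object$name,
    logistic = predict_ridge_logistic(object$fit, x),
    classification_via_regression =
      pmin(1, pmax(0, drop(cbind(1, x) %*% object$fit$coef))),
    random_forest =
      rowMeans(matrix(vapply(object$fit, predict_cart, numeric(nrow(x)),
                             x = x), nrow = nrow(x))),
    lmt = {
      leaves <- cart_leaf_of(object$fit$tree, x)
      out <- numeric(nrow(x))
      for (id in unique(leaves)) {
        idx <- which(leaves == id)
        m <- object$fit$models[[as.character(id)]]
        out[idx] <- if (is.null(m))
          object$fit$tree[id, "prob"]
        else predict_ridge_logistic(m, x[idx, , drop = FALSE])
      }
      out
    },
    random_subspace =
      rowMeans(matrix(vapply(object$fit, function(l)
        predict_cart(l$tree, x[, l$features, drop = FALSE]),
        numeric(nrow(x))), nrow = nrow(x)))
  )
}
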