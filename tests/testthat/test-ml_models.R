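sep_data <- function(n = 80, seed = 1) {
  set.seed(seed)
  y <- rep(c("up", "down"), each = n / 2)
  x <- cbind(s1 = ifelse(y == "up", 2, -2) + rnorm(n, 0, 0.2),
             s2 = rnorm(n))
  list(x = x, y = y)
}

test_that("logistic regression fits a separable problem perfectly", {
  d <- sep_data()
  m <- train_classifier("logistic", d$x, d$y)
  p <- predict(m, d$x)
  expect_equal(ifelse(p >= 0.5, "up", "down"), d$y)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("every registered classifier emits sane, seeded probabilities", {
  d <- simulate_labeled_features(200, 8, 4, effect_size = 3, seed = 9)
  for (name in c("logistic", "classification_via_regression",
                 "random_forest", "lmt", "random_subspace")) {
    m <- train_classifier(name, d$x, d$y, seed = 7, n_trees = 25)
    p <- predict(m, d$x)
    expect_true(all(p >= 0 & p <= 1), label = name)
    expect_gt(roc_auc(p, d$y)$auc, 0.8, label = paste(name, "training AUC"))
    m2 <- train_classifier(name, d$x, d$y, seed = 7, n_trees = 25)
    expect_identical(p, predict(m2, d$x),
                     label = paste(name, "seed determinism"))
  }
  expect_error(train_classifier("svm", d$x, d$y), "unknown classifier")
  expect_error(train_classifier("logistic", d$x, rep("up", 200)),
               "single class")
  xna <- d$x; xna[1, 1] <- NA
  expect_error(train_classifier("logistic", xna, d$y), "missing")
})

test_that("stratified_split hits exact totals with largest remainder", {
  ids <- sprintf("g%04d", 1:2674)
  labels <- rep(c("up", "down"), c(1600, 1074))
  sp <- stratified_split(ids, labels, 0.8, seed = 3)
  expect_length(sp$train, 2139)
  expect_length(sp$test, 535)
  expect_equal(sum(labels[match(sp$train, ids)] == "up"), 1280)
  expect_equal(sum(labels[match(sp$train, ids)] == "down"), 859)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)
  sp2 <- stratified_split(ids, labels, 0.8, seed = 3)
  expect_identical(sp, sp2)
  sp3 <- stratified_split(ids, labels, 0.8, seed = 4)
  expect_false(identical(sp$train, sp3$train))
  # N = 10 at 0.8 -> 8 / 2
  small <- stratified_split(paste0("g", 1:10), rep(c("up", "down"), 5), 0.8,
                            seed = 1)
  expect_length(small$train, 8)
  expect_warning(
    stratified_split(paste0("g", 1:5), c("up", "up", "up", "up", "down"),
                     0.8, seed = 1),
    "< 2 members")
})

test_that("compute_metrics reproduces the closed-form confusion table", {
  m <- compute_metrics(tp = 40, fp = 10, fn = 20, tn = 30)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 40 / 60)
  expect_equal(m$f_measure, 2 * 0.8 * (2 / 3) / (0.8 + 2 / 3))   # ~0.7273
  expect_equal(m$mcc, 1000 / sqrt(50 * 60 * 40 * 50))            # ~0.4082
  perfect <- compute_metrics(50, 0, 0, 50)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$mcc, 1)
  degenerate <- compute_metrics(0, 0, 10, 10)
  expect_equal(degenerate$precision, 0)
  expect_true("precision" %in% degenerate$undefined)
})

test_that("roc_auc equals the exhaustive pair-count oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1),
                       c("up", "up", "down", "down"))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c("up", "down"), 5))$auc, 0.5)
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.1),
                       c("up", "up", "down", "down"))$auc, 0.75)
  expect_error(roc_auc(runif(5), rep("up", 5)), "both classes")
  set.seed(77)
  for (rep in 1:25) {
    n <- sample(10:200, 1)
    y <- sample(c("up", "down"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    p <- round(runif(n), 2)   # rounding forces ties
    expect_equal(roc_auc(p, y)$auc, oracle_auc(p, y), tolerance = 1e-12)
  }
})

test_that("roc points trace the empirical curve", {
  r <- roc_auc(c(0.9, 0.8, 0.7, 0.6), c("up", "down", "up", "down"))$roc
  expect_equal(r$fpr, c(0, 0, 0.5, 0.5, 1))
  expect_equal(r$tpr, c(0, 0.5, 0.5, 1, 1))
})

test_that("cross_validate is deterministic and pools fold confusions", {
  d <- sep_data(n = 100, seed = 3)
  rownames(d$x) <- sprintf("g%03d", 1:100)
  cv <- cross_validate("logistic", d$x, d$y, folds = 5, seed = 11)
  expect_equal(cv$pooled$f_measure, 1)    # separable: perfect
  expect_equal(cv$pooled$mcc, 1)
  expect_equal(cv$auc, 1)
  expect_equal(nrow(cv$per_fold), 5)
  expect_equal(cv$pooled$tp + cv$pooled$fp + cv$pooled$fn + cv$pooled$tn,
               100)
  expect_equal(sum(cv$per_fold$tp), cv$pooled$tp)
  cv2 <- cross_validate("logistic", d$x, d$y, folds = 5, seed = 11)
  expect_identical(cv$probabilities, cv2$probabilities)
  expect_identical(cv$per_fold, cv2$per_fold)
})

test_that("cross_validate selects features inside folds only", {
  d <- simulate_labeled_features(150, 20, 3, effect_size = 3, seed = 5)
  cv <- cross_validate("logistic", d$x, d$y, folds = 5, seed = 5,
                       selector = "infogain", top_fraction = 0.15)
  expect_length(cv$selected, 5)
  for (feats in cv$selected) {
    expect_length(feats, 3)               # round_half_up(0.15 * 20)
    expect_true(all(grepl("^signal", feats)))
  }
  expect_gt(cv$auc, 0.9)
})

test_that("folds whose training data has one class are skipped", {
  set.seed(8)
  x <- matrix(rnorm(40), 20, 2,
              dimnames = list(paste0("g", 1:20), c("a", "b")))
  y <- c(rep("up", 19), "down")
  expect_warning(cv <- cross_validate("logistic", x, y, folds = 4,
                                      seed = 2),
                 "single-class")
  expect_lt(nrow(cv$per_fold), 4)
})
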