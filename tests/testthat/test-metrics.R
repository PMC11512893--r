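test_that("worked confusion examples give the textbook percentages", {
  # build label vectors realizing TP=50, TN=40, FP=5, FN=5 one-vs-rest
  truth <- c(rep("cyst", 55), rep("normal", 45))
  pred <- c(rep("cyst", 50), rep("normal", 5), rep("cyst", 5), rep("normal", 40))
  m <- compute_metrics(confusion_counts(truth, pred))
  row <- m$per_class[m$per_class$class == "cyst", ]
  expect_equal(row$accuracy, 90)
  expect_equal(row$sensitivity, 100 * 50 / 55)   # 90.909...
  expect_equal(row$precision, 100 * 50 / 55)
  expect_equal(row$f1, row$precision)            # equal arguments
})

test_that("metrics match brute-force per-sample counting on random vectors", {
  set.seed(21)
  classes <- c("normal", "cyst", "tumor", "stone")
  for (rep in 1:100) {
    n <- sample(20:60, 1)
    truth <- sample(classes, n, replace = TRUE)
    pred <- sample(classes, n, replace = TRUE)
    m <- compute_metrics(confusion_counts(truth, pred, classes))
    for (cl in classes) {
      tp <- sum(truth == cl & pred == cl)
      fn <- sum(truth == cl & pred != cl)
      fp <- sum(truth != cl & pred == cl)
      tn <- n - tp - fn - fp
      row <- m$per_class[m$per_class$class == cl, ]
      expect_equal(row$accuracy, 100 * (tp + tn) / n, tolerance = 1e-12)
      expect_equal(row$sensitivity,
                   if (tp + fn == 0) 0 else 100 * tp / (tp + fn),
                   tolerance = 1e-12)
      expect_equal(row$precision,
                   if (tp + fp == 0) 0 else 100 * tp / (tp + fp),
                   tolerance = 1e-12)
      expect_equal(row$specificity,
                   if (tn + fp == 0) 0 else 100 * tn / (tn + fp),
                   tolerance = 1e-12)
      prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
      sens <- if (tp + fn == 0) 0 else tp / (tp + fn)
      f1 <- if (prec + sens == 0) 0 else 100 * 2 * prec * sens / (prec + sens)
      expect_equal(row$f1, f1, tolerance = 1e-12)
      # confusion-matrix identities
      expect_identical(tp + fn, sum(truth == cl))
      expect_identical(tp + fp, sum(pred == cl))
    }
  }
})

test_that("zero-denominator metrics are flagged zeros, not errors", {
  truth <- rep("normal", 10)
  pred <- rep("normal", 10)
  m <- compute_metrics(confusion_counts(truth, pred))
  expect_true(all(is.finite(as.matrix(m$per_class[, 2:6]))))
  expect_true(any(m$per_class$flagged))
})

test_that("ROC analysis handles separable, random, and degenerate scores", {
  # perfectly separable
  truth <- rep(c("normal", "cyst", "tumor", "stone"), each = 5)
  probs <- outer(truth, c("normal", "cyst", "tumor", "stone"),
                 function(t, c) ifelse(t == c, 0.7, 0.1))
  r <- roc_curves(truth, probs, c("normal", "cyst", "tumor", "stone"))
  expect_true(all(r$auc[1:4] == 1))
  expect_equal(unname(r$auc["micro"]), 1)

  # label-independent probabilities approach AUC 0.5
  set.seed(30)
  n <- 4000
  truth <- sample(c("normal", "cyst", "tumor", "stone"), n, replace = TRUE)
  raw <- matrix(rexp(4 * n), n)
  probs <- raw / rowSums(raw)
  colnames(probs) <- c("normal", "cyst", "tumor", "stone")
  r <- roc_curves(truth, probs)
  expect_true(all(abs(r$auc[1:4] - 0.5) < 0.05))

  # micro AUC equals a brute-force count over all pooled (pos, neg) pairs
  truth2 <- sample(c("a", "b"), 12, replace = TRUE)
  p <- runif(12)
  probs2 <- cbind(a = p, b = 1 - p)
  r2 <- roc_curves(truth2, probs2, c("a", "b"))
  onehot <- as.vector(outer(truth2, c("a", "b"), `==`) * 1)
  sc <- as.vector(probs2)
  pos <- sc[onehot == 1]; neg <- sc[onehot == 0]
  pairs <- outer(pos, neg, function(x, y) (x > y) + 0.5 * (x == y))
  expect_equal(unname(r2$auc["micro"]), mean(pairs), tolerance = 1e-12)

  # single-class truth: that class's AUC is missing
  r3 <- roc_curves(rep("a", 5), cbind(a = rep(0.6, 5), b = rep(0.4, 5)),
                   c("a", "b"))
  expect_true(is.na(r3$auc["a"]) || is.na(r3$auc["b"]))
})

test_that("our trapezoidal AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  truth <- rbinom(80, 1, 0.4)
  score <- runif(80) + 0.6 * truth
  ours <- spinalzfnet:::binary_roc(truth, score)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})
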