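test_that("a separable toy problem is fit perfectly and duplication changes nothing", {
  X <- rbind(matrix(5, 5, 99), matrix(10, 5, 99)) +
    matrix(rnorm(10 * 99, sd = 0.01), 10)
  y <- rep(c("case", "control"), each = 5)
  m <- train_linear_svm(X, y)
  pr <- predict(m, X)
  expect_identical(as.character(pr$class), y)
  expect_true(all(pr$decision[1:5] > 0), info = "cases on the positive side")

  md <- train_linear_svm(rbind(X, X), c(y, y))
  expect_equal(predict(md, X)$decision, pr$decision, tolerance = 1e-6)

  expect_error(train_linear_svm(X, rep("case", 10)), class = "ccmorph_one_class")
})

test_that("an XOR configuration cannot be separated linearly", {
  X <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  y <- c("case", "case", "control", "control")
  # oracle: exhaustive check that no linear rule beats 3/4
  best <- 0
  for (a in seq(-1, 1, by = 0.25)) for (b in seq(-1, 1, by = 0.25))
    for (c0 in seq(-1.5, 1.5, by = 0.25)) {
      pred <- ifelse(X %*% c(a, b) + c0 > 0, "case", "control")
      best <- max(best, mean(pred == y), mean(pred != y))
    }
  expect_lte(best, 0.75)
  m <- train_linear_svm(X, y, C = 100)
  expect_lte(mean(as.character(predict(m, X)$class) == y), 0.75)
})

test_that("stratified folds are balanced, seed-reproducible, and shrink for small classes", {
  y <- rep(c("case", "control"), each = 13)
  f1 <- make_folds(y, 10, seed = 4)
  f2 <- make_folds(y, 10, seed = 4)
  expect_identical(as.integer(f1), as.integer(f2))
  expect_identical(attr(f1, "folds"), 10L)
  sizes <- table(as.integer(f1))
  expect_true(all(sizes %in% 2:3))
  per_class <- table(as.integer(f1), y)
  expect_true(all(abs(per_class[, 1] - per_class[, 2]) <= 1))
  expect_false(identical(as.integer(make_folds(y, 10, seed = 5)),
                         as.integer(f1)))

  expect_warning(f3 <- make_folds(rep(c("case", "control"), c(4, 22)), 10, seed = 1),
                 class = "ccmorph_folds_reduced")
  expect_identical(attr(f3, "folds"), 4L)
})

test_that("cross-validation predicts each subject exactly once, out of fold", {
  set.seed(8)
  X <- rbind(matrix(rnorm(13 * 99, 5, 0.2), 13), matrix(rnorm(13 * 99, 9, 0.2), 13))
  y <- rep(c("case", "control"), each = 13)
  cv <- cross_validate(X, y, folds = 10, seed = 2)
  expect_identical(cv$index, 1:26)
  expect_false(anyNA(cv$pred))
  expect_identical(mean(cv$pred == cv$truth), 1)     # hugely separable
  cv2 <- cross_validate(X, y, folds = 10, seed = 2)
  expect_identical(cv$decision, cv2$decision)
})

test_that("metrics reproduce the quoted formulas", {
  # perfect prediction
  m <- classification_metrics(rep(c("case", "control"), each = 5),
                              rep(c("case", "control"), each = 5))
  expect_equal(m$accuracy, 1)
  expect_true(all(m$per_class$precision == 1, m$per_class$recall == 1,
                  m$per_class$f_measure == 1))

  # tp=10, fp=1, fn=1 for the case class
  y_true <- c(rep("case", 11), rep("control", 10))
  y_pred <- c(rep("case", 10), "control", "case", rep("control", 9))
  m2 <- classification_metrics(y_true, y_pred)
  pc <- m2$per_class[m2$per_class$class == "case", ]
  expect_equal(pc$precision, 10 / 11)
  expect_equal(pc$recall, 10 / 11)
  expect_equal(pc$f_measure, 2 * (10 / 11)^2 / (2 * 10 / 11))
  expect_equal(m2$sensitivity, 10 / 11)

  # everything predicted one class
  y3 <- rep(c("case", "control"), each = 13)
  expect_warning(m3 <- classification_metrics(y3, rep("case", 26)),
                 class = "ccmorph_precision_undefined")
  expect_equal(m3$accuracy, 0.5)
  expect_equal(m3$specificity, 0)
  expect_equal(m3$error_rate, 1 - m3$accuracy)
})

test_that("ROC/AUC match the brute-force pair-counting oracle", {
  r <- roc_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1), positive = 1)
  expect_equal(r$auc, 0.75)
  expect_equal(r$auc, auc_pair_count(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1), 1))

  r2 <- roc_auc(c(1, 1, 1, 0, 0), rep(1, 5), positive = 1)  # all tied
  expect_equal(r2$auc, 0.5)

  set.seed(33)
  for (i in 1:25) {
    n <- sample(6:40, 1)
    y <- sample(c("case", "control"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n), sample(0:2, 1))     # induce ties
    r3 <- roc_auc(y, s, positive = "case")
    expect_equal(r3$auc, auc_pair_count(y, s, "case"), tolerance = 1e-12)
    # invariance under strictly increasing transforms
    expect_equal(roc_auc(y, exp(s), positive = "case")$auc, r3$auc,
                 tolerance = 1e-12)
    # curve is monotone from (0,0) to (1,1)
    expect_true(all(diff(r3$points$fpr) >= 0))
    expect_true(all(diff(r3$points$tpr) >= 0))
  }
  expect_error(roc_auc(rep("case", 4), rnorm(4), positive = "case"),
               class = "ccmorph_auc_undefined")
})

test_that("the cohort report is internally consistent", {
  co <- suppressWarnings(generate_cohort(generator_config(seed = 12)))
  rep <- classify_cohort(co, seed = 3)
  pc <- rep$per_class
  expect_equal(rep$sensitivity, pc$recall[pc$class == "case"])
  expect_equal(rep$specificity, pc$recall[pc$class == "control"])
  expect_equal(rep$accuracy, 1 - rep$error_rate)
  expect_equal(sum(rep$confusion), 26)
  expect_equal(rep$roc$case$auc,
               auc_pair_count(rep$cv$truth, rep$cv$decision, "case"))
  expect_equal(rep$roc$control$auc,
               auc_pair_count(rep$cv$truth, -rep$cv$decision, "control"))
  expect_identical(rep$seed, 3)
})
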