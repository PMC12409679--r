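test_that("knn prediction matches elementary cases", {
  x <- matrix(c(0, 0.1, 1, 1.1), ncol = 1)
  y <- c(0L, 0L, 1L, 1L)
  expect_identical(predict(knn_model(x, y, k = 3), 0.05), 0L)
  expect_identical(predict(knn_model(x, y, k = 1), 1.1), 1L)
  # query identical to a training point with K = 1 returns its label
  expect_identical(predict(knn_model(x, y, k = 1), 0.1), 0L)
  expect_error(knn_model(x, y, k = 5), "between 1 and")
  expect_error(predict(knn_model(x, y, k = 1), c(1, 2)), "dimension")
})

test_that("vote ties resolve by nearest tied class, then lowest ordinal", {
  # five equidistant neighbours, labels 0,0,1,1,2: classes 0 and 1 tie on
  # votes and on distance -> lowest ordinal wins
  ang <- 2 * pi * (0:4) / 5
  x <- cbind(cos(ang), sin(ang))
  y <- c(0L, 0L, 1L, 1L, 2L)
  expect_identical(predict(knn_model(x, y, k = 5), c(0, 0)), 0L)
  # tie on votes broken by the nearer tied class
  x2 <- matrix(c(0.1, 0.9, 2, 2.1), ncol = 1)
  y2 <- c(1L, 3L, 3L, 1L)
  expect_identical(predict(knn_model(x2, y2, k = 2), 0), 1L)
})

test_that("a vote over the whole training set returns its majority class", {
  x <- matrix(c(0, 1, 2, 10, 11), ncol = 1)
  y <- c(0L, 0L, 0L, 2L, 2L)
  m <- knn_model(x, y, k = 5)
  expect_identical(predict(m, 100), 0L)
  expect_identical(predict(m, -5), 0L)
})

test_that("knn agrees with exhaustive brute force on random datasets", {
  set.seed(202)
  for (i in 1:60) {
    n <- sample(5:30, 1)
    d <- sample(1:3, 1)
    x <- matrix(round(rnorm(n * d), 2), ncol = d)  # rounding induces ties
    y <- sample(0:4, n, replace = TRUE)
    k <- sample(seq(1, min(n, 13), by = 2), 1)
    m <- knn_model(x, y, k)
    for (j in 1:3) {
      q <- round(rnorm(d), 2)
      expect_identical(predict(m, q), knn_bf(x, y, k, q))
    }
  }
})

test_that("stratified 9:1 split draws exact per-class counts", {
  y <- rep(0:4, each = 40)
  sp <- stratified_split(y, seed = 7)
  expect_length(sp$train, 180)
  expect_length(sp$test, 20)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_true(all(table(y[sp$train]) == 36))
  expect_true(all(table(y[sp$test]) == 4))
  expect_identical(stratified_split(y, seed = 7), sp)
  expect_false(identical(stratified_split(y, seed = 8), sp))
  y2 <- c(rep(0:3, each = 40), rep(4L, 39))
  expect_error(stratified_split(y2, seed = 1), "grade 3 has only 39")
})

test_that("stratified folds partition the data evenly by class", {
  y <- rep(0:4, each = 40)
  fold_id <- stratified_kfold(y, folds = 10, seed = 3)
  expect_length(fold_id, 200)
  expect_true(all(table(fold_id) == 20))
  for (g in 0:4) expect_true(all(table(fold_id[y == g]) == 4))
  expect_identical(stratified_kfold(y, folds = 10, seed = 3), fold_id)
  expect_error(stratified_kfold(y, folds = 1), "at least 2 folds")
  expect_error(stratified_kfold(0:1, folds = 10), "more folds than samples")
})

test_that("cross-validation predicts each sample exactly once", {
  wide <- blob_wide(n_per_grade = 40, noise = 1.2, seed = 6)
  x <- as.matrix(wide[, c("rms_LB", "rms_SB", "rms_BR")])
  cv <- cross_validate(x, wide$grade, k = 5, folds = 10, seed = 2)
  expect_equal(sum(cv$confusion), 200)
  expect_true(all(rowSums(cv$confusion) == 40))
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracy))
  # equal fold sizes: pooled accuracy equals the mean of fold accuracies
  expect_equal(metrics(cv$confusion)$accuracy, cv$mean_accuracy)
})

test_that("well-separated classes cross-validate perfectly", {
  set.seed(8)
  grade <- rep(0:4, each = 20)
  x <- cbind(grade * 10 + rnorm(100, sd = 0.1), rnorm(100, sd = 0.1))
  cv <- cross_validate(x, grade, k = 5, folds = 10, seed = 1)
  expect_equal(cv$mean_accuracy, 1.0)
  expect_equal(unname(diag(cv$confusion)), rep(20, 5))
})

test_that("K selection scans the grid under one fold assignment", {
  wide <- blob_wide(n_per_grade = 20, noise = 1.0, seed = 9)
  x <- as.matrix(wide[, c("rms_LB", "iemg_LB", "ea_LB")])
  sel <- select_k(x, wide$grade, folds = 5, seed = 4)
  expect_true(sel$k %in% seq(1, 13, 2))
  expect_length(sel$accuracy, 7)
  expect_identical(select_k(x, wide$grade, folds = 5, seed = 4)$k, sel$k)
  expect_identical(select_k(x, wide$grade, grid = 5, folds = 5, seed = 4)$k, 5L)
  # ties go to the smallest K
  expect_identical(sel$accuracy[as.character(sel$k)],
                   max(sel$accuracy), ignore_attr = TRUE)
  expect_error(select_k(x, wide$grade, grid = integer(0)), "empty")
})

test_that("metrics recompute correctly from a confusion matrix", {
  cm <- confusion_matrix(c(0, 0, 1, 2, 2), c(0, 1, 1, 2, 0))
  rep_ <- metrics(cm)
  expect_equal(rep_$accuracy, 3 / 5)
  pc <- rep_$per_class
  expect_equal(pc$tp[1:3], c(1, 1, 1))
  expect_equal(pc$fn[1:3], c(1, 0, 1))
  expect_equal(pc$fp[1:3], c(1, 1, 0))
  expect_equal(pc$precision[2], 0.5)
  expect_equal(pc$recall[1], 0.5)
  # never-predicted class flagged rather than silently perfect
  expect_false(pc$precision_defined[4])
  expect_equal(pc$precision[4], 0)
  expect_error(metrics(matrix(0, 5, 5)), "empty")
  expect_error(metrics(matrix(-1, 2, 2)), "negative")
})

test_that("metrics agree with a brute-force recount of prediction pairs", {
  set.seed(10)
  true <- sample(0:4, 300, replace = TRUE)
  pred <- ifelse(runif(300) < 0.7, true, sample(0:4, 300, replace = TRUE))
  rep_ <- metrics(confusion_matrix(true, pred))
  for (g in 0:4) {
    expect_equal(rep_$per_class$tp[g + 1], sum(true == g & pred == g))
    expect_equal(rep_$per_class$fn[g + 1], sum(true == g & pred != g))
    expect_equal(rep_$per_class$fp[g + 1], sum(true != g & pred == g))
  }
  expect_equal(rep_$accuracy, mean(true == pred))
})

test_that("seven models are compared under an identical fold assignment", {
  wide <- blob_wide(n_per_grade = 20, noise = 0.8, seed = 12)
  cmp <- compare_models(wide, k = 5, folds = 5, seed = 3)
  expect_identical(nrow(cmp), 7L)
  expect_identical(sum(cmp$type == "single_channel"), 3L)
  expect_identical(sum(cmp$type == "single_feature"), 3L)
  cmp2 <- compare_models(wide, k = 5, folds = 5, seed = 3)
  expect_identical(attr(cmp, "fold_id"), attr(cmp2, "fold_id"))
  expect_equal(cmp$mean_accuracy, cmp2$mean_accuracy)
})

test_that("label shuffling drops every model to chance accuracy", {
  wide <- blob_wide(n_per_grade = 40, noise = 0.5, seed = 14)
  fused <- build_fused_dataset(wide, threshold = 0.7)
  model_x <- c(
    lapply(c("LB", "SB", "BR"), function(ch)
      as.matrix(wide[, paste(c("rms", "iemg", "ea"), ch, sep = "_")])),
    lapply(c("rms", "iemg", "ea"), function(ft)
      as.matrix(wide[, paste(ft, c("LB", "SB", "BR"), sep = "_")])),
    list(as.matrix(fused$data[, paste0("fused_", fused$retained)])))
  set.seed(15)
  y <- sample(wide$grade)
  fold_id <- stratified_kfold(y, folds = 10, seed = 5)
  acc <- vapply(model_x, function(x)
    cross_validate(x, y, k = 5, fold_id = fold_id)$mean_accuracy, numeric(1))
  se <- sqrt(0.2 * 0.8 / 200)
  expect_true(all(abs(acc - 0.2) < 3 * se + 1e-9))
})
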