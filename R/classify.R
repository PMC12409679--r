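#' k-nearest-neighbour model over labelled feature vectors
#'
#' Stores the training samples; prediction is a majority vote among the K
#' nearest training points by Euclidean distance.
#'
#' @param x numeric matrix of training feature vectors (rows = samples).
#' @param y integer MAS ordinals (0-4), one per row of `x`.
#' @param k number of neighbours (default 5, the cross-validated optimum of
#'   the grading study design).
#' @return An object of class `knn_model`.
#' @export
knn_model <- function(x, y, k = 5L) {
  x <- as.matrix(x)
  y <- as.integer(y)
  if (nrow(x) != length(y)) stop("x and y sizes disagree", call. = FALSE)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > nrow(x)) {
    stop("K must be between 1 and the number of training samples (",
         nrow(x), ")", call. = FALSE)
  }
  structure(list(x = x, y = y, k = k), class = "knn_model")
}

# Single-query vote with deterministic tie-breaks:
#  - neighbour distance ties at the K-boundary: stable (insertion) order;
#  - vote ties: class of the nearest neighbour belonging to a tied class;
#  - exact distance ties there: lowest MAS ordinal.
knn_vote <- function(x, y, k, q) {
  d <- sqrt(colSums((t(x) - q)^2))
  ord <- order(d)                     # stable for doubles
  nb <- ord[seq_len(k)]
  votes <- table(y[nb])
  cand <- as.integer(names(votes)[votes == max(votes)])
  if (length(cand) == 1L) return(cand)
  in_cand <- nb[y[nb] %in% cand]
  dmin <- min(d[in_cand])
  min(y[in_cand][d[in_cand] == dmin])
}

#' Predict MAS ordinals for query feature vectors
#'
#' @param object a [knn_model()].
#' @param newdata numeric matrix of query rows (or a single vector).
#' @param ... unused.
#' @return Integer vector of predicted ordinals.
#' @export
predict.knn_model <- function(object, newdata, ...) {
  q <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1L) else as.matrix(newdata)
  if (ncol(q) != ncol(object$x)) {
    stop("query dimension ", ncol(q), " does not match training dimension ",
         ncol(object$x), call. = FALSE)
  }
  vapply(seq_len(nrow(q)), function(i)
    knn_vote(object$x, object$y, object$k, q[i, ]), integer(1))
}

#' Stratified train/test split with exact per-class counts
#'
#' Mirrors the study's 9:1 protocol: from a balanced pool, draw
#' `train_per_class` training and `test_per_class` test samples per grade,
#' uniformly at random without replacement.
#'
#' @param y integer grade ordinals.
#' @param train_per_class,test_per_class per-grade counts (defaults 36 and 4).
#' @param seed RNG seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(y, train_per_class = 36L, test_per_class = 4L,
                             seed = 0L) {
  y <- as.integer(y)
  need <- train_per_class + test_per_class
  with_seed(seed, {
    train <- integer(0); test <- integer(0)
    for (g in sort(unique(y))) {
      idx <- which(y == g)
      if (length(idx) < need) {
        stop("grade ", decode_mas(g), " has only ", length(idx),
             " samples; need ", need, call. = FALSE)
      }
      pick <- sample(idx, need)
      train <- c(train, pick[seq_len(train_per_class)])
      test <- c(test, pick[train_per_class + seq_len(test_per_class)])
    }
    list(train = sort(train), test = sort(test))
  })
}

#' Stratified k-fold assignment
#'
#' Assigns each sample to one of `folds` folds so that every grade is spread
#' as evenly as possible across folds (exactly evenly for the balanced
#' 200-sample design: 4 per grade per fold).
#'
#' @param y integer grade ordinals.
#' @param folds number of folds (default 10).
#' @param seed RNG seed.
#' @return Integer vector of fold ids (1..folds), one per sample.
#' @export
stratified_kfold <- function(y, folds = 10L, seed = 0L) {
  y <- as.integer(y)
  folds <- as.integer(folds)
  if (folds < 2L) stop("need at least 2 folds for held-out evaluation", call. = FALSE)
  if (folds > length(y)) stop("more folds than samples", call. = FALSE)
  fold_id <- integer(length(y))
  with_seed(seed, {
    for (g in sort(unique(y))) {
      idx <- sample(which(y == g))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_id
}

#' Cross-validate a k-NN classifier
#'
#' Each fold is held out once, a model with the given K is trained on the
#' remaining folds, and the held-out samples are predicted - so every sample
#' is predicted exactly once. Fold confusion counts are summed into one
#' aggregated matrix; mean accuracy is the average of per-fold accuracies.
#'
#' @param x numeric feature matrix.
#' @param y integer grade ordinals.
#' @param k number of neighbours.
#' @param folds number of folds (default 10).
#' @param seed RNG seed for the fold assignment.
#' @param fold_id optional precomputed fold assignment (overrides
#'   `folds`/`seed`).
#' @return List with `confusion` (5 x 5 count matrix over MAS grades),
#'   `mean_accuracy`, `fold_accuracy`, `predictions` (per-sample data frame)
#'   and `fold_id`.
#' @export
cross_validate <- function(x, y, k = 5L, folds = 10L, seed = 0L,
                           fold_id = NULL) {
  x <- as.matrix(x); y <- as.integer(y)
  if (is.null(fold_id)) fold_id <- stratified_kfold(y, folds, seed)
  pred <- integer(length(y))
  acc <- numeric(length(unique(fold_id)))
  fids <- sort(unique(fold_id))
  for (i in seq_along(fids)) {
    f <- fids[i]
    te <- which(fold_id == f); tr <- which(fold_id != f)
    m <- knn_model(x[tr, , drop = FALSE], y[tr], k)
    pred[te] <- predict(m, x[te, , drop = FALSE])
    acc[i] <- mean(pred[te] == y[te])
  }
  list(confusion = confusion_matrix(y, pred),
       mean_accuracy = mean(acc), fold_accuracy = acc,
       predictions = data.frame(true = y, predicted = pred,
                                fold = fold_id),
       fold_id = fold_id)
}

#' Select K by cross-validated accuracy
#'
#' Evaluates every K on the grid (default odd 1..13) under one common fold
#' assignment and returns the K with the highest mean accuracy; ties go to
#' the smallest K.
#'
#' @inheritParams cross_validate
#' @param grid candidate K values.
#' @return List with `k` (selected), `accuracy` (named vector over the grid)
#'   and `fold_id`.
#' @export
select_k <- function(x, y, grid = seq(1L, 13L, by = 2L), folds = 10L,
                     seed = 0L, fold_id = NULL) {
  if (!length(grid)) stop("empty K grid", call. = FALSE)
  if (is.null(fold_id)) fold_id <- stratified_kfold(as.integer(y), folds, seed)
  acc <- vapply(grid, function(k)
    cross_validate(x, y, k = k, fold_id = fold_id)$mean_accuracy, numeric(1))
  names(acc) <- grid
  list(k = as.integer(grid[which.max(acc)]), accuracy = acc, fold_id = fold_id)
}

#' Confusion matrix over the five MAS grades
#'
#' @param true,predicted integer ordinal vectors.
#' @return 5 x 5 count matrix, rows = true grade, columns = predicted grade,
#'   dimnames in MAS labels.
#' @export
confusion_matrix <- function(true, predicted) {
  lv <- 0:4
  m <- table(factor(true, levels = lv), factor(predicted, levels = lv))
  m <- unclass(m)
  dimnames(m) <- list(true = mas_levels(), predicted = mas_levels())
  m
}

#' Per-class classification metrics from a confusion matrix
#'
#' For each grade c: TP = diagonal count, FN = rest of row c, FP = rest of
#' column c; precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = 2PR/(P+R); overall accuracy = trace/total. A class that is never
#' predicted (TP+FP = 0) gets precision 0 and is flagged as undefined rather
#' than silently reported.
#'
#' @param cm square nonnegative count matrix (true x predicted).
#' @return An `eval_report`: list with `per_class` data frame (`grade`, `tp`,
#'   `fn`, `fp`, `precision`, `recall`, `f1`, `precision_defined`) and
#'   `accuracy`.
#' @export
metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square", call. = FALSE)
  if (any(cm < 0)) stop("confusion matrix has negative counts", call. = FALSE)
  if (sum(cm) == 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  grade <- if (!is.null(rownames(cm))) rownames(cm) else as.character(seq_len(nrow(cm)) - 1L)
  rep_ <- metrics_from_counts(tp, fn, fp, grade = grade)
  rep_$accuracy <- sum(tp) / sum(cm)
  rep_
}

#' Per-class metrics directly from TP/FN/FP counts
#'
#' Same arithmetic as [metrics()], for use when only the per-class counts of
#' a published report are available (no full matrix).
#'
#' @param tp,fn,fp numeric vectors of per-class counts.
#' @param grade class labels (default MAS labels).
#' @return An `eval_report` (accuracy computed as sum(TP)/sum(TP+FN)).
#' @export
metrics_from_counts <- function(tp, fn, fp, grade = mas_levels()) {
  if (any(tp < 0 | fn < 0 | fp < 0)) stop("counts must be nonnegative", call. = FALSE)
  denom_p <- tp + fp
  precision <- ifelse(denom_p > 0, tp / denom_p, 0)
  precision_defined <- denom_p > 0
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  structure(list(
    per_class = data.frame(grade = grade, tp = as.numeric(tp),
                           fn = as.numeric(fn), fp = as.numeric(fp),
                           precision = precision, recall = recall, f1 = f1,
                           precision_defined = precision_defined,
                           row.names = NULL, stringsAsFactors = FALSE),
    accuracy = sum(tp) / sum(tp + fn)),
    class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 2L, ...) {
  pc <- x$per_class
  tab <- rbind(TP = pc$tp, FN = pc$fn, FP = pc$fp,
               Precision = round_half_up(pc$precision, digits),
               Recall = round_half_up(pc$recall, digits),
               `F1-Score` = round_half_up(pc$f1, digits))
  colnames(tab) <- paste("MAS", pc$grade)
  print(tab)
  cat(sprintf("Overall accuracy: %.1f%%\n", 100 * x$accuracy))
  invisible(x)
}

#' Compare fused, single-channel and single-feature models
#'
#' Evaluates seven k-NN models under one common stratified fold assignment:
#' three single-channel models (feature vector = that channel's RMS, iEMG,
#' EA), three single-feature models (vector = that feature across LB, SB,
#' BR), and the multichannel fused model (the fused RMS/iEMG/EA vector).
#'
#' @param wide normalized wide sample table (see [normalize_features()]).
#' @param k number of neighbours.
#' @param folds number of folds.
#' @param seed RNG seed for the fold assignment.
#' @param threshold correlation screening threshold for the fused model.
#' @param mode fusion mode, `"paper_global"` or `"fold_safe"`.
#' @return Data frame with `model`, `type`, `mean_accuracy`; the fold
#'   assignment is attached as attribute `fold_id`.
#' @export
compare_models <- function(wide, k = 5L, folds = 10L, seed = 0L,
                           threshold = 0.7, mode = "paper_global") {
  y <- wide$grade
  fold_id <- stratified_kfold(y, folds, seed)
  run <- function(x) cross_validate(x, y, k = k, fold_id = fold_id)$mean_accuracy
  res <- list()
  for (ch in emg_channels()) {
    res[[paste0("channel_", ch)]] <- c(
      type = "single_channel",
      acc = run(as.matrix(wide[, paste(c("rms", "iemg", "ea"), ch, sep = "_")])))
  }
  for (ft in c("rms", "iemg", "ea")) {
    res[[paste0("feature_", ft)]] <- c(
      type = "single_feature",
      acc = run(as.matrix(wide[, paste(ft, emg_channels(), sep = "_")])))
  }
  fused <- build_fused_dataset(wide, mode = mode, threshold = threshold,
                               fold_id = fold_id)
  res$fused <- c(
    type = "fused",
    acc = run(as.matrix(fused$data[, paste0("fused_", fused$retained)])))
  out <- data.frame(model = names(res),
                    type = vapply(res, `[[`, "", "type"),
                    mean_accuracy = as.numeric(vapply(res, `[[`, "", "acc")),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "fold_id") <- fold_id
  out
}
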