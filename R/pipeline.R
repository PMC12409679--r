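#' Select a balanced subset of samples per grade
#'
#' Mirrors the study's balancing step: from the pool of (recording, segment)
#' samples, draw `per_grade` samples of each MAS grade uniformly at random
#' without replacement.
#'
#' @param wide wide sample table (raw or normalized).
#' @param per_grade samples to keep per grade (default 40, giving 200 from
#'   the 240-segment design).
#' @param seed RNG seed.
#' @return The subset of `wide`, row order preserved.
#' @export
select_balanced <- function(wide, per_grade = 40L, seed = 0L) {
  keep <- with_seed(seed, {
    idx <- integer(0)
    for (g in sort(unique(wide$grade))) {
      pool <- which(wide$grade == g)
      if (length(pool) < per_grade) {
        stop("grade ", decode_mas(g), " has only ", length(pool),
             " samples; need ", per_grade, call. = FALSE)
      }
      idx <- c(idx, sample(pool, per_grade))
    }
    sort(idx)
  })
  wide[keep, , drop = FALSE]
}

#' Run the full grading analysis on an extracted feature table
#'
#' From the long per-segment feature table: balance the sample set across
#' grades, max-min normalize each feature/channel column, screen features by
#' Spearman correlation with the MAS grade, fuse the retained features across
#' channels with correlation-derived weights, select K by stratified 10-fold
#' cross-validation, evaluate the fused k-NN model, and compare it with the
#' single-channel and single-feature baselines under the same folds.
#'
#' @param features long feature table (see [extract_features()]).
#' @param per_grade balanced samples per grade (default 40).
#' @param threshold correlation screening threshold.
#' @param mode fusion mode, `"paper_global"` or `"fold_safe"`.
#' @param k_grid candidate K values for selection (default odd 1..13); set to
#'   a single value to skip selection.
#' @param folds cross-validation folds.
#' @param seed RNG seed driving sample selection and fold assignment.
#' @return A `grading_run`: list with `correlations`, `retained`, `weights`,
#'   `selected_k`, `k_accuracy`, `cv` (fused-model cross-validation result),
#'   `report` (an `eval_report`), `comparison` (model-comparison table),
#'   `fused`, `normalization`, `config` (run parameters).
#' @export
run_pipeline <- function(features, per_grade = 40L, threshold = 0.7,
                         mode = c("paper_global", "fold_safe"),
                         k_grid = seq(1L, 13L, by = 2L), folds = 10L,
                         seed = 0L) {
  mode <- match.arg(mode)
  wide <- features_wide(features)
  wide <- select_balanced(wide, per_grade = per_grade, seed = seed)
  norm <- normalize_features(wide)
  wide <- norm$data
  fold_id <- stratified_kfold(wide$grade, folds, seed)
  fused <- build_fused_dataset(wide, mode = mode, threshold = threshold,
                               fold_id = fold_id)
  x <- as.matrix(fused$data[, paste0("fused_", fused$retained)])
  y <- fused$data$grade
  sel <- select_k(x, y, grid = k_grid, fold_id = fold_id)
  cv <- cross_validate(x, y, k = sel$k, fold_id = fold_id)
  comparison <- compare_models(wide, k = sel$k, folds = folds, seed = seed,
                               threshold = threshold, mode = mode)
  structure(list(correlations = fused$correlations,
                 retained = fused$retained, weights = fused$weights,
                 selected_k = sel$k, k_accuracy = sel$accuracy, cv = cv,
                 report = metrics(cv$confusion), comparison = comparison,
                 fused = fused$data, normalization = norm$params,
                 config = list(per_grade = per_grade, threshold = threshold,
                               mode = mode, folds = folds, seed = seed)),
            class = "grading_run")
}

#' @export
print.grading_run <- function(x, ...) {
  cat("Multichannel sEMG spasticity grading run\n")
  cat("  retained features:", paste(toupper(x$retained), collapse = ", "), "\n")
  cat("  selected K:", x$selected_k,
      sprintf("(mean CV accuracy %.1f%%)\n", 100 * x$cv$mean_accuracy))
  print(x$report)
  cat("\nModel comparison (mean CV accuracy):\n")
  cmp <- x$comparison
  for (i in seq_len(nrow(cmp))) {
    cat(sprintf("  %-14s %5.1f%%\n", cmp$model[i], 100 * cmp$mean_accuracy[i]))
  }
  invisible(x)
}

#' Write the run's report files
#'
#' Emits the correlation/weight table (per channel and feature), the
#' per-class classification report, the model-comparison table, and a JSON
#' summary with provenance (parameters and seed).
#'
#' @param run a `grading_run` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
write_run_reports <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "correlations.csv")
  corr <- as.data.frame(run$correlations)
  corr <- cbind(channel = rownames(corr), corr, row.names = NULL)
  for (ft in run$retained) {
    corr[[paste0("weight_", ft)]] <- run$weights[, ft]
  }
  utils::write.csv(corr, p1, row.names = FALSE)

  p2 <- file.path(dir, "classification_report.csv")
  pc <- run$report$per_class
  tab <- data.frame(item = c("TP", "FN", "FP", "Precision", "Recall", "F1-Score"))
  for (i in seq_len(nrow(pc))) {
    tab[[paste0("MAS_", pc$grade[i])]] <- c(
      pc$tp[i], pc$fn[i], pc$fp[i],
      round_half_up(c(pc$precision[i], pc$recall[i], pc$f1[i]), 2L))
  }
  utils::write.csv(tab, p2, row.names = FALSE)

  p3 <- file.path(dir, "model_comparison.csv")
  utils::write.csv(run$comparison, p3, row.names = FALSE)

  p4 <- file.path(dir, "run_summary.json")
  jsonlite::write_json(list(
    parameters = run$config, selected_k = run$selected_k,
    k_accuracy = as.list(run$k_accuracy),
    retained = run$retained,
    mean_cv_accuracy = run$cv$mean_accuracy,
    overall_accuracy = run$report$accuracy,
    comparison = run$comparison), p4, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(c(p1, p2, p3, p4))
}

#' Read a confusion matrix from CSV
#'
#' Expects a square count matrix, optionally with a leading label column.
#'
#' @param path CSV path.
#' @return Numeric count matrix.
#' @export
read_confusion_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!is.numeric(df[[1L]])) {
    rn <- df[[1L]]
    df <- df[, -1L, drop = FALSE]
    rownames(df) <- rn
  }
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("confusion matrix file has non-numeric entries", call. = FALSE)
  if (nrow(m) != ncol(m)) stop("confusion matrix must be square", call. = FALSE)
  if (any(m < 0)) stop("confusion matrix has negative counts", call. = FALSE)
  m
}
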