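#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (tie-corrected), the coefficient used to
#' relate each normalized sEMG feature to the MAS ordinal.
#'
#' @param a,b numeric vectors of equal length >= 3; ties allowed.
#' @return Correlation coefficient in [-1, 1].
#' @export
spearman <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length", call. = FALSE)
  if (length(a) < 3L) stop("need at least 3 observations", call. = FALSE)
  ra <- rank(a); rb <- rank(b)
  if (stats::var(ra) == 0 || stats::var(rb) == 0) {
    stop("undefined correlation: zero rank variance", call. = FALSE)
  }
  stats::cor(ra, rb)
}

#' Correlate every feature/channel column with the MAS grade
#'
#' @param wide normalized wide sample table (see [normalize_features()]).
#' @return 3 x 5 matrix of Spearman coefficients, rows `LB`, `SB`, `BR`,
#'   columns `rms`, `iemg`, `ea`, `mpf`, `mf` (the layout of the study's
#'   correlation table).
#' @export
correlation_table <- function(wide) {
  feats <- c("rms", "iemg", "ea", "mpf", "mf")
  out <- matrix(NA_real_, 3L, 5L, dimnames = list(emg_channels(), feats))
  g <- wide$grade
  for (ch in emg_channels()) {
    for (ft in feats) {
      out[ch, ft] <- spearman(wide[[paste(ft, ch, sep = "_")]], g)
    }
  }
  out
}

#' Screen features by correlation magnitude
#'
#' A feature is retained only if its correlation with the MAS grade reaches
#' the threshold in magnitude on all three channels. With the study's
#' coefficients this keeps the time-domain features (RMS, iEMG, EA) and drops
#' the frequency-domain ones (MPF, MF).
#'
#' @param corr 3 x 5 correlation matrix from [correlation_table()].
#' @param threshold magnitude threshold (default 0.7).
#' @return Character vector of retained feature names.
#' @export
screen_features <- function(corr, threshold = 0.7) {
  keep <- apply(abs(corr) >= threshold, 2L, all)
  colnames(corr)[keep]
}

#' Correlation-derived channel weights
#'
#' For one feature with per-channel correlations `r = (r1, r2, r3)` against
#' the MAS grade, the channel weights are `w_i = r_i / (r1 + r2 + r3)`, which
#' sum to one. Mixed-sign correlation triples are rejected: the resulting
#' weights would fall outside [0, 1] and the fused value would no longer be a
#' convex combination of the channel values.
#'
#' @param r numeric vector of 3 correlation coefficients.
#' @return Numeric vector of 3 weights summing to 1.
#' @export
compute_weights <- function(r) {
  if (length(r) != 3L || anyNA(r)) stop("need 3 correlation coefficients", call. = FALSE)
  if (any(r > 0) && any(r < 0)) {
    stop("mixed-sign correlations: channel weights undefined", call. = FALSE)
  }
  s <- sum(r)
  if (abs(s) < 1e-12) stop("degenerate weights: correlations sum to zero", call. = FALSE)
  r / s
}

#' Fuse per-channel feature values with channel weights
#'
#' `e = w1*e1 + w2*e2 + w3*e3`: a convex combination of the three channels'
#' (normalized) values of one feature.
#'
#' @param e numeric vector of 3 channel values.
#' @param w numeric vector of 3 weights summing to 1.
#' @return Fused scalar.
#' @export
fuse <- function(e, w) {
  if (length(e) != 3L || length(w) != 3L) stop("need 3 values and 3 weights", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-9) stop("weights must sum to 1", call. = FALSE)
  sum(w * e)
}

fuse_columns <- function(wide, feature, w) {
  cols <- paste(feature, emg_channels(), sep = "_")
  as.numeric(as.matrix(wide[, cols]) %*% w)
}

#' Build the fused per-sample dataset
#'
#' Screens features against the MAS grade, derives channel weights from the
#' Spearman correlations, and collapses each retained feature's three channel
#' values into one fused value per sample.
#'
#' In `"paper_global"` mode, correlations and weights come from the full
#' sample population once. In `"fold_safe"` mode a fold assignment must be
#' supplied: each sample's fused values are computed with weights estimated
#' from the training folds only (its own fold excluded), so no label
#' information leaks from test to train during cross-validation. The
#' correlation screen itself is always global so the fused feature space is
#' identical across folds.
#'
#' @param wide normalized wide sample table.
#' @param mode `"paper_global"` (default) or `"fold_safe"`.
#' @param threshold screening threshold on the correlation magnitude.
#' @param fold_id integer fold assignment (required for `"fold_safe"`).
#' @return List with `data` (data frame: `sample_id`, one `fused_<feature>`
#'   column per retained feature, `grade`, `mas_label`), `correlations`,
#'   `weights` (3 x n_retained matrix), `retained`, `mode`.
#' @export
build_fused_dataset <- function(wide, mode = c("paper_global", "fold_safe"),
                                threshold = 0.7, fold_id = NULL) {
  mode <- match.arg(mode)
  corr <- correlation_table(wide)
  retained <- screen_features(corr, threshold)
  if (!length(retained)) stop("no feature passes the correlation screen", call. = FALSE)
  out <- data.frame(sample_id = wide$sample_id, stringsAsFactors = FALSE)
  weights <- matrix(NA_real_, 3L, length(retained),
                    dimnames = list(emg_channels(), retained))
  if (mode == "paper_global") {
    for (ft in retained) {
      weights[, ft] <- compute_weights(corr[, ft])
      out[[paste0("fused_", ft)]] <- fuse_columns(wide, ft, weights[, ft])
    }
  } else {
    if (is.null(fold_id) || length(fold_id) != nrow(wide)) {
      stop("fold_safe mode needs a fold assignment of length nrow(wide)",
           call. = FALSE)
    }
    for (ft in retained) out[[paste0("fused_", ft)]] <- NA_real_
    for (f in sort(unique(fold_id))) {
      train <- wide[fold_id != f, , drop = FALSE]
      ct <- correlation_table(train)
      for (ft in retained) {
        w <- compute_weights(ct[, ft])
        out[fold_id == f, paste0("fused_", ft)] <-
          fuse_columns(wide[fold_id == f, , drop = FALSE], ft, w)
      }
    }
    # report the global weights for reference
    for (ft in retained) weights[, ft] <- compute_weights(corr[, ft])
  }
  out$grade <- wide$grade
  out$mas_label <- wide$mas_label
  list(data = out, correlations = corr, weights = weights,
       retained = retained, mode = mode)
}

#' Round half away from zero
#'
#' Decimal rounding used for reported correlation/weight/metric tables
#' (base R's `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
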