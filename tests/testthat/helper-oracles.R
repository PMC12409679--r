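# Independent oracles and small fixtures used across test files.

# Steady-state amplitude of a tone in y: least-squares fit of sin/cos at f
# over the middle 40% of the signal (edge transients excluded).
tone_amplitude <- function(y, rate, f) {
  n <- length(y)
  idx <- round(n * 0.3):round(n * 0.7)
  t <- (idx - 1) / rate
  fit <- stats::lm(y[idx] ~ sin(2 * pi * f * t) + cos(2 * pi * f * t))
  sqrt(sum(stats::coef(fit)[2:3]^2))
}

make_tone <- function(f, rate = 1024, dur = 5, amp = 1) {
  amp * sin(2 * pi * f * (0:(rate * dur - 1)) / rate)
}

# Brute-force mid-ranks: count-based, independent of base rank().
midrank_bf <- function(v) {
  vapply(seq_along(v), function(i) {
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  }, numeric(1))
}

pearson_bf <- function(x, y) {
  xm <- x - sum(x) / length(x)
  ym <- y - sum(y) / length(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}

spearman_bf <- function(a, b) pearson_bf(midrank_bf(a), midrank_bf(b))

# Brute-force k-NN with the package's documented tie rules, coded
# independently via a sorted data frame.
knn_bf <- function(x, y, k, q) {
  d <- apply(x, 1, function(r) sqrt(sum((r - q)^2)))
  df <- data.frame(i = seq_along(d), d = d, y = y)
  df <- df[order(df$d, df$i), ]
  nb <- df[seq_len(k), ]
  cnt <- table(nb$y)
  cand <- as.integer(names(cnt)[cnt == max(cnt)])
  if (length(cand) == 1L) return(cand)
  sub <- nb[nb$y %in% cand, ]
  sub <- sub[sub$d == min(sub$d), ]
  min(sub$y)
}

# Short-protocol generator configuration for fast tests: same signal model,
# reduced durations and cohort size.
small_cfg <- function(...) {
  defaults <- list(n_patients_per_grade = 2L, trials_per_patient = 1L,
                   rest_duration = 2, cycle_duration = 3, cycles_per_loop = 2L,
                   loops = 2L, break_duration = 2, movement_duration = 1)
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

# The study's published per-feature Spearman coefficients (channels x
# features), used for the in-paper screening and weighting checks.
published_correlations <- function() {
  matrix(c(0.80, 0.71, 0.77, -0.41, -0.31,
           0.83, 0.79, 0.80, -0.65, -0.54,
           0.78, 0.73, 0.81, -0.49, -0.55),
         nrow = 3, byrow = TRUE,
         dimnames = list(c("LB", "SB", "BR"),
                         c("rms", "iemg", "ea", "mpf", "mf")))
}

# The study's published per-class confusion counts.
published_counts <- function() {
  list(tp = c(37, 33, 30, 25, 33),
       fn = c(3, 7, 10, 15, 7),
       fp = c(0, 6, 22, 11, 3))
}

# A synthetic wide sample table of Gaussian feature blobs: n_per_grade
# samples per grade, 15 feature columns each correlated with grade.
blob_wide <- function(n_per_grade = 40L, noise = 0.5, seed = 1L) {
  set.seed(seed)
  grade <- rep(0:4, each = n_per_grade)
  n <- length(grade)
  wide <- data.frame(sample_id = sprintf("s%03d", seq_len(n)),
                     subject_id = sprintf("s%03d", seq_len(n)),
                     trial_index = 1L, segment_id = "A",
                     stringsAsFactors = FALSE)
  for (feat in c("rms", "iemg", "ea", "mpf", "mf")) {
    for (ch in c("LB", "SB", "BR")) {
      wide[[paste(feat, ch, sep = "_")]] <- grade + rnorm(n, 0, noise)
    }
  }
  wide$mas_label <- decode_mas(grade)
  wide$grade <- grade
  wide
}
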