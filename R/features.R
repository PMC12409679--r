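#' Root-mean-square amplitude
#'
#' @param x numeric signal vector.
#' @return `sqrt(mean(x^2))`.
#' @export
emg_rms <- function(x) {
  if (length(x) < 1L) stop("rms undefined for an empty signal", call. = FALSE)
  sqrt(mean(x^2))
}

#' Integrated EMG
#'
#' Cumulative absolute amplitude over a segment, `sum(|x|)`. The sample-count
#' scale (no 1/rate factor) is immaterial downstream because features are
#' max-min normalized before use.
#'
#' @param x numeric signal vector.
#' @return Sum of absolute sample values.
#' @export
emg_iemg <- function(x) {
  if (length(x) < 1L) stop("iEMG undefined for an empty signal", call. = FALSE)
  sum(abs(x))
}

#' Locate strict local extrema, with endpoint anchors
#'
#' Interior maxima/minima are samples strictly greater/less than both
#' neighbours. The first and last samples are appended to both lists as
#' anchors so the envelope splines never extrapolate.
#'
#' @param x numeric signal vector, length >= 3.
#' @return List with sorted 1-based index vectors `maxima` and `minima`.
#' @export
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples to locate extrema", call. = FALSE)
  core <- x[2:(n - 1L)]
  up <- core > x[1:(n - 2L)] & core > x[3:n]
  dn <- core < x[1:(n - 2L)] & core < x[3:n]
  list(maxima = sort(unique(c(1L, which(up) + 1L, n))),
       minima = sort(unique(c(1L, which(dn) + 1L, n))))
}

#' Upper and lower signal envelopes by spline interpolation of extrema
#'
#' Fits a natural cubic interpolating spline through the (index, value)
#' local maxima for the upper envelope L(t) and through the local minima for
#' the lower envelope l(t), anchored at the first and last raw samples, then
#' evaluates both at every sample index.
#'
#' @param x numeric signal vector, length >= 3.
#' @return List with numeric vectors `upper` and `lower`, each `length(x)`.
#' @export
emg_envelope <- function(x) {
  ext <- find_extrema(x)
  idx <- seq_along(x)
  fit <- function(knots) {
    if (length(knots) < 2L) return(rep(x[knots], length(x)))
    stats::splinefun(knots, x[knots], method = "natural")(idx)
  }
  list(upper = fit(ext$maxima), lower = fit(ext$minima))
}

#' Envelope area of a segment
#'
#' The total envelope area is `EA = EA_up + EA_down` with
#' `EA_up = |integral of L(t)|` and `EA_down = |integral of l(t)|`: the
#' absolute value of the signed trapezoidal integral of each spline envelope
#' over the sample index axis (dt = 1 sample).
#'
#' @param x numeric signal vector, length >= 3.
#' @return Nonnegative scalar.
#' @export
envelope_area <- function(x) {
  env <- emg_envelope(x)
  abs(pracma::trapz(env$upper)) + abs(pracma::trapz(env$lower))
}

#' Welch-averaged one-sided power spectral density
#'
#' Averaged periodogram with Hann-tapered windows (default 1 s) at 50%
#' overlap. The density is scaled so that its integral over frequency
#' approximates the signal's mean square power (Parseval).
#'
#' @param x numeric signal vector, length >= 64.
#' @param rate sampling rate in samples/second.
#' @param window window length in samples (default `round(rate)`, capped at
#'   the signal length).
#' @param overlap fractional window overlap in [0, 1).
#' @return An `emg_spectrum`: list with `freq` (Hz, 0..rate/2) and `power`
#'   (density, signal units squared per Hz).
#' @export
power_spectrum <- function(x, rate, window = NULL, overlap = 0.5) {
  n <- length(x)
  if (n < 64L) stop("signal too short for spectral estimation (need >= 64 samples)",
                    call. = FALSE)
  win_n <- if (is.null(window)) as.integer(round(rate)) else as.integer(window)
  win_n <- min(win_n, n)
  step <- max(1L, as.integer(floor(win_n * (1 - overlap))))
  starts <- seq.int(1L, n - win_n + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win_n) - 1L) / (win_n - 1L))
  u <- sum(w^2)
  acc <- numeric(win_n)
  for (s in starts) {
    X <- stats::fft(x[s:(s + win_n - 1L)] * w)
    acc <- acc + Mod(X)^2
  }
  p <- acc / (length(starts) * rate * u)
  half <- win_n %/% 2L + 1L
  one <- p[seq_len(half)]
  # double interior bins to fold negative frequencies in
  last_paired <- if (win_n %% 2L == 0L) half - 1L else half
  if (last_paired >= 2L) one[2L:last_paired] <- 2 * one[2L:last_paired]
  structure(list(freq = (seq_len(half) - 1L) * rate / win_n, power = one,
                 df = rate / win_n),
            class = "emg_spectrum")
}

total_power <- function(spectrum) sum(spectrum$power)

#' Mean power frequency of a spectrum
#'
#' Power-weighted spectral centroid `sum(f * P) / sum(P)`.
#'
#' @param spectrum an `emg_spectrum` from [power_spectrum()].
#' @return Frequency in Hz.
#' @export
mpf <- function(spectrum) {
  tp <- total_power(spectrum)
  if (!is.finite(tp) || tp <= 0) {
    stop("mean power frequency undefined: spectrum has zero total power",
         call. = FALSE)
  }
  sum(spectrum$freq * spectrum$power) / tp
}

#' Median frequency of a spectrum
#'
#' Smallest frequency at which cumulative power reaches half the total.
#'
#' @inheritParams mpf
#' @return Frequency in Hz.
#' @export
mf <- function(spectrum) {
  tp <- total_power(spectrum)
  if (!is.finite(tp) || tp <= 0) {
    stop("median frequency undefined: spectrum has zero total power",
         call. = FALSE)
  }
  spectrum$freq[which(cumsum(spectrum$power) >= tp / 2)[1L]]
}

#' Max-min normalization
#'
#' Rescales a feature column to [0, 1] over its sample population:
#' `(x - min) / (max - min)`. The returned parameters allow applying the same
#' affine map to new values (fold-safe use).
#'
#' @param values numeric vector, length >= 2.
#' @return List with `values` (normalized), `x_min`, `x_max`.
#' @export
normalize_minmax <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values to normalize", call. = FALSE)
  lo <- min(values); hi <- max(values)
  if (hi == lo) {
    stop("degenerate feature: all values identical, max-min normalization undefined",
         call. = FALSE)
  }
  list(values = (values - lo) / (hi - lo), x_min = lo, x_max = hi)
}

#' Compute the five features of one preprocessed segment
#'
#' @param seg a preprocessed `emg_segment`.
#' @return One-row data frame: identity columns plus `rms`, `iemg`, `ea`,
#'   `mpf`, `mf`, `mas_label`.
#' @export
segment_features <- function(seg) {
  if (!inherits(seg, "emg_segment")) stop("`seg` must be an emg_segment", call. = FALSE)
  sp <- power_spectrum(seg$samples, seg$rate)
  data.frame(subject_id = seg$subject_id, trial_index = seg$trial_index,
             segment_id = seg$segment_id, channel = seg$channel,
             rms = emg_rms(seg$samples), iemg = emg_iemg(seg$samples),
             ea = envelope_area(seg$samples), mpf = mpf(sp), mf = mf(sp),
             mas_label = seg$grade, stringsAsFactors = FALSE)
}

#' Extract features from a list of preprocessed segments
#'
#' @param segments list of preprocessed `emg_segment` objects.
#' @return Long data frame, one row per (segment, channel), columns
#'   `subject_id`, `trial_index`, `segment_id`, `channel`, `rms`, `iemg`,
#'   `ea`, `mpf`, `mf`, `mas_label`.
#' @export
extract_features <- function(segments) {
  do.call(rbind, lapply(segments, segment_features))
}

#' Reshape the long feature table to one row per sample
#'
#' A sample is one (subject, trial, segment) unit; its 15 feature values
#' (5 features x 3 channels) become columns `rms_LB`, ..., `mf_BR`.
#'
#' @param features long feature table from [extract_features()].
#' @return Wide data frame with `sample_id`, identity columns, 15 feature
#'   columns, `mas_label` and `grade` (ordinal).
#' @export
features_wide <- function(features) {
  key <- interaction(features$subject_id, features$trial_index,
                     features$segment_id, drop = TRUE, lex.order = TRUE)
  samples <- !duplicated(key)
  wide <- data.frame(
    sample_id = paste(features$subject_id, features$trial_index,
                      features$segment_id, sep = "_")[samples],
    subject_id = features$subject_id[samples],
    trial_index = features$trial_index[samples],
    segment_id = features$segment_id[samples],
    stringsAsFactors = FALSE)
  for (feat in c("rms", "iemg", "ea", "mpf", "mf")) {
    for (ch in emg_channels()) {
      rows <- features$channel == ch
      m <- match(key[samples], key[rows])
      wide[[paste(feat, ch, sep = "_")]] <- features[[feat]][rows][m]
    }
  }
  wide$mas_label <- features$mas_label[samples]
  wide$grade <- encode_mas(wide$mas_label)
  if (anyNA(wide)) stop("incomplete feature table: some samples lack a channel",
                        call. = FALSE)
  wide
}

#' Normalize all feature columns of a wide sample table
#'
#' Applies [normalize_minmax()] to each feature-by-channel column jointly
#' over the table's samples (the normalization population).
#'
#' @param wide wide table from [features_wide()].
#' @param params optional data frame of `column`, `x_min`, `x_max` from an
#'   earlier call; when supplied, those parameters are applied instead of
#'   being re-estimated (fold-safe use).
#' @return List with `data` (normalized wide table) and `params`.
#' @export
normalize_features <- function(wide, params = NULL) {
  cols <- grep("^(rms|iemg|ea|mpf|mf)_(LB|SB|BR)$", names(wide), value = TRUE)
  if (is.null(params)) {
    params <- data.frame(column = cols, x_min = NA_real_, x_max = NA_real_,
                         stringsAsFactors = FALSE)
    for (i in seq_along(cols)) {
      nm <- normalize_minmax(wide[[cols[i]]])
      wide[[cols[i]]] <- nm$values
      params$x_min[i] <- nm$x_min
      params$x_max[i] <- nm$x_max
    }
  } else {
    for (i in seq_len(nrow(params))) {
      cl <- params$column[i]
      wide[[cl]] <- (wide[[cl]] - params$x_min[i]) /
        (params$x_max[i] - params$x_min[i])
    }
  }
  list(data = wide, params = params)
}
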