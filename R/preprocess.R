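#' Denoising filter specification
#'
#' Defaults follow standard sEMG practice for recordings at 1024 Hz: a
#' 20-450 Hz Butterworth band-pass (order 4) removes baseline drift, motion
#' artifact and out-of-band noise, and a 48-52 Hz band-stop (order 2)
#' suppresses powerline interference. Both are applied forward-backward
#' (zero-phase) so burst timing used by the envelope feature is preserved.
#'
#' @param bandpass_low,bandpass_high band-pass edges in Hz.
#' @param notch_low,notch_high notch stopband edges in Hz.
#' @param bandpass_order Butterworth order of the band-pass.
#' @param notch_order Butterworth order of the band-stop.
#' @param zero_phase apply filters forward-backward (default TRUE).
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(bandpass_low = 20, bandpass_high = 450,
                        notch_low = 48, notch_high = 52,
                        bandpass_order = 4L, notch_order = 2L,
                        zero_phase = TRUE) {
  if (!(bandpass_low > 0 && bandpass_low < bandpass_high)) {
    stop("need 0 < bandpass_low < bandpass_high", call. = FALSE)
  }
  if (!(notch_low > bandpass_low && notch_high < bandpass_high &&
        notch_low < notch_high)) {
    stop("notch band must lie inside the band-pass band", call. = FALSE)
  }
  structure(list(bandpass_low = bandpass_low, bandpass_high = bandpass_high,
                 notch_low = notch_low, notch_high = notch_high,
                 bandpass_order = as.integer(bandpass_order),
                 notch_order = as.integer(notch_order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# Zero-phase filtering with odd-reflection padding at both ends to suppress
# startup transients; pad length ~1 s (capped by signal length).
apply_iir <- function(filt, x, rate, zero_phase = TRUE) {
  n <- length(x)
  if (n < 2L) return(x)
  pad <- min(n - 1L, as.integer(round(rate)))
  left <- 2 * x[1L] - x[(pad + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - pad)]
  xp <- c(left, x, right)
  yp <- if (zero_phase) signal::filtfilt(filt, xp) else signal::filter(filt, xp)
  yp[(pad + 1L):(pad + n)]
}

check_rate <- function(rate, spec) {
  if (rate <= 2 * spec$bandpass_high) {
    stop("sampling rate ", rate, " Hz too low for a ", spec$bandpass_high,
         " Hz band edge (need rate > ", 2 * spec$bandpass_high, ")",
         call. = FALSE)
  }
}

#' Band-pass filter a signal
#'
#' @param x numeric signal vector (millivolts).
#' @param rate sampling rate in samples/second.
#' @param spec a [filter_spec()].
#' @return Filtered vector of the same length.
#' @export
bandpass <- function(x, rate, spec = filter_spec()) {
  check_rate(rate, spec)
  filt <- signal::butter(spec$bandpass_order,
                         c(spec$bandpass_low, spec$bandpass_high) / (rate / 2),
                         type = "pass")
  apply_iir(filt, x, rate, spec$zero_phase)
}

#' Notch (band-stop) filter a signal
#'
#' Suppresses the 48-52 Hz band around the 50 Hz powerline frequency.
#'
#' @inheritParams bandpass
#' @return Filtered vector of the same length.
#' @export
notch <- function(x, rate, spec = filter_spec()) {
  if (spec$notch_high >= rate / 2) {
    stop("notch band must lie below the Nyquist frequency", call. = FALSE)
  }
  filt <- signal::butter(spec$notch_order,
                         c(spec$notch_low, spec$notch_high) / (rate / 2),
                         type = "stop")
  apply_iir(filt, x, rate, spec$zero_phase)
}

#' Denoise one segment (band-pass then notch)
#'
#' @param seg an `emg_segment` from [split_segments()].
#' @param spec a [filter_spec()].
#' @return The segment with filtered samples; metadata unchanged.
#' @export
preprocess_segment <- function(seg, spec = filter_spec()) {
  if (!inherits(seg, "emg_segment")) stop("`seg` must be an emg_segment", call. = FALSE)
  seg$samples <- notch(bandpass(seg$samples, seg$rate, spec), seg$rate, spec)
  seg
}

#' Denoise all channels of a recording
#'
#' @param recording an [emg_recording()].
#' @param spec a [filter_spec()].
#' @return The recording with filtered signal matrix.
#' @export
preprocess_recording <- function(recording, spec = filter_spec()) {
  if (!inherits(recording, "emg_recording")) {
    stop("`recording` must be an emg_recording", call. = FALSE)
  }
  for (ch in colnames(recording$signal)) {
    recording$signal[, ch] <-
      notch(bandpass(recording$signal[, ch], recording$rate, spec),
            recording$rate, spec)
  }
  recording
}
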