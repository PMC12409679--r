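#' @keywords internal
emg_channels <- function() c("LB", "SB", "BR")

#' Construct a labelled multichannel sEMG recording
#'
#' A recording is one trial of one subject: three channels (channel 1 = long
#' head of biceps brachii, LB; channel 2 = short head, SB; channel 3 =
#' brachioradialis, BR) sampled at a common rate, with the physician's MAS
#' label attached.
#'
#' @param signal numeric matrix or data frame, one row per sample, columns
#'   named `LB`, `SB`, `BR` in that order; values in millivolts.
#' @param rate sampling rate in samples/second (study protocol: 1024).
#' @param grade MAS label, one of [mas_levels()].
#' @param subject_id subject identifier.
#' @param trial_index trial number (>= 1).
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(signal, rate = 1024, grade, subject_id = "S1",
                          trial_index = 1L) {
  signal <- as.matrix(signal)
  if (ncol(signal) != 3L) {
    stop("an sEMG recording must have exactly 3 channels (LB, SB, BR), got ",
         ncol(signal), call. = FALSE)
  }
  if (is.null(colnames(signal)) || !identical(colnames(signal), emg_channels())) {
    stop("channel columns must be named LB, SB, BR in that order", call. = FALSE)
  }
  storage.mode(signal) <- "double"
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a single positive number", call. = FALSE)
  }
  encode_mas(grade)  # validates
  trial_index <- as.integer(trial_index)
  if (is.na(trial_index) || trial_index < 1L) {
    stop("trial_index must be an integer >= 1", call. = FALSE)
  }
  structure(
    list(signal = signal, rate = rate, grade = as.character(grade),
         subject_id = as.character(subject_id), trial_index = trial_index),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "<emg_recording> %s trial %d | MAS %s | %d samples x 3 ch @ %g Hz (%.1f s)\n",
    x$subject_id, x$trial_index, x$grade, nrow(x$signal), x$rate,
    nrow(x$signal) / x$rate))
  invisible(x)
}

#' Read a recording from a delimited text file
#'
#' Expects comma-delimited text with header row `LB,SB,BR` and one sample per
#' row (millivolt floats), the interchange format written by
#' [write_recording()].
#'
#' @param path file path.
#' @param rate sampling rate in samples/second.
#' @param grade MAS label for the recording.
#' @param subject_id,trial_index recording identity.
#' @return An [emg_recording()].
#' @export
read_recording <- function(path, rate = 1024, grade, subject_id = "S1",
                           trial_index = 1L) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  want <- emg_channels()
  if (!identical(names(df), want)) {
    missing <- setdiff(want, names(df))
    extra <- setdiff(names(df), want)
    msg <- c(
      if (length(missing)) paste0("missing channel column(s): ",
                                  paste(missing, collapse = ", ")),
      if (length(extra)) paste0("unexpected column(s): ",
                                paste(extra, collapse = ", ")),
      if (!length(missing) && !length(extra)) "channel columns out of order"
    )
    stop("malformed signal file ", path, ": ", paste(msg, collapse = "; "),
         call. = FALSE)
  }
  sig <- matrix(NA_real_, nrow = nrow(df), ncol = 3L,
                dimnames = list(NULL, want))
  for (ch in want) {
    v <- suppressWarnings(as.numeric(df[[ch]]))
    bad <- which(is.na(v) & !is.na(df[[ch]]) & nzchar(trimws(df[[ch]])))
    if (anyNA(v)) {
      row <- if (length(bad)) bad[1L] else which(is.na(v))[1L]
      stop("non-numeric value in column ", ch, " at data row ", row,
           " of ", path, call. = FALSE)
    }
    sig[, ch] <- v
  }
  emg_recording(sig, rate = rate, grade = grade, subject_id = subject_id,
                trial_index = trial_index)
}

#' Write a recording to a delimited text file
#'
#' @param recording an [emg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path) {
  if (!inherits(recording, "emg_recording")) {
    stop("`recording` must be an emg_recording", call. = FALSE)
  }
  ok <- tryCatch({
    utils::write.csv(as.data.frame(recording$signal), path, row.names = FALSE,
                     quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write ", path, ": ", conditionMessage(ok),
                        call. = FALSE)
  invisible(path)
}

#' Split a recording's active span into contiguous segments
#'
#' Divides the active-movement span of each channel into `n_segments` equal
#' contiguous time slices (Segment A, B, C for the default 3) by sample index.
#' When the span length is not divisible, the remainder samples go to the
#' earliest segments, so segment lengths differ by at most one sample and the
#' segments partition the span exactly.
#'
#' @param recording an [emg_recording()].
#' @param span half-open sample interval `c(start, end)`, 0-based, within the
#'   recording: the active-movement portion to segment.
#' @param n_segments number of segments (default 3).
#' @return A list of `emg_segment` objects, ordered segment-major
#'   (A-LB, A-SB, A-BR, B-LB, ...). Each segment carries its samples, rate,
#'   channel, segment id, parent identity and MAS grade.
#' @export
split_segments <- function(recording, span, n_segments = 3L) {
  if (!inherits(recording, "emg_recording")) {
    stop("`recording` must be an emg_recording", call. = FALSE)
  }
  n <- nrow(recording$signal)
  if (length(span) != 2L || anyNA(span)) stop("span must be c(start, end)", call. = FALSE)
  start <- as.integer(span[1L]); end <- as.integer(span[2L])
  if (start < 0L || end > n || start >= end) {
    stop("span [", start, ", ", end, ") outside recording of ", n, " samples",
         call. = FALSE)
  }
  n_segments <- as.integer(n_segments)
  if (is.na(n_segments) || n_segments < 1L) stop("n_segments must be >= 1", call. = FALSE)
  len <- end - start
  if (n_segments > len) stop("more segments than samples in span", call. = FALSE)
  base <- len %/% n_segments
  rem <- len %% n_segments
  lens <- base + as.integer(seq_len(n_segments) <= rem)
  ends <- start + cumsum(lens)
  starts <- c(start, ends[-n_segments])
  ids <- LETTERS[seq_len(n_segments)]
  out <- vector("list", n_segments * 3L)
  i <- 0L
  for (s in seq_len(n_segments)) {
    idx <- (starts[s] + 1L):ends[s]  # 1-based row indices
    for (ch in emg_channels()) {
      i <- i + 1L
      out[[i]] <- structure(
        list(samples = recording$signal[idx, ch], rate = recording$rate,
             channel = ch, segment_id = ids[s],
             subject_id = recording$subject_id,
             trial_index = recording$trial_index, grade = recording$grade),
        class = "emg_segment")
    }
  }
  out
}

#' @export
print.emg_segment <- function(x, ...) {
  cat(sprintf("<emg_segment> %s trial %d seg %s ch %s | MAS %s | %d samples @ %g Hz\n",
              x$subject_id, x$trial_index, x$segment_id, x$channel, x$grade,
              length(x$samples), x$rate))
  invisible(x)
}

#' Read or write a cohort manifest
#'
#' The manifest is the interchange table between acquisition/simulation and
#' the analysis pipeline: one row per recording with its file path, MAS label
#' and active-span boundaries (0-based half-open sample interval).
#'
#' @param manifest data frame with columns `subject_id`, `trial_index`,
#'   `path`, `mas_label`, `span_start`, `span_end`.
#' @param path CSV file path.
#' @return `read_manifest()` returns the manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  need <- c("subject_id", "trial_index", "path", "mas_label",
            "span_start", "span_end")
  if (!all(need %in% names(manifest))) {
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  utils::write.csv(manifest[, need, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, colClasses = c(subject_id = "character",
                                             mas_label = "character"))
  encode_mas(df$mas_label)  # validates labels
  df
}
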