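#' Configuration of the synthetic sEMG cohort generator
#'
#' The generator emulates the clinical recording protocol: 2 min of rest,
#' then 3 loops of passive elbow flexion-extension (each loop = 3 consecutive
#' 30-s cycles, each cycle = 3 contiguous ~10-s flexion-extension movements)
#' with 30-s breaks between loops, then 2 min of rest, all at 1024 Hz.
#' During movement epochs each channel carries band-limited Gaussian noise
#' whose gain increases strictly with the MAS grade (stronger stretch-reflex
#' activity in more spastic muscle) and whose band centre shifts down with
#' grade (lower spectral content), plus baseline instrumentation noise and a
#' 50 Hz powerline tone everywhere.
#'
#' @param rate sampling rate, samples/second.
#' @param n_patients_per_grade patients simulated per MAS grade (default 8,
#'   giving 240 sample segments from 80 trials as in the study design).
#' @param trials_per_patient recording trials per patient.
#' @param rest_duration,cycle_duration,break_duration protocol timings in
#'   seconds.
#' @param cycles_per_loop,loops protocol counts.
#' @param movement_duration nominal duration of one flexion-extension
#'   movement in seconds.
#' @param baseline_sigma baseline noise SD, millivolts.
#' @param burst_gain_per_grade movement-burst RMS gain (millivolts) for
#'   grades 0,1,1+,2,3; must be strictly increasing.
#' @param burst_band Hz interval of the grade-0 movement burst noise.
#' @param spectral_shift_per_grade downward shift of the burst band centre
#'   per grade step, Hz (implemented by lowering the upper band edge by twice
#'   this amount per step).
#' @param powerline_freq,powerline_amp powerline tone frequency (Hz) and
#'   amplitude (millivolts).
#' @param channel_gain_jitter SD of the per-channel log-normal gain jitter
#'   (makes channels imperfectly correlated so fusion has signal to exploit).
#' @param patient_sigma SD of the per-patient log-normal gain factor
#'   (between-patient variability within a grade).
#' @param seed master RNG seed for cohort generation.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(rate = 1024, n_patients_per_grade = 8L,
                         trials_per_patient = 2L, rest_duration = 120,
                         cycle_duration = 30, cycles_per_loop = 3L, loops = 3L,
                         break_duration = 30, movement_duration = 10,
                         baseline_sigma = 0.01,
                         burst_gain_per_grade = c(0.05, 0.10, 0.18, 0.30, 0.50),
                         burst_band = c(30, 250),
                         spectral_shift_per_grade = 15,
                         powerline_freq = 50, powerline_amp = 0.05,
                         channel_gain_jitter = 0.10, patient_sigma = 0.20,
                         seed = 0L) {
  cfg <- list(rate = rate, n_patients_per_grade = as.integer(n_patients_per_grade),
              trials_per_patient = as.integer(trials_per_patient),
              rest_duration = rest_duration, cycle_duration = cycle_duration,
              cycles_per_loop = as.integer(cycles_per_loop),
              loops = as.integer(loops), break_duration = break_duration,
              movement_duration = movement_duration,
              baseline_sigma = baseline_sigma,
              burst_gain_per_grade = burst_gain_per_grade,
              burst_band = burst_band,
              spectral_shift_per_grade = spectral_shift_per_grade,
              powerline_freq = powerline_freq, powerline_amp = powerline_amp,
              channel_gain_jitter = channel_gain_jitter,
              patient_sigma = patient_sigma, seed = as.integer(seed))
  if (rate <= 0 || any(c(cfg$rest_duration, cfg$cycle_duration,
                         cfg$break_duration, cfg$movement_duration) <= 0)) {
    stop("rate and durations must be positive", call. = FALSE)
  }
  if (length(cfg$burst_gain_per_grade) != 5L ||
      any(diff(cfg$burst_gain_per_grade) <= 0)) {
    stop("burst_gain_per_grade must be 5 strictly increasing gains", call. = FALSE)
  }
  if (length(cfg$burst_band) != 2L || cfg$burst_band[1] <= 0 ||
      cfg$burst_band[1] >= cfg$burst_band[2]) {
    stop("burst_band must be an increasing positive Hz interval", call. = FALSE)
  }
  hi4 <- cfg$burst_band[2] - 2 * cfg$spectral_shift_per_grade * 4
  if (hi4 <= cfg$burst_band[1]) {
    stop("spectral_shift_per_grade too large: grade-3 burst band collapses",
         call. = FALSE)
  }
  if (cfg$burst_band[2] >= rate / 2) {
    stop("burst_band must lie below the Nyquist frequency", call. = FALSE)
  }
  n_ep <- cfg$cycle_duration / cfg$movement_duration
  if (abs(n_ep - round(n_ep)) > 1e-8 || round(n_ep) < 1) {
    stop("cycle_duration must be an integer multiple of movement_duration",
         call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

# protocol sample counts and active span (0-based half-open)
synth_layout <- function(config) {
  rate <- config$rate
  rest_n <- as.integer(round(config$rest_duration * rate))
  cycle_n <- as.integer(round(config$cycle_duration * rate))
  loop_n <- config$cycles_per_loop * cycle_n
  break_n <- as.integer(round(config$break_duration * rate))
  total <- 2L * rest_n + config$loops * loop_n + (config$loops - 1L) * break_n
  list(rest_n = rest_n, cycle_n = cycle_n, loop_n = loop_n, break_n = break_n,
       total = total,
       span = c(rest_n, rest_n + config$loops * loop_n +
                  (config$loops - 1L) * break_n))
}

# Hann amplitude envelope over one loop: one bump per movement epoch
loop_envelope <- function(config, layout) {
  n_ep <- round(config$cycle_duration / config$movement_duration)
  base <- layout$cycle_n %/% n_ep
  rem <- layout$cycle_n %% n_ep
  lens <- base + as.integer(seq_len(n_ep) <= rem)
  cyc <- unlist(lapply(lens, function(l)
    0.5 - 0.5 * cos(2 * pi * (seq_len(l) - 1L) / (l - 1L))))
  rep(cyc, config$cycles_per_loop)
}

#' Generate one synthetic sEMG recording
#'
#' @param grade MAS label, one of [mas_levels()].
#' @param config a [synth_config()].
#' @param seed RNG seed for this recording.
#' @param patient_gain multiplicative patient-level gain (drawn by
#'   [generate_cohort()]; default 1).
#' @param subject_id,trial_index identity metadata.
#' @return List with `recording` (an [emg_recording()]) and `span`
#'   (0-based half-open active-movement sample interval).
#' @export
generate_recording <- function(grade, config = synth_config(), seed = 0L,
                               patient_gain = 1, subject_id = "S1",
                               trial_index = 1L) {
  ord <- encode_mas(grade)
  lay <- synth_layout(config)
  rate <- config$rate
  band <- c(config$burst_band[1],
            config$burst_band[2] - 2 * config$spectral_shift_per_grade * ord)
  gain <- config$burst_gain_per_grade[ord + 1L] * patient_gain
  env <- loop_envelope(config, lay)
  loop_starts <- lay$span[1] + (seq_len(config$loops) - 1L) *
    (lay$loop_n + lay$break_n)
  filt <- signal::butter(4, band / (rate / 2), type = "pass")
  sig <- with_seed(seed, {
    phase <- stats::runif(1, 0, 2 * pi)
    pl <- if (config$powerline_amp > 0) {
      config$powerline_amp *
        sin(2 * pi * config$powerline_freq * (seq_len(lay$total) - 1L) / rate +
              phase)
    } else 0
    m <- matrix(0, lay$total, 3L, dimnames = list(NULL, emg_channels()))
    for (ch in emg_channels()) {
      jit <- exp(stats::rnorm(1, 0, config$channel_gain_jitter))
      x <- if (config$baseline_sigma > 0) {
        stats::rnorm(lay$total, 0, config$baseline_sigma)
      } else numeric(lay$total)
      if (gain > 0) {
        for (s0 in loop_starts) {
          nz <- stats::rnorm(lay$loop_n)
          bl <- apply_iir(filt, nz, rate)
          bl <- bl / stats::sd(bl)
          idx <- (s0 + 1L):(s0 + lay$loop_n)
          x[idx] <- x[idx] + gain * jit * bl * env
        }
      }
      m[, ch] <- x + pl
    }
    m
  })
  list(recording = emg_recording(sig, rate = rate, grade = grade,
                                 subject_id = subject_id,
                                 trial_index = trial_index),
       span = lay$span)
}

# Deterministic cohort plan: per-recording seeds and patient gains drawn
# from the master seed, so streaming and materializing routes agree exactly.
cohort_plan <- function(config) {
  with_seed(config$seed, {
    rows <- list()
    for (g in 0:4) {
      for (p in seq_len(config$n_patients_per_grade)) {
        pg <- exp(stats::rnorm(1, 0, config$patient_sigma))
        sid <- sprintf("G%dP%02d", g, p)
        for (t in seq_len(config$trials_per_patient)) {
          rows[[length(rows) + 1L]] <- data.frame(
            subject_id = sid, trial_index = t, mas_label = decode_mas(g),
            rec_seed = sample.int(.Machine$integer.max, 1L),
            patient_gain = pg, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a balanced synthetic cohort
#'
#' Materializes every recording of the cohort plan in memory: per grade,
#' `n_patients_per_grade` patients x `trials_per_patient` trials. For large
#' cohorts prefer [cohort_features()], which streams recordings one at a
#' time.
#'
#' @param config a [synth_config()].
#' @return A `synth_cohort`: list with `recordings` (list of
#'   [emg_recording()]), `manifest` (data frame incl. `span_start`,
#'   `span_end`, per-recording seeds) and `config`.
#' @export
generate_cohort <- function(config = synth_config()) {
  plan <- cohort_plan(config)
  lay <- synth_layout(config)
  recs <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    recs[[i]] <- generate_recording(plan$mas_label[i], config,
                                    seed = plan$rec_seed[i],
                                    patient_gain = plan$patient_gain[i],
                                    subject_id = plan$subject_id[i],
                                    trial_index = plan$trial_index[i])$recording
  }
  manifest <- cbind(plan, path = NA_character_,
                    span_start = lay$span[1], span_end = lay$span[2],
                    stringsAsFactors = FALSE)
  structure(list(recordings = recs, manifest = manifest, config = config),
            class = "synth_cohort")
}

#' Write a materialized cohort to disk
#'
#' One CSV signal file per recording plus the cohort manifest.
#'
#' @param cohort a `synth_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return Path of the written manifest, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  man <- cohort$manifest
  for (i in seq_along(cohort$recordings)) {
    rec <- cohort$recordings[[i]]
    fn <- sprintf("%s_t%d.csv", rec$subject_id, rec$trial_index)
    write_recording(rec, file.path(dir, fn))
    man$path[i] <- fn
  }
  write_manifest(man, file.path(dir, "manifest.csv"))
  invisible(file.path(dir, "manifest.csv"))
}

#' Extract the per-segment feature table of a cohort
#'
#' Runs preprocessing (band-pass + notch), segmentation of the active span
#' into thirds, and five-feature extraction for every recording. When given a
#' [synth_config()], recordings are generated, processed and discarded one at
#' a time so the full-protocol cohort never resides in memory.
#'
#' @param x a `synth_cohort` or a [synth_config()].
#' @param spec a [filter_spec()].
#' @param n_segments segments per recording (default 3).
#' @return Long feature data frame (see [extract_features()]).
#' @export
cohort_features <- function(x, spec = filter_spec(), n_segments = 3L) {
  one <- function(rec, span) {
    segs <- split_segments(rec, span, n_segments)
    extract_features(lapply(segs, preprocess_segment, spec = spec))
  }
  if (inherits(x, "synth_cohort")) {
    man <- x$manifest
    out <- lapply(seq_along(x$recordings), function(i)
      one(x$recordings[[i]], c(man$span_start[i], man$span_end[i])))
  } else if (inherits(x, "synth_config")) {
    plan <- cohort_plan(x)
    lay <- synth_layout(x)
    out <- lapply(seq_len(nrow(plan)), function(i) {
      g <- generate_recording(plan$mas_label[i], x, seed = plan$rec_seed[i],
                              patient_gain = plan$patient_gain[i],
                              subject_id = plan$subject_id[i],
                              trial_index = plan$trial_index[i])
      one(g$recording, g$span)
    })
  } else {
    stop("`x` must be a synth_cohort or synth_config", call. = FALSE)
  }
  do.call(rbind, out)
}

#' Extract the feature table of an on-disk cohort
#'
#' @param manifest_path path to a cohort manifest CSV (see
#'   [write_manifest()]); signal file paths are resolved relative to the
#'   manifest's directory.
#' @param rate sampling rate of the recordings.
#' @param spec a [filter_spec()].
#' @param n_segments segments per recording.
#' @return Long feature data frame.
#' @export
manifest_features <- function(manifest_path, rate = 1024,
                              spec = filter_spec(), n_segments = 3L) {
  man <- read_manifest(manifest_path)
  base <- dirname(manifest_path)
  out <- lapply(seq_len(nrow(man)), function(i) {
    rec <- read_recording(file.path(base, man$path[i]), rate = rate,
                          grade = man$mas_label[i],
                          subject_id = man$subject_id[i],
                          trial_index = man$trial_index[i])
    segs <- split_segments(rec, c(man$span_start[i], man$span_end[i]),
                           n_segments)
    extract_features(lapply(segs, preprocess_segment, spec = spec))
  })
  do.call(rbind, out)
}
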