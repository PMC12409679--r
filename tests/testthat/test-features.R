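test_that("rms and iemg match hand computation", {
  expect_equal(emg_rms(c(3, 4)), sqrt(12.5))
  expect_equal(emg_rms(rep(-2.5, 10)), 2.5)
  expect_equal(emg_rms(numeric(5)), 0)
  expect_equal(emg_iemg(c(1, -2, 3)), 6)
  expect_equal(emg_iemg(rep(-0.5, 8)), 4)
  expect_equal(emg_iemg(numeric(5)), 0)
  expect_error(emg_rms(numeric(0)), "empty")
  expect_error(emg_iemg(numeric(0)), "empty")
})

test_that("extrema detection finds strict peaks plus endpoint anchors", {
  ext <- find_extrema(c(0, 1, 0, -1, 0))
  expect_identical(ext$maxima, c(1L, 2L, 5L))
  expect_identical(ext$minima, c(1L, 4L, 5L))
  ext <- find_extrema(1:10)
  expect_identical(ext$maxima, c(1L, 10L))
  expect_identical(ext$minima, c(1L, 10L))
  expect_error(find_extrema(c(1, 2)), "3 samples")
  # P full periods of a sinusoid have P interior maxima and minima
  p <- 7L
  x <- sin(2 * pi * (0:(p * 100 - 1)) / 100)
  ext <- find_extrema(x)
  expect_identical(length(setdiff(ext$maxima, c(1L, length(x)))), p)
  expect_identical(length(setdiff(ext$minima, c(1L, length(x)))), p)
})

test_that("spline envelopes interpolate extrema and track a sinusoid", {
  # degenerate constant signal: both envelopes equal the constant
  env <- emg_envelope(rep(2.5, 50))
  expect_equal(env$upper, rep(2.5, 50))
  expect_equal(env$lower, rep(2.5, 50))
  # envelope passes exactly through an interior maximum
  x <- c(0, 1, 0.5, 3, 0.5, 1, 0)
  env <- emg_envelope(x)
  expect_equal(env$upper[4], 3)
  # unit sinusoid: envelopes near +/-1 away from the edges
  # natural-spline edge ripple from the endpoint anchors decays within a
  # few knot intervals, so assess the envelope well inside the signal
  x <- sin(2 * pi * (0:999) / 100)
  env <- emg_envelope(x)
  interior <- 300:700
  expect_lt(max(abs(env$upper[interior] - 1)), 0.05)
  expect_lt(max(abs(env$lower[interior] + 1)), 0.05)
})

test_that("envelope area follows the trapezoidal closed forms", {
  expect_equal(envelope_area(numeric(10)), 0)
  # constant c: both envelopes flat at c, each integrating to c*(N-1)
  n <- 200; c0 <- 0.7
  expect_equal(envelope_area(rep(c0, n)), 2 * c0 * (n - 1))
  # unit sinusoid over 10 periods: envelopes near +/-1, EA near 2*(N-1)
  x <- sin(2 * pi * (0:999) / 100)
  expect_lt(abs(envelope_area(x) - 2 * 999) / (2 * 999), 0.05)
})

test_that("EA is zero only for the identically zero signal", {
  expect_equal(envelope_area(numeric(64)), 0)
  set.seed(5)
  expect_gt(envelope_area(rnorm(64)), 0)
})

test_that("Welch spectrum localizes tones and conserves power", {
  rate <- 1024
  x <- make_tone(100)
  sp <- power_spectrum(x, rate)
  expect_lte(abs(sp$freq[which.max(sp$power)] - 100), sp$df)
  # Parseval: integrated density matches mean square power within 5%
  expect_lt(abs(sum(sp$power) * sp$df - mean(x^2)) / mean(x^2), 0.05)
  set.seed(9)
  w <- rnorm(8 * rate)
  sp <- power_spectrum(w, rate)
  expect_lt(abs(sum(sp$power) * sp$df - mean(w^2)) / mean(w^2), 0.05)
  # white noise: approximately flat density across interior bins
  interior <- sp$power[10:500]
  expect_lt(sd(interior) / mean(interior), 0.6)
  expect_equal(power_spectrum(numeric(128), rate)$power, rep(0, 65))
  expect_error(power_spectrum(numeric(10), rate), "too short")
})

test_that("mpf and mf behave on ideal and estimated spectra", {
  flat <- structure(list(freq = 0:512, power = rep(1, 513), df = 1),
                    class = "emg_spectrum")
  expect_equal(mpf(flat), 256)                 # centroid of uniform on [0, 512]
  expect_lte(abs(mf(flat) - 256), 1)
  rate <- 1024
  sp <- power_spectrum(make_tone(100), rate)
  expect_lte(abs(mpf(sp) - 100), sp$df)
  expect_lte(abs(mf(sp) - 100), sp$df)
  # two equal tones at 50 and 150 Hz: centroid at 100, median at the
  # cumulative half-power crossing
  sp2 <- power_spectrum(make_tone(50) + make_tone(150), rate)
  expect_lte(abs(mpf(sp2) - 100), sp2$df)
  cum <- cumsum(sp2$power)
  expect_equal(mf(sp2), sp2$freq[which(cum >= cum[length(cum)] / 2)[1]])
  expect_gte(mf(sp2), 50 - sp2$df); expect_lte(mf(sp2), 150 + sp2$df)
  zero <- structure(list(freq = 0:10, power = rep(0, 11), df = 1),
                    class = "emg_spectrum")
  expect_error(mpf(zero), "zero total power")
  expect_error(mf(zero), "zero total power")
})

test_that("max-min normalization maps to [0,1] and preserves order", {
  nm <- normalize_minmax(c(2, 4, 6))
  expect_equal(nm$values, c(0, 0.5, 1))
  expect_equal(nm$x_min, 2); expect_equal(nm$x_max, 6)
  set.seed(2)
  v <- rnorm(50)
  nm <- normalize_minmax(v)
  expect_equal(min(nm$values), 0); expect_equal(max(nm$values), 1)
  expect_identical(order(nm$values), order(v))
  expect_error(normalize_minmax(rep(1, 5)), "degenerate")
  expect_error(normalize_minmax(1), "at least 2")
})

test_that("feature extraction is counted, deterministic and homogeneous", {
  set.seed(7)
  sig <- matrix(rnorm(3 * 4096, sd = 0.1), ncol = 3,
                dimnames = list(NULL, c("LB", "SB", "BR")))
  rec <- emg_recording(sig, rate = 1024, grade = "2")
  segs <- lapply(split_segments(rec, c(0, 4096)), preprocess_segment)
  ft <- extract_features(segs)
  expect_identical(nrow(ft), 9L)                 # 3 segments x 3 channels
  expect_identical(ft, extract_features(segs))   # deterministic
  # doubling the signal doubles the amplitude features, leaves mpf/mf
  doubled <- lapply(segs, function(s) { s$samples <- 2 * s$samples; s })
  ft2 <- extract_features(doubled)
  expect_equal(ft2$rms, 2 * ft$rms)
  expect_equal(ft2$iemg, 2 * ft$iemg)
  expect_equal(ft2$ea, 2 * ft$ea)
  expect_equal(ft2$mpf, ft$mpf, tolerance = 1e-10)
  expect_equal(ft2$mf, ft$mf)
})

test_that("amplitude features scale homogeneously for arbitrary signals", {
  set.seed(13)
  for (i in 1:5) {
    x <- rnorm(300)
    a <- runif(1, 0.1, 10)
    expect_equal(emg_rms(a * x), a * emg_rms(x))
    expect_equal(emg_iemg(a * x), a * emg_iemg(x))
    expect_equal(envelope_area(a * x), a * envelope_area(x))
  }
})

test_that("wide reshaping and table normalization are consistent", {
  set.seed(21)
  sig <- matrix(rnorm(3 * 2048, sd = 0.1), ncol = 3,
                dimnames = list(NULL, c("LB", "SB", "BR")))
  ft <- rbind(
    extract_features(lapply(split_segments(
      emg_recording(sig, rate = 1024, grade = "0", subject_id = "A"),
      c(0, 2048)), preprocess_segment)),
    extract_features(lapply(split_segments(
      emg_recording(2 * sig, rate = 1024, grade = "3", subject_id = "B"),
      c(0, 2048)), preprocess_segment)))
  wide <- features_wide(ft)
  expect_identical(nrow(wide), 6L)
  expect_identical(ncol(wide), 4L + 15L + 2L)
  i <- which(wide$subject_id == "A" & wide$segment_id == "B")
  j <- ft$subject_id == "A" & ft$segment_id == "B" & ft$channel == "SB"
  expect_equal(wide$rms_SB[i], ft$rms[j])
  norm <- normalize_features(wide)
  for (cl in grep("_LB$", names(norm$data), value = TRUE)) {
    expect_equal(range(norm$data[[cl]]), c(0, 1))
  }
  # reapplying stored parameters reproduces the same mapping
  again <- normalize_features(wide, params = norm$params)
  expect_equal(again$data, norm$data)
})
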