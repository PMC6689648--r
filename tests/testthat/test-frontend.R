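# Acoustic front end: band-energy ratio, song regions, wideband envelope,
# peak detection, MFCCs and string building.

rate <- 16000
tone <- function(freq, dur = 1, a = 1000)
  audio_signal(a * sin(2 * pi * freq * seq_len(dur * rate) / rate), rate)

test_that("band-energy ratio separates in-band and out-of-band tones", {
  r_in <- compute_band_energy_ratio(tone(1000))
  expect_gt(min(r_in$r), 0.99)
  r_out <- compute_band_energy_ratio(tone(3000))
  expect_lt(max(r_out$r), 1e-6)
  # white noise: flat expected periodogram -> mean r ~ 1000/8000
  set.seed(7)
  wn <- audio_signal(stats::rnorm(2 * rate, sd = 500), rate)
  expect_lt(abs(mean(compute_band_energy_ratio(wn)$r) - 0.125), 0.02)
  # too-short signal gives an empty series, invalid bands error
  expect_length(compute_band_energy_ratio(tone(1000, dur = 0.001))$r, 0)
  expect_error(compute_band_energy_ratio(tone(1000),
                                         song_band = c(500, 9000)),
               "invalid bands")
  expect_error(compute_band_energy_ratio(tone(1000), window = 0.01,
                                         hop = 0.02))
})

test_that("song regions are maximal long runs above threshold", {
  mk <- function(r) structure(list(frame_times = seq_along(r) / 100 - 0.01,
                                   r = r, window = 0.02, hop = 0.01),
                              class = "frame_ratio_series")
  # 600 ms run -> one region spanning it
  r <- rep(0, 100); r[10:68] <- 0.9
  reg <- detect_song_regions(mk(r))
  expect_identical(nrow(reg), 1L)
  expect_equal(reg$end - reg$start, 0.60, tolerance = 1e-9)
  # 400 ms run -> dropped by the 500 ms minimum
  r2 <- rep(0, 100); r2[10:48] <- 0.9
  expect_identical(nrow(detect_song_regions(mk(r2))), 0L)
  # two runs separated by a sub-threshold gap -> two regions, sorted
  r3 <- rep(0, 200); r3[10:68] <- 0.9; r3[120:178] <- 0.9
  reg3 <- detect_song_regions(mk(r3))
  expect_identical(nrow(reg3), 2L)
  expect_true(all(diff(reg3$start) > 0))
  expect_true(all(reg3$end[-nrow(reg3)] <= reg3$start[-1]))
  expect_error(detect_song_regions(mk(r), threshold = 1.5))
})

test_that("region detection is invariant to amplitude scaling", {
  spec <- pulse_train_spec(c(0.5, 0.9), duration = 2, noise_sd = 2,
                           bed_regions = data.frame(start = 0.3, end = 1.2))
  sig <- synthesize_pulse_audio(spec, seed = 3)
  r1 <- detect_song_regions(compute_band_energy_ratio(sig))
  sig5 <- audio_signal(5 * sig$samples, sig$rate)
  r5 <- detect_song_regions(compute_band_energy_ratio(sig5))
  expect_equal(r1, r5)
})

test_that("wideband envelope is the nonnegative analytic magnitude sum", {
  z <- compute_wideband_envelope(audio_signal(numeric(1000), rate))
  expect_true(all(abs(z$values) < 1e-9))
  env <- compute_wideband_envelope(tone(1000, a = 1234))
  expect_true(all(env$values >= 0))
  # steady-state magnitude of a sinusoid equals its amplitude
  expect_equal(unname(range(env$values[4000:12000])), c(1234, 1234),
               tolerance = 1e-3)
  expect_error(compute_wideband_envelope(tone(1000), cutoffs = 500),
               "at least 2")
  expect_error(compute_wideband_envelope(tone(1000), cutoffs = c(500, 100)))
})

test_that("peak detection honours prominence and refractory rules", {
  spec <- pulse_train_spec(c(0.5, 0.9, 1.4, 1.8), duration = 3, noise_sd = 3)
  env <- compute_wideband_envelope(synthesize_pulse_audio(spec, seed = 2))
  pk <- detect_peaks(env, min_prominence = 100)
  expect_identical(nrow(pk), 4L)
  expect_true(all(abs(pk$time - pulse_apex_times(spec)) <= 0.010))
  expect_true(all(diff(pk$time) >= 0.150))
  # two equal bumps 100 ms apart: refractory keeps only the first
  spec2 <- pulse_train_spec(c(0.5, 0.6), duration = 2, pulse_width = 0.04)
  pk2 <- detect_peaks(compute_wideband_envelope(
    synthesize_pulse_audio(spec2)), min_prominence = 100)
  expect_identical(nrow(pk2), 1L)
  expect_equal(pk2$time, pulse_apex_times(spec2)[1], tolerance = 0.010)
  # insufficient prominence: no peaks
  spec3 <- pulse_train_spec(0.5, duration = 2, amplitude = 50)
  expect_identical(nrow(detect_peaks(compute_wideband_envelope(
    synthesize_pulse_audio(spec3)), min_prominence = 1e6)), 0L)
})

test_that("raising min_prominence never increases the peak count", {
  spec <- pulse_train_spec(c(0.4, 0.9, 1.5), duration = 2,
                           amplitude = c(500, 1500, 3000), noise_sd = 5)
  env <- compute_wideband_envelope(synthesize_pulse_audio(spec, seed = 9))
  counts <- vapply(c(10, 400, 1000, 2500, 1e5),
                   function(p) nrow(detect_peaks(env, min_prominence = p)),
                   0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("MFCC vectors are 13-dim, deterministic, and scale only in c0", {
  spec <- pulse_train_spec(c(0.5, 1.1), duration = 2, noise_sd = 2)
  sig <- synthesize_pulse_audio(spec, seed = 4)
  pk <- pulse_apex_times(spec)
  m <- extract_mfcc(sig, pk)
  expect_identical(dim(m), c(2L, 13L))
  expect_true(all(is.finite(m)))
  expect_identical(extract_mfcc(sig, pk), m)
  m3 <- extract_mfcc(audio_signal(3 * sig$samples, rate), pk)
  d <- abs(m3 - m)
  expect_lt(max(d[, -1]), 1e-8)       # only the energy coefficient moves
  expect_true(all(d[, 1] > 1))
  # window overrunning the end is zero-padded, not an error
  tail_peak <- length(sig$samples) / rate - 0.01
  expect_true(all(is.finite(extract_mfcc(sig, tail_peak))))
  expect_error(extract_mfcc(sig, 99), "outside")
})

test_that("strings group peaks by region and log discards", {
  regions <- data.frame(start = c(1, 3), end = c(2, 4))
  peaks <- data.frame(time = c(1.2, 1.5, 1.8, 2.5, 3.1, 3.9),
                      envelope_value = 1:6)
  vecs <- matrix(seq_len(6 * 13), 6, 13)
  bs <- build_strings(regions, peaks, vecs)
  expect_length(bs$strings, 2L)
  expect_identical(vapply(bs$strings, function(s) nrow(s$vectors), 0L),
                   c(3L, 2L))
  expect_identical(bs$n_discarded, 1L) # the peak at 2.5 s
  expect_identical(bs$strings[[1]]$vectors, vecs[1:3, ])
  # every vector's peak lies inside its region
  for (s in bs$strings)
    expect_true(all(s$peaks_s >= s$region["start"] &
                      s$peaks_s < s$region["end"]))
  expect_error(build_strings(regions, peaks, vecs[1:3, ]), "align")
})

test_that("feature strings survive a JSONL round trip", {
  beds <- data.frame(start = 0.3, end = 1.2)
  spec <- pulse_train_spec(c(0.5, 0.9), duration = 2, bed_regions = beds,
                           noise_sd = 3)
  res <- preprocess_audio(synthesize_pulse_audio(spec, seed = 5),
                          frontend_config(peak_min_prominence = 500))
  expect_identical(res$summary$n_strings, 1L)
  path <- withr::local_tempfile()
  write_strings_jsonl(res$strings, path)
  back <- read_strings_jsonl(path)
  expect_length(back, length(res$strings))
  expect_equal(back[[1]]$vectors, res$strings[[1]]$vectors,
               tolerance = 1e-12)
  expect_equal(back[[1]]$peaks_s, res$strings[[1]]$peaks_s)
})

test_that("WAV files round-trip through the PCM16 writer", {
  spec <- pulse_train_spec(0.3, duration = 1, noise_sd = 10)
  sig <- synthesize_pulse_audio(spec, seed = 6)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(sig, path)
  back <- read_wav(path)
  expect_equal(back$rate, rate)
  expect_lte(max(abs(back$samples - round(sig$samples))), 1)
  expect_error(read_wav(path, channel = 2), "channel")
})
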