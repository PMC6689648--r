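# Acoustic front end: song-region detection by band-energy ratio, wideband
# Hilbert envelope, syllable-like peak detection and per-peak MFCC strings.

#' Front-end configuration defaults
#'
#' All tunables of the preprocessing chain in one list: DFT framing (20 ms
#' windows, 10 ms hop), the 500-1500 Hz song band within the 0-8000 Hz total
#' band, the r > 0.6 region criterion with a 500 ms minimum duration, the
#' 80...7999 Hz six-band filter bank for the wideband envelope, the 300 ms /
#' 10 ms peak search with prominence >= 1.0 (waveform sample units) and a
#' 150 ms refractory interval, and 13 MFCCs over a 100 ms window per peak.
#'
#' @param ... named overrides of any default.
#' @return a named list of front-end parameters.
#' @export
frontend_config <- function(...) {
  cfg <- list(
    dft_window = 0.020, dft_hop = 0.010,
    song_band = c(500, 1500), total_band = c(0, 8000),
    region_threshold = 0.6, region_min_duration = 0.500,
    envelope_cutoffs = c(80, 260, 600, 1240, 2420, 4650, 7999),
    peak_search_window = 0.300, peak_hop = 0.010,
    peak_min_prominence = 1.0, peak_refractory = 0.150,
    mfcc_window = 0.100, n_mfcc = 13L, n_mels = 26L,
    mfcc_fmin = 0, mfcc_fmax = 8000, log_floor = 1e-10)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown front-end option(s): ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}

frame_starts <- function(n, rate, window, hop) {
  wlen <- round(window * rate); step <- round(hop * rate)
  if (n < wlen) return(integer(0))
  seq(1L, n - wlen + 1L, by = step)
}

#' Per-frame ratio of song-band to total-band energy
#'
#' Frames the signal (Hann taper), computes the DFT power spectrum, and
#' returns per frame the ratio r of summed power inside the song band to
#' summed power inside the total band. Zero-energy frames give r = 0.
#'
#' @param signal an [audio_signal()].
#' @param window,hop frame length and hop in seconds (window > hop > 0).
#' @param song_band,total_band numeric `c(lo, hi)` in Hz;
#'   `song_band` must lie within `total_band`, which must lie within
#'   `[0, rate/2]`.
#' @return a `frame_ratio_series`: list with `frame_times` (frame start
#'   times, seconds), `r`, `window`, `hop`.
#' @export
compute_band_energy_ratio <- function(signal, window = 0.020, hop = 0.010,
                                      song_band = c(500, 1500),
                                      total_band = c(0, 8000)) {
  if (!(window > hop && hop > 0)) stop("need window > hop > 0")
  nyq <- signal$rate / 2
  if (song_band[1] < total_band[1] || song_band[2] > total_band[2] ||
      total_band[1] < 0 || total_band[2] > nyq ||
      song_band[1] >= song_band[2] || total_band[1] >= total_band[2])
    stop("invalid bands: need song_band within total_band within [0, rate/2]")
  x <- signal$samples; rate <- signal$rate
  starts <- frame_starts(length(x), rate, window, hop)
  wlen <- round(window * rate)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(wlen) / (wlen + 1)) # Hann
  freqs <- (seq_len(wlen) - 1) * rate / wlen
  keep <- freqs <= nyq
  in_band <- function(b) keep & freqs >= b[1] & freqs <= b[2]
  sel_song <- in_band(song_band); sel_tot <- in_band(total_band)
  r <- vapply(starts, function(s) {
    p <- Mod(stats::fft(x[s:(s + wlen - 1)] * taper))^2
    tot <- sum(p[sel_tot])
    if (tot <= 0) 0 else sum(p[sel_song]) / tot
  }, 0)
  structure(list(frame_times = (starts - 1) / rate, r = r,
                 window = window, hop = hop),
            class = "frame_ratio_series")
}

#' Detect song regions as long runs of high band-energy ratio
#'
#' Maximal runs of consecutive frames with r > threshold become regions
#' (half-open `[start, end)`, from the first qualifying frame's start to the
#' last qualifying frame's end); runs spanning less than `min_duration`
#' seconds are dropped.
#'
#' @param ratios a `frame_ratio_series` from [compute_band_energy_ratio()].
#' @param threshold ratio threshold in (0, 1); frames must exceed it.
#' @param min_duration minimum region span in seconds.
#' @return data.frame with columns `start`, `end` (seconds), possibly empty.
#' @export
detect_song_regions <- function(ratios, threshold = 0.6,
                                min_duration = 0.500) {
  if (!(threshold > 0 && threshold < 1)) stop("`threshold` must be in (0, 1)")
  ok <- ratios$r > threshold
  out <- data.frame(start = numeric(0), end = numeric(0))
  if (!any(ok)) return(out)
  d <- diff(c(0L, as.integer(ok), 0L))
  runs <- cbind(which(d == 1L), which(d == -1L) - 1L)
  for (i in seq_len(nrow(runs))) {
    s <- ratios$frame_times[runs[i, 1]]
    e <- ratios$frame_times[runs[i, 2]] + ratios$window
    if (e - s >= min_duration)
      out <- rbind(out, data.frame(start = s, end = e))
  }
  out
}

# analytic (Hilbert) signal restricted to one frequency band, via FFT:
# retain positive frequencies inside [lo, hi] doubled, zero elsewhere
analytic_bandpass <- function(x, rate, lo, hi) {
  n <- length(x)
  X <- stats::fft(x)
  freqs <- (seq_len(n) - 1) * rate / n
  keep <- freqs >= lo & freqs <= hi & freqs > 0 & freqs < rate / 2
  Y <- complex(n)
  Y[keep] <- 2 * X[keep]
  dc <- freqs == 0 & lo <= 0
  Y[dc] <- X[dc]
  stats::fft(Y, inverse = TRUE) / n
}

#' Wideband envelope as the summed magnitude of band-limited analytic signals
#'
#' The signal is split into adjacent frequency bands by consecutive cutoff
#' pairs; each band's analytic signal magnitude (its Hilbert narrowband
#' envelope) is computed and the magnitudes are summed. Bandpassing is done
#' spectrally (ideal zero-phase band selection in the FFT domain), which
#' preserves peak timing exactly.
#'
#' @param signal an [audio_signal()].
#' @param cutoffs increasing cutoff frequencies in Hz; `n` cutoffs define
#'   `n - 1` bands (default: the 80...7999 Hz six-band bank).
#' @return a `wideband_envelope`: list with `values` (>= 0, same length as
#'   the input) and `rate`.
#' @export
compute_wideband_envelope <- function(signal,
                                      cutoffs = c(80, 260, 600, 1240,
                                                  2420, 4650, 7999)) {
  if (length(cutoffs) < 2) stop("need at least 2 cutoff frequencies")
  if (any(diff(cutoffs) <= 0)) stop("cutoffs must be strictly increasing")
  if (cutoffs[1] <= 0 || cutoffs[length(cutoffs)] > signal$rate / 2)
    stop("cutoffs must lie within (0, rate/2]")
  env <- numeric(length(signal$samples))
  for (b in seq_len(length(cutoffs) - 1)) {
    env <- env + Mod(analytic_bandpass(signal$samples, signal$rate,
                                       cutoffs[b], cutoffs[b + 1]))
  }
  structure(list(values = env, rate = signal$rate),
            class = "wideband_envelope")
}

#' Detect syllable-like peaks on a wideband envelope
#'
#' Slides a search window along the envelope; each window's maximum is a
#' peak candidate (identical candidates from overlapping windows are
#' collapsed; ties inside a window break to the earliest sample). A
#' candidate is accepted iff its prominence -- the best, over the windows
#' that proposed it, of (candidate value - window minimum) -- reaches
#' `min_prominence`, and no previously *accepted* peak lies within the
#' preceding refractory interval.
#'
#' @param envelope a `wideband_envelope`.
#' @param search_window sliding window length in seconds.
#' @param hop window slide step in seconds.
#' @param min_prominence required prominence in envelope (waveform sample)
#'   units.
#' @param refractory minimum separation from the previous accepted peak, in
#'   seconds.
#' @return data.frame with columns `time` (seconds) and `envelope_value`,
#'   sorted by time.
#' @export
detect_peaks <- function(envelope, search_window = 0.300, hop = 0.010,
                         min_prominence = 1.0, refractory = 0.150) {
  if (!(search_window > hop && hop > 0)) stop("need search_window > hop > 0")
  if (refractory < 0) stop("`refractory` must be >= 0")
  v <- envelope$values; rate <- envelope$rate
  starts <- frame_starts(length(v), rate, search_window, hop)
  wlen <- round(search_window * rate)
  prom <- new.env(parent = emptyenv())
  for (s in starts) {
    win <- v[s:(s + wlen - 1)]
    im <- which.max(win)             # earliest sample on ties
    # an argmax on the window edge is a clipped rising/falling flank, not a
    # local peak of the envelope; it is proposed only by windows where it
    # lies in the interior
    if (im == 1L || im == wlen) next
    idx <- s + im - 1L
    p <- v[idx] - min(win)
    key <- as.character(idx)
    cur <- prom[[key]]
    if (is.null(cur) || p > cur) prom[[key]] <- p
  }
  cand <- sort(as.integer(ls(prom)))
  out <- data.frame(time = numeric(0), envelope_value = numeric(0))
  last <- -Inf
  for (idx in cand) {
    t <- (idx - 1) / rate
    if (prom[[as.character(idx)]] >= min_prominence && t - last >= refractory) {
      out <- rbind(out, data.frame(time = t, envelope_value = v[idx]))
      last <- t
    }
  }
  out
}

mel_of <- function(f) 2595 * log10(1 + f / 700)
mel_inv <- function(m) 700 * (10^(m / 2595) - 1)

# triangular mel filter bank: n_mels filters over [fmin, fmax], rows sum the
# power spectrum bins (bin frequencies `freqs`)
mel_filterbank <- function(freqs, n_mels, fmin, fmax) {
  pts <- mel_inv(seq(mel_of(fmin), mel_of(fmax), length.out = n_mels + 2))
  fb <- matrix(0, n_mels, length(freqs))
  for (m in seq_len(n_mels)) {
    lo <- pts[m]; mid <- pts[m + 1]; hi <- pts[m + 2]
    up <- (freqs - lo) / (mid - lo)
    down <- (hi - freqs) / (hi - mid)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Extract MFCC vectors at peak times
#'
#' For each peak, takes the `window`-second audio segment starting at the
#' peak (zero-padded past the signal end), applies a Hann taper, and
#' computes `n_coeff` mel-frequency cepstral coefficients (c0..c12 by
#' default: 26 triangular mel filters over 0-8000 Hz, log power floored at
#' `log_floor`, orthonormal DCT-II). Amplitude scaling of the audio shifts
#' only c0.
#'
#' @param signal an [audio_signal()].
#' @param peak_times numeric vector of peak times in seconds (e.g. the
#'   `time` column of [detect_peaks()] output).
#' @param window analysis window length in seconds, starting at each peak.
#' @param n_coeff number of cepstral coefficients (default 13).
#' @param n_mels number of mel filters.
#' @param fmin,fmax mel filter bank frequency range in Hz (`fmax` defaults
#'   to the Nyquist frequency).
#' @param log_floor floor applied to filter energies before the log (guards
#'   silent windows).
#' @return numeric matrix, one row of `n_coeff` coefficients per peak.
#' @export
extract_mfcc <- function(signal, peak_times, window = 0.100, n_coeff = 13L,
                         n_mels = 26L, fmin = 0, fmax = NULL,
                         log_floor = 1e-10) {
  if (window <= 0) stop("`window` must be > 0")
  rate <- signal$rate
  fmax <- fmax %||% (rate / 2)
  wlen <- round(window * rate)
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(wlen) / (wlen + 1))
  nbin <- floor(wlen / 2) + 1
  freqs <- (seq_len(nbin) - 1) * rate / wlen
  fb <- mel_filterbank(freqs, n_mels, fmin, fmax)
  # orthonormal DCT-II over the n_mels log energies
  dct <- outer(0:(n_coeff - 1), 0:(n_mels - 1),
               function(i, j) cos(pi * (2 * j + 1) * i / (2 * n_mels)))
  dct <- dct * sqrt(2 / n_mels)
  dct[1, ] <- dct[1, ] / sqrt(2)
  out <- matrix(0, length(peak_times), n_coeff)
  n <- length(signal$samples)
  for (p in seq_along(peak_times)) {
    s0 <- round(peak_times[p] * rate) + 1L
    if (s0 < 1L || s0 > n) stop("peak time outside the signal")
    seg <- numeric(wlen)
    take <- min(wlen, n - s0 + 1L)
    seg[seq_len(take)] <- signal$samples[s0:(s0 + take - 1L)]
    pw <- Mod(stats::fft(seg * taper)[seq_len(nbin)])^2
    loge <- log(pmax(as.vector(fb %*% pw), log_floor))
    out[p, ] <- as.vector(dct %*% loge)
  }
  out
}

#' Group per-peak MFCC vectors into strings by song region
#'
#' Each region containing at least one peak yields one feature string with
#' that region's peak vectors in temporal order; peaks falling outside every
#' region (half-open `[start, end)` membership) are discarded and counted.
#'
#' @param regions data.frame from [detect_song_regions()].
#' @param peaks data.frame from [detect_peaks()] (aligned with `vectors`).
#' @param vectors matrix of MFCC vectors, one row per peak.
#' @return list with `strings` (list of `feature_string`: `string_id`,
#'   `region` = c(start, end), `peaks_s`, `vectors` matrix) and
#'   `n_discarded` (peaks outside every region).
#' @export
build_strings <- function(regions, peaks, vectors) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) != nrow(peaks))
    stop("`vectors` must align one-to-one with `peaks`")
  strings <- list(); discarded <- 0L
  for (g in seq_len(nrow(regions))) {
    inr <- which(peaks$time >= regions$start[g] & peaks$time < regions$end[g])
    if (!length(inr)) next
    inr <- inr[order(peaks$time[inr])]
    strings[[length(strings) + 1L]] <- structure(
      list(string_id = sprintf("region_%03d", g),
           region = c(start = regions$start[g], end = regions$end[g]),
           peaks_s = peaks$time[inr],
           vectors = vectors[inr, , drop = FALSE]),
      class = "feature_string")
  }
  assigned <- if (nrow(regions)) {
    vapply(peaks$time, function(t)
      any(t >= regions$start & t < regions$end), TRUE)
  } else rep(FALSE, nrow(peaks))
  list(strings = strings, n_discarded = sum(!assigned))
}

#' Run the full front-end chain on one audio signal
#'
#' band-energy ratio -> song regions -> wideband envelope -> peaks -> MFCCs
#' -> per-region feature strings.
#'
#' @param signal an [audio_signal()].
#' @param config a [frontend_config()].
#' @return list with `strings`, and `summary` (counts of regions, peaks,
#'   discarded peaks).
#' @export
preprocess_audio <- function(signal, config = frontend_config()) {
  ratios <- compute_band_energy_ratio(signal, config$dft_window,
                                      config$dft_hop, config$song_band,
                                      config$total_band)
  regions <- detect_song_regions(ratios, config$region_threshold,
                                 config$region_min_duration)
  env <- compute_wideband_envelope(signal, config$envelope_cutoffs)
  peaks <- detect_peaks(env, config$peak_search_window, config$peak_hop,
                        config$peak_min_prominence, config$peak_refractory)
  vecs <- extract_mfcc(signal, peaks$time, config$mfcc_window,
                       config$n_mfcc, config$n_mels, config$mfcc_fmin,
                       config$mfcc_fmax, config$log_floor)
  bs <- build_strings(regions, peaks, vecs)
  list(strings = bs$strings,
       summary = list(n_regions = nrow(regions), n_peaks = nrow(peaks),
                      n_strings = length(bs$strings),
                      n_discarded_peaks = bs$n_discarded))
}

#' Write feature strings as JSON Lines
#'
#' One JSON record per string: `string_id`, `region_start_s`,
#' `region_end_s`, `peaks_s`, `mfcc` (list of D-dim vectors).
#'
#' @param strings list of `feature_string` objects.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_strings_jsonl <- function(strings, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in strings) {
    rec <- list(string_id = s$string_id,
                region_start_s = unname(s$region["start"]),
                region_end_s = unname(s$region["end"]),
                peaks_s = s$peaks_s,
                mfcc = unname(apply(s$vectors, 1, as.numeric,
                                    simplify = FALSE)))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read feature strings from a JSON Lines file
#' @param path file written by [write_strings_jsonl()].
#' @return list of `feature_string` objects.
#' @export
read_strings_jsonl <- function(path) {
  lapply(readLines(path), function(line) {
    rec <- jsonlite::fromJSON(line, simplifyMatrix = FALSE)
    structure(list(string_id = rec$string_id,
                   region = c(start = rec$region_start_s,
                              end = rec$region_end_s),
                   peaks_s = as.numeric(unlist(rec$peaks_s)),
                   vectors = do.call(rbind, lapply(rec$mfcc, as.numeric))),
              class = "feature_string")
  })
}
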