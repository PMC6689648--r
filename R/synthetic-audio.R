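# Synthetic pulse-train audio for exercising the acoustic front end without
# field recordings.

#' Specify a synthetic pulse-train audio signal
#'
#' Band-limited carrier bursts ("pulses") at known times over an optional
#' noise floor, at the default 16 kHz sampling rate. The default
#' 1000 Hz carrier sits inside the 500-1500 Hz song band; amplitudes are on
#' the raw integer PCM scale the front end assumes.
#'
#' @param pulse_times pulse onset times in seconds.
#' @param duration total signal duration in seconds.
#' @param carrier carrier frequency in Hz.
#' @param pulse_width burst length in seconds.
#' @param amplitude peak carrier amplitude (sample units); recycled over
#'   pulses.
#' @param noise_sd standard deviation of the additive Gaussian noise floor.
#' @param rate sampling rate in samples/second.
#' @param bed_regions optional data.frame with `start`, `end` columns
#'   (seconds): intervals carrying a sustained low-amplitude in-band carrier
#'   so that the band-energy ratio stays high throughout, i.e. the planted
#'   song regions.
#' @param bed_amplitude amplitude of the sustained bed carrier.
#' @return a `pulse_train_spec` list.
#' @export
pulse_train_spec <- function(pulse_times, duration,
                             carrier = 1000, pulse_width = 0.08,
                             amplitude = 2000, noise_sd = 0,
                             rate = 16000, bed_regions = NULL,
                             bed_amplitude = 200) {
  if (carrier >= rate / 2) stop("carrier must be below the Nyquist frequency")
  if (length(pulse_times) &&
      (any(pulse_times < 0) || any(pulse_times + pulse_width > duration)))
    stop("pulses must lie within the signal")
  if (!is.null(bed_regions) &&
      (any(bed_regions$start < 0) || any(bed_regions$end > duration) ||
       any(bed_regions$end <= bed_regions$start)))
    stop("bed regions must be non-empty intervals within the signal")
  structure(list(pulse_times = pulse_times, duration = duration,
                 carrier = carrier, pulse_width = pulse_width,
                 amplitude = rep_len(amplitude, length(pulse_times)),
                 noise_sd = noise_sd, rate = rate,
                 bed_regions = bed_regions, bed_amplitude = bed_amplitude),
            class = "pulse_train_spec")
}

#' Synthesize audio from a pulse-train specification
#'
#' Each pulse is a Hann-shaped carrier burst, so the wideband envelope has a
#' single local maximum at the pulse centre. Reproducible given `seed`.
#'
#' @param spec a [pulse_train_spec()].
#' @param seed integer seed for the noise floor.
#' @return an [audio_signal()].
#' @export
synthesize_pulse_audio <- function(spec, seed = 1L) {
  n <- round(spec$duration * spec$rate)
  x <- if (spec$noise_sd > 0) {
    set.seed(seed)
    stats::rnorm(n, sd = spec$noise_sd)
  } else numeric(n)
  if (!is.null(spec$bed_regions)) {
    tall <- (seq_len(n) - 1) / spec$rate
    for (b in seq_len(nrow(spec$bed_regions))) {
      idx <- which(tall >= spec$bed_regions$start[b] &
                     tall < spec$bed_regions$end[b])
      x[idx] <- x[idx] +
        spec$bed_amplitude * sin(2 * pi * spec$carrier * tall[idx])
    }
  }
  wlen <- round(spec$pulse_width * spec$rate)
  shape <- 0.5 - 0.5 * cos(2 * pi * seq_len(wlen) / (wlen + 1)) # Hann bump
  tt <- seq_len(wlen) / spec$rate
  for (p in seq_along(spec$pulse_times)) {
    s0 <- round(spec$pulse_times[p] * spec$rate) + 1L
    idx <- s0:(s0 + wlen - 1L)
    x[idx] <- x[idx] +
      spec$amplitude[p] * shape * sin(2 * pi * spec$carrier * tt)
  }
  audio_signal(x, spec$rate)
}

#' Apex times of the pulses in a specification
#'
#' The envelope maximum of each Hann-shaped burst, used as ground truth when
#' checking peak detection timing.
#' @param spec a [pulse_train_spec()].
#' @return numeric vector of apex times in seconds.
#' @export
pulse_apex_times <- function(spec) spec$pulse_times + spec$pulse_width / 2
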